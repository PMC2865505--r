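#' @export
print.vbfit <- function(x, ...) {
  cat("Joint additive model of expression variability (variational Bayes)\n")
  cat(sprintf("  data: %d genes x %d individuals", nrow(x$Yc), ncol(x$Yc)))
  if (!is.null(x$snp_ids)) cat(sprintf(", %d SNPs", length(x$snp_ids)))
  cat("\n")
  cat(sprintf("  schedule: %s; K = %d hidden factors; %d sweep(s), %s\n",
              x$schedule, x$K, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  if (length(x$bound_trace))
    cat(sprintf("  variational bound: %.4f\n",
                x$bound_trace[length(x$bound_trace)]))
  invisible(x)
}

#' Summarise a fitted joint model
#'
#' @param object A [vbfit()] object.
#' @param variance_floor Passed to [active_factors()].
#' @param inclusion_cutoff Posterior inclusion probability above which a gene
#'   is counted as having a genetic association.
#' @param ... Unused.
#' @return A list of class `"summary.vbfit"`.
#' @export
summary.vbfit <- function(object, variance_floor = 1e-3,
                          inclusion_cutoff = 0.5, ...) {
  act <- if (!is.null(object$components$hidden))
    active_factors(object, variance_floor = variance_floor) else integer(0)
  n_assoc <- if (!is.null(object$components$genetic))
    sum(object$components$genetic$inclusion_prob > inclusion_cutoff) else NA_integer_
  out <- list(
    G = nrow(object$Yc), N = ncol(object$Yc),
    schedule = object$schedule, K = object$K,
    n_iter = object$n_iter, converged = object$converged,
    bound = if (length(object$bound_trace))
      object$bound_trace[length(object$bound_trace)] else NA_real_,
    active_factors = act,
    n_genetic_assoc = n_assoc,
    mean_noise_var = mean(object$noise$rate / object$noise$shape)
  )
  class(out) <- "summary.vbfit"
  out
}

#' @export
print.summary.vbfit <- function(x, ...) {
  cat(sprintf("vbfit: %d genes x %d individuals, schedule %s\n",
              x$G, x$N, x$schedule))
  cat(sprintf("  %d/%d hidden factors active; bound %.4f after %d sweep(s)%s\n",
              length(x$active_factors), x$K, x$bound, x$n_iter,
              if (x$converged) " (converged)" else ""))
  if (!is.na(x$n_genetic_assoc))
    cat(sprintf("  genes with posterior inclusion > 0.5: %d\n",
                x$n_genetic_assoc))
  cat(sprintf("  mean posterior noise variance: %.4f\n", x$mean_noise_var))
  invisible(x)
}

#' Extract posterior-mean coefficients from a fit
#'
#' @param object A [vbfit()] object.
#' @param component `"genetic"` (per-gene effect table), `"known"` (G x F
#'   weight matrix) or `"hidden"` (G x K loading matrix).
#' @param ... Unused.
#' @return A data.frame (genetic) or numeric matrix.
#' @export
coef.vbfit <- function(object, component = c("genetic", "known", "hidden"),
                       ...) {
  component <- match.arg(component)
  st <- object$components[[component]]
  if (is.null(st)) stop("component '", component, "' was not fitted")
  switch(component,
    genetic = genetic_effects(object),
    known = structure(st$weights_mean,
                      dimnames = list(object$gene_ids, rownames(t(st$H)))),
    hidden = structure(st$loadings_mean,
                       dimnames = list(object$gene_ids,
                                       paste0("factor", seq_len(st$K)))))
}

#' Confounder-corrected residuals of a fit
#'
#' @param object A [vbfit()] object.
#' @param remove Component contributions to subtract (default known + hidden;
#'   the genetic contribution is kept for downstream association testing).
#' @param ... Unused.
#' @return G x N numeric matrix (`NA` at missing entries).
#' @export
residuals.vbfit <- function(object, remove = c("known", "hidden"), ...) {
  remove <- remove[vapply(remove, function(nm)
    !is.null(object$components[[nm]]), logical(1))]
  corrected_expression(object, remove = remove)$values
}

#' @export
fitted.vbfit <- function(object, ...) {
  out <- matrix(0, nrow(object$Yc), ncol(object$Yc))
  for (st in object$components) if (!is.null(st)) out <- out + st$C
  out + object$gene_means
}

#' Factor activations of a fit
#'
#' Posterior-mean hidden factor activations (individuals x factors), e.g. for
#' correlating inferred factors with known sample properties.
#'
#' @param fit A [vbfit()] object.
#' @return N x K numeric matrix.
#' @export
factor_activations <- function(fit) {
  st <- fit$components$hidden
  if (is.null(st)) stop("no hidden component in this fit")
  structure(st$activations_mean,
            dimnames = list(fit$individual_ids,
                            paste0("factor", seq_len(st$K))))
}

#' Plot the convergence trace and factor relevance of a fit
#'
#' Left panel: variational bound per sweep. Right panel: variance explained
#' by each hidden factor's posterior-mean contribution.
#'
#' @param x A [vbfit()] object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.vbfit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$bound_trace), x$bound_trace, type = "b",
                 xlab = "sweep", ylab = "variational bound", ...)
  st <- x$components$hidden
  if (!is.null(st) && st$K > 0) {
    ev <- vapply(seq_len(st$K), function(k)
      mean(tcrossprod(st$loadings_mean[, k], st$activations_mean[, k])^2),
      numeric(1))
    graphics::barplot(sort(ev, decreasing = TRUE),
                      xlab = "hidden factor (sorted)",
                      ylab = "mean squared contribution")
  }
  invisible(x)
}
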