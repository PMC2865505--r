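#' Control parameters for the variational fit
#'
#' @param ard_shape,ard_rate Gamma prior on the ARD precisions of known and
#'   hidden factor weights (broad default 1e-3 / 1e-3).
#' @param noise_shape,noise_rate Gamma prior on the per-gene noise precisions.
#' @param prior_inclusion Prior probability in (0,1) that a gene has a SNP
#'   association; plays the role a significance threshold plays in classical
#'   association mapping.
#' @param slab_var Prior variance of the genetic effect per 1-sd of genotype.
#' @param max_iter Maximum number of update sweeps.
#' @param tol Relative bound-change convergence threshold.
#' @param center_genes Subtract each gene's observed mean before modelling
#'   (default). When off, an intercept covariate is added instead.
#' @param reselect_snp Re-select each gene's best SNP every sweep (default);
#'   when off the selection is frozen after the first genetic update.
#' @param init `"ml"` (deterministic maximum-likelihood-style initialisation)
#'   or `"random"` (activations sampled from their prior).
#' @param seed Integer seed used for any randomised initialisation.
#' @return A named list of class `"vb_control"`.
#' @export
vb_control <- function(ard_shape = 1e-3, ard_rate = 1e-3,
                       noise_shape = 1e-3, noise_rate = 1e-3,
                       prior_inclusion = 0.01, slab_var = 1,
                       max_iter = 1000, tol = 1e-5,
                       center_genes = TRUE, reselect_snp = TRUE,
                       init = c("ml", "random"), seed = 1L) {
  stopifnot(ard_shape > 0, ard_rate > 0, noise_shape > 0, noise_rate > 0,
            prior_inclusion > 0, prior_inclusion < 1, slab_var > 0,
            max_iter >= 1, tol > 0)
  structure(list(ard_shape = ard_shape, ard_rate = ard_rate,
                 noise_shape = noise_shape, noise_rate = noise_rate,
                 prior_inclusion = prior_inclusion, slab_var = slab_var,
                 max_iter = max_iter, tol = tol, center_genes = center_genes,
                 reselect_snp = reselect_snp, init = match.arg(init),
                 seed = as.integer(seed)),
            class = "vb_control")
}

#' Fit the joint additive model of expression variability
#'
#' Models the genes x individuals expression matrix as a sum of additive
#' contributions — a per-gene spike-and-slab single-SNP genetic effect, a
#' Bayesian regression on known covariates, and a factor-analysis model of
#' hidden confounders, each with automatic relevance determination — plus
#' per-gene Gaussian noise, and infers all posteriors by variational
#' coordinate ascent.
#'
#' Two schedules are available. `"joint"` iterates sweeps over
#' genetic, known, hidden and noise updates until the variational bound
#' converges, so hidden factors are learned in the presence of the genetic
#' model and widespread genetic signal (trans hotspots) is retained by the
#' genetic component. `"two-stage"` first fits known and hidden factors to
#' convergence with no genetic component, then runs a single genetic pass on
#' the factor residuals; it is cheaper and equivalent when the genetic signal
#' is approximately orthogonal to the factors.
#'
#' @param expr An [expression_matrix()] or plain G x N matrix.
#' @param geno Optional [genotype_matrix()] or S x N matrix.
#' @param covs Optional [covariate_matrix()] or F x N matrix.
#' @param K Maximum number of hidden factors (ARD switches surplus ones off).
#' @param schedule `"joint"` or `"two-stage"`.
#' @param control A [vb_control()] list.
#' @return An object of class `"vbfit"` with components states, noise state,
#'   the per-sweep variational bound trace, and the data (see
#'   [residual_for()], [corrected_expression()], [active_factors()],
#'   [genetic_effects()]).
#' @examples
#' sim <- simulate_eqtl_study(sim_config(G = 60, N = 30, S = 20, seed = 1))
#' fit <- vbfit(sim$expr, sim$geno, sim$covs, K = 5,
#'              control = vb_control(max_iter = 20))
#' fit
#' @export
vbfit <- function(expr, geno = NULL, covs = NULL, K = 10,
                  schedule = c("joint", "two-stage"),
                  control = vb_control()) {
  schedule <- match.arg(schedule)
  Y <- if (inherits(expr, "expression_matrix")) expr
       else expression_matrix(as.matrix(expr))
  Yv <- Y$values
  M <- Y$mask * 1
  G <- nrow(Yv); N <- ncol(Yv)
  if (!is.null(geno)) {
    gv <- .geno_values(geno)
    if (ncol(gv) != N) stop("genotype and expression individuals not aligned ",
                            "(use align_individuals())")
  }
  if (!is.null(covs)) {
    cv <- .cov_values(covs)
    if (ncol(cv) != N) stop("covariates and expression individuals not aligned")
  }
  if (identical(control$init, "random")) set.seed(control$seed)

  gene_means <- rep(0, G)
  Hv <- if (!is.null(covs)) .cov_values(covs) else NULL
  if (control$center_genes) {
    gene_means <- rowSums(Yv * M, na.rm = TRUE) / pmax(rowSums(M), 1)
    Yc <- Yv - gene_means
  } else {
    Yc <- Yv
    Hv <- rbind(intercept = rep(1, N), Hv)
  }
  Yc[M == 0] <- NA_real_

  fit <- structure(list(
    Yc = Yc, Y = Yv, mask = M, gene_means = gene_means,
    gene_ids = Y$gene_ids, individual_ids = Y$individual_ids,
    snp_ids = if (!is.null(geno) && inherits(geno, "genotype_matrix"))
      geno$snp_ids else if (!is.null(geno)) paste0("snp", seq_len(nrow(gv))),
    K = as.integer(K), schedule = schedule, control = control,
    components = list(genetic = NULL, known = NULL, hidden = NULL),
    noise = NULL, bound_trace = numeric(0), converged = FALSE, n_iter = 0L
  ), class = "vbfit")

  # --- initialisation (maximum-likelihood style) ---
  if (!is.null(Hv) && nrow(Hv) > 0)
    fit$components$known <- init_known_state(Yc, Hv, control, M)
  Rres <- Yc
  if (!is.null(fit$components$known)) Rres <- Yc - fit$components$known$C
  if (K > 0)
    fit$components$hidden <- init_hidden_state(Rres, K, control, M)
  if (!is.null(fit$components$hidden)) fit$K <- fit$components$hidden$K
  rv <- rowSums((ifelse(M == 1, Rres, 0))^2) / pmax(rowSums(M) - 1, 1)
  rv[rv <= 0 | !is.finite(rv)] <- 1
  nobs <- rowSums(M)
  fit$noise <- list(shape = control$noise_shape + nobs / 2,
                    rate = (control$noise_shape + nobs / 2) * rv)
  if (!is.null(geno) && schedule == "joint")
    fit$components$genetic <- .init_genetic_state(G, N, nrow(gv))

  run_sweeps <- function(fit, use_genetic) {
    prev <- if (length(fit$bound_trace)) fit$bound_trace[length(fit$bound_trace)]
            else -Inf
    for (it in seq_len(fit$control$max_iter)) {
      if (use_genetic)
        fit$components$genetic <- update_genetic(
          fit$components$genetic, residual_for(fit, "genetic"), geno,
          fit$noise, fit$control, fit$mask)
      if (!is.null(fit$components$known))
        fit$components$known <- update_known(
          fit$components$known, residual_for(fit, "known"),
          fit$noise, fit$control, fit$mask)
      if (!is.null(fit$components$hidden))
        fit$components$hidden <- update_hidden(
          fit$components$hidden, residual_for(fit, "hidden"),
          fit$noise, fit$control, fit$mask)
      ns <- update_noise(fit)
      fit$noise <- list(shape = ns$shape, rate = ns$rate)
      b <- .vb_bound(fit)
      fit$bound_trace <- c(fit$bound_trace, b)
      fit$n_iter <- fit$n_iter + 1L
      if (is.finite(prev) && abs(b - prev) < fit$control$tol * abs(b)) {
        fit$converged <- TRUE
        break
      }
      prev <- b
    }
    fit
  }

  if (schedule == "joint") {
    fit <- run_sweeps(fit, use_genetic = !is.null(geno))
  } else {
    fit <- run_sweeps(fit, use_genetic = FALSE)
    if (!is.null(geno)) {
      fit$components$genetic <- update_genetic(
        NULL, residual_for_null_genetic(fit), geno, fit$noise,
        fit$control, fit$mask)
      ns <- update_noise(fit)
      fit$noise <- list(shape = ns$shape, rate = ns$rate)
      fit$bound_trace <- c(fit$bound_trace, .vb_bound(fit))
    }
  }
  fit
}

# residual available to a genetic component not yet part of fit$components
residual_for_null_genetic <- function(fit) {
  R <- fit$Yc
  for (st in fit$components) if (!is.null(st)) R <- R - st$C
  R
}

#' Residual dataset seen by one component
#'
#' The observed (centred) expression minus the posterior-mean contributions of
#' every component other than the active one. Missing entries propagate as
#' `NA`.
#'
#' @param fit A [vbfit()] object.
#' @param component One of `"genetic"`, `"known"`, `"hidden"`, or `"noise"`
#'   (for `"noise"` all contributions are subtracted).
#' @return G x N numeric matrix.
#' @export
residual_for <- function(fit, component) {
  comps <- names(fit$components)
  if (!component %in% c(comps, "noise"))
    stop("unknown component label: '", component, "'")
  R <- fit$Yc
  for (nm in comps) {
    st <- fit$components[[nm]]
    if (!is.null(st) && nm != component) R <- R - st$C
  }
  R
}

#' Confounder-corrected expression
#'
#' Subtracts the posterior-mean contributions of the listed components from
#' the observed expression. By default the known and hidden factor
#' contributions are removed while the genetic contribution is kept, which is
#' the input expected by downstream association testing.
#'
#' @param fit A [vbfit()] object.
#' @param remove Character vector of component labels to remove (subset of
#'   the fitted components); `character(0)` returns the data unchanged.
#' @return An [expression_matrix()] of corrected values.
#' @export
corrected_expression <- function(fit, remove = c("known", "hidden")) {
  out <- fit$Y
  for (nm in remove) {
    if (!nm %in% names(fit$components))
      stop("unknown component label: '", nm, "'")
    st <- fit$components[[nm]]
    if (is.null(st))
      stop("component '", nm, "' was not fitted")
    out <- out - st$C
  }
  out[fit$mask == 0] <- NA_real_
  expression_matrix(out, gene_ids = fit$gene_ids,
                    individual_ids = fit$individual_ids,
                    mask = fit$mask == 1)
}

# full variational lower bound (constant terms included consistently;
# only differences are meaningful)
.vb_bound <- function(fit) {
  control <- fit$control
  comps <- Filter(Negate(is.null), fit$components)
  sse <- expected_residual_ss(fit$Yc, comps, fit$mask)
  nobs <- rowSums(fit$mask)
  a <- fit$noise$shape; b <- fit$noise$rate
  Elog <- digamma(a) - log(b)
  Etau <- a / b
  lik <- sum(nobs / 2 * (Elog - log(2 * pi)) - Etau * sse / 2)
  bound <- lik + sum(.gamma_bound(control$noise_shape, control$noise_rate, a, b))
  if (!is.null(fit$components$hidden))
    bound <- bound + .bound_hidden(fit$components$hidden, control)
  if (!is.null(fit$components$known))
    bound <- bound + .bound_known(fit$components$known, control)
  if (!is.null(fit$components$genetic))
    bound <- bound + .bound_genetic(fit$components$genetic, control)
  bound
}

#' Variational lower bound of a fit
#'
#' Recomputes the evidence lower bound (expected log-joint minus the entropy
#' of the factorised posterior) from the current state. Each coordinate
#' update weakly increases this quantity, which the fit uses as its
#' convergence monitor.
#'
#' @param fit A [vbfit()] object.
#' @return A finite scalar.
#' @export
variational_bound <- function(fit) .vb_bound(fit)
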