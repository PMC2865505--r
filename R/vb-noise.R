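# Per-gene noise precision model: tau_g ~ Gamma(noise_shape, noise_rate)
# a priori, with the conjugate posterior driven by the expected residual sum
# of squares under the current component posteriors.

#' Expected residual sum of squares per gene
#'
#' Computes `E[sum_n (y_gn - sum_m c_gn^(m))^2]` under the factorised
#' posterior: the squared mean residual plus the summed contribution
#' variances, restricted to observed entries. Used by the noise update and by
#' the variational bound.
#'
#' @param Y Expression matrix (values G x N; `NA` = missing) or
#'   [expression_matrix()].
#' @param contributions List of contribution states, each with elements
#'   `mean` (or `C`) and `var` (or `V`), all G x N.
#' @param mask Optional 0/1 observation mask.
#' @return Numeric vector of length G.
#' @export
expected_residual_ss <- function(Y, contributions, mask = NULL) {
  Yv <- .expr_values(Y)
  M <- .expr_mask(Y, mask)
  Ctot <- matrix(0, nrow(Yv), ncol(Yv))
  Vtot <- matrix(0, nrow(Yv), ncol(Yv))
  for (co in contributions) {
    Ctot <- Ctot + if (!is.null(co$mean)) co$mean else co$C
    Vtot <- Vtot + if (!is.null(co$var)) co$var else co$V
  }
  Y0 <- Yv
  Y0[M == 0] <- 0
  rowSums(((Y0 - Ctot)^2 + Vtot) * M)
}

.update_noise_state <- function(sse, nobs, control) {
  list(shape = control$noise_shape + nobs / 2,
       rate = control$noise_rate + sse / 2)
}

#' Update the per-gene noise precisions of a fit
#'
#' Conjugate gamma update: posterior shape is the prior shape plus half the
#' number of observed entries for the gene; posterior rate is the prior rate
#' plus half the expected residual sum of squares, the expectation taken over
#' all component posteriors (first and second moments).
#'
#' @param fit A fitted [vbfit()] object.
#' @return Noise state: `list(shape, rate, expected_precision)`, each of
#'   length G.
#' @export
update_noise <- function(fit) {
  comps <- Filter(Negate(is.null), fit$components)
  sse <- expected_residual_ss(fit$Yc, comps, fit$mask)
  nobs <- rowSums(fit$mask)
  ns <- .update_noise_state(sse, nobs, fit$control)
  ns$expected_precision <- ns$shape / ns$rate
  ns
}
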