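#' Initialise the known covariate regression state
#'
#' Weights start at their per-gene ordinary least squares solution (a
#' maximum-likelihood initialisation) with zero posterior covariance, and the
#' per-covariate ARD precisions at their prior mean.
#'
#' @param R Residual matrix (G x N) the component will model.
#' @param covs Covariates: a [covariate_matrix()] or plain F x N matrix.
#' @param control A [vb_control()] list.
#' @param mask Optional 0/1 observation mask.
#' @return A known factor state: list with `F_cov`, weight moments
#'   (`weights_mean` G x F, `weights_Evv`, `weights_diag2`, `weights_logdet`),
#'   ARD gamma posteriors (`ard_shape`, `ard_rate`) and contribution moments
#'   `C`, `V`.
#' @export
init_known_state <- function(R, covs, control = vb_control(), mask = NULL) {
  R <- .expr_values(R)
  M <- .expr_mask(R, mask)
  H <- t(.cov_values(covs))                      # N x F
  G <- nrow(R); Fk <- ncol(H)
  R0 <- R
  R0[M == 0] <- 0
  if (all(M == 1)) {
    HtH <- crossprod(H)
    Vm <- t(solve(HtH + diag(1e-10, Fk), t(R0 %*% H)))
  } else {
    Vm <- matrix(0, G, Fk)
    for (g in seq_len(G)) {
      obs <- M[g, ] == 1
      Hg <- H[obs, , drop = FALSE]
      Vm[g, ] <- drop(solve(crossprod(Hg) + diag(1e-10, Fk),
                            crossprod(Hg, R[g, obs])))
    }
  }
  state <- list(
    F_cov = Fk,
    H = H,
    HEvv = .vec_outer(H),
    weights_mean = Vm,
    weights_Evv = .vec_outer(Vm),
    weights_diag2 = Vm^2,
    weights_logdet = rep(0, G),
    ard_shape = rep(control$ard_shape, Fk),
    ard_rate = rep(control$ard_rate, Fk),
    C = tcrossprod(Vm, H),
    V = matrix(0, G, ncol(R))
  )
  class(state) <- "known_factor_state"
  state
}

#' One variational update of the known covariate model
#'
#' Bayesian linear regression of each gene on the observed covariates with a
#' per-covariate ARD prior: the per-gene weight posterior has precision
#' `diag(E[ard]) + E[tau_g] * H^T H` (sums restricted to observed entries),
#' followed by the per-covariate ARD gamma update (shape gains G/2) and a
#' refresh of the contribution moments. A constant-zero or duplicated
#' covariate is handled by the ARD prior rather than an error.
#'
#' @param state State from [init_known_state()] or a previous call.
#' @param R Residual matrix (G x N) for this component.
#' @param noise Noise state `list(shape, rate)` or expected precision vector.
#' @param control A [vb_control()] list.
#' @param mask Optional 0/1 observation mask.
#' @return The updated known factor state.
#' @export
update_known <- function(state, R, noise, control = vb_control(), mask = NULL) {
  if (state$F_cov == 0L) return(state)
  R <- .expr_values(R)
  M <- .expr_mask(R, mask)
  complete <- all(M == 1)
  R0 <- R
  R0[M == 0] <- 0
  Etau <- if (is.list(noise)) .Etau(noise) else noise
  Ealpha <- state$ard_shape / state$ard_rate
  G <- nrow(R0)

  w <- .update_loadings(R0, M, state$H, state$HEvv, Etau, Ealpha, complete)
  state$weights_mean <- w$mean
  state$weights_Evv <- w$Evv
  state$weights_diag2 <- w$diag2
  state$weights_logdet <- w$logdet

  state$ard_shape <- rep(control$ard_shape + G / 2, state$F_cov)
  state$ard_rate <- control$ard_rate + colSums(w$diag2) / 2

  cc <- .contribution(w$mean, w$Evv, state$H, state$HEvv)
  state$C <- cc$mean
  state$V <- cc$var
  state
}

.bound_known <- function(state, control) {
  if (state$F_cov == 0L) return(0)
  G <- nrow(state$weights_mean)
  Fk <- state$F_cov
  Ealpha <- state$ard_shape / state$ard_rate
  Elog_alpha <- digamma(state$ard_shape) - log(state$ard_rate)
  Sww <- colSums(state$weights_diag2)
  lpV <- sum(G / 2 * (Elog_alpha - log(2 * pi)) - Ealpha * Sww / 2)
  hV <- sum(Fk * log(2 * pi * exp(1)) / 2 + state$weights_logdet / 2)
  ard <- sum(.gamma_bound(control$ard_shape, control$ard_rate,
                          state$ard_shape, state$ard_rate))
  lpV + hV + ard
}
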