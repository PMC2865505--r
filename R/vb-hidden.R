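#' Initialise the hidden factor state
#'
#' Activations start at the top-`K` principal component scores of the residual
#' (scaled to unit variance, matching their standard-normal prior), loadings at
#' zero, and the per-factor relevance (ARD) precisions at their prior mean, so
#' the initial hidden contribution is exactly zero. With `init = "random"` the
#' activations are instead drawn from their prior.
#'
#' @param R Residual matrix (G x N) the component will model.
#' @param K Maximum number of hidden factors (clamped to `min(G, N)`).
#' @param control A [vb_control()] list.
#' @param mask Optional 0/1 observation mask (missing entries of `R` may be
#'   `NA`).
#' @return A hidden factor state: list with `K`, loading moments
#'   (`loadings_mean` G x K, `loadings_Evv`, `loadings_diag2`,
#'   `loadings_logdet`), activation moments (`activations_mean` N x K,
#'   `activations_Evv`, `activations_diag2`, `activations_logdet`), ARD gamma
#'   posteriors (`ard_shape`, `ard_rate`, length K) and the contribution
#'   moments `C` (posterior mean, G x N) and `V` (posterior variance).
#' @export
init_hidden_state <- function(R, K, control = vb_control(), mask = NULL) {
  R <- .expr_values(R)
  M <- .expr_mask(R, mask)
  G <- nrow(R); N <- ncol(R)
  K <- as.integer(K)
  if (K > min(G, N)) {
    warning("K exceeds min(G, N); clamping to ", min(G, N))
    K <- min(G, N)
  }
  R0 <- R
  R0[M == 0] <- 0
  if (identical(control$init, "random")) {
    Xm <- matrix(stats::rnorm(N * K), N, K)
  } else {
    sv <- svd(R0, nu = 0, nv = K)
    Xm <- sv$v[, seq_len(K), drop = FALSE] * sqrt(N)
  }
  state <- list(
    K = K,
    loadings_mean = matrix(0, G, K),
    loadings_Evv = matrix(0, G, K * K),
    loadings_diag2 = matrix(0, G, K),
    loadings_logdet = rep(0, G),
    activations_mean = Xm,
    activations_Evv = .vec_outer(Xm),
    activations_diag2 = Xm^2,
    activations_logdet = rep(0, N),
    ard_shape = rep(control$ard_shape, K),
    ard_rate = rep(control$ard_rate, K),
    C = matrix(0, G, N),
    V = matrix(0, G, N)
  )
  class(state) <- "hidden_factor_state"
  state
}

#' One variational update of the hidden factor model
#'
#' Conjugate coordinate-ascent sweep of the Bayesian factor analysis model
#' with automatic relevance determination: loadings given activation moments,
#' then activations given loading moments, then the per-factor ARD gamma
#' posteriors (shape gains G/2, rate gains half the summed loading second
#' moments), and finally the contribution moments are refreshed.
#'
#' @param state A hidden factor state from [init_hidden_state()] or a
#'   previous call.
#' @param R Residual matrix (G x N) for this component (see [residual_for()]).
#' @param noise Noise state `list(shape, rate)` per gene, or a numeric vector
#'   of expected precisions.
#' @param control A [vb_control()] list (ARD prior shape/rate).
#' @param mask Optional 0/1 observation mask.
#' @return The updated hidden factor state.
#' @export
update_hidden <- function(state, R, noise, control = vb_control(), mask = NULL) {
  if (state$K == 0L) return(state)
  R <- .expr_values(R)
  M <- .expr_mask(R, mask)
  complete <- all(M == 1)
  R0 <- R
  R0[M == 0] <- 0
  Etau <- if (is.list(noise)) .Etau(noise) else noise
  Ealpha <- state$ard_shape / state$ard_rate
  G <- nrow(R0)

  w <- .update_loadings(R0, M, state$activations_mean, state$activations_Evv,
                        Etau, Ealpha, complete)
  state$loadings_mean <- w$mean
  state$loadings_Evv <- w$Evv
  state$loadings_diag2 <- w$diag2
  state$loadings_logdet <- w$logdet

  x <- .update_activations(R0, M, w$mean, w$Evv, Etau, complete)
  state$activations_mean <- x$mean
  state$activations_Evv <- x$Evv
  state$activations_diag2 <- x$diag2
  state$activations_logdet <- x$logdet

  state$ard_shape <- rep(control$ard_shape + G / 2, state$K)
  state$ard_rate <- control$ard_rate + colSums(w$diag2) / 2

  cc <- .contribution(w$mean, w$Evv, x$mean, x$Evv)
  state$C <- cc$mean
  state$V <- cc$var
  state
}

# bound terms owned by the hidden component (prior expectations + entropies)
.bound_hidden <- function(state, control) {
  if (state$K == 0L) return(0)
  G <- nrow(state$loadings_mean)
  N <- nrow(state$activations_mean)
  K <- state$K
  Ealpha <- state$ard_shape / state$ard_rate
  Elog_alpha <- digamma(state$ard_shape) - log(state$ard_rate)
  Sww <- colSums(state$loadings_diag2)
  lpW <- sum(G / 2 * (Elog_alpha - log(2 * pi)) - Ealpha * Sww / 2)
  hW <- sum(K * log(2 * pi * exp(1)) / 2 + state$loadings_logdet / 2)
  lpX <- -N * K / 2 * log(2 * pi) - sum(state$activations_diag2) / 2
  hX <- sum(K * log(2 * pi * exp(1)) / 2 + state$activations_logdet / 2)
  ard <- sum(.gamma_bound(control$ard_shape, control$ard_rate,
                          state$ard_shape, state$ard_rate))
  lpW + hW + lpX + hX + ard
}

#' Indices of factors carrying signal
#'
#' A factor is called active when the variance of its posterior-mean
#' contribution across the matrix exceeds `variance_floor` times the total
#' variance of the residual it was fit to. Unused factors are switched off by
#' the ARD prior, so their contribution variance collapses towards zero.
#'
#' @param state A hidden factor state, or a fitted [vbfit()] object (the
#'   residual is then taken from the fit).
#' @param R Residual matrix the state was fit to (ignored for `vbfit` input).
#' @param variance_floor Fraction of total residual variance below which a
#'   factor counts as switched off.
#' @return Integer vector of active factor indices, sorted by explained
#'   variance (descending).
#' @export
active_factors <- function(state, R = NULL, variance_floor = 1e-3) {
  if (inherits(state, "vbfit")) {
    fit <- state
    if (is.null(fit$components$hidden)) return(integer(0))
    R <- residual_for(fit, "hidden")
    state <- fit$components$hidden
  }
  if (is.null(R)) stop("R (the residual the state was fit to) is required")
  R <- .expr_values(R)
  total <- mean(R[!is.na(R)]^2)
  if (!is.finite(total) || total <= 0) return(integer(0))
  K <- state$K
  if (K == 0L) return(integer(0))
  ev <- vapply(seq_len(K), function(k) {
    ck <- tcrossprod(state$loadings_mean[, k], state$activations_mean[, k])
    mean(ck^2)
  }, numeric(1))
  idx <- which(ev > variance_floor * total)
  idx[order(ev[idx], decreasing = TRUE)]
}
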