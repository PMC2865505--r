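# Spike-and-slab genetic effect model with the single-best-SNP bottleneck:
# per gene, only the most relevant SNP carries a (possibly zero) effect, with
# a Bernoulli inclusion indicator whose prior probability controls model
# complexity.

# Standardise genotype rows for the VB update: missing (-1) mean-imputed,
# then centred and scaled to unit variance (denominator N). Monomorphic SNPs
# are flagged and excluded from selection.
.standardise_genotypes <- function(geno) {
  X <- .geno_values(geno)
  storage.mode(X) <- "double"
  X[X < 0] <- NA_real_
  mu <- rowMeans(X, na.rm = TRUE)
  idx <- which(is.na(X))
  if (length(idx)) X[idx] <- mu[(idx - 1) %% nrow(X) + 1]
  X <- X - mu
  s2 <- rowMeans(X^2)
  poly <- s2 > 0 & is.finite(s2)
  X[poly, ] <- X[poly, , drop = FALSE] / sqrt(s2[poly])
  list(X = X, poly = poly)
}

#' Select the most relevant SNP for one gene
#'
#' Returns the candidate SNP maximising the marginal likelihood of a linear
#' effect on the residual vector, which (with a common slab prior across
#' standardised SNPs) is the SNP with the largest absolute Pearson correlation.
#' Ties are broken by the lowest SNP index. Missing genotype/expression pairs
#' are dropped per candidate.
#'
#' @param r Residual expression vector for the gene (length N; may contain
#'   `NA`).
#' @param geno A [genotype_matrix()] or S x N matrix (missing coded -1).
#' @param candidates Integer indices of candidate SNPs (default all).
#' @return The selected SNP index, or `NA` if every candidate is monomorphic
#'   or has fewer than 3 complete pairs.
#' @export
select_best_snp <- function(r, geno, candidates = NULL) {
  X <- .geno_values(geno)
  storage.mode(X) <- "double"
  X[X < 0] <- NA_real_
  if (is.null(candidates)) candidates <- seq_len(nrow(X))
  best <- NA_integer_
  best_ac <- -Inf
  for (s in candidates) {
    ok <- !is.na(r) & !is.na(X[s, ])
    if (sum(ok) < 3L) next
    x <- X[s, ok]
    if (stats::var(x) == 0) next
    ac <- abs(stats::cor(r[ok], x))
    if (is.finite(ac) && ac > best_ac + 1e-12) {
      best_ac <- ac
      best <- s
    }
  }
  best
}

# null genetic state (no selected SNPs, zero contribution)
.init_genetic_state <- function(G, N, S) {
  structure(list(
    selected_snp = rep(NA_integer_, G),
    inclusion_prob = rep(0, G),
    weight_mean = rep(0, G),
    weight_var = rep(0, G),
    C = matrix(0, G, N),
    V = matrix(0, G, N),
    n_snps = S
  ), class = "genetic_state")
}

#' One variational update of the genetic effect model
#'
#' For each gene the best SNP is (re-)selected by marginal likelihood over
#' standardised genotypes, the Gaussian posterior of its effect weight is
#' computed conditional on inclusion, and the posterior inclusion probability
#' follows from the Bayes factor between the slab and the spike weighted by
#' the prior inclusion probability. The selected SNP carries a uniform prior
#' over the polymorphic candidates, so the inclusion odds are penalised by
#' the log candidate count — the Bayesian counterpart of a per-gene
#' multiple-testing correction. Contribution moments account for both
#' weight and inclusion uncertainty. Missing genotypes are mean-imputed for
#' this update (association *tests* instead drop incomplete pairs).
#'
#' @param state A genetic state from a previous call, or `NULL` to start from
#'   the null state.
#' @param R Residual matrix (G x N) for the genetic component.
#' @param geno A [genotype_matrix()] or S x N matrix.
#' @param noise Noise state `list(shape, rate)` or expected precision vector.
#' @param control A [vb_control()] list (`prior_inclusion`, `slab_var`,
#'   `reselect_snp`).
#' @param mask Optional 0/1 observation mask.
#' @return Updated genetic state: per gene `selected_snp`, `inclusion_prob`,
#'   `weight_mean`, `weight_var` (moments of the effect per 1-sd genotype,
#'   conditional on inclusion) and contribution moments `C`, `V`.
#' @export
update_genetic <- function(state, R, geno, noise, control = vb_control(),
                           mask = NULL) {
  R <- .expr_values(R)
  M <- .expr_mask(R, mask)
  G <- nrow(R); N <- ncol(R)
  std <- if (!is.null(state) && !is.null(state$.std)) state$.std
         else .standardise_genotypes(geno)
  X <- std$X
  poly <- std$poly
  S <- nrow(X)
  if (is.null(state)) state <- .init_genetic_state(G, N, S)
  Etau <- if (is.list(noise)) .Etau(noise) else noise
  pi0 <- control$prior_inclusion
  s0 <- control$slab_var
  complete <- all(M == 1)
  R0 <- R
  R0[M == 0] <- 0
  nobs <- rowSums(M)

  B <- tcrossprod(R0, X)                         # G x S: sum_n r_gn x_sn
  if (complete) {
    ssx <- matrix(N, G, S)
  } else {
    ssx <- M %*% t(X^2)
  }
  A <- 1 / s0 + Etau * ssx                       # G x S posterior precisions
  logBF <- (Etau * B)^2 / (2 * A) - log(s0 * A) / 2
  logBF[, !poly] <- -Inf

  sel <- state$selected_snp
  if (control$reselect_snp || all(is.na(sel))) {
    sel <- apply(logBF, 1, function(z) {
      j <- which.max(z)
      if (!length(j) || !is.finite(z[j])) NA_integer_ else j
    })
  }
  sel[nobs < 3L] <- NA_integer_
  has <- !is.na(sel)
  idx <- cbind(seq_len(G)[has], sel[has])

  # the selected SNP carries a uniform prior over the polymorphic
  # candidates, so the per-gene inclusion odds are penalised by log(S_poly);
  # without this, best-of-S selection would inflate the Bayes factor and
  # spuriously protect null genes' top SNP from factor absorption
  n_poly <- max(1L, sum(poly))
  rho <- rep(0, G); m <- rep(0, G); s2 <- rep(0, G)
  if (any(has)) {
    Ag <- A[idx]
    s2[has] <- 1 / Ag
    m[has] <- Etau[has] * B[idx] / Ag
    rho[has] <- stats::plogis(stats::qlogis(pi0) - log(n_poly) + logBF[idx])
  }

  C <- matrix(0, G, N); V <- matrix(0, G, N)
  if (any(has)) {
    Xsel <- X[sel[has], , drop = FALSE]
    C[has, ] <- (rho[has] * m[has]) * Xsel
    E2 <- (rho[has] * (m[has]^2 + s2[has])) * Xsel^2
    V[has, ] <- pmax(E2 - C[has, , drop = FALSE]^2, 0)
  }

  state$selected_snp <- sel
  state$inclusion_prob <- rho
  state$weight_mean <- m
  state$weight_var <- s2
  state$C <- C
  state$V <- V
  state$n_poly <- n_poly
  state$.std <- std
  state
}

# -KL(q || p) of the spike-and-slab block; genes with no selection sit at the
# null state (rho = 0) and contribute log(1 - pi0).
.bound_genetic <- function(state, control) {
  pi0 <- control$prior_inclusion
  s0 <- control$slab_var
  rho <- state$inclusion_prob
  m <- state$weight_mean
  s2 <- state$weight_var
  has <- !is.na(state$selected_snp)
  xlx <- function(p, q) ifelse(p > 0, p * (log(p) - log(q)), 0)
  kl <- rep(-log(1 - pi0), length(rho))
  if (any(has)) {
    klw <- (log(s0 / s2[has]) + (s2[has] + m[has]^2) / s0 - 1) / 2
    kl[has] <- xlx(rho[has], pi0) + xlx(1 - rho[has], 1 - pi0) +
      rho[has] * (klw + log(state$n_poly %||% 1))
  }
  -sum(kl)
}

#' Export the genetic component as a table
#'
#' @param fit A fitted [vbfit()] object with a genetic component.
#' @return data.frame with `gene_id`, `snp_id`, `inclusion_prob`,
#'   `weight_mean`.
#' @export
genetic_effects <- function(fit) {
  st <- fit$components$genetic
  if (is.null(st)) stop("no genetic component in this fit")
  sel <- st$selected_snp
  data.frame(gene_id = fit$gene_ids,
             snp_id = ifelse(is.na(sel), NA_character_, fit$snp_ids[sel]),
             inclusion_prob = st$inclusion_prob,
             weight_mean = st$weight_mean,
             stringsAsFactors = FALSE)
}
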