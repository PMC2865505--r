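# Baseline confounder-correction methods used for comparison with the joint
# Bayesian model: plain covariate regression ("standard"), truncated PCA,
# permutation-calibrated PCA (significance-tested eigenvalues), and a
# surrogate-variable procedure that rebuilds each significant eigengene from
# the gene subset it is associated with.

.correction_result <- function(method, n_components, components, residuals,
                               Y, settings) {
  res <- expression_matrix(residuals, gene_ids = Y$gene_ids,
                           individual_ids = Y$individual_ids,
                           mask = Y$mask)
  structure(list(method = method, n_components = n_components,
                 components = components, residuals = res,
                 settings = settings),
            class = "expression_correction")
}

#' @export
print.expression_correction <- function(x, ...) {
  cat(sprintf("expression_correction [%s]: %d component(s) removed, %d x %d residuals\n",
              x$method, x$n_components, nrow(x$residuals$values),
              ncol(x$residuals$values)))
  invisible(x)
}

# per-gene OLS residuals on covariates (centring if none); drops linearly
# dependent covariate columns with a warning
.ols_residualise <- function(Y, covs) {
  Yv <- .expr_values(Y)
  M <- .expr_mask(Y)
  if (is.null(covs)) {
    mu <- rowSums(ifelse(M == 1, Yv, 0)) / pmax(rowSums(M), 1)
    R <- Yv - mu
    R[M == 0] <- NA_real_
    return(R)
  }
  H <- cbind(1, t(.cov_values(covs)))                 # N x (F+1), intercept
  qrH <- qr(H)
  if (qrH$rank < ncol(H)) {
    warning("dropping ", ncol(H) - qrH$rank,
            " linearly dependent covariate column(s)")
    H <- H[, qrH$pivot[seq_len(qrH$rank)], drop = FALSE]
  }
  R <- Yv
  if (all(M == 1)) {
    R <- t(stats::lm.fit(H, t(Yv))$residuals)
  } else {
    for (g in seq_len(nrow(Yv))) {
      obs <- M[g, ] == 1
      fitg <- stats::lm.fit(H[obs, , drop = FALSE], Yv[g, obs])
      R[g, obs] <- fitg$residuals
      R[g, !obs] <- NA_real_
    }
  }
  R
}

#' Standard correction: known covariates only
#'
#' Removes the per-gene ordinary least squares fit on the known covariates
#' (or just the gene means when no covariates are given); hidden factors are
#' not modelled. This is the baseline residual set for association testing
#' without hidden-factor correction.
#'
#' @param Y An [expression_matrix()] or matrix.
#' @param covs Optional [covariate_matrix()] or F x N matrix.
#' @return An `expression_correction` with `n_components = 0`.
#' @export
correct_standard <- function(Y, covs = NULL) {
  if (!inherits(Y, "expression_matrix")) Y <- expression_matrix(as.matrix(Y))
  R <- .ols_residualise(Y, covs)
  .correction_result("standard", 0L, matrix(0, ncol(Y$values), 0), R, Y,
                     list(covs = !is.null(covs)))
}

#' PCA correction with a fixed number of components
#'
#' After removing the known-covariate fit, subtracts the rank-`K` truncated
#' singular value decomposition of the residual matrix. Complexity is
#' controlled solely by `K`: at `K = min(G, N)` PCA can explain all the
#' variability in the data.
#'
#' @param Y An [expression_matrix()] or matrix.
#' @param covs Optional covariates, regressed out first.
#' @param K Number of principal components to remove (1..min(G, N)).
#' @return An `expression_correction`; `components` holds the top-K right
#'   singular vectors scaled by their singular values (N x K).
#' @export
correct_pca <- function(Y, covs = NULL, K) {
  if (!inherits(Y, "expression_matrix")) Y <- expression_matrix(as.matrix(Y))
  G <- nrow(Y$values); N <- ncol(Y$values)
  if (K < 1 || K > min(G, N)) stop("K must be in 1..min(G, N)")
  R <- .ols_residualise(Y, covs)
  R0 <- ifelse(is.na(R), 0, R)
  sv <- svd(R0)
  K <- as.integer(K)
  recon <- sv$u[, seq_len(K), drop = FALSE] %*%
    (sv$d[seq_len(K)] * t(sv$v[, seq_len(K), drop = FALSE]))
  out <- R - recon
  comp <- sv$v[, seq_len(K), drop = FALSE] %*% diag(sv$d[seq_len(K)], K)
  .correction_result("pca", K, comp, out, Y, list(K = K))
}

#' Number of significant principal components by permutation
#'
#' Sequentially tests each eigenvalue's variance fraction against its null
#' distribution obtained from matrices in which every gene's values are
#' independently permuted across individuals, and stops at the first
#' non-significant component. This calibrates the component count against
#' what is expected by chance at cutoff `alpha`.
#'
#' @param Y An [expression_matrix()] or matrix (known covariates should be
#'   regressed out beforehand if present; see [correct_sva()]).
#' @param alpha Significance cutoff per component.
#' @param n_perm Number of permuted matrices (>= 20).
#' @param seed Integer seed (deterministic output).
#' @return Integer component count.
#' @export
pcasig_num_components <- function(Y, alpha = 0.01, n_perm = 100, seed = 1L) {
  if (n_perm < 20) stop("n_perm must be >= 20")
  Yv <- .expr_values(Y)
  Yv[is.na(Yv)] <- 0
  G <- nrow(Yv); N <- ncol(Yv)
  kmax <- min(G, N)
  d <- svd(Yv, nu = 0, nv = 0)$d
  frac <- d^2 / sum(d^2)
  set.seed(seed)
  null_frac <- matrix(0, n_perm, kmax)
  for (p in seq_len(n_perm)) {
    Yp <- Yv
    for (g in seq_len(G)) Yp[g, ] <- Yv[g, sample.int(N)]
    dp <- svd(Yp, nu = 0, nv = 0)$d
    null_frac[p, ] <- dp^2 / sum(dp^2)
  }
  # empirical tail proportion (no continuity term): a component whose
  # variance fraction exceeds every permutation is significant at any
  # cutoff, which is what makes the component count rigid across alpha
  count <- 0L
  for (k in seq_len(kmax)) {
    pval <- mean(null_frac[, k] >= frac[k])
    if (pval >= alpha) break
    count <- k
  }
  count
}

#' Permutation-calibrated PCA correction
#'
#' [correct_pca()] with the component count chosen by
#' [pcasig_num_components()] on the covariate-regressed residuals.
#'
#' @inheritParams correct_pca
#' @inheritParams pcasig_num_components
#' @return An `expression_correction` (identical to the standard correction
#'   when no component is significant).
#' @export
correct_pcasig <- function(Y, covs = NULL, alpha = 0.01, n_perm = 100,
                           seed = 1L) {
  if (!inherits(Y, "expression_matrix")) Y <- expression_matrix(as.matrix(Y))
  R <- .ols_residualise(Y, covs)
  K <- pcasig_num_components(R, alpha = alpha, n_perm = n_perm, seed = seed)
  if (K == 0L) {
    out <- correct_standard(Y, covs)
    out$method <- "pcasig"
    out$settings <- list(alpha = alpha, n_perm = n_perm, K = 0L)
    return(out)
  }
  out <- correct_pca(Y, covs, K)
  out$method <- "pcasig"
  out$settings <- list(alpha = alpha, n_perm = n_perm, K = K)
  out
}

#' Surrogate-variable correction
#'
#' Builds hidden-covariate estimates from significant eigengenes restricted
#' to their associated gene subsets: (i) residualise on known covariates;
#' (ii) count significant eigengenes by the gene-wise permutation test of
#' [pcasig_num_components()]; (iii) for each, identify the genes
#' significantly associated with it (correlation t-test at the same cutoff,
#' Bonferroni-adjusted over genes); (iv) rebuild the surrogate as the leading
#' eigengene of that gene subset only; (v) return the residuals of a joint
#' regression of the expression on covariates plus surrogates. Accommodates
#' sparse, non-orthogonal confounders that plain PCA averages away.
#'
#' @inheritParams correct_pcasig
#' @return An `expression_correction`; `components` holds the surrogate
#'   variables (N x K).
#' @export
correct_sva <- function(Y, covs = NULL, alpha = 0.01, n_perm = 100,
                        seed = 1L) {
  if (!inherits(Y, "expression_matrix")) Y <- expression_matrix(as.matrix(Y))
  R <- .ols_residualise(Y, covs)
  n_sig <- pcasig_num_components(R, alpha = alpha, n_perm = n_perm,
                                 seed = seed)
  if (n_sig == 0L) {
    out <- correct_standard(Y, covs)
    out$method <- "sva"
    out$settings <- list(alpha = alpha, n_perm = n_perm, K = 0L)
    return(out)
  }
  R0 <- ifelse(is.na(R), 0, R)
  G <- nrow(R0); N <- ncol(R0)
  sv <- svd(R0, nu = 0, nv = n_sig)
  surrogates <- matrix(0, N, n_sig)
  for (k in seq_len(n_sig)) {
    eg <- sv$v[, k]
    # genes significantly associated with this eigengene
    p <- apply(R0, 1, function(y) corr_t_test(y, eg)$p_nominal)
    keep <- which(pmin(p * G, 1) < alpha)
    if (length(keep) < 2L) keep <- order(p)[seq_len(min(10L, G))]
    svk <- svd(R0[keep, , drop = FALSE], nu = 0, nv = 1)
    v1 <- svk$v[, 1]
    if (sum(v1 * eg) < 0) v1 <- -v1       # orient like the eigengene
    surrogates[, k] <- v1
  }
  covs_all <- rbind(if (!is.null(covs)) .cov_values(covs),
                    t(surrogates))
  rownames(covs_all) <- c(if (!is.null(covs)) rownames(.cov_values(covs)),
                          paste0("sv", seq_len(n_sig)))
  out_res <- .ols_residualise(Y, covs_all)
  .correction_result("sva", n_sig, surrogates, out_res, Y,
                     list(alpha = alpha, n_perm = n_perm))
}
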