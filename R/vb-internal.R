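# Internal building blocks shared by the variational component updates.
#
# Conventions: expression/residual matrices are G x N (genes x individuals),
# activations/covariates are N x K inside the updates. Second moments of
# K-vectors are carried row-wise as vec(E[z z^T]) in an (n x K^2) matrix so
# that contribution second moments reduce to a single matrix product
# (tr(A B) = vec(A) . vec(B) for symmetric A, B).

# row-wise vec of the outer product: (n x K) -> (n x K^2)
.vec_outer <- function(A) {
  K <- ncol(A)
  A[, rep(seq_len(K), times = K), drop = FALSE] *
    A[, rep(seq_len(K), each = K), drop = FALSE]
}

# E[log p(tau)] + H[q(tau)] for gamma prior (a0,b0) and posterior (a,b);
# vectorised over posteriors.
.gamma_bound <- function(a0, b0, a, b) {
  Elog <- digamma(a) - log(b)
  E <- a / b
  a0 * log(b0) - lgamma(a0) + (a0 - 1) * Elog - b0 * E +
    a - log(b) + lgamma(a) + (1 - a) * digamma(a)
}

# Conjugate update of per-gene regression weights given activation moments.
# R0: residual with missing entries set to 0 (G x N); M: 0/1 observation mask;
# Am: activation means (N x K); AEvv: row-wise vec second moments (N x K^2);
# Etau: expected noise precision per gene; Ealpha: expected prior precision
# per column (ARD). Posterior per gene g: precision diag(Ealpha) + Etau_g * S_g
# with S_g = sum_{n obs} E[a_n a_n^T].
#
# When the data are complete S_g is shared, and the solve for all genes
# reduces to one eigendecomposition plus elementwise scaling.
.update_loadings <- function(R0, M, Am, AEvv, Etau, Ealpha, complete) {
  G <- nrow(R0)
  K <- ncol(Am)
  B <- R0 %*% Am                         # G x K data terms
  if (complete) {
    S <- matrix(colSums(AEvv), K, K)
    D <- sqrt(Ealpha)
    A0 <- S / tcrossprod(D)
    A0 <- (A0 + t(A0)) / 2
    eig <- eigen(A0, symmetric = TRUE)
    lam <- pmax(eig$values, 0)
    U <- eig$vectors
    Q <- U / D                           # diag(1/D) %*% U
    scal <- 1 / (1 + outer(Etau, lam))   # G x K posterior spectrum
    Bu <- sweep(B, 2, D, "/") %*% U
    Wm <- ((Bu * scal) %*% t(Q)) * Etau
    P <- matrix(0, K, K * K)             # row j = vec(q_j q_j^T)
    for (j in seq_len(K)) P[j, ] <- as.vector(tcrossprod(Q[, j]))
    WEvv <- .vec_outer(Wm) + scal %*% P
    Wdiag2 <- Wm^2 + scal %*% t(Q^2)
    Wlogdet <- rowSums(log(scal)) - sum(log(Ealpha))
  } else {
    Svec <- M %*% AEvv                   # G x K^2, per-gene vec(S_g)
    Wm <- matrix(0, G, K)
    WEvv <- matrix(0, G, K * K)
    Wdiag2 <- matrix(0, G, K)
    Wlogdet <- numeric(G)
    IK <- diag(Ealpha, K)
    for (g in seq_len(G)) {
      Lam <- IK + Etau[g] * matrix(Svec[g, ], K, K)
      Lam <- (Lam + t(Lam)) / 2
      Sig <- chol2inv(chol(Lam))
      mu <- drop(Etau[g] * Sig %*% B[g, ])
      Eww <- tcrossprod(mu) + Sig
      Wm[g, ] <- mu
      WEvv[g, ] <- as.vector(Eww)
      Wdiag2[g, ] <- diag(Eww)
      Wlogdet[g] <- as.numeric(determinant(Sig, logarithm = TRUE)$modulus)
    }
  }
  list(mean = Wm, Evv = WEvv, diag2 = Wdiag2, logdet = Wlogdet)
}

# Conjugate update of factor activations given loading moments, under a
# standard-normal prior (identity prior precision).
.update_activations <- function(R0, M, Wm, WEvv, Etau, complete) {
  N <- ncol(R0)
  K <- ncol(Wm)
  Wt <- Wm * Etau
  B <- crossprod(R0, Wt)                 # N x K
  WE <- WEvv * Etau
  if (complete) {
    Tm <- matrix(colSums(WE), K, K)
    Psi <- diag(K) + (Tm + t(Tm)) / 2
    ch <- chol(Psi)
    Sig <- chol2inv(ch)
    Xm <- B %*% Sig
    XEvv <- .vec_outer(Xm) +
      matrix(as.vector(Sig), N, K * K, byrow = TRUE)
    Xdiag2 <- Xm^2 + matrix(diag(Sig), N, K, byrow = TRUE)
    Xlogdet <- rep(-2 * sum(log(diag(ch))), N)
  } else {
    Tn <- crossprod(M, WE)               # N x K^2
    Xm <- matrix(0, N, K)
    XEvv <- matrix(0, N, K * K)
    Xdiag2 <- matrix(0, N, K)
    Xlogdet <- numeric(N)
    for (n in seq_len(N)) {
      Psi <- diag(K) + matrix(Tn[n, ], K, K)
      Psi <- (Psi + t(Psi)) / 2
      Sig <- chol2inv(chol(Psi))
      mu <- drop(Sig %*% B[n, ])
      Exx <- tcrossprod(mu) + Sig
      Xm[n, ] <- mu
      XEvv[n, ] <- as.vector(Exx)
      Xdiag2[n, ] <- diag(Exx)
      Xlogdet[n] <- as.numeric(determinant(Sig, logarithm = TRUE)$modulus)
    }
  }
  list(mean = Xm, Evv = XEvv, diag2 = Xdiag2, logdet = Xlogdet)
}

# First/second contribution moments from loading and activation moments.
.contribution <- function(Wm, WEvv, Am, AEvv) {
  C <- tcrossprod(Wm, Am)
  V <- pmax(WEvv %*% t(AEvv) - C^2, 0)
  list(mean = C, var = V)
}

# expected precision from a noise state (list(shape, rate))
.Etau <- function(noise) noise$shape / noise$rate

# coerce inputs to plain value matrices
.expr_values <- function(Y) if (inherits(Y, "expression_matrix")) Y$values else as.matrix(Y)
.expr_mask <- function(Y, mask = NULL) {
  if (!is.null(mask)) return(mask * 1)
  if (inherits(Y, "expression_matrix")) return(Y$mask * 1)
  (!is.na(as.matrix(Y))) * 1
}
.cov_values <- function(covs) {
  if (inherits(covs, "covariate_matrix")) covs$values else as.matrix(covs)
}
.geno_values <- function(geno) {
  if (inherits(geno, "genotype_matrix")) geno$values else as.matrix(geno)
}
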