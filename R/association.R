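# Residual-based eQTL calling: correlation t-test, rank test, per-gene
# permutation test, nested likelihood-ratio test, Bonferroni control,
# cis/trans classification and an empirical FDR estimator.

#' Correlation t-test between an expression and a genotype vector
#'
#' Pearson correlation on complete pairs, with `t = r * sqrt(n-2) /
#' sqrt(1-r^2)` on `n - 2` degrees of freedom and a two-sided p-value.
#' A constant genotype is flagged untestable (`p = 1`).
#'
#' @param y Expression vector (may contain `NA`).
#' @param x Genotype vector (missing coded `NA` or -1).
#' @return List with `r`, `stat`, `p_nominal`, `n_used`, `testable`.
#' @export
corr_t_test <- function(y, x) {
  x <- as.numeric(x)
  x[x < -0.5 & x > -1.5] <- NA_real_   # -1 missing code
  ok <- !is.na(y) & !is.na(x)
  n <- sum(ok)
  if (n < 3L || stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0)
    return(list(r = NA_real_, stat = NA_real_, p_nominal = 1, n_used = n,
                testable = FALSE))
  r <- stats::cor(y[ok], x[ok])
  if (abs(r) >= 1) {
    tt <- sign(r) * Inf
    p <- 0
  } else {
    tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(r = r, stat = tt, p_nominal = p, n_used = n, testable = TRUE)
}

#' Rank-based association test
#'
#' [corr_t_test()] applied to midranks of the expression values (genotype
#' untransformed); invariant to monotone transforms of the expression.
#'
#' @inheritParams corr_t_test
#' @return As [corr_t_test()].
#' @export
rank_test <- function(y, x) {
  yr <- y
  ok <- !is.na(y)
  yr[ok] <- rank(y[ok])
  corr_t_test(yr, x)
}

#' Nested-model likelihood-ratio association test
#'
#' Chi-squared test with one degree of freedom on the log likelihood ratio
#' for adding the genotype term to a per-gene Gaussian model.
#'
#' @inheritParams corr_t_test
#' @return As [corr_t_test()] (`stat` is the LR chi-squared statistic).
#' @export
lrt_test <- function(y, x) {
  base <- corr_t_test(y, x)
  if (!base$testable) return(base)
  n <- base$n_used
  lr <- -n * log(1 - base$r^2)
  base$stat <- lr
  base$p_nominal <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  base
}

#' Per-gene permutation test for the best SNP
#'
#' The test statistic is the maximum absolute correlation over the SNP set;
#' its null distribution is obtained by permuting the individual labels of
#' the expression vector (preserving linkage among SNPs). The empirical
#' p-value is `(1 + #{null >= observed}) / (1 + n_perm)`; deterministic for a
#' given seed.
#'
#' @param y Expression vector.
#' @param X_snps Genotype matrix slice (S x N, missing coded -1) or
#'   [genotype_matrix()].
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return List with `best_snp`, `r`, `stat` (max |r|), `p`, `n_used`.
#' @export
permutation_test <- function(y, X_snps, n_perm = 1000, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  X <- .geno_values(X_snps)
  storage.mode(X) <- "double"
  X[X < 0] <- NA_real_
  ok <- !is.na(y) & colSums(is.na(X)) == 0
  # pairwise-complete handling: restrict to individuals complete across the
  # slice when genotypes have missingness, else just observed expression
  if (any(is.na(X))) {
    yv <- y[ok]; Xv <- X[, ok, drop = FALSE]
  } else {
    obs <- !is.na(y)
    yv <- y[obs]; Xv <- X[, obs, drop = FALSE]
  }
  n <- length(yv)
  if (n < 3L) return(list(best_snp = NA_integer_, r = NA_real_,
                          stat = NA_real_, p = 1, n_used = n))
  sdx <- apply(Xv, 1, stats::sd)
  poly <- sdx > 0
  if (!any(poly)) return(list(best_snp = NA_integer_, r = NA_real_,
                              stat = NA_real_, p = 1, n_used = n))
  Xs <- scale(t(Xv[poly, , drop = FALSE]))        # n x S', standardised
  ys <- as.numeric(scale(yv))
  if (any(!is.finite(ys)))
    return(list(best_snp = NA_integer_, r = NA_real_, stat = NA_real_,
                p = 1, n_used = n))
  set.seed(seed)
  perm_idx <- replicate(n_perm, sample.int(n))
  Yp <- cbind(ys, matrix(ys[perm_idx], n, n_perm))
  cors <- crossprod(Xs, Yp) / (n - 1)             # S' x (1 + n_perm)
  maxabs <- apply(abs(cors), 2, max)
  obs_stat <- maxabs[1]
  p <- (1 + sum(maxabs[-1] >= obs_stat)) / (1 + n_perm)
  best_local <- which.max(abs(cors[, 1]))
  best <- which(poly)[best_local]
  list(best_snp = best, r = cors[best_local, 1], stat = obs_stat, p = p,
       n_used = n)
}

#' Per-gene Bonferroni adjustment
#'
#' @param p_nominal Nominal p-value(s).
#' @param n_snps_tested Number of SNPs tested for the gene.
#' @return `min(1, p * n)`.
#' @export
bonferroni_per_gene <- function(p_nominal, n_snps_tested) {
  stopifnot(n_snps_tested >= 1)
  pmin(1, p_nominal * n_snps_tested)
}

#' Classify an association as cis or trans
#'
#' Window mode (outbred designs): cis iff the SNP lies on the same chromosome
#' and within 1 Mb (inclusive) of the probe midpoint. Chromosome mode
#' (inbred-strain crosses): cis iff probe and locus share a chromosome.
#' Strand is ignored; only positions matter.
#'
#' @param gene_chrom,gene_midpoint Probe annotation (chromosome, midpoint bp).
#' @param snp_chrom,snp_pos SNP annotation.
#' @param mode `"window"` or `"chromosome"`.
#' @param window_bp Window half-width in bp (default 1e6).
#' @return `"cis"` or `"trans"`.
#' @export
classify_location <- function(gene_chrom, gene_midpoint, snp_chrom, snp_pos,
                              mode = c("window", "chromosome"),
                              window_bp = 1e6) {
  mode <- match.arg(mode)
  if (any(is.na(c(gene_chrom, gene_midpoint, snp_chrom, snp_pos))))
    stop("missing annotation for gene or SNP")
  same <- gene_chrom == snp_chrom
  if (mode == "chromosome") return(ifelse(same, "cis", "trans"))
  ifelse(same & abs(as.numeric(snp_pos) - as.numeric(gene_midpoint)) <= window_bp,
         "cis", "trans")
}

#' Map eQTLs on (corrected) expression
#'
#' For every gene, finds the best SNP by absolute correlation (pairwise
#' complete observations), computes the chosen test's p-value, applies
#' per-gene Bonferroni correction over the number of SNPs tested (the
#' permutation test is already family-wise per gene), calls significance at
#' the per-gene false positive rate `fpr`, and classifies the association as
#' cis or trans.
#'
#' @param R Corrected expression: [expression_matrix()] or matrix.
#' @param geno A [genotype_matrix()].
#' @param annotations A [probe_annotation()] (required unless `mode` is
#'   `"none"`).
#' @param test `"ttest"`, `"rank"`, `"perm"`, or `"lrt"`.
#' @param fpr Per-gene family-wise false positive rate (default 0.001).
#' @param mode cis/trans rule: `"window"`, `"chromosome"`, or `"none"` to
#'   skip location classification.
#' @param n_perm,seed Permutation-test settings (`test = "perm"` only).
#' @return List of class `"eqtl_scan"`: `results` (one row per gene:
#'   `gene_id`, `snp_id`, `r`, `stat`, `p_nominal`, `p_adjusted`,
#'   `significant`, `location_class`, `n_used`) and `summary`
#'   (`n_genes_tested`, `n_significant`, `n_cis`, `n_trans`, `fpr`, `test`,
#'   `mode`).
#' @export
map_eqtls <- function(R, geno, annotations = NULL,
                      test = c("ttest", "rank", "perm", "lrt"), fpr = 0.001,
                      mode = c("window", "chromosome", "none"),
                      n_perm = 1000, seed = 1L) {
  test <- match.arg(test)
  mode <- match.arg(mode)
  Rv <- .expr_values(R)
  gene_ids <- if (inherits(R, "expression_matrix")) R$gene_ids
              else rownames(Rv)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(Rv)))
  X <- .geno_values(geno)
  snp_ids <- if (inherits(geno, "genotype_matrix")) geno$snp_ids
             else paste0("snp", seq_len(nrow(X)))
  if (ncol(Rv) != ncol(X))
    stop("expression and genotypes must be aligned to the same individuals")
  G <- nrow(Rv); S <- nrow(X)
  testfun <- switch(test, ttest = corr_t_test, rank = rank_test,
                    lrt = lrt_test, perm = NULL)
  complete <- !anyNA(Rv) && !any(X < 0)

  out <- vector("list", G)
  if (test != "perm" && complete) {
    # fast path: all best-SNP correlations in one matrix product
    Rw <- if (test == "rank") t(apply(Rv, 1, rank)) else Rv
    Rs <- Rw - rowMeans(Rw)
    rnorm2 <- sqrt(rowSums(Rs^2))
    Xs <- X - rowMeans(X)
    xnorm2 <- sqrt(rowSums(Xs^2))
    poly <- xnorm2 > 0
    cors <- matrix(0, G, S)
    ok_g <- rnorm2 > 0
    cors[ok_g, poly] <- (Rs[ok_g, , drop = FALSE] / rnorm2[ok_g]) %*%
      t(Xs[poly, , drop = FALSE] / xnorm2[poly])
    acors <- abs(cors)
    acors[, !poly] <- -1
    for (g in seq_len(G)) {
      if (!ok_g[g] || !any(poly)) {
        out[[g]] <- list(snp = NA_integer_, r = NA_real_, stat = NA_real_,
                         p_nom = 1, p_adj = 1, n_used = ncol(Rv))
        next
      }
      best <- which.max(acors[g, ])
      tr <- testfun(Rv[g, ], X[best, ])
      out[[g]] <- list(snp = best, r = tr$r, stat = tr$stat,
                       p_nom = tr$p_nominal,
                       p_adj = bonferroni_per_gene(tr$p_nominal, S),
                       n_used = tr$n_used)
    }
  } else {
    for (g in seq_len(G)) {
      y <- Rv[g, ]
      if (test == "perm") {
        pt <- permutation_test(y, X, n_perm = n_perm, seed = seed + g)
        best <- pt$best_snp
        row <- list(snp = best, r = pt$r, stat = pt$stat, p_nom = pt$p,
                    p_adj = pt$p, n_used = pt$n_used)
      } else {
        yy <- if (test == "rank") {
          yr <- y; ok <- !is.na(y); yr[ok] <- rank(y[ok]); yr
        } else y
        best <- select_best_snp(yy, X)
        if (is.na(best)) {
          row <- list(snp = NA_integer_, r = NA_real_, stat = NA_real_,
                      p_nom = 1, p_adj = 1, n_used = sum(!is.na(y)))
        } else {
          tr <- testfun(y, X[best, ])
          row <- list(snp = best, r = tr$r, stat = tr$stat,
                      p_nom = tr$p_nominal,
                      p_adj = bonferroni_per_gene(tr$p_nominal, S),
                      n_used = tr$n_used)
        }
      }
      out[[g]] <- row
    }
  }
  snp_idx <- vapply(out, function(z) as.integer(z$snp %||% NA_integer_),
                    integer(1))
  res <- data.frame(
    gene_id = gene_ids,
    snp_id = ifelse(is.na(snp_idx), NA_character_, snp_ids[snp_idx]),
    snp_index = snp_idx,
    r = vapply(out, function(z) z$r, numeric(1)),
    stat = vapply(out, function(z) z$stat, numeric(1)),
    p_nominal = vapply(out, function(z) z$p_nom, numeric(1)),
    p_adjusted = vapply(out, function(z) z$p_adj, numeric(1)),
    n_used = vapply(out, function(z) z$n_used, numeric(1)),
    stringsAsFactors = FALSE
  )
  res$significant <- res$p_adjusted <= fpr & !is.na(res$snp_id)
  res$location_class <- NA_character_
  if (mode != "none") {
    if (is.null(annotations)) stop("annotations required for cis/trans mode")
    ann <- annotations[match(res$gene_id, annotations$gene_id), ]
    miss <- which(is.na(ann$gene_id) & !is.na(res$snp_id))
    if (length(miss))
      stop("missing probe annotation for gene(s): ",
           paste(utils::head(res$gene_id[miss], 5), collapse = ", "))
    gchr <- ann$chrom
    gmid <- ann$midpoint_bp
    schr <- geno$chrom[snp_idx]
    spos <- geno$pos_bp[snp_idx]
    has <- !is.na(snp_idx)
    res$location_class[has] <- classify_location(gchr[has], gmid[has],
                                                 schr[has], spos[has], mode)
  }
  sig <- res$significant
  summary <- list(
    n_genes_tested = G,
    n_significant = sum(sig),
    n_cis = sum(sig & res$location_class == "cis", na.rm = TRUE),
    n_trans = sum(sig & res$location_class == "trans", na.rm = TRUE),
    fpr = fpr, test = test, mode = mode
  )
  structure(list(results = res, summary = summary), class = "eqtl_scan")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.eqtl_scan <- function(x, ...) {
  s <- x$summary
  cat(sprintf("eQTL scan (%s test, per-gene FPR %g): %d/%d genes significant",
              s$test, s$fpr, s$n_significant, s$n_genes_tested))
  if (s$mode != "none")
    cat(sprintf(" (%d cis, %d trans)", s$n_cis, s$n_trans))
  cat("\n")
  invisible(x)
}

#' Empirical FDR by genotype permutation
#'
#' Permutes the individual labels of the genotype matrix as a whole
#' (preserving linkage among SNPs), re-runs the scan, and estimates the FDR
#' at the configured threshold as the mean significant-gene count over
#' permuted datasets divided by the observed count (capped at 1).
#'
#' @param scan An `eqtl_scan` from [map_eqtls()].
#' @param R,geno The inputs that produced `scan`.
#' @param n_perm Number of genotype permutations.
#' @param seed Integer seed.
#' @param ... Further arguments passed on to [map_eqtls()].
#' @return List with `fdr` (`NA` if no observed positives), `n_observed`,
#'   `mean_null`.
#' @export
empirical_fdr <- function(scan, R, geno, n_perm = 20, seed = 1L, ...) {
  n_obs <- scan$summary$n_significant
  X <- .geno_values(geno)
  set.seed(seed)
  null_counts <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    idx <- sample.int(ncol(X))
    gp <- genotype_matrix(X[, idx, drop = FALSE],
                          snp_ids = if (inherits(geno, "genotype_matrix"))
                            geno$snp_ids else NULL,
                          individual_ids = colnames(X),
                          chrom = if (inherits(geno, "genotype_matrix"))
                            geno$chrom else NULL,
                          pos_bp = if (inherits(geno, "genotype_matrix"))
                            geno$pos_bp else NULL,
                          ploidy = if (inherits(geno, "genotype_matrix"))
                            geno$ploidy else 2)
    ns <- map_eqtls(R, gp, test = scan$summary$test, fpr = scan$summary$fpr,
                    mode = "none", seed = seed + p, ...)
    null_counts[p] <- ns$summary$n_significant
  }
  if (n_obs == 0)
    return(list(fdr = NA_real_, n_observed = 0L,
                mean_null = mean(null_counts)))
  list(fdr = min(1, mean(null_counts) / n_obs), n_observed = n_obs,
       mean_null = mean(null_counts))
}
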