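#' Configuration for the synthetic eQTL study generator
#'
#' Defaults reproduce the benchmark design: three known and seven hidden
#' global factors whose magnitudes vary over a wide range, three trans
#' hotspot regulators each driving 15% of the genes, cis eQTLs for a fifth
#' of the genes, independent SNPs, and gene-specific Gaussian noise. With
#' these defaults the global (known + hidden + hotspot) components account
#' for roughly two thirds of the total expression variance.
#'
#' @param G,N,S Number of genes, individuals, SNPs.
#' @param n_known,n_hidden,n_hotspots Number of known covariates, hidden
#'   factors and hotspot regulator genes.
#' @param hotspot_target_frac Fraction of genes driven by each regulator.
#' @param frac_cis_genes Fraction of genes with a cis eQTL (regulators are
#'   drawn from these).
#' @param effect_size_range Absolute cis effect size per genotype unit.
#' @param factor_scale_range Per-factor loading standard deviation (applies
#'   to known, hidden and hotspot factors; drawn once per factor).
#' @param noise_sd_range Gene-specific noise standard deviation.
#' @param maf_range Allele frequency range for the independent SNPs.
#' @param ploidy 1 (haploid/inbred-cross genotypes, default) or 2.
#' @param regulator_signal `"latent"` (regulator's noise-free genetic signal
#'   drives targets, default) or `"observed"` (its noisy expression does).
#' @param seed Integer seed; the generator is deterministic given the config.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(G = 1000, N = 100, S = 500,
                       n_known = 3, n_hidden = 7, n_hotspots = 3,
                       hotspot_target_frac = 0.15, frac_cis_genes = 0.2,
                       effect_size_range = c(1, 2.5),
                       factor_scale_range = c(0.25, 0.7),
                       noise_sd_range = c(0.8, 1.4),
                       maf_range = c(0.1, 0.9),
                       ploidy = 1, regulator_signal = c("latent", "observed"),
                       seed = 1L) {
  stopifnot(G >= 1, N >= 2, S >= 1, n_known >= 0, n_hidden >= 0,
            n_hotspots >= 0, hotspot_target_frac >= 0,
            hotspot_target_frac <= 1, frac_cis_genes >= 0,
            frac_cis_genes <= 1, ploidy %in% c(1, 2))
  structure(list(G = G, N = N, S = S, n_known = n_known, n_hidden = n_hidden,
                 n_hotspots = n_hotspots,
                 hotspot_target_frac = hotspot_target_frac,
                 frac_cis_genes = frac_cis_genes,
                 effect_size_range = effect_size_range,
                 factor_scale_range = factor_scale_range,
                 noise_sd_range = noise_sd_range, maf_range = maf_range,
                 ploidy = ploidy,
                 regulator_signal = match.arg(regulator_signal),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an eQTL study with known, hidden and genetic global factors
#'
#' Generates genotypes (i.i.d. per SNP), cis eQTL effects, hotspot regulators
#' whose genetic signal linearly drives a random 15% target set (mimicking a
#' variant in a transcriptional regulator), known covariates (the first is a
#' 0/1 indicator, e.g. gender), standard-normal hidden factor activations
#' with factor-specific magnitudes, and gene-specific Gaussian noise. All
#' per-component contribution matrices sum exactly to the returned expression
#' matrix and are recorded as ground truth.
#'
#' @param config A [sim_config()].
#' @return List with `expr` ([expression_matrix()]), `geno`
#'   ([genotype_matrix()] with positions on a synthetic genome), `covs`
#'   ([covariate_matrix()]), `annotations` ([probe_annotation()]), and
#'   `truth`: contribution matrices (`genetic_cis`, `genetic_hotspot`,
#'   `known`, `hidden`, `noise`), `eqtl_map` (per gene, causal SNP index or
#'   `NA`), `regulator_genes`, `regulator_snps`, `hotspot_targets` (list of
#'   target index sets), plus the per-factor scales used.
#' @export
simulate_eqtl_study <- function(config = sim_config()) {
  cf <- config
  set.seed(cf$seed)
  G <- cf$G; N <- cf$N; S <- cf$S

  n_cis <- round(cf$frac_cis_genes * G)
  if (cf$n_hotspots > n_cis)
    stop("more hotspot regulators than cis genes; increase frac_cis_genes")
  if (n_cis > min(G, S))
    stop("more cis genes than genes or SNPs available")

  # --- genotypes: independent SNPs on a synthetic genome -------------------
  maf <- stats::runif(S, cf$maf_range[1], cf$maf_range[2])
  X <- matrix(stats::rbinom(S * N, cf$ploidy, rep(maf, N)), S, N)
  # synthetic map: 20 chromosomes, SNPs spaced 200 kb; probes midway
  chrom <- paste0("chr", ((seq_len(S) - 1) %% 20) + 1)
  pos <- (((seq_len(S) - 1) %/% 20) + 1) * 200000L
  geno <- genotype_matrix(X, snp_ids = sprintf("snp%04d", seq_len(S)),
                          individual_ids = sprintf("ind%03d", seq_len(N)),
                          chrom = chrom, pos_bp = pos, ploidy = cf$ploidy)

  gene_ids <- sprintf("gene%04d", seq_len(G))
  ind_ids <- geno$individual_ids

  # --- cis eQTLs -----------------------------------------------------------
  cis_genes <- sort(sample.int(G, n_cis))
  cis_snps <- sample.int(S, n_cis)
  eqtl_map <- rep(NA_integer_, G)
  eqtl_map[cis_genes] <- cis_snps
  beta <- stats::runif(n_cis, cf$effect_size_range[1], cf$effect_size_range[2]) *
    sample(c(-1, 1), n_cis, replace = TRUE)
  C_cis <- matrix(0, G, N)
  if (n_cis > 0) {
    Xc <- X[cis_snps, , drop = FALSE]
    Xc <- Xc - rowMeans(Xc)
    C_cis[cis_genes, ] <- beta * Xc
  }

  # probe annotations: cis genes sit next to their SNP, others random
  ann_chrom <- chrom[ifelse(is.na(eqtl_map), sample.int(S, G, replace = TRUE),
                            eqtl_map)]
  ann_pos <- pos[ifelse(is.na(eqtl_map), sample.int(S, G, replace = TRUE),
                        eqtl_map)] + 50000L
  annotations <- probe_annotation(gene_ids, ann_chrom, ann_pos)

  # --- hotspot regulators --------------------------------------------------
  C_hot <- matrix(0, G, N)
  regulators <- integer(0)
  regulator_snps <- integer(0)
  targets <- list()
  hot_scales <- numeric(0)
  if (cf$n_hotspots > 0) {
    regulators <- sample(cis_genes, cf$n_hotspots)
    regulator_snps <- eqtl_map[regulators]
    n_targets <- round(cf$hotspot_target_frac * G)
    if (n_targets > G - n_cis)
      stop("hotspot_target_frac too large for the non-cis gene pool")
    hot_scales <- stats::runif(cf$n_hotspots, cf$factor_scale_range[1],
                               cf$factor_scale_range[2])
    for (h in seq_len(cf$n_hotspots)) {
      reg <- regulators[h]
      sig <- C_cis[reg, ]
      if (cf$regulator_signal == "observed")
        sig <- sig + stats::rnorm(N, 0, 0.5)   # regulator's own noise
      s <- stats::sd(sig)
      if (s > 0) sig <- sig / s                # unit-variance driver
      # targets are drawn from genes without their own cis eQTL, so
      # immediate (cis) and downstream (trans) signal stay separable
      tg <- sample(which(is.na(eqtl_map)), n_targets)
      targets[[h]] <- sort(tg)
      # loading sd inflated by 1/sqrt(target fraction) so each hotspot
      # factor's overall magnitude matches a dense global factor of the
      # same drawn scale
      w <- stats::rnorm(n_targets, 0,
                        hot_scales[h] / sqrt(cf$hotspot_target_frac))
      C_hot[tg, ] <- C_hot[tg, , drop = FALSE] + tcrossprod(w, sig)
    }
  }

  # --- known covariates ----------------------------------------------------
  C_known <- matrix(0, G, N)
  covs <- NULL
  known_scales <- numeric(0)
  if (cf$n_known > 0) {
    Hk <- matrix(stats::rnorm(cf$n_known * N), cf$n_known, N)
    if (cf$n_known >= 1) Hk[1, ] <- stats::rbinom(N, 1, 0.5)  # 0/1 indicator
    known_scales <- stats::runif(cf$n_known, cf$factor_scale_range[1],
                                 cf$factor_scale_range[2])
    Wk <- matrix(stats::rnorm(G * cf$n_known), G, cf$n_known) *
      rep(known_scales, each = G)
    Hc <- Hk - rowMeans(Hk)
    C_known <- Wk %*% Hc
    covs <- covariate_matrix(Hk,
                             covariate_ids = c("indicator",
                                               paste0("cov", seq_len(cf$n_known)[-1]))[seq_len(cf$n_known)],
                             individual_ids = ind_ids)
  }

  # --- hidden factors ------------------------------------------------------
  C_hidden <- matrix(0, G, N)
  hidden_scales <- numeric(0)
  hidden_activations <- NULL
  if (cf$n_hidden > 0) {
    Xh <- matrix(stats::rnorm(cf$n_hidden * N), cf$n_hidden, N)
    hidden_scales <- stats::runif(cf$n_hidden, cf$factor_scale_range[1],
                                  cf$factor_scale_range[2])
    Wh <- matrix(stats::rnorm(G * cf$n_hidden), G, cf$n_hidden) *
      rep(hidden_scales, each = G)
    C_hidden <- Wh %*% Xh
    hidden_activations <- t(Xh)
  }

  # --- noise and assembly --------------------------------------------------
  noise_sd <- stats::runif(G, cf$noise_sd_range[1], cf$noise_sd_range[2])
  E <- matrix(stats::rnorm(G * N), G, N) * noise_sd
  Y <- C_cis + C_hot + C_known + C_hidden + E

  expr <- expression_matrix(Y, gene_ids = gene_ids, individual_ids = ind_ids)
  truth <- list(genetic_cis = C_cis, genetic_hotspot = C_hot,
                known = C_known, hidden = C_hidden, noise = E,
                eqtl_map = eqtl_map, regulator_genes = regulators,
                regulator_snps = regulator_snps, hotspot_targets = targets,
                hidden_activations = hidden_activations,
                hidden_scales = hidden_scales, known_scales = known_scales,
                hotspot_scales = hot_scales, noise_sd = noise_sd,
                config = cf)
  list(expr = expr, geno = geno, covs = covs, annotations = annotations,
       truth = truth)
}
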