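test_that("correlation t-test matches the textbook formulas", {
  y <- c(1, 2, 3, 5); x <- c(0, 1, 1, 2)
  got <- corr_t_test(y, x)
  want <- oracle_corr_t(y, x)
  expect_equal(got$r, want$r, tolerance = 1e-10)
  expect_equal(got$stat, want$stat, tolerance = 1e-10)
  expect_equal(got$p_nominal, want$p, tolerance = 1e-10)
  expect_identical(got$n_used, 4L)

  # degenerate perfect fit
  perf <- corr_t_test(c(0, 1, 2, 0, 1), c(0L, 1L, 2L, 0L, 1L))
  expect_equal(perf$r, 1)
  expect_equal(perf$p_nominal, 0)

  # constant genotype is untestable
  flat <- corr_t_test(rnorm(5), rep(1L, 5))
  expect_false(flat$testable)
  expect_equal(flat$p_nominal, 1)

  # -1 genotype codes drop pairwise
  expect_identical(corr_t_test(1:6, c(0, 1, -1, 0, 1, 1))$n_used, 5L)
})

test_that("null p-values are uniform", {
  set.seed(40)
  n <- 10; reps <- 1e4
  x <- rep(c(0, 1), each = n / 2)
  xs <- x - mean(x)
  Y <- matrix(rnorm(reps * n), reps, n)
  # vectorised Pearson r against the fixed balanced genotype
  Yc <- Y - rowMeans(Y)
  r <- (Yc %*% xs) / sqrt(rowSums(Yc^2) * sum(xs^2))
  tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * pt(-abs(tt), df = n - 2)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
  # spot-check the vectorised oracle against corr_t_test itself
  one <- corr_t_test(Y[1, ], x)
  expect_equal(one$p_nominal, p[1], tolerance = 1e-12)
})

test_that("rank test is invariant to monotone transforms and tames outliers", {
  set.seed(41)
  y <- rnorm(20); x <- rbinom(20, 1, 0.5)
  a <- rank_test(y, x)
  b <- rank_test(exp(y), x)                  # monotone transform
  expect_equal(a$stat, b$stat, tolerance = 1e-12)
  # already a permutation of 1..n: identical to the Pearson test
  yr <- sample(1:20)
  expect_equal(rank_test(yr, x)$stat, corr_t_test(yr, x)$stat,
               tolerance = 1e-12)
  # one extreme outlier aligned with the genotype: rank p less extreme
  y2 <- rnorm(20, 0, 0.1); y2[x == 1][1] <- 50
  expect_gt(rank_test(y2, x)$p_nominal, corr_t_test(y2, x)$p_nominal)
})

test_that("nested likelihood-ratio test agrees with the correlation test", {
  set.seed(42)
  y <- rnorm(30) + 0.8 * rbinom(30, 1, 0.5)
  x <- rbinom(30, 1, 0.5)
  lr <- lrt_test(y, x)
  tt <- corr_t_test(y, x)
  expect_equal(lr$stat, -30 * log(1 - tt$r^2), tolerance = 1e-10)
  # both tests order hypotheses identically
  expect_equal(sign(log(lr$p_nominal) - log(0.05)) == 1,
               lr$p_nominal > 0.05)
})

test_that("permutation test: extreme case, determinism, analytic cross-check", {
  set.seed(43)
  n <- 40
  x <- matrix(rbinom(n, 1, 0.5), 1, n)
  y <- 3 * x[1, ] + rnorm(n, 0, 0.3)
  pt1 <- permutation_test(y, x, n_perm = 200, seed = 5)
  expect_equal(pt1$p, 1 / 201)               # beats every permutation
  pt2 <- permutation_test(y, x, n_perm = 200, seed = 5)
  expect_identical(pt1, pt2)
  expect_error(permutation_test(y, x, n_perm = 10), "n_perm")

  # single SNP, moderate signal: empirical p within Monte-Carlo error of
  # the analytic correlation-test p
  y2 <- 0.45 * x[1, ] + rnorm(n, 0, 1)
  p_perm <- permutation_test(y2, x, n_perm = 1e4, seed = 6)$p
  p_t <- corr_t_test(y2, x[1, ])$p_nominal
  mc_sd <- sqrt(p_t * (1 - p_t) / 1e4)
  expect_lt(abs(p_perm - p_t), 3 * mc_sd + 2 / 1e4)
})

test_that("per-gene Bonferroni control caps at one", {
  expect_equal(bonferroni_per_gene(0.03, 1), 0.03)
  expect_equal(bonferroni_per_gene(1e-6, 55000), 0.055)
  expect_equal(bonferroni_per_gene(0.5, 10), 1)
  expect_true(all(diff(bonferroni_per_gene(c(1e-5, 1e-4, 1e-2), 50)) > 0))
})

test_that("cis/trans classification honours window and chromosome modes", {
  expect_equal(classify_location("chr1", 2e6, "chr1", 2.9e6, "window"), "cis")
  expect_equal(classify_location("chr1", 2e6, "chr1", 3e6, "window"), "cis")
  expect_equal(classify_location("chr1", 2e6, "chr1", 3.5e6, "window"),
               "trans")
  expect_equal(classify_location("chr1", 2e6, "chr2", 2e6, "window"), "trans")
  expect_equal(classify_location("chr1", 1e6, "chr1", 9e7, "chromosome"),
               "cis")
  expect_equal(classify_location("chr1", 1e6, "chr2", 1e6, "chromosome"),
               "trans")
  expect_error(classify_location("chr1", NA, "chr1", 5), "missing annotation")
})

test_that("scan on null data is calibrated at the nominal per-gene FPR", {
  set.seed(44)
  G <- 400; N <- 60; S <- 30
  Y <- matrix(rnorm(G * N), G, N)
  X <- matrix(rbinom(S * N, 1, 0.5), S, N)
  scan <- map_eqtls(Y, X, test = "ttest", fpr = 0.05, mode = "none")
  n_sig <- scan$summary$n_significant
  expect_lt(abs(n_sig - 0.05 * G), 3 * sqrt(G * 0.05 * 0.95) + 1)
})

test_that("planted strong cis effects are recovered on clean residuals", {
  set.seed(45)
  sim <- simulate_eqtl_study(sim_config(G = 150, N = 80, S = 60,
                                        n_hidden = 0, n_known = 0,
                                        n_hotspots = 0,
                                        effect_size_range = c(3, 4),
                                        noise_sd_range = c(0.3, 0.4),
                                        seed = 45))
  scan <- map_eqtls(sim$expr, sim$geno, sim$annotations, test = "ttest",
                    fpr = 0.001, mode = "window")
  sens <- eqtl_sensitivity(scan, sim$truth, "immediate")
  expect_gte(sens$sensitivity, 0.95)
  expect_gte(sens$specificity, 0.98)
  # called cis eQTLs sit within the annotation window by construction
  sig <- scan$results[scan$results$significant, ]
  expect_gt(mean(sig$location_class == "cis"), 0.9)
})

test_that("t, rank and permutation tests call nearly the same gene sets", {
  set.seed(46)
  sim <- simulate_eqtl_study(sim_config(G = 120, N = 80, S = 40,
                                        n_hidden = 0, n_known = 0,
                                        n_hotspots = 0,
                                        effect_size_range = c(2, 3.5),
                                        noise_sd_range = c(0.5, 0.8),
                                        seed = 46))
  sets <- lapply(c("ttest", "rank", "perm"), function(tst)
    which(map_eqtls(sim$expr, sim$geno, test = tst, fpr = 0.001,
                    mode = "none", n_perm = 1000,
                    seed = 46)$results$significant))
  for (i in 2:3) {
    sym <- length(union(sets[[1]], sets[[i]])) -
      length(intersect(sets[[1]], sets[[i]]))
    expect_lte(sym / max(1, length(union(sets[[1]], sets[[i]]))), 0.05)
  }
})

test_that("empirical FDR is near one on null data and small with signal", {
  set.seed(47)
  G <- 100; N <- 50; S <- 20
  Ynull <- matrix(rnorm(G * N), G, N)
  X <- matrix(rbinom(S * N, 1, 0.5), S, N)
  scan0 <- map_eqtls(Ynull, X, test = "ttest", fpr = 0.2, mode = "none")
  f0 <- empirical_fdr(scan0, Ynull, X, n_perm = 10, seed = 1)
  if (f0$n_observed > 0) expect_gt(f0$fdr, 0.5)

  sim <- simulate_eqtl_study(sim_config(G = G, N = N, S = S, n_hidden = 0,
                                        n_known = 0, n_hotspots = 0,
                                        effect_size_range = c(3, 4),
                                        noise_sd_range = c(0.3, 0.4),
                                        seed = 47))
  scan1 <- map_eqtls(sim$expr, sim$geno, test = "ttest", fpr = 0.001,
                     mode = "none")
  f1 <- empirical_fdr(scan1, sim$expr, sim$geno, n_perm = 10, seed = 2)
  expect_lt(f1$fdr, 0.05)
  f1b <- empirical_fdr(scan1, sim$expr, sim$geno, n_perm = 10, seed = 2)
  expect_identical(f1, f1b)
})
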