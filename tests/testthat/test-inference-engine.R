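test_that("residual_for subtracts exactly the other components' means", {
  sim <- tiny_sim(G = 20, N = 10, S = 8, seed = 20)
  fit <- vbfit(sim$expr, sim$geno, sim$covs, K = 3,
               control = vb_control(max_iter = 10))
  comps <- Filter(Negate(is.null), fit$components)
  for (active in names(comps)) {
    # brute-force oracle: direct summation over the other components
    expected <- fit$Yc
    for (nm in setdiff(names(comps), active))
      expected <- expected - comps[[nm]]$C
    expect_equal(residual_for(fit, active), expected, tolerance = 1e-12)
  }
  # algebraic identity: residual_for(A) + mean(A) is the same for all A
  tot <- lapply(names(comps), function(nm)
    residual_for(fit, nm) - comps[[nm]]$C)
  for (i in seq_along(tot)[-1])
    expect_equal(tot[[1]], tot[[i]], tolerance = 1e-12)
  expect_error(residual_for(fit, "nonsense"), "unknown component")
})

test_that("missing entries propagate through residuals", {
  sim <- tiny_sim(G = 15, N = 12, S = 5, seed = 21)
  Y <- sim$expr$values
  Y[2, 3] <- NA
  fit <- vbfit(expression_matrix(Y), covs = sim$covs, K = 2,
               control = vb_control(max_iter = 10))
  expect_true(is.na(residual_for(fit, "hidden")[2, 3]))
  expect_monotone_bound(fit)
})

test_that("noise update recovers the hand-computed gamma posterior", {
  # no components, broad prior, one gene with values {+1, -1}
  # (gene mean is zero, so centring leaves the data untouched)
  Y <- matrix(c(1, -1), 1, 2)
  fit <- vbfit(Y, K = 0, control = vb_control())
  ns <- update_noise(fit)
  expect_equal(ns$shape, 1e-3 + 1, ignore_attr = TRUE)
  expect_equal(ns$rate, 1e-3 + 1, ignore_attr = TRUE)  # E[RSS] = 2
  expect_equal(ns$expected_precision, 1, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("an exact fit leaves the prior rate untouched", {
  # contributions reproduce Y with zero posterior variance
  Y <- matrix(rnorm(12), 3, 4)
  comps <- list(list(mean = Y, var = matrix(0, 3, 4)))
  sse <- expected_residual_ss(Y, comps)
  expect_equal(sse, rep(0, 3))
})

test_that("expected residual sum of squares matches Monte-Carlo sampling", {
  set.seed(22)
  G <- 3; N <- 5
  Y <- matrix(rnorm(G * N), G, N)
  comps <- list(
    list(mean = matrix(rnorm(G * N), G, N),
         var = matrix(rexp(G * N, 2), G, N)),
    list(mean = matrix(rnorm(G * N), G, N),
         var = matrix(rexp(G * N, 2), G, N))
  )
  sse <- expected_residual_ss(Y, comps)
  ndraw <- 1e5
  mc <- matrix(0, G, 1)
  acc <- numeric(G)
  for (d in seq_len(ndraw)) {
    Ctot <- matrix(0, G, N)
    for (co in comps)
      Ctot <- Ctot + co$mean + matrix(rnorm(G * N), G, N) * sqrt(co$var)
    acc <- acc + rowSums((Y - Ctot)^2)
  }
  expect_equal(sse, acc / ndraw, tolerance = 0.01)
})

test_that("a K = 0 fit with no genotypes reduces to the per-gene noise model", {
  Y <- matrix(rnorm(40), 8, 5)
  fit <- vbfit(Y, K = 0, control = vb_control(max_iter = 5))
  expect_null(fit$components$hidden)
  expect_null(fit$components$genetic)
  expect_equal(residual_for(fit, "noise"), Y - rowMeans(Y),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("noiseless rank-1 data is reproduced by a single surviving factor", {
  set.seed(23)
  Y <- tcrossprod(rnorm(50), rnorm(20))
  fit <- vbfit(Y, K = 5, control = vb_control(max_iter = 300))
  expect_monotone_bound(fit)
  expect_length(active_factors(fit), 1)
  relerr <- norm(fit$Yc - fit$components$hidden$C, "F") / norm(fit$Yc, "F")
  expect_lt(relerr, 1e-3)
})

test_that("the bound matches an independently coded scalar-case evaluation", {
  # single gene, single factor, conjugate model: recompute every bound term
  # from the state with scalar formulas
  set.seed(24)
  Y <- matrix(rnorm(6, 0, 1.2), 1, 6)
  ctl <- vb_control()          # gene centring, so no intercept covariate
  fit <- vbfit(Y, K = 1, control = ctl)
  Y <- fit$Yc                  # bound is evaluated on the centred data
  st <- fit$components$hidden
  a0 <- ctl$ard_shape; b0 <- ctl$ard_rate
  an <- ctl$noise_shape; bn <- ctl$noise_rate
  N <- 6
  Eww <- st$loadings_Evv[1, 1]
  vw <- Eww - st$loadings_mean[1]^2
  Exx <- st$activations_Evv[, 1]
  vx <- Exx - st$activations_mean[, 1]^2
  atau <- fit$noise$shape; btau <- fit$noise$rate
  Etau <- atau / btau; Elogtau <- digamma(atau) - log(btau)
  sse <- sum((Y[1, ] - st$C[1, ])^2 + st$V[1, ])
  gamma_term <- function(a0, b0, a, b) {
    a0 * log(b0) - lgamma(a0) + (a0 - 1) * (digamma(a) - log(b)) -
      b0 * a / b + a - log(b) + lgamma(a) + (1 - a) * digamma(a)
  }
  Ealpha <- st$ard_shape / st$ard_rate
  Elogalpha <- digamma(st$ard_shape) - log(st$ard_rate)
  manual <-
    N / 2 * (Elogtau - log(2 * pi)) - Etau * sse / 2 +
    gamma_term(an, bn, atau, btau) +
    0.5 * (Elogalpha - log(2 * pi)) - Ealpha * Eww / 2 +
    0.5 * log(2 * pi * exp(1) * vw) +
    sum(-0.5 * log(2 * pi) - Exx / 2) +
    sum(0.5 * log(2 * pi * exp(1) * vx)) +
    gamma_term(a0, b0, st$ard_shape, st$ard_rate)
  expect_equal(variational_bound(fit), manual, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("perturbing the noise state lowers the bound; its update restores it", {
  sim <- tiny_sim(G = 30, N = 20, S = 10, seed = 25)
  fit <- vbfit(sim$expr, covs = sim$covs, K = 3,
               control = vb_control(max_iter = 50))
  b_opt <- variational_bound(fit)
  pert <- fit
  pert$noise$rate <- pert$noise$rate * 2   # halve the expected precision
  expect_lt(variational_bound(pert), b_opt)
  ns <- update_noise(pert)
  pert$noise <- list(shape = ns$shape, rate = ns$rate)
  expect_gte(variational_bound(pert) + 1e-9 * abs(b_opt), b_opt)
})

test_that("fits are bitwise deterministic given identical inputs", {
  sim <- tiny_sim(G = 40, N = 25, S = 12, seed = 26)
  f1 <- vbfit(sim$expr, sim$geno, sim$covs, K = 4,
              control = vb_control(max_iter = 30))
  f2 <- vbfit(sim$expr, sim$geno, sim$covs, K = 4,
              control = vb_control(max_iter = 30))
  expect_identical(f1$bound_trace, f2$bound_trace)
  expect_identical(f1$components$hidden$loadings_mean,
                   f2$components$hidden$loadings_mean)
})

test_that("K larger than N is clamped with a warning", {
  Y <- matrix(rnorm(200), 20, 10)
  expect_warning(fit <- vbfit(Y, K = 15, control = vb_control(max_iter = 5)),
                 "clamping")
  expect_identical(fit$K, 10L)
})

test_that("corrected expression removes exactly the requested components", {
  sim <- tiny_sim(G = 30, N = 20, S = 10, seed = 27)
  fit <- vbfit(sim$expr, sim$geno, sim$covs, K = 3,
               control = vb_control(max_iter = 30))
  expect_identical(corrected_expression(fit, character(0))$values,
                   sim$expr$values)
  ce <- corrected_expression(fit)    # default removes known + hidden
  expect_equal(ce$values,
               sim$expr$values - fit$components$known$C -
                 fit$components$hidden$C, tolerance = 1e-12)
  expect_error(corrected_expression(vbfit(sim$expr, K = 2,
                                          control = vb_control(max_iter = 3)),
                                    remove = "known"),
               "not fitted")
})

test_that("schedules find the same associations when genetics is orthogonal", {
  # no hotspots: genetic signal independent of the global factors; the
  # cheaper two-stage schedule then finds the same associations as the
  # joint schedule
  sim <- simulate_eqtl_study(sim_config(G = 200, N = 80, S = 60,
                                        n_hotspots = 0, seed = 28))
  ctl <- vb_control(max_iter = 150)
  fj <- vbfit(sim$expr, sim$geno, sim$covs, K = 10, "joint", ctl)
  ft <- vbfit(sim$expr, sim$geno, sim$covs, K = 10, "two-stage", ctl)
  sj <- which(map_eqtls(corrected_expression(fj), sim$geno, test = "ttest",
                        fpr = 0.001, mode = "none")$results$significant)
  st <- which(map_eqtls(corrected_expression(ft), sim$geno, test = "ttest",
                        fpr = 0.001, mode = "none")$results$significant)
  sym <- length(union(sj, st)) - length(intersect(sj, st))
  expect_lte(sym / max(1, length(union(sj, st))), 0.05)
  expect_monotone_bound(fj)
  expect_monotone_bound(ft)
})

test_that("a fitted model round-trips through the text archive", {
  sim <- tiny_sim(G = 15, N = 10, S = 6, seed = 29)
  fit <- vbfit(sim$expr, sim$geno, sim$covs, K = 2,
               control = vb_control(max_iter = 10))
  dir <- withr::local_tempdir()
  save_vbfit(fit, dir)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$K, fit$K)
  expect_equal(meta$bound_trace, fit$bound_trace, tolerance = 1e-12)
  W <- as.matrix(read.table(file.path(dir, "hidden_loadings_mean.tsv")))
  expect_equal(unname(W), unname(fit$components$hidden$loadings_mean),
               tolerance = 1e-12)
})
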