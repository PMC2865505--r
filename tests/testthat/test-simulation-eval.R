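test_that("component contributions sum exactly to the expression matrix", {
  sim <- tiny_sim(G = 80, N = 40, S = 30, seed = 50)
  tr <- sim$truth
  total <- tr$genetic_cis + tr$genetic_hotspot + tr$known + tr$hidden +
    tr$noise
  expect_equal(unname(sim$expr$values), total, tolerance = 1e-12)
})

test_that("zero-magnitude config produces pure noise with empty truth", {
  sim <- simulate_eqtl_study(sim_config(G = 30, N = 20, S = 10,
                                        effect_size_range = c(0, 0),
                                        factor_scale_range = c(0, 0),
                                        seed = 51))
  expect_equal(max(abs(sim$truth$genetic_cis)), 0)
  expect_equal(max(abs(sim$truth$genetic_hotspot)), 0)
  expect_equal(max(abs(sim$truth$known)), 0)
  expect_equal(max(abs(sim$truth$hidden)), 0)
  expect_equal(unname(sim$expr$values), sim$truth$noise, tolerance = 1e-12)
})

test_that("default configuration carries 7 hidden and 3 hotspot factors", {
  cf <- sim_config()
  expect_equal(cf$n_hidden, 7)
  expect_equal(cf$n_hotspots, 3)
  expect_equal(cf$n_known, 3)
  expect_equal(cf$hotspot_target_frac, 0.15)
  sim <- tiny_sim(G = 100, N = 30, S = 40, seed = 52)
  expect_length(sim$truth$regulator_genes, 3)
  expect_length(sim$truth$hotspot_targets, 3)
  expect_length(sim$truth$hotspot_targets[[1]], round(0.15 * 100))
  # regulators have a cis eQTL; their targets do not
  expect_true(all(!is.na(sim$truth$eqtl_map[sim$truth$regulator_genes])))
  expect_true(all(is.na(sim$truth$eqtl_map[unlist(sim$truth$hotspot_targets)])))
})

test_that("the generator is deterministic and rejects infeasible configs", {
  a <- tiny_sim(seed = 53)
  b <- tiny_sim(seed = 53)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$truth$eqtl_map, b$truth$eqtl_map)
  expect_error(simulate_eqtl_study(sim_config(G = 20, N = 10, S = 10,
                                              frac_cis_genes = 0.1,
                                              n_hotspots = 3, seed = 1)),
               "regulators")
})

test_that("contribution MSE matches a direct elementwise computation", {
  sim <- tiny_sim(G = 5, N = 4, S = 3, seed = 54, n_hotspots = 1,
                  n_known = 1, n_hidden = 2, frac_cis_genes = 0.4)
  tr <- sim$truth
  est <- matrix(rnorm(20), 5, 4)
  want <- mean((est - tr$hidden)^2)
  expect_equal(mse_contribution(est, tr, "hidden"), want, tolerance = 1e-12)
  want2 <- mean((est - tr$hidden - tr$genetic_hotspot)^2)
  expect_equal(mse_contribution(est, tr, "hidden+genetic_global"), want2,
               tolerance = 1e-12)
  expect_equal(mse_contribution(tr$hidden, tr, "hidden"), 0)
  expect_equal(mse_contribution(matrix(0, 5, 4), tr, "hidden"),
               mean(tr$hidden^2))
  expect_error(mse_contribution(matrix(0, 2, 2), tr, "hidden"), "shape")
})

test_that("eQTL recovery metrics agree with a brute-force set comparison", {
  sim <- tiny_sim(G = 50, N = 30, S = 25, seed = 55)
  tr <- sim$truth
  # construct calls: all true immediate pairs + 2 false positives
  res <- data.frame(gene_id = sim$expr$gene_ids,
                    snp_index = NA_integer_, significant = FALSE)
  cis <- which(!is.na(tr$eqtl_map))
  res$snp_index[cis] <- tr$eqtl_map[cis]
  res$significant[cis] <- TRUE
  nulls <- setdiff(seq_len(50), union(cis, unlist(tr$hotspot_targets)))
  fp <- nulls[1:2]
  res$significant[fp] <- TRUE
  res$snp_index[fp] <- 1L
  got <- eqtl_sensitivity(res, tr, "immediate")
  expect_equal(got$sensitivity, 1)
  expect_equal(got$specificity, 1 - 2 / length(nulls))
  # brute force recount
  rec <- sum(vapply(cis, function(g)
    res$significant[g] && res$snp_index[g] == tr$eqtl_map[g], logical(1)))
  expect_equal(got$n_recovered, rec)

  empty <- res; empty$significant <- FALSE
  e <- eqtl_sensitivity(empty, tr, "immediate")
  expect_equal(e$sensitivity, 0)
  expect_equal(e$specificity, 1)

  # downstream: exactly the target -> regulator-SNP pairs
  res2 <- data.frame(gene_id = sim$expr$gene_ids,
                     snp_index = NA_integer_, significant = FALSE)
  for (h in seq_along(tr$hotspot_targets)) {
    tg <- tr$hotspot_targets[[h]]
    res2$snp_index[tg] <- tr$regulator_snps[h]
    res2$significant[tg] <- TRUE
  }
  d <- eqtl_sensitivity(res2, tr, "downstream")
  # brute-force oracle over the target -> regulator-SNP pairs (genes hit by
  # two hotspots can only carry one call, so recompute the expectation)
  hits <- 0; npairs <- 0
  for (h in seq_along(tr$hotspot_targets)) for (g in tr$hotspot_targets[[h]]) {
    npairs <- npairs + 1
    hits <- hits + (res2$significant[g] &&
                      res2$snp_index[g] == tr$regulator_snps[h])
  }
  expect_equal(d$sensitivity, hits / npairs)
  expect_equal(d$specificity, 1)
})

test_that("benchmark table carries the expected reference rows", {
  cf <- sim_config(G = 100, N = 40, S = 30, seed = 56)
  tab <- run_benchmark(cf, methods = c("standard", "ideal", "pca"),
                       K_grid = c(2, 5),
                       control = vb_control(max_iter = 20))
  expect_error(run_benchmark(cf, methods = "nonsense"), "unknown method")
  std <- tab[tab$method == "standard", ]
  sim <- simulate_eqtl_study(cf)
  expect_equal(std$mse_hidden, mean(sim$truth$hidden^2), tolerance = 1e-12)
  expect_equal(std$mse_combined,
               mean((sim$truth$hidden + sim$truth$genetic_hotspot)^2),
               tolerance = 1e-12)
  expect_equal(nrow(tab[tab$method == "pca", ]), 2)
  # deterministic given the config seed
  tab2 <- run_benchmark(cf, methods = c("standard", "ideal", "pca"),
                        K_grid = c(2, 5),
                        control = vb_control(max_iter = 20))
  expect_identical(tab, tab2)
})
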