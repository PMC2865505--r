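# Shared fixtures and oracles for the test suite; everything is generated
# in code at test time.

# small simulated study (fast default sizes for unit tests)
tiny_sim <- function(G = 60, N = 30, S = 20, seed = 1, ...) {
  simulate_eqtl_study(sim_config(G = G, N = N, S = S, seed = seed, ...))
}

expect_monotone_bound <- function(fit, tol = 1e-6) {
  bt <- fit$bound_trace
  if (length(bt) >= 2) {
    drops <- diff(bt) + tol * abs(bt[-1])
    expect_true(all(drops >= 0),
                label = sprintf("bound trace non-decreasing (min step %.3g)",
                                min(diff(bt))))
  }
  invisible(fit)
}

# independent textbook computation of the correlation t-test
oracle_corr_t <- function(y, x) {
  n <- length(y)
  r <- sum((y - mean(y)) * (x - mean(x))) /
    sqrt(sum((y - mean(y))^2) * sum((x - mean(x))^2))
  tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * pt(-abs(tt), df = n - 2)
  list(r = r, stat = tt, p = p)
}

# write a matrix as the TSV layout read_expression() expects
write_expr_tsv <- function(values, path) {
  df <- data.frame(id = rownames(values), values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
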