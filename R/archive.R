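#' Save a fitted model to a plain-text archive
#'
#' Writes the posterior summaries as tab-separated arrays plus a JSON
#' metadata block (hyperparameters, ids, schedule, bound trace) into a
#' directory, so a fit can be inspected or reloaded without R serialisation.
#'
#' @param fit A [vbfit()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_vbfit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, name) {
    utils::write.table(m, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  meta <- list(schedule = fit$schedule, K = fit$K,
               control = unclass(fit$control),
               gene_ids = fit$gene_ids, individual_ids = fit$individual_ids,
               snp_ids = fit$snp_ids, bound_trace = fit$bound_trace,
               converged = fit$converged, n_iter = fit$n_iter,
               components = names(Filter(Negate(is.null), fit$components)))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  wr(cbind(fit$noise$shape, fit$noise$rate), "noise_gamma")
  wr(fit$gene_means, "gene_means")
  if (!is.null(fit$components$hidden)) {
    h <- fit$components$hidden
    wr(h$loadings_mean, "hidden_loadings_mean")
    wr(h$activations_mean, "hidden_activations_mean")
    wr(cbind(h$ard_shape, h$ard_rate), "hidden_ard_gamma")
    wr(h$C, "hidden_contribution")
  }
  if (!is.null(fit$components$known)) {
    k <- fit$components$known
    wr(k$weights_mean, "known_weights_mean")
    wr(cbind(k$ard_shape, k$ard_rate), "known_ard_gamma")
    wr(k$C, "known_contribution")
  }
  if (!is.null(fit$components$genetic)) {
    utils::write.table(genetic_effects(fit),
                       file.path(dir, "genetic_effects.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    wr(fit$components$genetic$C, "genetic_contribution")
  }
  invisible(dir)
}

#' Export factor activations as TSV (individuals x factors)
#'
#' @param fit A [vbfit()] object with a hidden component.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_factors <- function(fit, path) {
  A <- factor_activations(fit)
  utils::write.table(data.frame(individual_id = rownames(A), A,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
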