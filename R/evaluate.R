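# Evaluation of confounder-recovery and eQTL-recovery performance against
# simulation ground truth.

#' Estimated confounding contribution of a method
#'
#' For a fitted [vbfit()] object, the posterior-mean hidden factor
#' contribution (optionally plus the genetic contribution, for comparisons
#' against hidden-plus-genetic truth). For an `expression_correction`, the
#' variance removed beyond the known covariates: the standard-corrected
#' residuals minus the method's residuals.
#'
#' @param object A [vbfit()] or `expression_correction` object.
#' @param Y,covs Original data (required for `expression_correction` input).
#' @param include_genetic Add the genetic component's contribution (`vbfit`
#'   only).
#' @return G x N numeric matrix.
#' @export
estimated_confounding <- function(object, Y = NULL, covs = NULL,
                                  include_genetic = FALSE) {
  if (inherits(object, "vbfit")) {
    est <- if (!is.null(object$components$hidden))
      object$components$hidden$C else matrix(0, nrow(object$Yc), ncol(object$Yc))
    if (include_genetic && !is.null(object$components$genetic))
      est <- est + object$components$genetic$C
    return(est)
  }
  if (inherits(object, "expression_correction")) {
    if (is.null(Y)) stop("Y is required for expression_correction input")
    std <- correct_standard(Y, covs)
    return(std$residuals$values - object$residuals$values)
  }
  stop("unsupported object")
}

#' Mean squared error of an estimated confounding contribution
#'
#' Mean over all matrix entries of the squared difference between an
#' estimated contribution and the selected ground-truth component sum.
#'
#' @param estimated G x N matrix (e.g. from [estimated_confounding()]).
#' @param truth The `truth` element of [simulate_eqtl_study()] output.
#' @param which `"hidden"` (hidden factors only) or `"hidden+genetic_global"`
#'   (hidden plus hotspot contributions).
#' @return Scalar MSE.
#' @export
mse_contribution <- function(estimated, truth,
                             which = c("hidden", "hidden+genetic_global")) {
  which <- match.arg(which)
  target <- truth$hidden
  if (which == "hidden+genetic_global") target <- target + truth$genetic_hotspot
  estimated <- as.matrix(estimated)
  if (!identical(dim(estimated), dim(target)))
    stop("shape mismatch between estimate and truth")
  mean((estimated - target)^2)
}

#' Sensitivity and specificity of eQTL recovery
#'
#' Immediate associations are gene-to-causal-SNP pairs of the simulated eQTL
#' map; downstream associations are hotspot-target-gene-to-regulator-SNP
#' pairs. A call counts as correct when the gene is significant and its
#' called SNP is the causal one (or within `snp_window` indices of it).
#' Specificity is computed over true-null genes (no immediate/downstream
#' effect respectively).
#'
#' @param calls An `eqtl_scan` from [map_eqtls()] or its `results`
#'   data.frame.
#' @param truth The `truth` element of [simulate_eqtl_study()] output.
#' @param which `"immediate"` or `"downstream"`.
#' @param snp_window Allowed index distance between called and causal SNP.
#' @return List with `sensitivity`, `specificity`, `n_true`, `n_recovered`.
#' @export
eqtl_sensitivity <- function(calls, truth,
                             which = c("immediate", "downstream"),
                             snp_window = 0L) {
  which <- match.arg(which)
  res <- if (inherits(calls, "eqtl_scan")) calls$results else calls
  G <- length(truth$eqtl_map)
  hit <- function(called, causal)
    !is.na(called) & abs(called - causal) <= snp_window
  # true nulls: genes with neither a cis eQTL nor a hotspot regulator acting
  # on them (hotspot targets carry a real association to the regulator SNP)
  affected <- union(which(!is.na(truth$eqtl_map)),
                    unlist(truth$hotspot_targets))
  null_genes <- setdiff(seq_len(G), affected)
  if (which == "immediate") {
    true_genes <- which(!is.na(truth$eqtl_map))
    causal <- truth$eqtl_map[true_genes]
    rec <- res$significant[true_genes] &
      hit(res$snp_index[true_genes], causal)
  } else {
    pairs_gene <- integer(0); pairs_snp <- integer(0)
    for (h in seq_along(truth$hotspot_targets)) {
      tg <- truth$hotspot_targets[[h]]
      pairs_gene <- c(pairs_gene, tg)
      pairs_snp <- c(pairs_snp, rep(truth$regulator_snps[h], length(tg)))
    }
    rec <- res$significant[pairs_gene] &
      hit(res$snp_index[pairs_gene], pairs_snp)
  }
  sens <- if (length(rec)) mean(rec) else NA_real_
  spec <- if (length(null_genes)) mean(!res$significant[null_genes])
          else NA_real_
  list(sensitivity = sens, specificity = spec,
       n_true = length(rec), n_recovered = sum(rec))
}

#' Benchmark confounder-correction methods on simulated data
#'
#' Generates one dataset from `config`, applies each requested method across
#' its settings grid, and reports confounder-recovery MSEs, immediate and
#' downstream eQTL sensitivity/specificity, and the number of components
#' used. `"ideal"` removes the simulated known and hidden contributions
#' exactly (genetic signal kept); `"standard"` removes only the covariate
#' fit.
#'
#' @param config A [sim_config()].
#' @param methods Subset of `c("standard", "ideal", "pca", "pcasig", "sva",
#'   "two-stage", "joint")`.
#' @param K_grid Component counts for `"pca"`, `"two-stage"`, `"joint"`.
#' @param alpha_grid Significance cutoffs for `"pcasig"`, `"sva"`.
#' @param test,fpr,mode Association-test settings (see [map_eqtls()]).
#' @param n_perm Permutations for the eigenvalue tests.
#' @param control [vb_control()] for the variational fits.
#' @return data.frame with one row per method x setting.
#' @export
run_benchmark <- function(config = sim_config(),
                          methods = c("standard", "ideal", "pca",
                                      "two-stage", "joint"),
                          K_grid = c(10), alpha_grid = c(0.01),
                          test = "ttest", fpr = 0.001, mode = "none",
                          n_perm = 100, control = vb_control()) {
  known_methods <- c("standard", "ideal", "pca", "pcasig", "sva",
                     "two-stage", "joint")
  bad <- setdiff(methods, known_methods)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  sim <- simulate_eqtl_study(config)
  Y <- sim$expr; covs <- sim$covs; geno <- sim$geno
  ann <- if (mode == "none") NULL else sim$annotations

  eval_one <- function(method, setting, est, resid, n_comp) {
    scan <- map_eqtls(resid, geno, ann, test = test, fpr = fpr, mode = mode)
    imm <- eqtl_sensitivity(scan, sim$truth, "immediate")
    dwn <- eqtl_sensitivity(scan, sim$truth, "downstream")
    data.frame(method = method, setting = setting, n_components = n_comp,
               mse_hidden = mse_contribution(est, sim$truth, "hidden"),
               mse_combined = mse_contribution(est, sim$truth,
                                               "hidden+genetic_global"),
               sens_immediate = imm$sensitivity,
               spec_immediate = imm$specificity,
               sens_downstream = dwn$sensitivity,
               n_significant = scan$summary$n_significant,
               stringsAsFactors = FALSE)
  }

  G <- nrow(Y$values); N <- ncol(Y$values)
  rows <- list()
  for (m in methods) {
    if (m == "standard") {
      cr <- correct_standard(Y, covs)
      rows[[length(rows) + 1]] <-
        eval_one(m, NA_real_, matrix(0, G, N), cr$residuals, 0L)
    } else if (m == "ideal") {
      ideal <- Y$values - sim$truth$hidden - sim$truth$known
      ideal <- ideal - rowMeans(ideal)
      rows[[length(rows) + 1]] <-
        eval_one(m, NA_real_, sim$truth$hidden, ideal, NA_integer_)
    } else if (m == "pca") {
      for (K in K_grid) {
        cr <- correct_pca(Y, covs, K)
        est <- estimated_confounding(cr, Y, covs)
        rows[[length(rows) + 1]] <- eval_one(m, K, est, cr$residuals, K)
      }
    } else if (m %in% c("pcasig", "sva")) {
      for (a in alpha_grid) {
        cr <- if (m == "pcasig")
          correct_pcasig(Y, covs, alpha = a, n_perm = n_perm,
                         seed = config$seed)
        else correct_sva(Y, covs, alpha = a, n_perm = n_perm,
                         seed = config$seed)
        est <- estimated_confounding(cr, Y, covs)
        rows[[length(rows) + 1]] <-
          eval_one(m, a, est, cr$residuals, cr$n_components)
      }
    } else {
      sched <- if (m == "joint") "joint" else "two-stage"
      for (K in K_grid) {
        fit <- vbfit(Y, geno, covs, K = K, schedule = sched,
                     control = control)
        est <- estimated_confounding(fit)
        rows[[length(rows) + 1]] <-
          eval_one(m, K, est, corrected_expression(fit),
                   length(active_factors(fit)))
      }
    }
  }
  do.call(rbind, rows)
}
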