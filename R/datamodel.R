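#' Construct an expression matrix object
#'
#' Container for a genes x individuals matrix of expression values with an
#' observation mask. Missing measurements are kept as `NA` in `values` and
#' flagged `FALSE` in `mask`.
#'
#' @param values Numeric matrix, genes in rows, individuals in columns.
#' @param gene_ids Character vector of unique gene/probe identifiers (rows).
#' @param individual_ids Character vector of unique sample identifiers (columns).
#' @param mask Logical matrix of the same shape; `TRUE` marks an observed entry.
#'   Defaults to `!is.na(values)`.
#' @return An object of class `"expression_matrix"`: a list with elements
#'   `values`, `gene_ids`, `individual_ids`, `mask`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              individual_ids = colnames(values),
                              mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(values)))
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  individual_ids <- as.character(individual_ids)
  if (length(gene_ids) != nrow(values))
    stop("length(gene_ids) != nrow(values)")
  if (length(individual_ids) != ncol(values))
    stop("length(individual_ids) != ncol(values)")
  .check_unique(gene_ids, "gene id")
  .check_unique(individual_ids, "individual id")
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(values))) stop("mask shape does not match values")
  values[!mask] <- NA_real_
  if (any(!is.finite(values[mask])))
    stop("observed expression entries must be finite")
  dimnames(values) <- list(gene_ids, individual_ids)
  dimnames(mask) <- dimnames(values)
  structure(list(values = values, gene_ids = gene_ids,
                 individual_ids = individual_ids, mask = mask),
            class = "expression_matrix")
}

#' Construct a genotype matrix object
#'
#' SNPs x individuals integer genotype codes: `{0,1}` for haploid/inbred-cross
#' data or additive dosages `{0,1,2}` for diploids. Missing genotypes are
#' coded `-1`.
#'
#' @param values Integer matrix, SNPs in rows, individuals in columns.
#' @param snp_ids,individual_ids Unique identifiers for rows / columns.
#' @param chrom Character vector, chromosome per SNP.
#' @param pos_bp Positive integer vector, 1-based position per SNP.
#' @param ploidy 1 or 2; declares the allowed code alphabet.
#' @return Object of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(values, snp_ids = rownames(values),
                            individual_ids = colnames(values),
                            chrom = NULL, pos_bp = NULL, ploidy = 2) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(nrow(values)))
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(ncol(values)))
  snp_ids <- as.character(snp_ids)
  individual_ids <- as.character(individual_ids)
  .check_unique(snp_ids, "SNP id")
  .check_unique(individual_ids, "individual id")
  if (!ploidy %in% c(1L, 2L)) stop("ploidy must be 1 or 2")
  values[is.na(values)] <- -1L
  alphabet <- c(-1L, 0L:as.integer(ploidy))
  bad <- which(!(values %in% alphabet))
  if (length(bad)) {
    bad_snp <- snp_ids[((bad[1] - 1) %% nrow(values)) + 1]
    stop(sprintf("genotype code outside {%s} alphabet at SNP '%s'",
                 paste(alphabet, collapse = ","), bad_snp))
  }
  if (is.null(chrom)) chrom <- rep(NA_character_, nrow(values))
  if (is.null(pos_bp)) pos_bp <- rep(NA_integer_, nrow(values))
  chrom <- as.character(chrom)
  pos_bp <- as.integer(pos_bp)
  if (length(chrom) != nrow(values) || length(pos_bp) != nrow(values))
    stop("chrom/pos_bp length must equal the number of SNPs")
  if (any(!is.na(pos_bp) & pos_bp < 1L)) stop("pos_bp must be positive (1-based)")
  dimnames(values) <- list(snp_ids, individual_ids)
  structure(list(values = values, snp_ids = snp_ids,
                 individual_ids = individual_ids,
                 chrom = chrom, pos_bp = pos_bp, ploidy = as.integer(ploidy)),
            class = "genotype_matrix")
}

#' Construct a covariate matrix object
#'
#' Known covariates x individuals (e.g. gender indicator, batch, environment).
#' Binary covariates should be coded 0/1.
#'
#' @param values Numeric matrix, covariates in rows, individuals in columns.
#' @param covariate_ids,individual_ids Unique identifiers.
#' @return Object of class `"covariate_matrix"`.
#' @export
covariate_matrix <- function(values, covariate_ids = rownames(values),
                             individual_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(covariate_ids)) covariate_ids <- paste0("cov", seq_len(nrow(values)))
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(ncol(values)))
  covariate_ids <- as.character(covariate_ids)
  individual_ids <- as.character(individual_ids)
  .check_unique(covariate_ids, "covariate id")
  .check_unique(individual_ids, "individual id")
  if (any(!is.finite(values))) stop("covariate values must be finite")
  dimnames(values) <- list(covariate_ids, individual_ids)
  structure(list(values = values, covariate_ids = covariate_ids,
                 individual_ids = individual_ids),
            class = "covariate_matrix")
}

#' Probe annotation table
#'
#' @param gene_id Character vector of unique gene/probe ids.
#' @param chrom Chromosome per gene.
#' @param midpoint_bp Positive integer, 1-based probe midpoint.
#' @return data.frame of class `"probe_annotation"`.
#' @export
probe_annotation <- function(gene_id, chrom, midpoint_bp) {
  gene_id <- as.character(gene_id)
  .check_unique(gene_id, "gene id")
  midpoint_bp <- as.integer(midpoint_bp)
  if (any(is.na(midpoint_bp)) || any(midpoint_bp < 1L))
    stop("midpoint_bp must be positive (1-based)")
  ann <- data.frame(gene_id = gene_id, chrom = as.character(chrom),
                    midpoint_bp = midpoint_bp, stringsAsFactors = FALSE)
  class(ann) <- c("probe_annotation", "data.frame")
  ann
}

.check_unique <- function(ids, what) {
  d <- ids[duplicated(ids)]
  if (length(d))
    stop(sprintf("duplicate %s: '%s'", what, d[1]))
  invisible(TRUE)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d individuals (%d missing entries)\n",
              nrow(x$values), ncol(x$values), sum(!x$mask)))
  invisible(x)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d SNPs x %d individuals, ploidy %d\n",
              nrow(x$values), ncol(x$values), x$ploidy))
  invisible(x)
}

#' @export
print.covariate_matrix <- function(x, ...) {
  cat(sprintf("covariate_matrix: %d covariates x %d individuals\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)
#' @export
dim.genotype_matrix <- function(x) dim(x$values)
#' @export
dim.covariate_matrix <- function(x) dim(x$values)
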