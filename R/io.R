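#' Read an expression matrix from tab-separated text
#'
#' Expects one header row of individual ids and one leading column of gene ids
#' (or the transpose, with `dialect = "genes-in-cols"`). Non-numeric or empty
#' cells become missing entries.
#'
#' @param path File path.
#' @param dialect `"genes-in-rows"` (default) or `"genes-in-cols"`.
#' @param exclude Optional character vector of gene ids to drop after
#'   reading (e.g. probes overlapping known variants).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, dialect = c("genes-in-rows", "genes-in-cols"),
                            exclude = NULL) {
  dialect <- match.arg(dialect)
  tab <- .read_tsv_matrix(path)
  if (dialect == "genes-in-cols") {
    tab$values <- t(tab$values)
    tmp <- tab$row_ids; tab$row_ids <- tab$col_ids; tab$col_ids <- tmp
  }
  if (!is.null(exclude)) {
    keep <- !(tab$row_ids %in% exclude)
    tab$values <- tab$values[keep, , drop = FALSE]
    tab$row_ids <- tab$row_ids[keep]
  }
  expression_matrix(tab$values, gene_ids = tab$row_ids,
                    individual_ids = tab$col_ids)
}

#' Read covariates from tab-separated text
#'
#' Same layout as [read_expression()]: header row of individual ids, leading
#' column of covariate ids.
#'
#' @param path File path.
#' @return A [covariate_matrix()].
#' @export
read_covariates <- function(path) {
  tab <- .read_tsv_matrix(path)
  covariate_matrix(tab$values, covariate_ids = tab$row_ids,
                   individual_ids = tab$col_ids)
}

#' Read a genotype matrix
#'
#' Tab-separated layout: columns `snp_id`, `chrom`, `pos`, then one column per
#' individual (header row carries individual ids). Alternatively a VCF file
#' (`format = "vcf"`), whose GT fields are converted to additive dosages.
#'
#' @param path File path.
#' @param ploidy 1 (haploid / inbred cross, codes 0/1) or 2 (dosages 0/1/2).
#' @param format `"tsv"` or `"vcf"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, ploidy = 2, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "vcf") return(.read_genotypes_vcf(path, ploidy))
  lines <- readLines(path)
  if (!length(lines)) stop("empty genotype file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1]))
    stop(sprintf("ragged genotype file: line %d has %d fields, expected %d",
                 which(nf != nf[1])[1], nf[nf != nf[1]][1], nf[1]))
  header <- fields[[1]]
  if (length(header) < 4L)
    stop("genotype file needs columns snp_id, chrom, pos plus >=1 individual")
  ind_ids <- header[-(1:3)]
  body <- fields[-1]
  snp_ids <- vapply(body, `[[`, "", 1L)
  chrom <- vapply(body, `[[`, "", 2L)
  pos_chr <- vapply(body, `[[`, "", 3L)
  pos <- suppressWarnings(as.integer(pos_chr))
  if (any(is.na(pos)))
    stop("missing or non-numeric position for SNP '",
         snp_ids[which(is.na(pos))[1]], "'")
  vals <- matrix(NA_integer_, length(body), length(ind_ids))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.integer(body[[i]][-(1:3)]))
    ok <- !is.na(v)
    bad <- v[ok][!(v[ok] %in% c(-1L, 0L:as.integer(ploidy)))]
    if (length(bad))
      stop(sprintf("genotype code %d outside ploidy-%d alphabet at SNP '%s'",
                   bad[1], ploidy, snp_ids[i]))
    v[is.na(v)] <- -1L
    vals[i, ] <- v
  }
  genotype_matrix(vals, snp_ids = snp_ids, individual_ids = ind_ids,
                  chrom = chrom, pos_bp = pos, ploidy = ploidy)
}

.read_genotypes_vcf <- function(path, ploidy) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF input requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  # additive dosage: count of alternate alleles; "." -> missing
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(-1L)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(-1L)
    sum(as.integer(alleles) > 0L)
  })
  fix <- vcfR::getFIX(v)
  snp_ids <- fix[, "ID"]
  noid <- is.na(snp_ids) | snp_ids == "."
  snp_ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  genotype_matrix(dose, snp_ids = snp_ids, individual_ids = colnames(gt),
                  chrom = fix[, "CHROM"], pos_bp = as.integer(fix[, "POS"]),
                  ploidy = ploidy)
}

#' Read probe annotations (gene_id, chrom, midpoint)
#'
#' @param path Tab-separated file with header `gene_id`, `chrom`, `midpoint_bp`.
#' @return A [probe_annotation()].
#' @export
read_probe_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "midpoint_bp")
  if (!all(need %in% names(tab)))
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  probe_annotation(tab$gene_id, tab$chrom, tab$midpoint_bp)
}

#' Write a matrix object to tab-separated text
#'
#' Writes the layout that [read_expression()] / [read_covariates()] /
#' [read_genotypes()] read back; finite values round-trip bit-exactly
#' (full precision), missing entries are written as `NA`.
#'
#' @param x An `expression_matrix`, `covariate_matrix`, `genotype_matrix`
#'   or plain matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  if (inherits(x, "genotype_matrix")) {
    vals <- x$values
    vals[vals < 0L] <- NA_integer_
    df <- data.frame(snp_id = x$snp_ids, chrom = x$chrom, pos = x$pos_bp,
                     vals, check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  vals <- if (is.list(x)) x$values else as.matrix(x)
  out <- cbind(id = rownames(vals),
               matrix(vapply(vals, function(z)
                 if (is.na(z)) "NA" else format(z, digits = 17),
                 character(1)), nrow(vals)))
  colnames(out) <- c("id", colnames(vals))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv_matrix <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1]))
    stop(sprintf("ragged file %s: line %d has %d fields, expected %d",
                 path, which(nf != nf[1])[1], nf[nf != nf[1]][1], nf[1]))
  header <- fields[[1]]
  col_ids <- header[-1]
  body <- fields[-1]
  row_ids <- vapply(body, `[[`, "", 1L)
  vals <- matrix(NA_real_, length(body), length(col_ids))
  for (i in seq_along(body))
    vals[i, ] <- suppressWarnings(as.numeric(body[[i]][-1]))
  list(values = vals, row_ids = row_ids, col_ids = col_ids)
}

#' Restrict expression, genotype and covariate data to shared individuals
#'
#' All inputs are subset to the intersection of their individual ids, in the
#' order they appear in the expression matrix (canonical order). Dropped ids
#' are reported via `message()`. Idempotent.
#'
#' @param expr [expression_matrix()].
#' @param geno [genotype_matrix()] or `NULL`.
#' @param covs [covariate_matrix()] or `NULL`.
#' @return List with elements `expr`, `geno`, `covs` (the latter two `NULL`
#'   if not supplied).
#' @export
align_individuals <- function(expr, geno = NULL, covs = NULL) {
  ids <- expr$individual_ids
  for (other in list(geno, covs))
    if (!is.null(other)) ids <- ids[ids %in% other$individual_ids]
  if (length(ids) == 0L) stop("no shared individual ids between inputs")
  dropped <- setdiff(unique(c(expr$individual_ids,
                              if (!is.null(geno)) geno$individual_ids,
                              if (!is.null(covs)) covs$individual_ids)), ids)
  if (length(dropped))
    message("align_individuals: dropped ", length(dropped), " individual(s): ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ..." else "")
  expr_out <- expression_matrix(expr$values[, ids, drop = FALSE],
                                gene_ids = expr$gene_ids, individual_ids = ids,
                                mask = expr$mask[, ids, drop = FALSE])
  geno_out <- if (!is.null(geno))
    genotype_matrix(geno$values[, ids, drop = FALSE], snp_ids = geno$snp_ids,
                    individual_ids = ids, chrom = geno$chrom,
                    pos_bp = geno$pos_bp, ploidy = geno$ploidy)
  covs_out <- if (!is.null(covs))
    covariate_matrix(covs$values[, ids, drop = FALSE],
                     covariate_ids = covs$covariate_ids, individual_ids = ids)
  list(expr = expr_out, geno = geno_out, covs = covs_out)
}
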