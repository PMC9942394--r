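#' Build a genotype table
#'
#' The central container of the package: a tibble with one row per biallelic
#' SNP and one integer column per sample holding the alternate-allele dosage
#' (0, 1, 2, or `NA` for a missing call). Site-level columns are `chrom`,
#' `pos` (0-based), `ref`, `alt`, `dp` (total read depth) and `mq` (RMS
#' mapping quality). All window arithmetic in the package is 0-based
#' half-open; [read_vcf()] converts from the 1-based VCF convention at the
#' boundary.
#'
#' @param sites A data frame with columns `chrom`, `pos` (0-based integer
#'   position), `ref`, `alt`, and optionally `dp` and `mq`.
#' @param genotypes An integer matrix, sites x samples, of alt-allele dosages
#'   in `{0, 1, 2, NA}`; column names are the sample identifiers.
#' @return A `geno_tbl`: a tibble of sites with per-sample dosage columns and
#'   a `samples` attribute listing the sample columns in order.
#' @examples
#' sites <- tibble::tibble(chrom = "chr1", pos = c(10L, 99L),
#'                         ref = "A", alt = "T")
#' gt <- matrix(c(0L, 2L, 1L, 0L), 2, 2, dimnames = list(NULL, c("s1", "s2")))
#' genotype_table(sites, gt)
#' @export
genotype_table <- function(sites, genotypes) {
  sites <- tibble::as_tibble(sites)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  if (!is.matrix(genotypes)) genotypes <- as.matrix(genotypes)
  if (nrow(sites) != nrow(genotypes)) {
    stop("`sites` and `genotypes` must have the same number of rows",
         call. = FALSE)
  }
  samples <- colnames(genotypes)
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(genotypes)))
  if (anyDuplicated(samples)) stop("duplicate sample names", call. = FALSE)
  bad <- intersect(samples, c("chrom", "pos", "ref", "alt", "dp", "mq"))
  if (length(bad)) {
    stop("sample names clash with site columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!"dp" %in% names(sites)) sites$dp <- NA_integer_
  if (!"mq" %in% names(sites)) sites$mq <- NA_real_
  storage.mode(genotypes) <- "integer"
  ok <- genotypes %in% c(0L, 1L, 2L, NA)
  if (!all(ok)) stop("genotype dosages must be 0, 1, 2 or NA", call. = FALSE)
  out <- dplyr::bind_cols(
    sites[, c("chrom", "pos", "ref", "alt", "dp", "mq")],
    tibble::as_tibble(genotypes)
  )
  out <- dplyr::arrange(out, .data$chrom, .data$pos)
  if (anyDuplicated(out[, c("chrom", "pos")])) {
    stop("duplicate (chrom, pos) sites", call. = FALSE)
  }
  new_geno_tbl(out, samples)
}

new_geno_tbl <- function(tbl, samples) {
  tbl <- tibble::as_tibble(tbl)
  attr(tbl, "samples") <- samples
  class(tbl) <- c("geno_tbl", class(tbl))
  tbl
}

#' Sample identifiers of a genotype table
#'
#' @param gt A genotype table from [genotype_table()] or [read_vcf()].
#' @return Character vector of sample names, in column order.
#' @export
gt_samples <- function(gt) {
  s <- attr(gt, "samples")
  if (!is.null(s) && all(s %in% names(gt))) return(s)
  # attribute lost through a dplyr verb: recover from column layout
  setdiff(names(gt), c("chrom", "pos", "ref", "alt", "dp", "mq"))
}

#' Extract the dosage matrix from a genotype table
#'
#' @param gt A genotype table.
#' @param samples Optional subset of sample names.
#' @return Integer matrix, sites x samples, of alt-allele dosages.
#' @export
gt_dosage <- function(gt, samples = NULL) {
  if (is.null(samples)) samples <- gt_samples(gt)
  missing <- setdiff(samples, names(gt))
  if (length(missing)) {
    stop("samples not present in genotype table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(gt[, samples, drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

#' Per-site alternate-allele frequency in a set of samples
#'
#' Frequencies are computed over non-missing called alleles only.
#'
#' @inheritParams gt_dosage
#' @return A tibble with columns `chrom`, `pos`, `n_called` (called
#'   chromosomes) and `freq` (alt-allele frequency; `NaN` where no call).
#' @export
gt_allele_freq <- function(gt, samples = NULL) {
  m <- gt_dosage(gt, samples)
  called <- 2L * rowSums(!is.na(m))
  alt <- rowSums(m, na.rm = TRUE)
  tibble::tibble(chrom = gt$chrom, pos = gt$pos,
                 n_called = called, freq = alt / called)
}

#' @export
print.geno_tbl <- function(x, ...) {
  samples <- gt_samples(x)
  cat(sprintf("# A genotype table: %d sites x %d samples\n",
              nrow(x), length(samples)))
  NextMethod()
  invisible(x)
}
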