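#' Site-quality filter configuration
#'
#' Defaults follow a standard high-quality SNP filter for population
#' resequencing: total depth in \[6, 100\] reads, RMS mapping quality >= 20,
#' minor-allele frequency >= 0.1 and per-site missingness <= 0.1. All
#' comparisons are inclusive as written.
#'
#' @param min_depth,max_depth Inclusive bounds on `INFO/DP` (reads).
#' @param min_rms_mq Minimum RMS mapping quality.
#' @param min_maf Minimum minor-allele frequency, computed over non-missing
#'   called alleles.
#' @param max_missing Maximum fraction of samples with a missing genotype.
#' @param per_population Optional list of sample vectors; when supplied, the
#'   MAF and missingness criteria must hold within every listed set rather
#'   than over the whole cohort.
#' @return A `site_filter_config` list.
#' @export
site_filter_config <- function(min_depth = 6, max_depth = 100,
                               min_rms_mq = 20, min_maf = 0.1,
                               max_missing = 0.1, per_population = NULL) {
  stopifnot(min_maf >= 0, min_maf <= 0.5,
            max_missing >= 0, max_missing <= 1,
            min_depth <= max_depth)
  structure(list(min_depth = min_depth, max_depth = max_depth,
                 min_rms_mq = min_rms_mq, min_maf = min_maf,
                 max_missing = max_missing, per_population = per_population),
            class = "site_filter_config")
}

#' Apply site-quality filters to a genotype table
#'
#' A site is kept iff its depth lies in `[min_depth, max_depth]`, RMS MQ
#' >= `min_rms_mq`, minor-allele frequency >= `min_maf` and missing-genotype
#' fraction <= `max_missing`. Sites with missing DP or MQ fail the
#' corresponding criterion (quality unknown is not quality sufficient).
#' Each rejected site is attributed to its first failing criterion, in the
#' order depth-low, depth-high, MQ, MAF, missingness, so the counts
#' partition the rejected sites.
#'
#' @param gt A genotype table.
#' @param cfg A [site_filter_config()].
#' @return The filtered genotype table, with attribute `rejections`: a named
#'   integer vector of per-criterion rejection counts.
#' @export
apply_site_filters <- function(gt, cfg = site_filter_config()) {
  if (nrow(gt) == 0L) stop("empty genotype table", call. = FALSE)
  sample_sets <- cfg$per_population %||% list(gt_samples(gt))
  maf_ok <- rep(TRUE, nrow(gt))
  miss_ok <- rep(TRUE, nrow(gt))
  for (set in sample_sets) {
    m <- gt_dosage(gt, set)
    n_miss <- rowSums(is.na(m))
    called <- 2L * (ncol(m) - n_miss)
    p <- rowSums(m, na.rm = TRUE) / called
    maf <- pmin(p, 1 - p)
    ok <- if (cfg$min_maf <= 0) TRUE else !is.na(maf) & maf >= cfg$min_maf
    maf_ok <- maf_ok & ok
    miss_ok <- miss_ok & (n_miss / ncol(m)) <= cfg$max_missing
  }
  fail <- cbind(
    depth_low  = is.na(gt$dp) | gt$dp < cfg$min_depth,
    depth_high = !is.na(gt$dp) & gt$dp > cfg$max_depth,
    mq         = is.na(gt$mq) | gt$mq < cfg$min_rms_mq,
    maf        = !maf_ok,
    missing    = !miss_ok
  )
  # vacuous bounds keep NA-quality sites: a 0/-Inf threshold means "no filter"
  if (cfg$min_depth <= 0) fail[is.na(gt$dp), "depth_low"] <- FALSE
  if (cfg$min_rms_mq <= 0) fail[is.na(gt$mq), "mq"] <- FALSE
  first_fail <- apply(fail, 1L, function(f) which(f)[1])
  keep <- is.na(first_fail)
  rejections <- vapply(seq_len(ncol(fail)), function(j)
    sum(first_fail == j, na.rm = TRUE), integer(1))
  names(rejections) <- colnames(fail)
  out <- gt[keep, , drop = FALSE]
  out <- new_geno_tbl(out, gt_samples(gt))
  if (nrow(out) == 0L) warning("all sites removed by filters", call. = FALSE)
  attr(out, "rejections") <- rejections
  out
}
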