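#' Full per-window statistic vector for one contrast
#'
#' Computes, over sliding windows, everything the sweep caller consumes for
#' one focal-vs-control contrast: Weir-Cockerham F_ST (ratio of sums),
#' nucleotide diversity in each group, the log2 diversity ratio
#' (control over focal, so sweeps in the focal group are large positive
#' values), absolute divergence Dxy, and Tajima's D per group. Windows with
#' fewer than `spec$min_snps` usable SNPs are flagged `masked` and excluded
#' from quantile thresholds downstream.
#'
#' @param gt A genotype table (typically already site-filtered).
#' @param popmap A `pop_map` from [read_population_map()] or
#'   [population_map()].
#' @param focal Population or group name of the focal (e.g. high-altitude)
#'   population.
#' @param control Population or group name(s) of the control group; pooled
#'   populations are treated as a single population.
#' @param spec A [window_spec()].
#' @param chrom_lengths Named vector of chromosome lengths in bp; defaults
#'   to the last SNP position + 1 per chromosome present in `gt`.
#' @return A `sweep_windows` tibble: `chrom`, `start`, `end`, `n_snps`,
#'   `fst`, `pi_control`, `pi_focal`, `log2_pi_ratio`, `dxy`,
#'   `tajd_control`, `tajd_focal`, `masked`.
#' @export
window_stats <- function(gt, popmap, focal, control, spec = window_spec(),
                         chrom_lengths = NULL) {
  focal_s <- resolve_samples(popmap, focal)
  control_s <- resolve_samples(popmap, control)
  if (length(intersect(focal_s, control_s))) {
    stop("focal and control groups share samples", call. = FALSE)
  }
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(gt$pos, gt$chrom, function(p) max(p) + 1L)
    chrom_lengths <- chrom_lengths[unique(gt$chrom)]
  }
  windows <- enumerate_windows(chrom_lengths, spec)
  fst <- windowed_fst(gt, control_s, focal_s, windows)
  pi_c <- windowed_pi(gt, control_s, windows)
  pi_f <- windowed_pi(gt, focal_s, windows)
  dxy <- windowed_dxy(gt, control_s, focal_s, windows)
  td_c <- tajimas_d(gt, control_s, windows)
  td_f <- tajimas_d(gt, focal_s, windows)
  out <- windows
  out$n_snps <- fst$n_fst_sites
  out$fst <- fst$fst
  out$pi_control <- pi_c$pi
  out$pi_focal <- pi_f$pi
  out$log2_pi_ratio <- log2_pi_ratio(pi_c$pi, pi_f$pi)
  out$dxy <- dxy$dxy
  out$tajd_control <- td_c$tajimas_d
  out$tajd_focal <- td_f$tajimas_d
  out$masked <- fst$n_fst_sites < spec$min_snps
  class(out) <- c("sweep_windows", class(out))
  attr(out, "contrast") <- list(focal = focal, control = control)
  attr(out, "spec") <- spec
  out
}

#' Write / read the window table as TSV
#'
#' The file carries a commented header naming the column units and round
#' trips bit-exactly through [read_window_stats()].
#'
#' @param windows A `sweep_windows` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_stats <- function(windows, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# sweepscan window statistics",
    "# chrom,start,end: 0-based half-open bp; n_snps: usable SNPs",
    "# fst: Weir-Cockerham ratio-of-sums; pi_*: diversity per bp",
    "# log2_pi_ratio: log2(pi_control/pi_focal); dxy: divergence per bp",
    "# tajd_*: Tajima's D (unitless); masked: below min-SNP floor"
  ), con)
  tbl <- as.data.frame(windows)
  num <- vapply(tbl, is.double, logical(1))
  tbl[num] <- lapply(tbl[num], function(x) format_num(x))
  utils::write.table(tbl, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_stats
#' @export
read_window_stats <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  out <- tibble::as_tibble(out)
  class(out) <- c("sweep_windows", class(out))
  out
}
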