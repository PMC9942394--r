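#' Sliding-window specification
#'
#' The scan default is a 40-kb window advanced in 20-kb steps, with windows
#' containing fewer than `min_snps` usable SNPs masked from outlier calling.
#'
#' @param window_size Window length in bp.
#' @param step_size Step between window starts in bp; must not exceed
#'   `window_size`.
#' @param min_snps Minimum SNPs for a window's statistics to be used.
#' @return A `window_spec` list.
#' @export
window_spec <- function(window_size = 40000L, step_size = 20000L,
                        min_snps = 10L) {
  stopifnot(window_size > 0, step_size > 0, step_size <= window_size)
  structure(list(window_size = as.integer(window_size),
                 step_size = as.integer(step_size),
                 min_snps = as.integer(min_snps)),
            class = "window_spec")
}

#' Enumerate sliding windows over chromosomes
#'
#' Windows start at 0 and advance by `step_size`; any window extending past
#' the chromosome end is truncated there, so every base is covered by at
#' least one window and trailing partial windows are kept.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param spec A [window_spec()].
#' @return Tibble of `chrom`, `start`, `end` (0-based half-open), ordered.
#' @export
enumerate_windows <- function(chrom_lengths, spec = window_spec()) {
  stopifnot(all(chrom_lengths > 0), !is.null(names(chrom_lengths)))
  purrr::map_dfr(names(chrom_lengths), function(chrom) {
    len <- as.integer(chrom_lengths[[chrom]])
    # a new window opens only while a full step remains before the end,
    # so short chromosomes yield one window and trailing partials are kept
    starts <- seq.int(0L, max(0L, len - spec$step_size), by = spec$step_size)
    ends <- pmin(starts + spec$window_size, len)
    keep <- starts < ends
    tibble::tibble(chrom = chrom, start = starts[keep], end = ends[keep])
  })
}

# index: for each window row, the site row indices falling inside it
window_site_index <- function(gt, windows) {
  purrr::pmap(windows[, c("chrom", "start", "end")], function(chrom, start, end) {
    which(gt$chrom == chrom & gt$pos >= start & gt$pos < end)
  })
}
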