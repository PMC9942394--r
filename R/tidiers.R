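#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a scanned contrast into its called segments
#'
#' @param x A `sweep_contrast` from [run_scan()].
#' @param ... Unused.
#' @return Tibble of called sweep segments with peak statistics, support
#'   flags and (when annotated) comma-separated gene names.
#' @method tidy sweep_contrast
#' @export
tidy.sweep_contrast <- function(x, ...) {
  seg <- tibble::as_tibble(x$segments)
  if ("genes" %in% names(seg)) {
    seg$genes <- vapply(seg$genes, paste, character(1), collapse = ",")
  }
  seg$contrast <- x$name
  dplyr::relocate(seg, "contrast")
}

#' One-row summary of a scanned contrast
#'
#' @param x A `sweep_contrast` from [run_scan()].
#' @param ... Unused.
#' @return One-row tibble: window counts, realised thresholds, outlier,
#'   segment and gene counts, and validator concordance fractions.
#' @method glance sweep_contrast
#' @export
glance.sweep_contrast <- function(x, ...) {
  conc <- x$concordance
  frac <- function(v) {
    if (is.null(conc)) return(NA_real_)
    f <- conc$fraction[conc$validator == v]
    if (length(f)) as.numeric(f) else NA_real_
  }
  tibble::tibble(
    contrast = x$name,
    n_windows = nrow(x$windows),
    n_masked = sum(x$windows$masked),
    fst_threshold = x$thresholds$fst_threshold,
    pi_ratio_threshold = x$thresholds$pi_ratio_threshold,
    n_outlier_windows = nrow(x$outliers),
    n_segments = nrow(x$segments),
    n_genes = if (is.null(x$gene_set)) NA_integer_ else nrow(x$gene_set),
    xpclr_concordance = frac("xpclr"),
    dxy_concordance = frac("dxy")
  )
}

#' Tidy a calibration grid
#'
#' @param x An `iwm_calibration` from [calibrate_iwm_to_fst()].
#' @param ... Unused.
#' @return The grid tibble with a `best` flag per cell.
#' @method tidy iwm_calibration
#' @export
tidy.iwm_calibration <- function(x, ...) {
  g <- x$grid
  g$best <- g$split_time == x$best_model$split_time &
    g$migration_rate == x$best_model$migration_rate
  g
}

#' One-row summary of a calibration
#'
#' @param x An `iwm_calibration`.
#' @param ... Unused.
#' @return One-row tibble with the fitted cell, its discrepancy, the
#'   neutral mean F_ST and the 99th-percentile neutral envelope.
#' @method glance iwm_calibration
#' @export
glance.iwm_calibration <- function(x, ...) {
  tibble::tibble(
    split_time = x$best_model$split_time,
    migration_rate = x$best_model$migration_rate,
    mean_neutral_fst = mean(x$neutral_fst, na.rm = TRUE),
    envelope_99 = x$envelope_99,
    discrepancy = x$discrepancy,
    converged = x$converged
  )
}
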