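#' Nearest-rank top-quantile threshold
#'
#' The top set is the `floor(quantile * n)` largest values (at least 1);
#' the threshold is the smallest value in that set and values qualify by
#' `>=`. Non-finite values (masked windows, infinite ratios) are excluded
#' from the computation but an infinite ratio still qualifies downstream.
#'
#' @param values Numeric vector of unmasked window statistics.
#' @param quantile Upper tail mass in (0, 0.5); default 0.01.
#' @return The threshold value.
#' @export
empirical_quantile_threshold <- function(values, quantile = 0.01) {
  stopifnot(quantile > 0, quantile < 0.5)
  v <- values[is.finite(values)]
  if (!length(v)) stop("no finite values to threshold", call. = FALSE)
  k <- max(1L, floor(quantile * length(v)))
  sort(v, decreasing = TRUE)[k]
}

#' Joint F_ST / diversity-ratio outlier thresholds
#'
#' @param windows A `sweep_windows` tibble (see [window_stats()]).
#' @param quantile Upper tail mass for both statistics.
#' @return An `outlier_thresholds` list with `fst_threshold`,
#'   `pi_ratio_threshold` and `quantile`.
#' @export
outlier_thresholds <- function(windows, quantile = 0.01) {
  unmasked <- !windows$masked
  structure(list(
    fst_threshold = empirical_quantile_threshold(windows$fst[unmasked],
                                                 quantile),
    pi_ratio_threshold = empirical_quantile_threshold(
      windows$log2_pi_ratio[unmasked], quantile),
    quantile = quantile
  ), class = "outlier_thresholds")
}

#' Call joint top-quantile outlier windows
#'
#' A window qualifies iff `fst >= fst_threshold` and
#' `log2_pi_ratio >= pi_ratio_threshold` simultaneously; masked windows
#' never qualify. An infinite diversity ratio (focal diversity zero)
#' exceeds any threshold.
#'
#' @param windows A `sweep_windows` tibble.
#' @param thresholds An [outlier_thresholds()] computed on the same table.
#' @return The qualifying rows of `windows`.
#' @export
call_joint_outliers <- function(windows, thresholds) {
  ok <- !windows$masked &
    !is.na(windows$fst) & windows$fst >= thresholds$fst_threshold &
    !is.na(windows$log2_pi_ratio) &
    windows$log2_pi_ratio >= thresholds$pi_ratio_threshold
  windows[ok, , drop = FALSE]
}

# merge overlapping or book-ended intervals; carries a peak over `score`
merge_intervals <- function(tbl) {
  if (!nrow(tbl)) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_merged = integer(),
                          peak_score = numeric()))
  }
  tbl <- dplyr::arrange(tbl, .data$chrom, .data$start, .data$end)
  grp <- integer(nrow(tbl))
  g <- 1L
  cur_end <- tbl$end[1]
  grp[1] <- g
  for (i in seq_len(nrow(tbl))[-1]) {
    if (tbl$chrom[i] == tbl$chrom[i - 1] && tbl$start[i] <= cur_end) {
      cur_end <- max(cur_end, tbl$end[i])
    } else {
      g <- g + 1L
      cur_end <- tbl$end[i]
    }
    grp[i] <- g
  }
  tbl$..grp <- grp
  out <- dplyr::summarise(
    dplyr::group_by(tbl, .data$..grp),
    chrom = dplyr::first(.data$chrom),
    start = min(.data$start), end = max(.data$end),
    n_merged = dplyr::n(),
    peak_score = if ("score" %in% names(tbl)) max(.data$score) else NA_real_,
    .groups = "drop"
  )
  out$..grp <- NULL
  out
}

#' Merge outlier windows into sweep segments
#'
#' Overlapping or book-ended (shared-boundary) outlier windows on one
#' chromosome merge into a single segment; peak statistics are maxima over
#' the merged windows.
#'
#' @param outliers Outlier windows from [call_joint_outliers()].
#' @return A `sweep_segments` tibble: `chrom`, `start`, `end`, `n_windows`,
#'   `peak_fst`, `peak_log2_pi_ratio`. Segments are sorted and
#'   non-overlapping.
#' @export
merge_windows_to_segments <- function(outliers) {
  if (!nrow(outliers)) {
    out <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_windows = integer(),
                          peak_fst = numeric(), peak_log2_pi_ratio = numeric())
    class(out) <- c("sweep_segments", class(out))
    return(out)
  }
  tbl <- dplyr::arrange(tibble::as_tibble(outliers), .data$chrom,
                        .data$start, .data$end)
  merged <- merge_intervals(tbl[, c("chrom", "start", "end")])
  peaks <- purrr::pmap_dfr(merged[, c("chrom", "start", "end")],
                           function(chrom, start, end) {
    inside <- tbl$chrom == chrom & tbl$start < end & tbl$end > start
    tibble::tibble(peak_fst = max(tbl$fst[inside]),
                   peak_log2_pi_ratio = max(tbl$log2_pi_ratio[inside]))
  })
  out <- dplyr::bind_cols(
    merged[, c("chrom", "start", "end", "n_merged")], peaks)
  names(out)[names(out) == "n_merged"] <- "n_windows"
  class(out) <- c("sweep_segments", class(out))
  out
}

#' Assign genes to sweep segments
#'
#' A gene is assigned to a segment iff the 0-based half-open intervals
#' overlap by at least 1 bp. The contrast-level gene set is the union over
#' segments, deduplicated by `gene_id`.
#'
#' @param segments A `sweep_segments` tibble.
#' @param genes A gene annotation tibble from [read_gene_annotations()].
#' @return `segments` with a list-column `genes` (gene names per segment)
#'   and attribute `gene_set` (deduplicated tibble of all hit genes).
#' @export
annotate_genes <- function(segments, genes) {
  hit_ids <- character(0)
  gene_lists <- purrr::pmap(
    segments[, c("chrom", "start", "end")],
    function(chrom, start, end) {
      hit <- genes$chrom == chrom & genes$start < end & genes$end > start
      genes$gene_name[hit]
    })
  gene_ids <- purrr::pmap(
    segments[, c("chrom", "start", "end")],
    function(chrom, start, end) {
      hit <- genes$chrom == chrom & genes$start < end & genes$end > start
      genes$gene_id[hit]
    })
  out <- segments
  out$genes <- gene_lists
  hit_ids <- unique(unlist(gene_ids))
  attr(out, "gene_set") <- genes[genes$gene_id %in% hit_ids, , drop = FALSE]
  out
}

#' Cross-method concordance of candidate genes
#'
#' Fraction of the candidate gene set (e.g. joint F_ST/diversity-ratio
#' outlier genes) also flagged by a validating method (XP-CLR or Dxy),
#' with the candidate count as denominator.
#'
#' @param candidate_genes,validator_genes Character vectors in one gene
#'   namespace.
#' @return A list: `fraction`, `n_candidate`, `n_overlap`, `overlap`.
#' @export
cross_method_concordance <- function(candidate_genes, validator_genes) {
  candidate_genes <- unique(candidate_genes)
  if (!length(candidate_genes)) {
    stop("empty candidate gene set: concordance undefined", call. = FALSE)
  }
  overlap <- intersect(candidate_genes, unique(validator_genes))
  list(fraction = length(overlap) / length(candidate_genes),
       n_candidate = length(candidate_genes),
       n_overlap = length(overlap),
       overlap = sort(overlap))
}

#' Venn cell counts across contrasts
#'
#' Full inclusion-exclusion cells for 2 or more gene sets (e.g. the
#' candidate genes of several altitude contrasts).
#'
#' @param gene_sets Named list of character vectors.
#' @return Tibble with one row per non-empty membership pattern: one
#'   logical column per set, `n`, and a list-column `genes`.
#' @export
contrast_overlap <- function(gene_sets) {
  stopifnot(length(gene_sets) >= 2, !is.null(names(gene_sets)))
  gene_sets <- lapply(gene_sets, unique)
  all_genes <- unique(unlist(gene_sets))
  member <- vapply(gene_sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1,
                                             dimnames = list(NULL, names(gene_sets)))
  pattern <- apply(member, 1L, function(r) paste(as.integer(r), collapse = ""))
  cells <- split(all_genes, pattern)
  out <- purrr::map_dfr(names(cells), function(p) {
    flags <- as.logical(as.integer(strsplit(p, "")[[1]]))
    row <- tibble::as_tibble(as.list(stats::setNames(flags, names(gene_sets))))
    row$n <- length(cells[[p]])
    row$genes <- list(sort(cells[[p]]))
    row
  })
  dplyr::arrange(out, dplyr::desc(.data$n))
}

#' Allele-frequency trajectories along the altitude gradient
#'
#' Orders populations by altitude and reports, per candidate site, the
#' per-population alternate-allele frequencies, the Spearman rank
#' correlation between altitude rank and frequency, and an
#' `altitude_increasing` flag: frequencies non-decreasing along the
#' gradient, total rise at least `min_rise`, and strictly higher in the
#' top population than in the bottom one. Sites with a population entirely
#' missing are reported `incomplete` and never flagged.
#'
#' @param gt A genotype table.
#' @param popmap A `pop_map` with altitudes for every population.
#' @param sites Tibble of candidate sites with `chrom`, `pos`; defaults to
#'   all sites in `gt`.
#' @param min_rise Minimum total frequency rise bottom-to-top.
#' @return Tibble keyed by `chrom`, `pos` with one frequency column per
#'   population (altitude order), `rank_correlation`, `total_rise`,
#'   `incomplete`, `altitude_increasing`.
#' @export
allele_frequency_trajectory <- function(gt, popmap, sites = NULL,
                                        min_rise = 0.2) {
  ord <- altitude_order(popmap)
  if (nrow(ord) < 3) {
    stop("need >= 3 populations with distinct altitudes", call. = FALSE)
  }
  if (is.null(sites)) sites <- gt[, c("chrom", "pos")]
  key <- paste(gt$chrom, gt$pos)
  rows <- match(paste(sites$chrom, sites$pos), key)
  if (anyNA(rows)) {
    stop("candidate site(s) absent from genotype table", call. = FALSE)
  }
  freqs <- lapply(ord$population, function(p) {
    s <- resolve_samples(popmap, p)
    gt_allele_freq(gt, s)$freq[rows]
  })
  fmat <- do.call(cbind, freqs)
  colnames(fmat) <- ord$population
  incomplete <- apply(fmat, 1L, anyNA)
  nondec <- apply(fmat, 1L, function(f) all(diff(f) >= 0, na.rm = TRUE))
  rise <- fmat[, ncol(fmat)] - fmat[, 1L]
  rho <- apply(fmat, 1L, function(f) {
    if (anyNA(f) || stats::sd(f) == 0) return(NA_real_)
    suppressWarnings(stats::cor(seq_along(f), f, method = "spearman"))
  })
  out <- dplyr::bind_cols(
    tibble::tibble(chrom = sites$chrom, pos = sites$pos),
    tibble::as_tibble(fmat)
  )
  out$rank_correlation <- rho
  out$total_rise <- rise
  out$incomplete <- incomplete
  out$altitude_increasing <- !incomplete & nondec &
    !is.na(rise) & rise >= min_rise & rise > 0
  out
}
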