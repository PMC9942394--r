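#' Calibrate an isolation-with-migration model to an observed F_ST summary
#'
#' Grid search over `(split_time, migration_rate)`: each cell simulates
#' `n_replicates` independent neutral loci, computes the Weir-Cockerham
#' F_ST of each locus (haplotypes paired into diploids, ratio of sums over
#' sites), and scores the cell against the target — absolute difference of
#' means, or the sum of absolute differences at the given quantiles. The
#' best cell's full neutral F_ST distribution and its nearest-rank 99th
#' percentile (the "neutral envelope") are returned; empirical top-tail
#' F_ST exceeding that envelope is the classic signature of divergent
#' selection rather than drift.
#'
#' @param target Either a single number (target mean F_ST) or a numeric
#'   vector of target quantile values matching `probs`.
#' @param template An [iwm_model()] supplying sample sizes and theta.
#' @param split_grid,migration_grid Numeric grids searched exhaustively.
#' @param n_replicates Loci simulated per cell.
#' @param probs When `target` is a vector: the quantile probabilities.
#' @param tolerance Best discrepancy above this sets `converged = FALSE`.
#' @param seed Integer seed.
#' @return An `iwm_calibration` list: `best_model`, `grid` (tibble of cell
#'   summaries), `neutral_fst` (best cell's per-locus values),
#'   `envelope_99`, `discrepancy`, `converged`.
#' @export
calibrate_iwm_to_fst <- function(target, template = iwm_model(),
                                 split_grid = c(0, 0.1, 0.25, 0.5, 1),
                                 migration_grid = c(0, 1, 10),
                                 n_replicates = 100L, probs = NULL,
                                 tolerance = 0.05, seed = 1L) {
  stopifnot(length(split_grid) >= 1, length(migration_grid) >= 1)
  cells <- expand.grid(split_time = split_grid,
                       migration_rate = migration_grid)
  sims <- vector("list", nrow(cells))
  grid <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    model <- iwm_model(sample_sizes = template$sample_sizes,
                       theta = template$theta,
                       split_time = cells$split_time[i],
                       migration_rate = cells$migration_rate[i],
                       deme_sizes = template$deme_sizes,
                       locus_length = template$locus_length)
    # per-cell seed derived deterministically; kept below 2^31
    fst <- neutral_fst_distribution(model, n_replicates,
                                    seed = (seed + 7919L * i) %% 2147483629L)
    sims[[i]] <<- fst
    disc <- if (is.null(probs)) {
      abs(mean(fst, na.rm = TRUE) - target)
    } else {
      sum(abs(stats::quantile(fst, probs, na.rm = TRUE, names = FALSE) -
                target))
    }
    tibble::tibble(split_time = cells$split_time[i],
                   migration_rate = cells$migration_rate[i],
                   mean_fst = mean(fst, na.rm = TRUE),
                   discrepancy = disc)
  })
  best <- which.min(grid$discrepancy)
  neutral <- sims[[best]]
  neutral_ok <- neutral[is.finite(neutral)]
  k <- max(1L, floor(0.01 * length(neutral_ok)))
  structure(list(
    best_model = iwm_model(sample_sizes = template$sample_sizes,
                           theta = template$theta,
                           split_time = grid$split_time[best],
                           migration_rate = grid$migration_rate[best],
                           deme_sizes = template$deme_sizes,
                           locus_length = template$locus_length),
    grid = grid,
    neutral_fst = neutral,
    envelope_99 = sort(neutral_ok, decreasing = TRUE)[k],
    discrepancy = grid$discrepancy[best],
    converged = grid$discrepancy[best] <= tolerance
  ), class = "iwm_calibration")
}

#' Per-locus neutral F_ST distribution under a demographic model
#'
#' Simulates independent loci and returns each locus's Weir-Cockerham
#' F_ST (consecutive haplotypes paired into diploids; ratio of sums over
#' the locus's sites). Loci with no usable site give `NA`.
#'
#' @param model A two-deme [iwm_model()].
#' @param n_replicates Number of loci.
#' @param seed Integer seed.
#' @return Numeric vector of length `n_replicates`.
#' @export
neutral_fst_distribution <- function(model, n_replicates, seed = 1L) {
  stopifnot(length(model$sample_sizes) == 2L)
  blocks <- simulate_neutral_iwm(model, n_replicates, seed)
  vapply(blocks, function(b) block_fst(b), numeric(1))
}

# whole-locus WC F_ST of a two-deme haplotype block
block_fst <- function(block) {
  if (ncol(block$haps) == 0L) return(NA_real_)
  gt <- block_to_genotable(block)
  samples <- gt_samples(gt)
  demes <- attr(gt, "demes")
  comp <- site_fst_components(gt, samples[demes == 1L], samples[demes == 2L])
  u <- comp$usable
  if (!any(u)) return(NA_real_)
  sum(comp$a[u]) / sum(comp$a[u] + comp$b[u] + comp$c[u])
}

# pair consecutive haplotypes within each deme into diploid dosages
block_to_genotable <- function(block, chrom = "sim", locus_length = NULL) {
  demes <- block$demes %||% rep(1L, nrow(block$haps))
  if (any(tabulate(demes) %% 2L != 0L)) {
    stop("odd haplotype count in a deme: cannot pair into diploids",
         call. = FALSE)
  }
  L <- locus_length %||% 1
  ord <- order(demes)
  haps <- block$haps[ord, , drop = FALSE]
  demes <- demes[ord]
  first <- seq(1L, nrow(haps), by = 2L)
  dosage <- haps[first, , drop = FALSE] + haps[first + 1L, , drop = FALSE]
  ind_deme <- demes[first]
  samples <- paste0("p", ind_deme, "_i",
                    stats::ave(ind_deme, ind_deme, FUN = seq_along))
  rownames(dosage) <- NULL
  dosage <- t(dosage)
  colnames(dosage) <- samples
  pos <- unique_bp_positions(block$positions, L)
  gt <- genotype_table(
    tibble::tibble(chrom = chrom, pos = pos,
                   ref = "A", alt = "T"),
    dosage
  )
  attr(gt, "demes") <- ind_deme
  gt
}

# relative [0,1] or bp positions -> sorted unique integer bp; colliding
# sites are shifted to the next free bp, keeping order and count
unique_bp_positions <- function(positions, locus_length = NULL) {
  if (!length(positions)) return(integer(0))
  rel <- !is.null(locus_length) && locus_length > 1 && max(positions) <= 1
  pos <- as.integer(floor(if (rel) positions * locus_length else positions))
  for (i in seq_along(pos)[-1]) {
    if (pos[i] <= pos[i - 1L]) pos[i] <- pos[i - 1L] + 1L
  }
  pos
}
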