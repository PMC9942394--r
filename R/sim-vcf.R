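#' Convert simulated haplotypes to a diploid genotype table / VCF
#'
#' Consecutive haplotypes within each deme are paired into diploids.
#' Relative positions are scaled to bp (collisions resolved by shifting to
#' the next free bp, preserving order and record count). Site depth is
#' drawn from `dp_fun` (default Poisson, mean 30) and RMS mapping quality
#' from `mq_fun` (default constant 60); both can be overridden to inject
#' degraded-quality sites and exercise the filters.
#'
#' @param block A haplotype block (`haps`, `positions`, optional `demes`)
#'   from [simulate_neutral_iwm()] or [simulate_sweep()].
#' @param chrom Chromosome name for the emitted sites.
#' @param locus_length Length in bp used to scale relative positions.
#' @param offset Added to all bp positions.
#' @param dp_fun,mq_fun Generators: `function(n)` returning `n` depths /
#'   mapping qualities.
#' @param path Optional path; when given, the VCF text is written there.
#' @param seed Integer seed for the quality-field draws.
#' @return List: `gt` (a [genotype_table()]), `truth` (tibble of `sample`,
#'   `deme`), `path`.
#' @export
haplotypes_to_vcf <- function(block, chrom = "chr1",
                              locus_length = 40000L, offset = 0L,
                              dp_fun = function(n) stats::rpois(n, 30),
                              mq_fun = function(n) rep(60, n),
                              path = NULL, seed = 1L) {
  demes <- block$demes %||% rep(1L, nrow(block$haps))
  if (any(tabulate(demes) %% 2L != 0L)) {
    stop("odd haplotype count in a deme: cannot pair into diploids",
         call. = FALSE)
  }
  set.seed(seed)
  gt <- block_to_genotable(block, chrom = chrom,
                           locus_length = locus_length)
  gt$pos <- gt$pos + as.integer(offset)
  n <- nrow(gt)
  gt$dp <- as.integer(dp_fun(n))
  gt$mq <- as.numeric(mq_fun(n))
  truth <- tibble::tibble(sample = gt_samples(gt),
                          deme = attr(gt, "demes"))
  if (!is.null(path)) write_vcf(gt, path)
  list(gt = gt, truth = truth, path = path)
}

#' Simulate a two-population genome scan dataset with planted sweeps
#'
#' Builds a multi-chromosome diploid dataset under a two-deme
#' isolation-with-migration background: each chromosome is a series of
#' independently simulated neutral blocks, except around planted sweep
#' positions, where a longer block is simulated neutrally and then pushed
#' through the forward Wright-Fisher sweep simulator in the focal deme
#' (deme 2), so the focal population carries a hard sweep — locally
#' collapsed diversity and elevated differentiation — against an untouched
#' control population.
#'
#' @param model A two-deme [iwm_model()]; `theta` is interpreted per
#'   `block_length`.
#' @param n_chrom,chrom_length Genome layout (chromosomes x bp).
#' @param block_length Independent-locus length in bp.
#' @param sweep_chroms Chromosome indices carrying one planted sweep each,
#'   at the chromosome midpoint.
#' @param sweep_cfg A [sweep_sim_config()]; its `locus_length` (a multiple
#'   of `block_length`) sets the swept region's span.
#' @param seed Integer seed controlling the whole dataset.
#' @return List: `gt` (genotype table for all chromosomes), `popmap`
#'   (`control` pop at low altitude, `focal` at high), `genes` (a
#'   deterministic synthetic gene tiling), `truth` (tibble of `chrom`,
#'   `sweep_pos`), `chrom_lengths`.
#' @export
simulate_scan_genome <- function(model = iwm_model(sample_sizes = c(20L, 20L),
                                                   theta = 10,
                                                   split_time = 0.1,
                                                   migration_rate = 0),
                                 n_chrom = 10L, chrom_length = 1e6,
                                 block_length = 10000L,
                                 sweep_chroms = c(2L, 5L, 8L),
                                 sweep_cfg = sweep_sim_config(),
                                 seed = 1L) {
  stopifnot(length(model$sample_sizes) == 2L,
            sweep_cfg$locus_length %% block_length == 0,
            chrom_length %% block_length == 0)
  set.seed(seed)
  n_blocks <- chrom_length / block_length
  sweep_span <- sweep_cfg$locus_length / block_length
  chrom_names <- sprintf("chr%02d", seq_len(n_chrom))
  site_tbls <- list()
  dosages <- list()
  truth <- tibble::tibble(chrom = character(), sweep_pos = numeric())

  for (ci in seq_len(n_chrom)) {
    chrom <- chrom_names[ci]
    has_sweep <- ci %in% sweep_chroms
    # sweep region: `sweep_span` blocks centred on the chromosome midpoint
    sweep_start_block <- if (has_sweep)
      floor(n_blocks / 2) - floor(sweep_span / 2) + 1L else NA_integer_
    b <- 1L
    while (b <= n_blocks) {
      block_seed <- sample.int(2147483600L, 1L)
      offset <- (b - 1L) * block_length
      if (has_sweep && b == sweep_start_block) {
        len <- sweep_cfg$locus_length
        # found the swept region on `sweep_span` independent genealogies so
        # the fixed haplotype is a mosaic, as it would be with recombination
        sub <- simulate_neutral_iwm(model, sweep_span, seed = block_seed)
        blk <- stitch_blocks(sub, block_length)
        blk <- plant_sweep(blk, sweep_cfg, model$sample_sizes,
                           seed = block_seed + 1L)
        truth <- dplyr::bind_rows(truth, tibble::tibble(
          chrom = chrom, sweep_pos = offset + sweep_cfg$sweep_position))
        b <- b + sweep_span
      } else {
        len <- block_length
        blk <- simulate_neutral_iwm(model, 1L, seed = block_seed)[[1]]
        b <- b + 1L
      }
      conv <- haplotypes_to_vcf(blk, chrom = chrom, locus_length = len,
                                offset = offset, seed = block_seed + 2L)
      site_tbls[[length(site_tbls) + 1L]] <-
        conv$gt[, c("chrom", "pos", "ref", "alt", "dp", "mq")]
      dosages[[length(dosages) + 1L]] <- gt_dosage(conv$gt)
      sample_names <- gt_samples(conv$gt)
      sample_demes <- conv$truth$deme
    }
  }
  sites <- dplyr::bind_rows(site_tbls)
  dosage <- do.call(rbind, dosages)
  colnames(dosage) <- sample_names
  gt <- genotype_table(sites, dosage)
  popmap <- population_map(
    tibble::tibble(sample = sample_names,
                   population = c("control", "focal")[sample_demes],
                   altitude = c(100, 2600)[sample_demes]),
    groups = list(low = "control")
  )
  chrom_lengths <- stats::setNames(rep(chrom_length, n_chrom), chrom_names)
  list(gt = gt, popmap = popmap,
       genes = simulate_gene_annotation(chrom_lengths),
       truth = truth, chrom_lengths = chrom_lengths)
}

# concatenate independent loci into one block with bp positions
stitch_blocks <- function(blocks, block_length) {
  haps <- do.call(cbind, lapply(blocks, `[[`, "haps"))
  positions <- unlist(lapply(seq_along(blocks), function(j) {
    (j - 1L) * block_length + blocks[[j]]$positions * block_length
  }))
  list(haps = haps, positions = positions, demes = blocks[[1]]$demes)
}

# run the forward sweep in deme 2 of a two-deme neutral block
plant_sweep <- function(block, sweep_cfg, sample_sizes, seed) {
  focal_rows <- which(block$demes == 2L)
  founders <- list(haps = block$haps[focal_rows, , drop = FALSE],
                   positions = block$positions)
  cfg <- sweep_cfg
  cfg$sample_size <- length(focal_rows)
  swept <- simulate_sweep(cfg, founders = founders, seed = seed)
  # merge: control rows keep the neutral sites; focal rows get swept sites
  ctrl_rows <- which(block$demes == 1L)
  ctrl_pos <- if (length(block$positions) && max(block$positions) <= 1)
    block$positions * cfg$locus_length else block$positions
  all_pos <- sort(unique(c(ctrl_pos, swept$positions)))
  n_total <- nrow(block$haps)
  haps <- matrix(0L, nrow = n_total, ncol = length(all_pos))
  haps[ctrl_rows, match(ctrl_pos, all_pos)] <-
    block$haps[ctrl_rows, , drop = FALSE]
  haps[focal_rows, match(swept$positions, all_pos)] <- swept$haps
  # drop sites monomorphic across everyone (sweep can fix or purge alleles)
  seg <- colSums(haps) > 0L & colSums(haps) < n_total
  list(haps = haps[, seg, drop = FALSE], positions = all_pos[seg],
       demes = block$demes)
}

#' Deterministic synthetic gene tiling
#'
#' Regularly spaced synthetic genes (for annotation and concordance tests):
#' one `gene_length` gene every `spacing` bp on the + strand.
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param gene_length,spacing Gene span and start-to-start spacing in bp.
#' @return A gene annotation tibble (`chrom`, `start`, `end`, `strand`,
#'   `gene_id`, `gene_name`).
#' @export
simulate_gene_annotation <- function(chrom_lengths, gene_length = 10000L,
                                     spacing = 25000L) {
  purrr::map_dfr(names(chrom_lengths), function(chrom) {
    starts <- seq(5000L, chrom_lengths[[chrom]] - gene_length,
                  by = spacing)
    tibble::tibble(chrom = chrom, start = starts,
                   end = starts + gene_length, strand = "+",
                   gene_id = sprintf("%s_g%03d", chrom,
                                     seq_along(starts)),
                   gene_name = sprintf("%s_g%03d", chrom,
                                       seq_along(starts)))
  })
}
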