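#' Assemble a scan run configuration
#'
#' Inputs may be file paths (VCF, population map, BED/GFF3 genes) or the
#' corresponding in-memory objects. Every referenced population must exist
#' in the map; this is validated before any computation.
#'
#' @param vcf Path to a VCF, or a [genotype_table()].
#' @param popmap Path to a population map, or a `pop_map`.
#' @param genes Path to BED/GFF3, a gene tibble, or `NULL`.
#' @param contrasts List of `list(name=, focal=, control=)` entries.
#' @param window A [window_spec()].
#' @param filter A [site_filter_config()], or `NULL` to skip filtering.
#' @param quantile Top-quantile mass for outlier calling (both statistics,
#'   and the XP-CLR / Dxy validators).
#' @param xpclr An [xpclr_config()], or `NULL` to skip the XP-CLR
#'   validation.
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for any stochastic step.
#' @return A `run_config` list.
#' @export
run_config <- function(vcf, popmap, genes = NULL, contrasts,
                       window = window_spec(),
                       filter = site_filter_config(),
                       quantile = 0.01, xpclr = xpclr_config(),
                       chrom_lengths = NULL, out_dir = ".", seed = 1L) {
  stopifnot(is.list(contrasts))
  for (ct in contrasts) {
    if (is.null(ct$name) || is.null(ct$focal) || is.null(ct$control)) {
      stop("each contrast needs `name`, `focal` and `control`",
           call. = FALSE)
    }
  }
  structure(list(vcf = vcf, popmap = popmap, genes = genes,
                 contrasts = contrasts, window = window, filter = filter,
                 quantile = quantile, xpclr = xpclr,
                 chrom_lengths = chrom_lengths, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the [run_config()] arguments; `window`, `filter` and
#' `xpclr` sub-maps mirror the fields of their constructors.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(
    vcf = y$vcf, popmap = y$popmap, genes = y$genes,
    contrasts = y$contrasts,
    window = do.call(window_spec, y$window %||% list()),
    filter = if (isFALSE(y$filter)) NULL else
      do.call(site_filter_config, y$filter %||% list()),
    quantile = y$quantile %||% 0.01,
    xpclr = if (isFALSE(y$xpclr)) NULL else
      do.call(xpclr_config, y$xpclr %||% list()),
    chrom_lengths = if (!is.null(y$chrom_lengths))
      unlist(y$chrom_lengths) else NULL,
    out_dir = y$out_dir %||% ".", seed = y$seed %||% 1L
  )
}

#' Run the full selective-sweep scan
#'
#' Pipeline order: site filtering, per-contrast window statistics, joint
#' top-quantile F_ST / diversity-ratio outlier calling, merging into
#' segments, gene annotation, XP-CLR and Dxy validation with gene-level
#' concordance, and (when three or more populations carry altitudes)
#' allele-frequency-altitude trajectories of candidate SNPs. Thresholds
#' are recomputed per contrast on that contrast's window table. Re-running
#' with identical inputs and seed reproduces byte-identical files.
#'
#' @param cfg A [run_config()].
#' @return A `scan_run` list: per-contrast `sweep_contrast` results, the
#'   manifest, and the output directory. Files written per contrast:
#'   `<name>_windows.tsv`, `<name>_thresholds.tsv`, `<name>_segments.bed`,
#'   `<name>_genes.tsv`, `<name>_concordance.tsv`,
#'   `<name>_trajectory.tsv`, plus a run `manifest.json`.
#' @export
run_scan <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  gt <- if (is.character(cfg$vcf)) read_vcf(cfg$vcf) else cfg$vcf
  popmap <- if (is.character(cfg$popmap)) read_population_map(cfg$popmap)
    else cfg$popmap
  genes <- if (is.character(cfg$genes)) read_gene_annotations(cfg$genes)
    else cfg$genes
  # validate contrasts before any computation
  for (ct in cfg$contrasts) {
    resolve_samples(popmap, ct$focal)
    resolve_samples(popmap, ct$control)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg$filter)) gt <- apply_site_filters(gt, cfg$filter)
  if (!length(cfg$contrasts)) {
    warning("empty contrast list: writing manifest only", call. = FALSE)
  }
  results <- lapply(cfg$contrasts, function(ct) {
    scan_one_contrast(gt, popmap, genes, ct, cfg)
  })
  names(results) <- vapply(cfg$contrasts, `[[`, "", "name")
  manifest <- write_manifest(cfg, results)
  structure(list(contrasts = results, manifest = manifest,
                 out_dir = cfg$out_dir),
            class = "scan_run")
}

scan_one_contrast <- function(gt, popmap, genes, ct, cfg) {
  set.seed(cfg$seed)
  windows <- window_stats(gt, popmap, ct$focal, ct$control,
                          spec = cfg$window,
                          chrom_lengths = cfg$chrom_lengths)
  thr <- outlier_thresholds(windows, cfg$quantile)
  outliers <- call_joint_outliers(windows, thr)
  segments <- merge_windows_to_segments(outliers)

  # Dxy validation: top-quantile windows merged to regions
  unmasked <- !windows$masked & !is.na(windows$dxy)
  dxy_thr <- empirical_quantile_threshold(windows$dxy[unmasked],
                                          cfg$quantile)
  dxy_regions <- merge_intervals(
    windows[unmasked & windows$dxy >= dxy_thr, c("chrom", "start", "end")])

  # XP-CLR validation
  xp <- NULL
  xp_regions <- NULL
  xp_thr <- NA_real_
  if (!is.null(cfg$xpclr)) {
    focal_s <- resolve_samples(popmap, ct$focal)
    control_s <- resolve_samples(popmap, ct$control)
    xp <- xpclr_scores(gt, control_s, focal_s, cfg$xpclr,
                       chrom_lengths = cfg$chrom_lengths)
    xp_thr <- empirical_quantile_threshold(xp$score[!is.na(xp$score)],
                                           cfg$quantile)
    xp_regions <- xpclr_outlier_regions(xp, cfg$quantile,
                                        cfg$xpclr$grid_spacing)
  }

  seg_ann <- segments
  concordance <- NULL
  gene_set <- NULL
  if (!is.null(genes)) {
    seg_ann <- annotate_genes(segments, genes)
    gene_set <- attr(seg_ann, "gene_set")
    dxy_genes <- overlapping_genes(dxy_regions, genes)
    concordance <- tibble::tibble(
      validator = "dxy",
      n_candidate = length(gene_set$gene_id),
      n_overlap = length(intersect(gene_set$gene_id, dxy_genes)),
      fraction = NA_real_
    )
    if (!is.null(xp_regions)) {
      xp_genes <- overlapping_genes(xp_regions, genes)
      concordance <- dplyr::bind_rows(concordance, tibble::tibble(
        validator = "xpclr",
        n_candidate = length(gene_set$gene_id),
        n_overlap = length(intersect(gene_set$gene_id, xp_genes)),
        fraction = NA_real_
      ))
    }
    concordance$fraction <- ifelse(concordance$n_candidate > 0,
                                   concordance$n_overlap /
                                     concordance$n_candidate, NA_real_)
  }
  seg_ann$supported_by_dxy <- segment_supported(segments, dxy_regions)
  seg_ann$supported_by_xpclr <- if (!is.null(xp_regions))
    segment_supported(segments, xp_regions) else NA

  # trajectories of candidate SNPs along the altitude gradient
  trajectory <- NULL
  alts <- unique(stats::na.omit(popmap$altitude))
  if (length(alts) >= 3 && nrow(segments)) {
    cand <- candidate_sites(gt, segments)
    if (nrow(cand)) {
      trajectory <- allele_frequency_trajectory(gt, popmap, cand)
    }
  }

  res <- structure(list(
    name = ct$name, focal = ct$focal, control = ct$control,
    windows = windows, thresholds = thr, dxy_threshold = dxy_thr,
    xpclr_threshold = xp_thr, outliers = outliers, segments = seg_ann,
    gene_set = gene_set, concordance = concordance,
    xpclr = xp, trajectory = trajectory
  ), class = "sweep_contrast")
  write_contrast_files(res, cfg$out_dir)
  res
}

overlapping_genes <- function(regions, genes) {
  if (is.null(regions) || !nrow(regions)) return(character(0))
  hits <- purrr::pmap(regions[, c("chrom", "start", "end")],
                      function(chrom, start, end) {
    genes$gene_id[genes$chrom == chrom & genes$start < end &
                    genes$end > start]
  })
  unique(unlist(hits))
}

segment_supported <- function(segments, regions) {
  if (!nrow(segments)) return(logical(0))
  if (is.null(regions) || !nrow(regions)) return(rep(FALSE, nrow(segments)))
  purrr::pmap_lgl(segments[, c("chrom", "start", "end")],
                  function(chrom, start, end) {
    any(regions$chrom == chrom & regions$start < end & regions$end > start)
  })
}

candidate_sites <- function(gt, segments) {
  keep <- rep(FALSE, nrow(gt))
  for (i in seq_len(nrow(segments))) {
    keep <- keep | (gt$chrom == segments$chrom[i] &
                      gt$pos >= segments$start[i] &
                      gt$pos < segments$end[i])
  }
  gt[keep, c("chrom", "pos")]
}

write_contrast_files <- function(res, out_dir) {
  pre <- file.path(out_dir, res$name)
  write_window_stats(res$windows, paste0(pre, "_windows.tsv"))

  thr_tbl <- data.frame(
    statistic = c("fst", "log2_pi_ratio", "dxy", "xpclr"),
    threshold = format_num(c(res$thresholds$fst_threshold,
                             res$thresholds$pi_ratio_threshold,
                             res$dxy_threshold, res$xpclr_threshold)),
    quantile = format_num(rep(res$thresholds$quantile, 4))
  )
  utils::write.table(thr_tbl, paste0(pre, "_thresholds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  seg <- res$segments
  bed <- data.frame(chrom = seg$chrom, start = seg$start, end = seg$end,
                    name = if (nrow(seg)) paste0(res$name, "_seg",
                                                 seq_len(nrow(seg)))
                           else character(0),
                    score = format_num(seg$peak_fst))
  utils::write.table(bed, paste0(pre, "_segments.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  gene_tbl <- if (!is.null(res$gene_set) && nrow(res$gene_set)) {
    data.frame(gene_id = res$gene_set$gene_id,
               gene_name = res$gene_set$gene_name)
  } else data.frame(gene_id = character(0), gene_name = character(0))
  utils::write.table(gene_tbl, paste0(pre, "_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  conc <- res$concordance
  if (is.null(conc)) {
    conc <- tibble::tibble(validator = character(0),
                           n_candidate = integer(0),
                           n_overlap = integer(0), fraction = numeric(0))
  }
  conc$fraction <- format_num(conc$fraction)
  utils::write.table(as.data.frame(conc), paste0(pre, "_concordance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  con <- file(paste0(pre, "_trajectory.tsv"), "w")
  if (is.null(res$trajectory)) {
    writeLines(paste("# trajectory requires >= 3 populations with",
                     "altitudes and >= 1 candidate SNP"), con)
  } else {
    tr <- as.data.frame(res$trajectory)
    num <- vapply(tr, is.double, logical(1))
    tr[num] <- lapply(tr[num], format_num)
    utils::write.table(tr, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  close(con)
  invisible(res)
}

write_manifest <- function(cfg, results) {
  input_md5 <- list()
  for (nm in c("vcf", "popmap", "genes")) {
    if (is.character(cfg[[nm]]) && length(cfg[[nm]]) == 1 &&
        file.exists(cfg[[nm]])) {
      input_md5[[nm]] <- unname(tools::md5sum(cfg[[nm]]))
    }
  }
  cfg_txt <- paste(deparse(cfg[setdiff(names(cfg), "out_dir")]),
                   collapse = "\n")
  tmp <- tempfile()
  writeLines(cfg_txt, tmp)
  outputs <- sort(setdiff(list.files(cfg$out_dir, full.names = FALSE),
                          "manifest.json"))
  manifest <- list(
    tool = "sweepscan",
    version = as.character(utils::packageVersion("sweepscan")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(tmp)),
    inputs = input_md5,
    contrasts = names(results),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(cfg$out_dir, outputs))), outputs))
  )
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

#' Simulation utilities behind one entry point
#'
#' Thin, validated pass-through to the synthetic-data operations, writing
#' results (ms-format text, VCF, grid reports) into `out_dir`.
#'
#' @param what `"neutral"`, `"sweep"` or `"calibrate"`.
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param model An [iwm_model()] (`neutral`, `calibrate`).
#' @param n_replicates Replicate count (`neutral`).
#' @param sweep_cfg A [sweep_sim_config()] (`sweep`).
#' @param target,split_grid,migration_grid Calibration inputs
#'   (`calibrate`); see [calibrate_iwm_to_fst()].
#' @return The simulation result, invisibly; files land in `out_dir`.
#' @export
run_simulate <- function(what = c("neutral", "sweep", "calibrate"),
                         out_dir = ".", seed = 1L, model = iwm_model(),
                         n_replicates = 100L,
                         sweep_cfg = sweep_sim_config(),
                         target = NULL, split_grid = c(0, 0.25, 0.5, 1),
                         migration_grid = c(0, 1, 10)) {
  what <- match.arg(what)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (what == "neutral") {
    blocks <- simulate_neutral_iwm(model, n_replicates, seed)
    write_ms(blocks, file.path(out_dir, "neutral.ms"))
    invisible(blocks)
  } else if (what == "sweep") {
    swept <- simulate_sweep(sweep_cfg, seed = seed)
    block <- list(haps = swept$haps,
                  positions = swept$positions / sweep_cfg$locus_length,
                  demes = rep(1L, nrow(swept$haps)))
    write_ms(block, file.path(out_dir, "sweep.ms"))
    haplotypes_to_vcf(block, locus_length = sweep_cfg$locus_length,
                      path = file.path(out_dir, "sweep.vcf"), seed = seed)
    utils::write.table(
      data.frame(sweep_position = swept$sweep_position,
                 generations = swept$generations,
                 restarts = swept$restarts),
      file.path(out_dir, "sweep_truth.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    invisible(swept)
  } else {
    if (is.null(target)) stop("`target` required for calibration",
                              call. = FALSE)
    cal <- calibrate_iwm_to_fst(target, template = model,
                                split_grid = split_grid,
                                migration_grid = migration_grid,
                                seed = seed)
    grid <- cal$grid
    grid$mean_fst <- format_num(grid$mean_fst)
    grid$discrepancy <- format_num(grid$discrepancy)
    utils::write.table(as.data.frame(grid),
                       file.path(out_dir, "calibration_grid.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(split_time = cal$best_model$split_time,
           migration_rate = cal$best_model$migration_rate,
           discrepancy = cal$discrepancy, converged = cal$converged,
           envelope_99 = cal$envelope_99),
      file.path(out_dir, "calibration_best.json"),
      auto_unbox = TRUE, digits = NA)
    invisible(cal)
  }
}
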