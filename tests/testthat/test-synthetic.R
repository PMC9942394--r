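test_that("simulations are pure functions of model and seed", {
  m <- iwm_model(sample_sizes = c(6L, 6L), theta = 8, split_time = 0.4)
  a <- simulate_neutral_iwm(m, 3L, seed = 123)
  b <- simulate_neutral_iwm(m, 3L, seed = 123)
  expect_identical(a, b)
  c_ <- simulate_neutral_iwm(m, 3L, seed = 124)
  expect_false(identical(a, c_))

  cfg <- sweep_sim_config(n_diploids = 50L, s = 0.5, locus_length = 20000L,
                          sample_size = 10L)
  s1 <- simulate_sweep(cfg, seed = 5)
  s2 <- simulate_sweep(cfg, seed = 5)
  expect_identical(s1$haps, s2$haps)
  expect_identical(s1$positions, s2$positions)
})

test_that("model validation rejects impossible demographies", {
  expect_error(iwm_model(split_time = -1))
  expect_error(iwm_model(migration_rate = -0.5))
  expect_error(iwm_model(theta = 0))
  expect_error(iwm_model(rho = 5), "rho")
})

test_that("zero split time with zero migration collapses to panmixia", {
  m <- iwm_model(sample_sizes = c(10L, 10L), theta = 10,
                 split_time = 0, migration_rate = 0)
  fst <- neutral_fst_distribution(m, 300, seed = 31)
  expect_lt(abs(mean(fst, na.rm = TRUE)), 0.02)
})

test_that("site-frequency spectrum matches the ms-compatible oracle", {
  skip_if(Sys.which("mspms") == "", "mspms not on PATH")
  n_rep <- 800
  ours <- simulate_neutral_iwm(iwm_model(sample_sizes = 10L, theta = 5),
                               n_rep, seed = 61)
  sfs_ours <- rep(0, 9)
  for (b in ours) {
    if (ncol(b$haps) == 0) next
    tab <- tabulate(colSums(b$haps), nbins = 9)
    sfs_ours <- sfs_ours + tab
  }
  ms_out <- tempfile()
  system2("mspms", c("10", as.character(n_rep), "-t", "5",
                     "-seeds", "71", "72", "73"), stdout = ms_out)
  sfs_ms <- rep(0, 9)
  for (b in read_ms(readLines(ms_out))) {
    if (ncol(b$haps) == 0) next
    sfs_ms <- sfs_ms + tabulate(colSums(b$haps), nbins = 9)
  }
  p <- suppressWarnings(chisq.test(rbind(sfs_ours, sfs_ms))$p.value)
  expect_gt(p, 1e-3)

  # Tajima's D distribution: mean agrees with the oracle's (its common
  # expectation is slightly negative in finite samples, so 0 is not the
  # reference point here)
  mean_D <- function(blocks) {
    taj <- vapply(blocks, function(b) {
      if (ncol(b$haps) < 3) return(NA_real_)
      S <- ncol(b$haps); n <- nrow(b$haps); pfr <- colMeans(b$haps)
      pi_t <- sum(2 * pfr * (1 - pfr) * n / (n - 1))
      k <- sweepscan:::tajima_constants(n)
      (pi_t - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
    }, numeric(1))
    taj <- taj[!is.na(taj)]
    c(mean(taj), sd(taj) / sqrt(length(taj)))
  }
  d_ours <- mean_D(ours)
  d_ms <- mean_D(read_ms(readLines(ms_out)))
  expect_lt(abs(d_ours[1] - d_ms[1]),
            3 * sqrt(d_ours[2]^2 + d_ms[2]^2))
})

test_that("neutral fixation probability of a new mutation is 1/(2N)", {
  set.seed(88)
  n_runs <- 5000
  N <- 20L
  fixed <- vapply(seq_len(n_runs), function(i) wf_trajectory(N, 0)$fixed,
                  logical(1))
  p_hat <- mean(fixed)
  p0 <- 1 / (2 * N)
  se <- sqrt(p0 * (1 - p0) / n_runs)
  expect_lt(abs(p_hat - p0), 3 * se)
})

test_that("a sweep carves a diversity trough at the selected site", {
  # 2Ns = 100 over a 1 Mb locus; N chosen large enough that the sweep takes
  # tens of generations, giving recombination time to free the flanks
  cfg <- sweep_sim_config(n_diploids = 500L, s = 0.1, locus_length = 1e6,
                          sample_size = 20L)
  n_rep <- 50
  trough_lower <- logical(n_rep)
  founder_model <- iwm_model(sample_sizes = 20L, theta = 10)
  for (r in seq_len(n_rep)) {
    if (r %% 10 == 1) {
      blocks <- simulate_neutral_iwm(founder_model, 100L, seed = 700 + r)
      founders <- sweepscan:::stitch_blocks(blocks, 10000L)
    }
    sw <- simulate_sweep(cfg, founders = founders, seed = 800 + r)
    pi_of <- function(lo, hi) {
      j <- sw$positions >= lo & sw$positions < hi
      if (!any(j)) return(0)
      p <- colMeans(sw$haps[, j, drop = FALSE])
      n <- nrow(sw$haps)
      sum(2 * p * (1 - p) * n / (n - 1)) / (hi - lo)
    }
    centre <- pi_of(480000, 520000)
    flanks <- (pi_of(0, 40000) + pi_of(960000, 1e6)) / 2
    trough_lower[r] <- centre < flanks
  }
  expect_gte(mean(trough_lower), 0.9)
})

test_that("haplotype pairing, collision shifts and the round-trip identity", {
  blk <- list(haps = rbind(c(1L, 0L), c(0L, 0L), c(0L, 1L), c(1L, 1L)),
              positions = c(0.2, 0.6))
  conv <- haplotypes_to_vcf(blk, locus_length = 100L, seed = 1)
  expect_equal(nrow(conv$gt), 2L)
  expect_equal(gt_samples(conv$gt), c("p1_i1", "p1_i2"))
  expect_equal(unname(gt_dosage(conv$gt)),
               rbind(c(1L, 1L), c(0L, 2L)))   # paired consecutive rows

  # two sites colliding on one bp: second shifted, count preserved
  coll <- list(haps = rbind(c(1L, 0L), c(0L, 1L)),
               positions = c(0.51, 0.512))
  conv2 <- haplotypes_to_vcf(coll, locus_length = 100L, seed = 1)
  expect_equal(conv2$gt$pos, c(51L, 52L))

  expect_error(haplotypes_to_vcf(list(haps = matrix(0L, 3, 1),
                                      positions = 0.5)), "odd")
})

test_that("simulate -> VCF -> read -> windowed pi reproduces the haplotype value", {
  m <- iwm_model(sample_sizes = c(10L, 10L), theta = 30, split_time = 0.2)
  blk <- simulate_neutral_iwm(m, 1L, seed = 13)[[1]]
  conv <- haplotypes_to_vcf(blk, locus_length = 30000L, seed = 2)
  path <- tempfile(fileext = ".vcf")
  write_vcf(conv$gt, path)
  back <- read_vcf(path)
  win <- tibble::tibble(chrom = "chr1", start = 0L, end = 30000L)
  for (deme in 1:2) {
    rows <- blk$demes == deme
    p <- colMeans(blk$haps[rows, , drop = FALSE])
    n <- sum(rows)
    direct <- sum(2 * p * (1 - p) * n / (n - 1)) / 30000
    via_vcf <- windowed_pi(back, conv$truth$sample[conv$truth$deme == deme],
                           win)$pi
    expect_equal(via_vcf, direct, tolerance = 1e-10)
  }
})

test_that("quality-field injection lets the filters reject degraded sites", {
  m <- iwm_model(sample_sizes = c(4L, 4L), theta = 20)
  blk <- simulate_neutral_iwm(m, 1L, seed = 3)[[1]]
  conv <- haplotypes_to_vcf(blk, locus_length = 10000L,
                            dp_fun = function(n) rep(3L, n), seed = 4)
  out <- suppressWarnings(apply_site_filters(conv$gt))
  expect_equal(nrow(out), 0L)
  expect_equal(unname(attr(out, "rejections")["depth_low"]), nrow(conv$gt))
})

test_that("degenerate target calibrates to the panmictic corner", {
  cal <- calibrate_iwm_to_fst(
    0, template = iwm_model(sample_sizes = c(10L, 10L), theta = 10),
    split_grid = c(0, 0.5), migration_grid = c(0, 10),
    n_replicates = 80L, seed = 5)
  expect_lt(abs(mean(cal$neutral_fst, na.rm = TRUE)), 0.02)
  expect_true(cal$best_model$split_time == 0 ||
                cal$best_model$migration_rate == 10)
  expect_true(cal$converged)
})

test_that("the neutral envelope is exceeded by exactly the top 1 percent", {
  cal <- calibrate_iwm_to_fst(
    0.2, template = iwm_model(sample_sizes = c(10L, 10L), theta = 10),
    split_grid = c(0.25), migration_grid = c(0),
    n_replicates = 200L, seed = 9)
  v <- cal$neutral_fst[is.finite(cal$neutral_fst)]
  k <- max(1L, floor(0.01 * length(v)))
  expect_equal(sum(v >= cal$envelope_99), k)
})

test_that("scan-genome truth table matches the planted layout", {
  ds <- simulate_scan_genome(n_chrom = 2L, chrom_length = 4e5,
                             sweep_chroms = 2L, seed = 19)
  expect_equal(ds$truth$chrom, "chr02")
  expect_equal(nrow(ds$gt[ds$gt$chrom == "chr01", ]) > 100, TRUE)
  expect_setequal(unique(ds$popmap$population), c("control", "focal"))
  expect_equal(resolve_samples(ds$popmap, "low"),
               ds$popmap$sample[ds$popmap$population == "control"])
  # swept region: focal diversity collapsed relative to control
  gt <- ds$gt
  reg <- gt$chrom == "chr02" & gt$pos >= ds$truth$sweep_pos - 20000 &
    gt$pos < ds$truth$sweep_pos + 20000
  foc <- resolve_samples(ds$popmap, "focal")
  ctl <- resolve_samples(ds$popmap, "control")
  win <- tibble::tibble(chrom = "chr02",
                        start = ds$truth$sweep_pos - 20000,
                        end = ds$truth$sweep_pos + 20000)
  expect_lt(windowed_pi(gt, foc, win)$pi, windowed_pi(gt, ctl, win)$pi)
})
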