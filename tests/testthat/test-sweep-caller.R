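test_that("nearest-rank threshold takes the floor(q*n) largest values", {
  expect_equal(empirical_quantile_threshold(1:200, 0.01), 199)
  expect_equal(empirical_quantile_threshold(1:50, 0.01), 50)  # min-1 rule
  set.seed(2024)
  x <- rnorm(10000)
  expect_lt(abs(empirical_quantile_threshold(x, 0.01) - qnorm(0.99)), 0.1)
  expect_error(empirical_quantile_threshold(c(NA, Inf)), "no finite")
})

test_that("joint outliers require both thresholds simultaneously", {
  thr <- structure(list(fst_threshold = 0.44, pi_ratio_threshold = log2(2.27),
                        quantile = 0.01), class = "outlier_thresholds")
  w <- tibble::tibble(
    chrom = "chr1", start = c(0, 1, 2, 3) * 100, end = c(1, 2, 3, 4) * 100,
    fst = c(0.9, 0.9, 0.1, 0.45),
    log2_pi_ratio = c(3.0, 0.1, 3.0, Inf),
    masked = c(FALSE, FALSE, FALSE, FALSE))
  out <- call_joint_outliers(w, thr)
  expect_equal(out$start, c(0, 300))              # both exceed; Inf counts
  w$masked[1] <- TRUE
  expect_equal(call_joint_outliers(w, thr)$start, 300)  # masked never qualify
})

test_that("a constructed window table yields exactly its planted outliers", {
  set.seed(7)
  n <- 1000
  w <- tibble::tibble(
    chrom = rep(sprintf("c%d", 1:10), each = 100),
    start = rep(seq(0, 99) * 40000, 10), end = start + 40000,
    fst = runif(n, 0, 0.3),
    log2_pi_ratio = runif(n, -1, 1),
    masked = FALSE)
  planted <- sample(n, 12)
  w$fst[planted] <- runif(12, 0.6, 0.9)
  w$log2_pi_ratio[planted] <- runif(12, 2, 4)
  thr <- structure(list(fst_threshold = 0.6, pi_ratio_threshold = 2,
                        quantile = 0.01), class = "outlier_thresholds")
  out <- call_joint_outliers(w, thr)
  expect_equal(nrow(out), 12L)
  expect_setequal(paste(out$chrom, out$start),
                  paste(w$chrom[planted], w$start[planted]))
})

test_that("overlapping and book-ended windows merge; peaks are maxima", {
  w <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(0, 20000, 0), end = c(40000, 60000, 40000),
    fst = c(0.5, 0.7, 0.6), log2_pi_ratio = c(2, 3, 2.5), masked = FALSE)
  seg <- merge_windows_to_segments(w)
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$end[seg$chrom == "chr1"], 60000)
  expect_equal(seg$peak_fst[seg$chrom == "chr1"], 0.7)
  expect_equal(seg$n_windows, c(2L, 1L))

  single <- merge_windows_to_segments(w[3, ])
  expect_equal(tibble::as_tibble(single)[, c("chrom", "start", "end")],
               w[3, c("chrom", "start", "end")])

  adjacent <- tibble::tibble(chrom = "chr1", start = c(0, 40000),
                             end = c(40000, 80000), fst = c(0.5, 0.6),
                             log2_pi_ratio = c(2, 2), masked = FALSE)
  expect_equal(merge_windows_to_segments(adjacent)$end, 80000)
})

test_that("raising either threshold never adds a segment", {
  set.seed(17)
  w <- tibble::tibble(
    chrom = rep("chr1", 200), start = seq(0, 199) * 20000,
    end = start + 40000, fst = runif(200), log2_pi_ratio = rnorm(200),
    masked = FALSE)
  base_thr <- structure(list(fst_threshold = 0.5, pi_ratio_threshold = 0,
                             quantile = 0.01), class = "outlier_thresholds")
  base <- call_joint_outliers(w, base_thr)
  for (bump in list(c(0.2, 0), c(0, 0.8), c(0.1, 0.5))) {
    thr2 <- base_thr
    thr2$fst_threshold <- thr2$fst_threshold + bump[1]
    thr2$pi_ratio_threshold <- thr2$pi_ratio_threshold + bump[2]
    tighter <- call_joint_outliers(w, thr2)
    expect_true(all(paste(tighter$chrom, tighter$start) %in%
                      paste(base$chrom, base$start)))
    expect_lte(nrow(merge_windows_to_segments(tighter)),
               nrow(merge_windows_to_segments(base)))
  }
})

test_that("gene assignment uses >= 1 bp overlap with half-open bounds", {
  seg <- merge_windows_to_segments(tibble::tibble(
    chrom = "chr1", start = 0, end = 60000, fst = 0.9,
    log2_pi_ratio = 3, masked = FALSE))
  genes <- tibble::tibble(
    chrom = "chr1", start = c(10000, 59999, 60000),
    end = c(20000, 70000, 70000), strand = "+",
    gene_id = c("gA", "gB", "gC"), gene_name = c("gA", "gB", "gC"))
  ann <- annotate_genes(seg, genes)
  expect_setequal(ann$genes[[1]], c("gA", "gB"))  # gC excluded: half-open
})

test_that("gene assignment equals the quadratic all-pairs oracle", {
  set.seed(99)
  segs <- tibble::tibble(
    chrom = sample(c("c1", "c2", "c3"), 100, replace = TRUE),
    start = sample(0:500000, 100))
  segs$end <- segs$start + sample(1000:80000, 100, replace = TRUE)
  segs$fst <- runif(100); segs$log2_pi_ratio <- runif(100)
  segs <- dplyr::arrange(segs, chrom, start)
  genes <- tibble::tibble(
    chrom = sample(c("c1", "c2", "c3"), 500, replace = TRUE),
    start = sample(0:550000, 500))
  genes$end <- genes$start + sample(200:20000, 500, replace = TRUE)
  genes$strand <- "+"
  genes$gene_id <- paste0("g", 1:500)
  genes$gene_name <- genes$gene_id
  seg_cls <- structure(segs, class = c("sweep_segments", class(segs)))
  ann <- annotate_genes(seg_cls, genes)
  oracle <- oracle_overlaps(segs, genes)
  for (i in seq_len(nrow(segs))) {
    expect_setequal(ann$genes[[i]], oracle[[i]])
  }
})

test_that("concordance is the candidate-denominated overlap fraction", {
  r <- cross_method_concordance(c("g1", "g2", "g3", "g4"), c("g2", "g3", "g5"))
  expect_equal(r$fraction, 0.5)
  expect_equal(r$overlap, c("g2", "g3"))
  expect_equal(cross_method_concordance(c("a", "b"), c("a", "b"))$fraction, 1)
  expect_equal(cross_method_concordance(c("a", "b"), c("x"))$fraction, 0)
  expect_error(cross_method_concordance(character(0), "a"), "empty")
})

test_that("contrast overlap produces inclusion-exclusion cells", {
  cells <- contrast_overlap(list(A = c("a", "b"), B = c("b", "c"),
                                 C = c("c", "d")))
  n_of <- function(a, b, cc) cells$n[cells$A == a & cells$B == b & cells$C == cc]
  expect_equal(n_of(TRUE, TRUE, FALSE), 1L)   # b
  expect_equal(n_of(FALSE, TRUE, TRUE), 1L)   # c
  expect_length(n_of(TRUE, TRUE, TRUE), 0L)   # empty triple cell absent
  expect_equal(sum(cells$n), 4L)              # |union|

  same <- contrast_overlap(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(nrow(same), 1L)
  expect_equal(same$n, 2L)

  set.seed(5)
  sets <- lapply(1:3, function(i) sample(letters, sample(5:15, 1)))
  names(sets) <- c("S1", "S2", "S3")
  rand <- contrast_overlap(sets)
  expect_equal(sum(rand$n), length(unique(unlist(sets))))
})

test_that("altitude-increasing sites need monotone rise above the floor", {
  pops <- paste0("P", 1:6)
  pm <- population_map(tibble::tibble(
    sample = paste0("s", 1:6), population = pops,
    altitude = c(80, 300, 700, 1000, 2000, 2600)))
  freq_site <- function(f) matrix(as.integer(round(f * 2)), nrow = 1)
  build <- function(freqs) {
    dosage <- do.call(rbind, lapply(freqs, function(f)
      as.integer(round(f * 2))))
    colnames(dosage) <- paste0("s", 1:6)
    gt_from_dosage(dosage)
  }
  gt <- build(list(c(0, 0, 0.5, 0.5, 0.5, 1),
                   c(0.5, 0.5, 0.5, 0.5, 0, 1),
                   c(0, 0, 0, 0, 0, 0.5)))
  tr <- allele_frequency_trajectory(gt, pm, min_rise = 0.2)
  expect_equal(tr$altitude_increasing, c(TRUE, FALSE, TRUE))
  expect_equal(tr$rank_correlation[1], cor(1:6, c(0, 0, 1, 1, 1, 2),
                                           method = "spearman"))
  # a rise below the floor is not flagged
  tr2 <- allele_frequency_trajectory(gt, pm, min_rise = 1.2)
  expect_false(any(tr2$altitude_increasing[3]))
})

test_that("strictly monotone frequencies flag with rank correlation 1", {
  # 6 populations x 3 diploids: alt counts 0..5 of 6 -> distinct frequencies
  pm <- population_map(tibble::tibble(
    sample = paste0("s", 1:18), population = rep(paste0("P", 1:6), each = 3),
    altitude = rep(1:6 * 100, each = 3)))
  counts <- list(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1),
                 c(2, 1, 1), c(2, 2, 1))
  dosage <- matrix(as.integer(unlist(counts)), nrow = 1,
                   dimnames = list(NULL, paste0("s", 1:18)))
  tr <- allele_frequency_trajectory(gt_from_dosage(dosage), pm)
  expect_true(tr$altitude_increasing)
  expect_equal(tr$rank_correlation, 1)
})

test_that("a population with no calls marks the site incomplete", {
  pm <- population_map(tibble::tibble(
    sample = paste0("s", 1:4), population = paste0("P", 1:4),
    altitude = 1:4 * 100))
  dosage <- matrix(c(0L, NA, 1L, 2L), nrow = 1,
                   dimnames = list(NULL, paste0("s", 1:4)))
  tr <- allele_frequency_trajectory(gt_from_dosage(dosage), pm)
  expect_true(tr$incomplete)
  expect_false(tr$altitude_increasing)
})
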