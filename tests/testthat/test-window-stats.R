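test_that("a fixed difference gives F_ST = 1 and Dxy = 1/L", {
  dosage <- matrix(c(rep(2L, 5), rep(0L, 5)), nrow = 1)
  colnames(dosage) <- paste0("s", 1:10)
  gt <- gt_from_dosage(dosage, pos = 5L)
  g1 <- paste0("s", 1:5); g2 <- paste0("s", 6:10)
  comp <- site_fst_components(gt, g1, g2)
  expect_gt(comp$a, 0)
  expect_equal(comp$b, 0)
  expect_equal(comp$c, 0)
  expect_equal(comp$a / (comp$a + comp$b + comp$c), 1)

  win <- whole_window(gt, 50L)
  expect_equal(windowed_fst(gt, g1, g2, win)$fst, 1)
  expect_equal(windowed_dxy(gt, g1, g2, win)$dxy, 1 / 50)
})

test_that("identical genotype vectors give a non-positive a component", {
  dosage <- matrix(rep(c(0L, 1L, 2L, 1L), 2), nrow = 1)
  colnames(dosage) <- paste0("s", 1:8)
  gt <- gt_from_dosage(dosage)
  comp <- site_fst_components(gt, paste0("s", 1:4), paste0("s", 5:8))
  expect_lte(comp$a, 0)
})

test_that("monomorphic sites are excluded as unusable sentinels", {
  dosage <- rbind(rep(0L, 8), rep(2L, 8), c(rep(0L, 4), rep(2L, 4)))
  colnames(dosage) <- paste0("s", 1:8)
  gt <- gt_from_dosage(dosage)
  comp <- site_fst_components(gt, paste0("s", 1:4), paste0("s", 5:8))
  expect_equal(comp$usable, c(FALSE, FALSE, TRUE))
  expect_true(all(is.na(comp$a[1:2])))
})

test_that("variance components match the ANOVA-route oracle to 1e-12", {
  for (seed in 1:20) {
    fx <- random_fixture(seed, missing_rate = ifelse(seed %% 3 == 0, 0.1, 0))
    comp <- site_fst_components(fx$gt, fx$group1, fx$group2)
    d1 <- gt_dosage(fx$gt, fx$group1)
    d2 <- gt_dosage(fx$gt, fx$group2)
    for (i in seq_len(nrow(fx$gt))) {
      oracle <- oracle_wc_site(d1[i, ], d2[i, ])
      expect_equal(comp$a[i], unname(oracle["a"]), tolerance = 1e-12)
      expect_equal(comp$b[i], unname(oracle["b"]), tolerance = 1e-12)
      expect_equal(comp$c[i], unname(oracle["c"]), tolerance = 1e-12)
    }
  }
})

test_that("windowed F_ST is the ratio of summed components", {
  fx <- random_fixture(31)
  win <- whole_window(fx$gt)
  comp <- site_fst_components(fx$gt, fx$group1, fx$group2)
  u <- comp$usable
  expect_equal(windowed_fst(fx$gt, fx$group1, fx$group2, win)$fst,
               sum(comp$a[u]) / sum((comp$a + comp$b + comp$c)[u]))
  mor <- windowed_fst(fx$gt, fx$group1, fx$group2, win,
                      method = "mean_of_ratios")$fst
  expect_equal(mor, mean((comp$a / (comp$a + comp$b + comp$c))[u]))
})

test_that("a single heterozygous diploid gives pi = 0.01 over 100 bp", {
  dosage <- matrix(1L, 1, 1, dimnames = list(NULL, "s1"))
  gt <- gt_from_dosage(dosage, pos = 50L)
  expect_equal(windowed_pi(gt, "s1", whole_window(gt, 100L))$pi, 0.01)
})

test_that("identical haplotypes give pi = 0 and masked empty windows", {
  dosage <- matrix(2L, 3, 4, dimnames = list(NULL, paste0("s", 1:4)))
  gt <- gt_from_dosage(dosage)
  expect_equal(windowed_pi(gt, paste0("s", 1:4), whole_window(gt, 100L))$pi, 0)
  empty <- tibble::tibble(chrom = "chr9", start = 0L, end = 100L)
  expect_true(is.na(windowed_pi(gt, paste0("s", 1:4), empty)$pi))
})

test_that("log2 ratio follows the control-over-focal sign convention", {
  expect_equal(log2_pi_ratio(0.02, 0.005), 2)
  expect_equal(log2_pi_ratio(0.013, 0.013), 0)
  expect_equal(log2_pi_ratio(0.005, 0.02), -2)
  expect_equal(log2_pi_ratio(0.01, 0), Inf)
  expect_true(is.na(log2_pi_ratio(NA, 0.01)))
  # antisymmetry under group swap
  for (seed in 1:5) {
    set.seed(seed)
    p <- runif(2, 1e-4, 0.02)
    expect_equal(log2_pi_ratio(p[1], p[2]), -log2_pi_ratio(p[2], p[1]))
  }
})

test_that("pi and Dxy are invariant to REF/ALT relabelling; Dxy symmetric", {
  fx <- random_fixture(47)
  win <- whole_window(fx$gt)
  flipped <- fx$gt
  for (s in gt_samples(fx$gt)) flipped[[s]] <- 2L - flipped[[s]]
  expect_equal(windowed_pi(fx$gt, fx$group1, win)$pi,
               windowed_pi(flipped, fx$group1, win)$pi)
  expect_equal(windowed_dxy(fx$gt, fx$group1, fx$group2, win)$dxy,
               windowed_dxy(flipped, fx$group1, fx$group2, win)$dxy)
  expect_equal(windowed_dxy(fx$gt, fx$group1, fx$group2, win)$dxy,
               windowed_dxy(fx$gt, fx$group2, fx$group1, win)$dxy)
  expect_equal(windowed_fst(fx$gt, fx$group1, fx$group2, win)$fst,
               windowed_fst(flipped, fx$group1, fx$group2, win)$fst)
})

test_that("equal frequency vectors make Dxy the pooled-diversity value", {
  dosage <- rbind(c(0L, 1L, 2L, 0L, 1L, 2L), c(2L, 2L, 0L, 2L, 2L, 0L))
  colnames(dosage) <- paste0("s", 1:6)
  gt <- gt_from_dosage(dosage)
  g1 <- paste0("s", 1:3); g2 <- paste0("s", 4:6)
  p <- rowSums(gt_dosage(gt, g1)) / 6
  expect_equal(windowed_dxy(gt, g1, g2, whole_window(gt, 100L))$dxy,
               sum(2 * p * (1 - p)) / 100)
})

test_that("Tajima's D is exactly 0 at n = 2 whenever S > 0", {
  for (S in c(1, 4, 9)) {
    dosage <- matrix(1L, S, 1, dimnames = list(NULL, "s1"))
    gt <- gt_from_dosage(dosage)
    d <- tajimas_d(gt, "s1", whole_window(gt, 1000L), min_segsites = 1L)
    expect_equal(d$tajimas_d, 0)
    expect_equal(d$n_segsites, S)
  }
})

test_that("Tajima constants come from the closed-form harmonic sums", {
  k <- sweepscan:::tajima_constants(10)
  expect_equal(k$a1, sum(1 / 1:9), tolerance = 1e-12)
  expect_equal(k$a2, sum(1 / (1:9)^2), tolerance = 1e-12)
  expect_equal(k$b1, 11 / 27, tolerance = 1e-12)
  expect_equal(k$e2,
               (k$b2 - 12 / (10 * k$a1) + k$a2 / k$a1^2) / (k$a1^2 + k$a2),
               tolerance = 1e-12)
})

test_that("windowed statistics match the brute-force oracle on fixtures", {
  for (seed in c(3, 8, 13)) {
    fx <- random_fixture(seed)
    win <- whole_window(fx$gt)
    L <- win$end
    d1 <- gt_dosage(fx$gt, fx$group1)
    d2 <- gt_dosage(fx$gt, fx$group2)
    expect_equal(windowed_pi(fx$gt, fx$group1, win)$pi,
                 oracle_windowed_pi(d1, L), tolerance = 1e-10)
    expect_equal(windowed_dxy(fx$gt, fx$group1, fx$group2, win)$dxy,
                 oracle_windowed_dxy(d1, d2, L), tolerance = 1e-10)
    d_pkg <- tajimas_d(fx$gt, fx$group1, win, min_segsites = 1L)$tajimas_d
    expect_equal(d_pkg, oracle_tajima(d1), tolerance = 1e-10)
  }
})

test_that("windows below the SNP floor are masked in window_stats", {
  fx <- random_fixture(55)
  pm <- population_map(tibble::tibble(
    sample = gt_samples(fx$gt),
    population = c(rep("low", length(fx$group1)),
                   rep("high", length(fx$group2))),
    altitude = c(rep(100, length(fx$group1)),
                 rep(2000, length(fx$group2)))))
  w <- window_stats(fx$gt, pm, focal = "high", control = "low",
                    spec = window_spec(2000, 1000, min_snps = 5),
                    chrom_lengths = c(chr1 = 10000))
  expect_true(all(w$masked == (w$n_snps < 5)))
  expect_true(all(w$fst[!w$masked] <= 1 + 1e-12))
})
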