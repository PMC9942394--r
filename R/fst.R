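#' Weir-Cockerham variance components at each site
#'
#' Computes, per biallelic site, the three variance components of the
#' Weir-Cockerham (1984) F-statistics estimator for two populations of
#' diploids with unequal sample sizes: `a` (among populations), `b` (among
#' individuals within populations) and `c` (within individuals), using
#' observed heterozygote counts. The per-site ratio `a/(a+b+c)` is the
#' single-site F_ST estimate; windowed F_ST sums components first (see
#' [windowed_fst()]).
#'
#' Sites where fewer than two individuals are called in either group, or
#' that are monomorphic across both groups, get `NA` components and are
#' excluded from windowed sums.
#'
#' @param gt A genotype table.
#' @param group1,group2 Character vectors of sample names.
#' @return Tibble with `chrom`, `pos`, `a`, `b`, `c`, `usable` (logical).
#' @references Weir, B.S. & Cockerham, C.C. (1984) Estimating F-statistics
#'   for the analysis of population structure. Evolution 38:1358-1370.
#' @export
site_fst_components <- function(gt, group1, group2) {
  m1 <- gt_dosage(gt, group1)
  m2 <- gt_dosage(gt, group2)
  n1 <- rowSums(!is.na(m1))          # called diploid individuals
  n2 <- rowSums(!is.na(m2))
  p1 <- rowSums(m1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(m2, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(m1 == 1L, na.rm = TRUE) / n1   # observed het frequency
  h2 <- rowSums(m2 == 1L, na.rm = TRUE) / n2

  r <- 2
  n_bar <- (n1 + n2) / r
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)

  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2

  usable <- n1 >= 2 & n2 >= 2 & p_bar > 0 & p_bar < 1
  a[!usable] <- NA_real_
  b[!usable] <- NA_real_
  cc[!usable] <- NA_real_
  tibble::tibble(chrom = gt$chrom, pos = gt$pos,
                 a = a, b = b, c = cc, usable = usable)
}

#' Windowed Weir-Cockerham F_ST
#'
#' Combines per-site variance components within each window as a ratio of
#' sums, `sum(a) / sum(a + b + c)` (the "weighted" convention), or
#' optionally as the mean of per-site ratios. Windows with no usable site
#' are masked (`NA`).
#'
#' @inheritParams site_fst_components
#' @param windows Window tibble from [enumerate_windows()].
#' @param method `"ratio_of_sums"` (default) or `"mean_of_ratios"`.
#' @return `windows` with columns `n_fst_sites` and `fst` appended. Negative
#'   estimates are retained, not clamped.
#' @export
windowed_fst <- function(gt, group1, group2, windows,
                         method = c("ratio_of_sums", "mean_of_ratios")) {
  method <- match.arg(method)
  comp <- site_fst_components(gt, group1, group2)
  idx <- window_site_index(gt, windows)
  stats <- purrr::map_dfr(idx, function(i) {
    u <- i[comp$usable[i]]
    if (!length(u)) {
      return(tibble::tibble(n_fst_sites = 0L, fst = NA_real_))
    }
    fst <- if (method == "ratio_of_sums") {
      sum(comp$a[u]) / sum(comp$a[u] + comp$b[u] + comp$c[u])
    } else {
      mean(comp$a[u] / (comp$a[u] + comp$b[u] + comp$c[u]))
    }
    tibble::tibble(n_fst_sites = length(u), fst = fst)
  })
  dplyr::bind_cols(windows, stats)
}
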