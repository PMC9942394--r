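#' Windowed nucleotide diversity (theta-pi)
#'
#' Per-site diversity uses the unbiased estimator
#' `(n/(n-1)) * 2*p*(1-p)` with `n` the called chromosomes at the site
#' (equivalently, the mean number of pairwise differences among the called
#' sequences). The window value is the sum over sites divided by the full
#' window length in bp: monomorphic and uncallable bases contribute zero to
#' the numerator but remain in the denominator, matching the convention of
#' the standard windowed-diversity tools.
#'
#' @param gt A genotype table.
#' @param group Character vector of sample names.
#' @param windows Window tibble from [enumerate_windows()].
#' @return `windows` with `n_pi_sites` and `pi` (per bp) appended; windows
#'   with no called site are masked (`NA`).
#' @export
windowed_pi <- function(gt, group, windows) {
  site <- site_pi(gt, group)
  idx <- window_site_index(gt, windows)
  stats <- purrr::map_dfr(seq_len(nrow(windows)), function(w) {
    i <- idx[[w]]
    i <- i[!is.na(site$pi[i])]
    if (!length(i)) return(tibble::tibble(n_pi_sites = 0L, pi = NA_real_))
    tibble::tibble(
      n_pi_sites = length(i),
      pi = sum(site$pi[i]) / (windows$end[w] - windows$start[w])
    )
  })
  dplyr::bind_cols(windows, stats)
}

# per-site unbiased pairwise diversity; NA when < 2 called chromosomes
site_pi <- function(gt, group) {
  af <- gt_allele_freq(gt, group)
  n <- af$n_called
  p <- af$freq
  pi <- ifelse(n >= 2, n / (n - 1) * 2 * p * (1 - p), NA_real_)
  tibble::tibble(chrom = af$chrom, pos = af$pos, n = n, pi = pi)
}

#' Windowed absolute divergence (Dxy)
#'
#' Per-site divergence between two groups is
#' `p1*(1-p2) + p2*(1-p1)` from the group allele frequencies; the window
#' value is the per-site sum divided by the full window length in bp.
#' Dxy, unlike F_ST, is not normalised by within-group diversity, so it
#' validates divergence independently of diversity loss.
#'
#' @inheritParams windowed_pi
#' @param group1,group2 Character vectors of sample names.
#' @return `windows` with `n_dxy_sites` and `dxy` (per bp) appended; masked
#'   (`NA`) where either group has no call in the window.
#' @export
windowed_dxy <- function(gt, group1, group2, windows) {
  af1 <- gt_allele_freq(gt, group1)
  af2 <- gt_allele_freq(gt, group2)
  d <- af1$freq * (1 - af2$freq) + af2$freq * (1 - af1$freq)
  d[af1$n_called == 0L | af2$n_called == 0L] <- NA_real_
  idx <- window_site_index(gt, windows)
  stats <- purrr::map_dfr(seq_len(nrow(windows)), function(w) {
    i <- idx[[w]]
    i <- i[!is.na(d[i])]
    if (!length(i)) return(tibble::tibble(n_dxy_sites = 0L, dxy = NA_real_))
    tibble::tibble(n_dxy_sites = length(i),
                   dxy = sum(d[i]) / (windows$end[w] - windows$start[w]))
  })
  dplyr::bind_cols(windows, stats)
}

#' log2 diversity ratio
#'
#' `log2(pi_group1 / pi_group2)` with group1 the control (e.g. low-altitude)
#' population and group2 the focal population, so that a sweep in the focal
#' population — diversity purged — yields a large positive value.
#' `pi_group2 = 0` with `pi_group1 > 0` returns `Inf` (reported, but
#' excluded from quantile thresholds); both zero or either `NA` returns
#' `NA`.
#'
#' @param pi_group1,pi_group2 Numeric vectors of windowed diversities.
#' @return Numeric vector of log2 ratios.
#' @export
log2_pi_ratio <- function(pi_group1, pi_group2) {
  out <- ifelse(pi_group1 > 0 & pi_group2 == 0, Inf,
                ifelse(pi_group1 == 0 & pi_group2 == 0, NA_real_,
                       log2(pi_group1 / pi_group2)))
  out[is.na(pi_group1) | is.na(pi_group2)] <- NA_real_
  out
}

#' Windowed Tajima's D
#'
#' The classical Tajima (1989) statistic
#' `D = (pi_total - S/a1) / sqrt(e1*S + e2*S*(S-1))`, with `pi_total` the
#' sum over window sites of the mean pairwise difference
#' (`2*p*(1-p)*n/(n-1)`), `S` the number of segregating sites among the
#' group's called chromosomes, and the constants `a1..e2` from the sample
#' size. With missing data the per-window `n` is the modal called-chromosome
#' count across the window's segregating sites.
#'
#' @inheritParams windowed_pi
#' @param min_segsites Windows with fewer segregating sites are masked.
#' @return `windows` with `n_segsites` and `tajimas_d` appended; masked
#'   (`NA`) when `S < min_segsites` or `n < 2`.
#' @references Tajima, F. (1989) Statistical method for testing the neutral
#'   mutation hypothesis by DNA polymorphism. Genetics 123:585-595.
#' @export
tajimas_d <- function(gt, group, windows, min_segsites = 3L) {
  af <- gt_allele_freq(gt, group)
  seg <- af$n_called >= 2L & af$freq > 0 & af$freq < 1
  pi_site <- 2 * af$freq * (1 - af$freq) * af$n_called / (af$n_called - 1)
  idx <- window_site_index(gt, windows)
  stats <- purrr::map_dfr(idx, function(i) {
    i <- i[seg[i]]
    S <- length(i)
    if (S < max(1L, min_segsites)) {
      return(tibble::tibble(n_segsites = S, tajimas_d = NA_real_))
    }
    n_tab <- table(af$n_called[i])
    n <- as.integer(names(n_tab)[which.max(n_tab)])
    k <- tajima_constants(n)
    pi_total <- sum(pi_site[i])
    num <- pi_total - S / k$a1
    denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
    # at n = 2 both estimators coincide and the variance constants vanish:
    # the statistic is identically 0, not 0/0
    d <- if (abs(num) < 1e-12) 0 else num / denom
    tibble::tibble(n_segsites = S, tajimas_d = d)
  })
  dplyr::bind_cols(windows, stats)
}

# Tajima (1989) normalising constants for a sample of n chromosomes
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}
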