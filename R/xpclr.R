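#' Configuration for the composite-likelihood differentiation scan
#'
#' Parameters of the XP-CLR-style scan contrasting a focal population
#' against a reference. At each grid point the focal allele frequency of
#' each nearby SNP is modelled given the reference frequency under neutral
#' drift (a Brownian density of variance `omega * p * (1-p)` with the mass
#' outside \[0,1\] absorbed at the boundaries) and under a sweep centred at
#' the grid point, in which a lineage escapes hitchhiking with probability
#' `1 - exp(-r * d * log(2 * sweep_pop_size) / s)` — increasing with
#' recombination distance `r*d`, decreasing with selection strength `s`.
#'
#' @param grid_spacing Spacing of evaluation points (bp).
#' @param window_radius SNPs within this distance of a grid point
#'   contribute to its score (bp).
#' @param max_snps Cap on contributing SNPs (nearest kept).
#' @param min_snps Grid points with fewer SNPs are masked.
#' @param selection_grid Candidate selection coefficients; 0 (neutrality)
#'   is always prepended. Default: 0 plus a logarithmic grid up to 0.5.
#' @param omega Drift scale; `NULL` (default) estimates it genome-wide by
#'   method of moments from the (ref, focal) frequency pairs.
#' @param recombination_rate Per-bp recombination rate used to convert
#'   physical distance to `r`.
#' @param sweep_pop_size Effective size entering the escape-probability
#'   term through `log(2N)`.
#' @param n_quad Number of abscissae for the frequency integral.
#' @return An `xpclr_config` list.
#' @export
xpclr_config <- function(grid_spacing = 20000, window_radius = 100000,
                         max_snps = 60, min_snps = 5,
                         selection_grid = 10^seq(-4, log10(0.5), length.out = 6),
                         omega = NULL, recombination_rate = 1e-8,
                         sweep_pop_size = 1e4, n_quad = 32) {
  stopifnot(grid_spacing > 0, all(selection_grid >= 0),
            is.null(omega) || omega > 0)
  selection_grid <- sort(unique(c(0, selection_grid)))
  structure(list(grid_spacing = grid_spacing, window_radius = window_radius,
                 max_snps = max_snps, min_snps = min_snps,
                 selection_grid = selection_grid, omega = omega,
                 recombination_rate = recombination_rate,
                 sweep_pop_size = sweep_pop_size, n_quad = n_quad),
            class = "xpclr_config")
}

#' Method-of-moments drift scale from genome-wide frequency pairs
#'
#' Estimates `omega` such that `Var(p_focal | p_ref) = omega * p*(1-p)`,
#' subtracting the binomial sampling variance of both sample frequencies.
#'
#' @param p_ref,p_focal Allele-frequency vectors.
#' @param n_ref,n_focal Called chromosome counts per site.
#' @return A positive scalar, floored at 0.005 (below that the drift
#'   density is narrower than the scan's frequency quadrature resolves,
#'   and a scan is uninformative anyway).
#' @export
estimate_omega <- function(p_ref, p_focal, n_ref, n_focal) {
  keep <- !is.na(p_ref) & !is.na(p_focal) & p_ref > 0 & p_ref < 1 &
    n_ref > 1 & n_focal > 1
  p1 <- p_ref[keep]; p2 <- p_focal[keep]
  num <- (p2 - p1)^2 - p1 * (1 - p1) / n_ref[keep] -
    p2 * (1 - p2) / n_focal[keep]
  max(mean(num) / mean(p1 * (1 - p1)), 5e-3)
}

#' Composite-likelihood scan scores along the genome
#'
#' For every grid point, the score is twice the difference between the
#' sweep-model composite log-likelihood maximised over `selection_grid` and
#' the neutral composite log-likelihood. Since neutrality (s = 0) is in the
#' grid, scores are non-negative, and exactly 0 where the neutral model is
#' already the maximum; ties prefer the smaller selection value.
#'
#' @param gt A genotype table.
#' @param ref_group,focal_group Character vectors of sample names.
#' @param cfg An [xpclr_config()].
#' @param chrom_lengths Named vector of chromosome lengths (bp); defaults to
#'   last SNP position + 1.
#' @return An `xpclr_scores` tibble: `chrom`, `grid_pos`, `n_snps`, `score`,
#'   `argmax_selection` (`NA` score where `n_snps < min_snps`).
#' @export
xpclr_scores <- function(gt, ref_group, focal_group, cfg = xpclr_config(),
                         chrom_lengths = NULL) {
  af1 <- gt_allele_freq(gt, ref_group)
  af2 <- gt_allele_freq(gt, focal_group)
  # polymorphic-in-reference SNPs carry the differentiation signal
  use <- !is.na(af1$freq) & !is.na(af2$freq) & af1$freq > 0 & af1$freq < 1 &
    af2$n_called > 0
  omega <- cfg$omega %||%
    estimate_omega(af1$freq[use], af2$freq[use],
                   af1$n_called[use], af2$n_called[use])
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(gt$pos, gt$chrom, function(p) max(p) + 1L)
    chrom_lengths <- chrom_lengths[unique(gt$chrom)]
  }
  # midpoint quadrature over the latent post-drift frequency
  xq <- (seq_len(cfg$n_quad) - 0.5) / cfg$n_quad
  wq <- 1 / cfg$n_quad
  sels <- cfg$selection_grid

  out <- purrr::map_dfr(names(chrom_lengths), function(chrom) {
    len <- chrom_lengths[[chrom]]
    grid <- seq(cfg$grid_spacing / 2, len, by = cfg$grid_spacing)
    on_chrom <- which(use & af1$chrom == chrom)
    pos <- gt$pos[on_chrom]
    p1 <- af1$freq[on_chrom]
    k2 <- round(af2$freq[on_chrom] * af2$n_called[on_chrom])
    n2 <- af2$n_called[on_chrom]
    sd1 <- sqrt(omega * p1 * (1 - p1))
    mass0 <- stats::pnorm(0, p1, sd1)
    mass1 <- stats::pnorm(1, p1, sd1, lower.tail = FALSE)
    # continuous part, renormalised so the three pieces sum to 1 per SNP
    dens <- vapply(xq, function(x) stats::dnorm(x, p1, sd1),
                   numeric(length(p1)))
    if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(p1))
    cont <- rowSums(dens) * wq
    norm <- mass0 + mass1 + cont
    purrr::map_dfr(grid, function(g) {
      d <- abs(pos - g)
      near <- which(d <= cfg$window_radius)
      if (length(near) > cfg$max_snps) {
        near <- near[order(d[near])][seq_len(cfg$max_snps)]
      }
      if (length(near) < cfg$min_snps) {
        return(tibble::tibble(chrom = chrom, grid_pos = g,
                              n_snps = length(near), score = NA_real_,
                              argmax_selection = NA_real_))
      }
      cll <- vapply(sels, function(s) {
        cc <- if (s <= 0) rep(1, length(near)) else
          1 - exp(-cfg$recombination_rate * d[near] *
                    log(2 * cfg$sweep_pop_size) / s)
        ll <- xpclr_snp_loglik(p1[near], k2[near], n2[near],
                               mass0[near], mass1[near], dens[near, , drop = FALSE],
                               norm[near], xq, wq, cc)
        sum(ll)
      }, numeric(1))
      best <- which(cll >= max(cll) - 1e-9)[1]  # ties -> smaller s
      tibble::tibble(chrom = chrom, grid_pos = g, n_snps = length(near),
                     score = max(0, 2 * (cll[best] - cll[sels == 0])),
                     argmax_selection = sels[best])
    })
  })
  class(out) <- c("xpclr_scores", class(out))
  attr(out, "omega") <- omega
  out
}

# per-SNP log-likelihood of the focal allele count under the sweep model
# with per-SNP escape probability cc (cc = 1 recovers neutrality exactly)
xpclr_snp_loglik <- function(p1, k, n, mass0, mass1, dens, norm, xq, wq, cc) {
  ns <- length(p1)
  nx <- length(xq)
  # latent x from the drift density; hitchhiking maps it to c*x + (1-c)*B
  lik_B <- function(B) {
    p2 <- cc * matrix(xq, ns, nx, byrow = TRUE) + (1 - cc) * B
    bin <- matrix(stats::dbinom(rep(k, nx), rep(n, nx), as.vector(p2)),
                  ns, nx)
    rowSums(dens * bin) * wq +
      mass0 * stats::dbinom(k, n, (1 - cc) * B) +
      mass1 * stats::dbinom(k, n, cc + (1 - cc) * B)
  }
  lik <- (p1 * lik_B(1) + (1 - p1) * lik_B(0)) / pmax(norm, 1e-12)
  log(pmax(lik, 1e-300))
}

#' Outlier regions from scan scores
#'
#' Marks the top-`quantile` grid scores (nearest-rank threshold over
#' unmasked scores) and merges adjacent outlier grid points into regions,
#' each grid point contributing `grid_spacing/2` on either side.
#'
#' @param scores An `xpclr_scores` tibble.
#' @param quantile Upper tail mass, default 0.01.
#' @param grid_spacing Spacing used for the scan (bp).
#' @return Tibble of `chrom`, `start`, `end`, `peak_score`.
#' @export
xpclr_outlier_regions <- function(scores, quantile = 0.01,
                                  grid_spacing = NULL) {
  ok <- !is.na(scores$score)
  thr <- empirical_quantile_threshold(scores$score[ok], quantile)
  gs <- grid_spacing %||%
    min(diff(sort(unique(scores$grid_pos[scores$chrom == scores$chrom[1]]))))
  hits <- scores[ok & scores$score >= thr, , drop = FALSE]
  if (!nrow(hits)) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), peak_score = numeric()))
  }
  win <- tibble::tibble(chrom = hits$chrom,
                        start = pmax(0, hits$grid_pos - gs / 2),
                        end = hits$grid_pos + gs / 2,
                        score = hits$score)
  merged <- merge_intervals(win)
  merged
}
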