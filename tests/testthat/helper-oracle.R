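# brute-force per-site oracles, written as literal transcriptions that stay
# independent of the package's vectorised implementations

# Weir-Cockerham variance components via the random-effects ANOVA route:
# allele copies y in {0,1}, mean squares among populations / among
# individuals / within individuals, then the classic moment equations.
# An algebraically independent derivation of the same estimator.
oracle_wc_site <- function(geno1, geno2) {
  geno1 <- geno1[!is.na(geno1)]
  geno2 <- geno2[!is.na(geno2)]
  n1 <- length(geno1); n2 <- length(geno2)
  if (n1 < 2 || n2 < 2) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  copies <- function(g) lapply(g, function(d) {
    if (d == 0) c(0, 0) else if (d == 1) c(0, 1) else c(1, 1)
  })
  y <- list(copies(geno1), copies(geno2))
  n_i <- c(n1, n2)
  n_tot <- n1 + n2
  ybar_pop <- vapply(y, function(pop) mean(unlist(pop)), 0)
  ybar_all <- sum(n_i * ybar_pop) / n_tot
  if (ybar_all <= 0 || ybar_all >= 1) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  SSG <- 0; SSI <- 0; SSP <- 0
  for (p in 1:2) {
    for (j in seq_along(y[[p]])) {
      yij <- y[[p]][[j]]
      SSG <- SSG + sum((yij - mean(yij))^2)
      SSI <- SSI + 2 * (mean(yij) - ybar_pop[p])^2
    }
    SSP <- SSP + 2 * n_i[p] * (ybar_pop[p] - ybar_all)^2
  }
  MSG <- SSG / n_tot
  MSI <- SSI / (n_tot - 2)
  MSP <- SSP / (2 - 1)
  n_c <- (n_tot - (n1^2 + n2^2) / n_tot) / (2 - 1)
  c(a = (MSP - MSI) / (2 * n_c),
    b = (MSI - MSG) / 2,
    c = MSG)
}

# per-site diversity: literal mean number of pairwise differences among
# the called allele copies
oracle_site_pi <- function(geno) {
  geno <- geno[!is.na(geno)]
  alleles <- unlist(lapply(geno, function(d) {
    if (d == 0) c(0, 0) else if (d == 1) c(0, 1) else c(1, 1)
  }))
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  diff <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) diff <- diff + as.integer(alleles[i] != alleles[j])
  }
  diff / choose(n, 2)
}

# windowed pi: sum of per-site values over the full window length
oracle_windowed_pi <- function(dosage, window_length) {
  sum(vapply(seq_len(nrow(dosage)), function(i)
    oracle_site_pi(dosage[i, ]), 0), na.rm = TRUE) / window_length
}

# per-site Dxy: mean difference over all between-group allele pairs
oracle_site_dxy <- function(geno1, geno2) {
  alleles <- function(g) unlist(lapply(g[!is.na(g)], function(d) {
    if (d == 0) c(0, 0) else if (d == 1) c(0, 1) else c(1, 1)
  }))
  a1 <- alleles(geno1); a2 <- alleles(geno2)
  if (!length(a1) || !length(a2)) return(NA_real_)
  diff <- 0
  for (x in a1) for (y in a2) diff <- diff + as.integer(x != y)
  diff / (length(a1) * length(a2))
}

oracle_windowed_dxy <- function(d1, d2, window_length) {
  sum(vapply(seq_len(nrow(d1)), function(i)
    oracle_site_dxy(d1[i, ], d2[i, ]), 0), na.rm = TRUE) / window_length
}

# Tajima's D from S and the summed per-site pairwise differences,
# constants written out directly from the 1989 definitions
oracle_tajima <- function(dosage) {
  pi_vals <- vapply(seq_len(nrow(dosage)), function(i)
    oracle_site_pi(dosage[i, ]), 0)
  n_called <- 2 * rowSums(!is.na(dosage))
  freq <- rowMeans(dosage, na.rm = TRUE) / 2
  seg <- n_called >= 2 & freq > 0 & freq < 1
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  # sample size for the constants: modal called count over segregating sites
  tab <- table(n_called[seg])
  n <- as.integer(names(tab)[which.max(tab)])
  pi_vals <- pi_vals[seg]
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (sum(pi_vals) - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# quadratic all-pairs interval overlap (0-based half-open)
oracle_overlaps <- function(segments, genes) {
  hits <- list()
  for (i in seq_len(nrow(segments))) {
    found <- character(0)
    for (j in seq_len(nrow(genes))) {
      if (segments$chrom[i] == genes$chrom[j] &&
          segments$start[i] < genes$end[j] &&
          genes$start[j] < segments$end[i]) {
        found <- c(found, genes$gene_name[j])
      }
    }
    hits[[i]] <- found
  }
  hits
}
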