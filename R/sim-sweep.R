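#' Forward sweep-simulation configuration
#'
#' Discrete-generation Wright-Fisher simulation of a hard selective sweep:
#' a single beneficial copy is introduced at `sweep_position` and the run
#' is conditioned on fixation by restarting on loss (up to `max_restarts`).
#' Selection is genic: a parent is drawn with weight `(1+s)^g` where `g` is
#' its beneficial-copy count, so `2Ns = 2 * n_diploids * s`.
#'
#' @param n_diploids Diploid population size N.
#' @param s Per-copy selection coefficient (> 0).
#' @param locus_length Locus length in bp.
#' @param sweep_position Position of the selected site in bp (within locus).
#' @param recomb_rate,mut_rate Per-bp per-generation rates.
#' @param sample_size Haplotypes sampled at fixation.
#' @param max_restarts Restart cap for conditioning on fixation.
#' @return A `sweep_sim_config` list.
#' @export
sweep_sim_config <- function(n_diploids = 100L, s = 0.5,
                             locus_length = 80000L,
                             sweep_position = locus_length / 2,
                             recomb_rate = 1e-8, mut_rate = 1e-8,
                             sample_size = 20L, max_restarts = 10000L) {
  stopifnot(s > 0, sweep_position > 0, sweep_position < locus_length,
            sample_size <= 2L * n_diploids)
  structure(list(n_diploids = as.integer(n_diploids), s = s,
                 locus_length = as.integer(locus_length),
                 sweep_position = sweep_position,
                 recomb_rate = recomb_rate, mut_rate = mut_rate,
                 sample_size = as.integer(sample_size),
                 max_restarts = as.integer(max_restarts)),
            class = "sweep_sim_config")
}

#' Allele-count trajectory of a new mutation under Wright-Fisher sampling
#'
#' The selection core of the sweep simulator, run without haplotypes: a
#' single copy in `2N` with genic selection `s` (0 = neutral tracking),
#' followed until fixation or loss.
#'
#' @param n_diploids Diploid population size.
#' @param s Selection coefficient; `s = 0` gives neutral drift, for which
#'   the fixation probability is `1/(2N)`.
#' @return List with `fixed` (logical) and `counts` (copy number per
#'   generation, starting at 1).
#' @export
wf_trajectory <- function(n_diploids, s = 0) {
  two_n <- 2L * n_diploids
  count <- 1L
  counts <- count
  while (count > 0L && count < two_n) {
    p <- count / two_n
    p_sel <- p * (1 + s) / (p * (1 + s) + (1 - p))
    count <- stats::rbinom(1L, two_n, p_sel)
    counts <- c(counts, count)
  }
  list(fixed = count == two_n, counts = counts)
}

#' Simulate a hard selective sweep forward in time
#'
#' Starts from founder haplotypes (resampled to 2N copies), introduces one
#' beneficial copy at `cfg$sweep_position`, and runs Wright-Fisher
#' generations with genic selection, crossover recombination
#' (Poisson(`recomb_rate * locus_length`) breakpoints per meiosis) and new
#' neutral mutations (infinite-sites, continuous bp positions) until the
#' beneficial allele fixes; runs losing it restart with a fresh carrier.
#' Hitchhiking leaves the sampled haplotypes depleted of diversity around
#' the sweep site.
#'
#' @param cfg A [sweep_sim_config()].
#' @param founders Optional founder haplotypes: a list of sorted numeric
#'   vectors of derived-allele positions in bp, or a haplotype block from
#'   [simulate_neutral_iwm()] (relative positions are scaled by
#'   `cfg$locus_length`). `NULL` starts from a monomorphic population.
#' @param seed Integer seed; identical seeds give identical haplotypes.
#' @return List: `haps` (0/1 matrix, `sample_size` x sites), `positions`
#'   (bp, sorted, including the swept site), `sweep_position`,
#'   `generations`, `restarts`.
#' @export
simulate_sweep <- function(cfg, founders = NULL, seed = 1L) {
  stopifnot(inherits(cfg, "sweep_sim_config"))
  set.seed(seed)
  founder_list <- founders_as_positions(founders, cfg$locus_length)
  two_n <- 2L * cfg$n_diploids
  for (restart in 0:cfg$max_restarts) {
    pop <- founder_list[sample.int(length(founder_list), two_n,
                                   replace = TRUE)]
    carrier <- sample.int(two_n, 1L)
    pop[[carrier]] <- sort(c(pop[[carrier]], cfg$sweep_position))
    res <- run_sweep_generations(pop, cfg)
    if (res$fixed) {
      idx <- sample.int(two_n, cfg$sample_size)
      return(c(positions_to_block(res$pop[idx], cfg$locus_length),
               list(sweep_position = cfg$sweep_position,
                    generations = res$generations, restarts = restart)))
    }
  }
  stop("beneficial allele never fixed within the restart cap; ",
       "increase s or 2Ns", call. = FALSE)
}

founders_as_positions <- function(founders, locus_length) {
  if (is.null(founders)) return(list(numeric(0)))
  if (is.list(founders) && !is.null(founders$haps)) {
    pos_bp <- if (length(founders$positions) && max(founders$positions) <= 1)
      founders$positions * locus_length else founders$positions
    return(lapply(seq_len(nrow(founders$haps)), function(i) {
      pos_bp[founders$haps[i, ] == 1L]
    }))
  }
  founders
}

run_sweep_generations <- function(pop, cfg) {
  two_n <- length(pop)
  L <- cfg$locus_length
  sweep_pos <- cfg$sweep_position
  gen <- 0L
  repeat {
    has_b <- vapply(pop, function(h) any(h == sweep_pos), logical(1))
    nb <- sum(has_b)
    if (nb == 0L) return(list(fixed = FALSE, generations = gen))
    if (nb == two_n) return(list(fixed = TRUE, pop = pop, generations = gen))
    gen <- gen + 1L
    # diploid fitness (1+s)^copies; genic selection
    copies <- has_b[seq(1L, two_n, by = 2L)] + has_b[seq(2L, two_n, by = 2L)]
    w <- (1 + cfg$s)^copies
    parents <- sample.int(two_n / 2L, two_n, replace = TRUE, prob = w)
    n_cross <- stats::rpois(two_n, cfg$recomb_rate * L)
    n_mut <- stats::rpois(two_n, cfg$mut_rate * L)
    pop <- lapply(seq_len(two_n), function(i) {
      pa <- parents[i]
      h1 <- pop[[2L * pa - 1L]]
      h2 <- pop[[2L * pa]]
      g <- make_gamete(h1, h2, n_cross[i], L)
      if (n_mut[i] > 0L) g <- sort(c(g, stats::runif(n_mut[i], 0, L)))
      g
    })
  }
}

# meiosis: alternate segments of the two parental haplotypes
make_gamete <- function(h1, h2, n_cross, L) {
  if (stats::runif(1L) < 0.5) { tmp <- h1; h1 <- h2; h2 <- tmp }
  if (n_cross == 0L) return(h1)
  breaks <- sort(stats::runif(n_cross, 0, L))
  cuts <- c(0, breaks, L)
  out <- numeric(0)
  for (k in seq_len(length(cuts) - 1L)) {
    src <- if (k %% 2L == 1L) h1 else h2
    out <- c(out, src[src >= cuts[k] & src < cuts[k + 1L]])
  }
  out
}

# sampled position lists -> 0/1 matrix over the union of positions
positions_to_block <- function(hap_pos, locus_length) {
  all_pos <- sort(unique(unlist(hap_pos)))
  haps <- matrix(0L, nrow = length(hap_pos), ncol = length(all_pos))
  for (i in seq_along(hap_pos)) {
    haps[i, match(hap_pos[[i]], all_pos)] <- 1L
  }
  list(haps = haps, positions = all_pos)
}
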