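#' Isolation-with-migration demographic model
#'
#' Scaling follows the ms conventions: time in units of 4N0 generations,
#' `theta = 4*N0*mu` per locus, `migration_rate = 4*N0*m` (the `-I`
#' parameter), and `split_time` the time of the ancestral merge (the `-ej`
#' parameter). Before `split_time` (looking back), demes exchange migrants
#' symmetrically; at `split_time` all lineages join a single ancestral pool
#' of relative size `deme_sizes[1]`.
#'
#' @param sample_sizes Integer vector: sampled chromosomes per deme.
#' @param theta Population mutation rate `4*N0*mu` for the whole locus.
#' @param split_time Merge time in 4N0 generations; 0 means panmixia.
#' @param migration_rate Scaled migration rate `4*N0*m` (total per lineage,
#'   split equally among the other demes); 0 means complete isolation.
#' @param deme_sizes Relative deme sizes (N_i / N0).
#' @param rho Scaled recombination rate; only `rho = 0` is supported —
#'   windows are simulated as independent loci (see the methods vignette).
#' @param locus_length Locus length in bp (used when exporting to VCF).
#' @return An `iwm_model` list.
#' @export
iwm_model <- function(sample_sizes = c(20L, 20L), theta = 10,
                      split_time = 0.5, migration_rate = 0,
                      deme_sizes = rep(1, length(sample_sizes)),
                      rho = 0, locus_length = 40000L) {
  stopifnot(split_time >= 0, migration_rate >= 0, theta > 0,
            sum(sample_sizes) >= 2, all(deme_sizes > 0),
            length(deme_sizes) == length(sample_sizes))
  if (rho != 0) {
    stop("rho > 0 is not supported: simulate windows as independent loci",
         call. = FALSE)
  }
  structure(list(sample_sizes = as.integer(sample_sizes), theta = theta,
                 split_time = split_time, migration_rate = migration_rate,
                 deme_sizes = deme_sizes, rho = rho,
                 locus_length = as.integer(locus_length)),
            class = "iwm_model")
}

#' Simulate neutral haplotypes under isolation with migration
#'
#' Hudson-style structured coalescent: within-deme pair coalescence at rate
#' `2/x_i`, per-lineage migration at rate `migration_rate` while
#' `t < split_time`, a single ancestral pool afterwards; infinite-sites
#' mutations dropped on branches at rate `theta` per lineage per unit
#' time (time in 4N0 generations, so `E[S] = theta * a_{n-1}`). A pure function of `(model, n_replicates, seed)`.
#'
#' @param model An [iwm_model()].
#' @param n_replicates Number of independent loci to simulate.
#' @param seed Integer seed recorded in the output.
#' @return List of haplotype blocks, each a list with `haps` (0/1 matrix,
#'   chromosomes x sites, demes stacked in order), `positions` (sorted,
#'   relative in \[0, 1\]), `demes` (deme index per row) and `seed`.
#' @export
simulate_neutral_iwm <- function(model, n_replicates = 1L, seed = 1L) {
  stopifnot(inherits(model, "iwm_model"))
  set.seed(seed)
  demes0 <- rep(seq_along(model$sample_sizes), model$sample_sizes)
  lapply(seq_len(n_replicates), function(r) {
    tree <- sim_coalescent_tree(demes0, model)
    block <- drop_mutations(tree, model$theta, length(demes0))
    block$demes <- demes0
    block$seed <- seed
    block
  })
}

# one structured-coalescent genealogy; returns branches (leaf sets, lengths)
sim_coalescent_tree <- function(demes0, model) {
  n <- length(demes0)
  leaf_sets <- lapply(seq_len(n), identity)
  deme <- demes0
  birth <- numeric(n)
  t <- 0
  merged <- model$split_time <= 0 || length(model$sample_sizes) == 1L
  if (merged) deme <- rep(1L, n)
  br_sets <- vector("list", 2L * n)
  br_len <- numeric(2L * n)
  nb <- 0L
  while (length(leaf_sets) > 1L) {
    k <- tabulate(deme, nbins = length(model$deme_sizes))
    coal_rates <- k * (k - 1) / model$deme_sizes
    mig_rate <- if (!merged && length(k) > 1L)
      model$migration_rate * sum(k) else 0
    total <- sum(coal_rates) + mig_rate
    if (total <= 0) {           # isolated singletons: jump to the merge
      t <- model$split_time
    } else {
      wait <- stats::rexp(1L, total)
      if (!merged && t + wait >= model$split_time) {
        t <- model$split_time
      } else {
        t <- t + wait
        u <- stats::runif(1L) * total
        if (u < mig_rate) {      # migration: move one lineage
          i <- sample.int(length(deme), 1L)
          others <- setdiff(seq_along(model$deme_sizes), deme[i])
          deme[i] <- if (length(others) == 1L) others else sample(others, 1L)
        } else {                 # coalescence in deme d
          d <- sample.int(length(coal_rates), 1L, prob = coal_rates)
          pair <- sample(which(deme == d), 2L)
          for (j in pair) {
            nb <- nb + 1L
            br_sets[[nb]] <- leaf_sets[[j]]
            br_len[nb] <- t - birth[j]
          }
          leaf_sets[[pair[1]]] <- sort(c(leaf_sets[[pair[1]]],
                                         leaf_sets[[pair[2]]]))
          birth[pair[1]] <- t
          leaf_sets <- leaf_sets[-pair[2]]
          birth <- birth[-pair[2]]
          deme <- deme[-pair[2]]
        }
        next
      }
    }
    # reached the split: all lineages join the ancestral pool (deme 1)
    merged <- TRUE
    deme <- rep(1L, length(leaf_sets))
  }
  list(sets = br_sets[seq_len(nb)], lengths = br_len[seq_len(nb)])
}

# infinite-sites mutations: Poisson(theta * total length), branch-weighted
# (per-lineage rate 4*N0*mu = theta when time is counted in 4N0 generations)
drop_mutations <- function(tree, theta, n) {
  total_len <- sum(tree$lengths)
  n_mut <- stats::rpois(1L, theta * total_len)
  if (n_mut == 0L) {
    return(list(haps = matrix(0L, nrow = n, ncol = 0L),
                positions = numeric(0)))
  }
  branch <- sample.int(length(tree$lengths), n_mut, replace = TRUE,
                       prob = tree$lengths)
  pos <- sort(stats::runif(n_mut))
  haps <- matrix(0L, nrow = n, ncol = n_mut)
  for (j in seq_len(n_mut)) {
    haps[tree$sets[[branch[j]]], j] <- 1L
  }
  list(haps = haps, positions = pos)
}
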