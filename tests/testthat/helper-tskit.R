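# cross-implementation oracle: msprime simulations with tskit statistics,
# exchanged through temp files (tskit's site statistics use the same
# unbiased estimators as the package's windowed formulas)

tskit_fixture <- function(seed, n_per_deme = 8, sequence_length = 10000,
                          mu = 2e-4) {
  out_json <- tempfile(fileext = ".json")
  out_geno <- tempfile(fileext = ".txt")
  script <- sprintf('
import json, sys
import msprime, numpy as np

seed = %d
n = %d
L = %d
mu = %s
dem = msprime.Demography()
dem.add_population(name="A", initial_size=1000)
dem.add_population(name="B", initial_size=1000)
dem.add_population(name="anc", initial_size=1000)
dem.add_population_split(time=400, derived=["A", "B"], ancestral="anc")
ts = msprime.sim_ancestry(samples={"A": n, "B": n}, demography=dem,
                          sequence_length=L, random_seed=seed)
ts = msprime.sim_mutations(ts, rate=mu, random_seed=seed + 1,
                           model=msprime.BinaryMutationModel())
sets = [list(range(0, 2 * n)), list(range(2 * n, 4 * n))]
res = {
  "diversity_A": float(ts.diversity(sets[0])),
  "diversity_B": float(ts.diversity(sets[1])),
  "divergence": float(ts.divergence(sets)),
  "tajimas_d_A": float(ts.Tajimas_D(sets[0])),
  "tajimas_d_B": float(ts.Tajimas_D(sets[1])),
  "positions": [float(s.position) for s in ts.sites()],
}
G = ts.genotype_matrix()
np.savetxt(sys.argv[1], G, fmt="%%d")
with open(sys.argv[2], "w") as fh:
    json.dump(res, fh)
', seed, n_per_deme, sequence_length, format(mu, scientific = FALSE))
  script_path <- tempfile(fileext = ".py")
  writeLines(script, script_path)
  status <- system2("python", c(script_path, out_geno, out_json),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("python/msprime oracle failed")
  stats <- jsonlite::read_json(out_json, simplifyVector = TRUE)
  haps <- as.matrix(utils::read.table(out_geno))
  dimnames(haps) <- NULL
  list(haps = t(haps),            # haplotypes x sites
       positions = stats$positions,
       stats = stats,
       n_per_deme = n_per_deme,
       sequence_length = sequence_length)
}
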