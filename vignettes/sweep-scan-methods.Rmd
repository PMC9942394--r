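---
title: "Methods: windowed sweep scans, composite-likelihood validation and coalescent calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed sweep scans, composite-likelihood validation and coalescent calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistics it computes,
the models behind its simulators, the tunable parameters that matter, and
the choices made where the design was genuinely open. Nothing here states
an empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Problem setting

Populations of one species sampled along an environmental gradient (the
motivating case: ~80 to ~2,600 m above sea level) are contrasted pairwise:
a focal (higher-altitude) population against a control group, possibly a
pooled union of several low-altitude populations, which the package treats
as a single population. A recent hard selective sweep in the focal
population leaves three linked footprints: locally elevated allele-frequency
differentiation (F~ST~), locally purged focal diversity (large
θ~π,control~/θ~π,focal~), and a negative Tajima's D. The scan computes these
in sliding windows, calls candidates where F~ST~ *and* the diversity ratio
are jointly in the empirical top 1%, and cross-validates with an
XP-CLR-style composite-likelihood scan and with absolute divergence D~xy~.

## Site filters

A site passes iff total depth DP ∈ [6, 100] reads, RMS mapping quality
≥ 20, minor-allele frequency ≥ 0.1 (computed over non-missing called
alleles — the standard convention) and missing-genotype fraction ≤ 0.1.
All comparisons are inclusive, exactly as written. Sites with absent DP or
MQ fail the corresponding criterion (unknown quality is not sufficient
quality), except under vacuous thresholds (0 / ∞), which disable the test.
Rejection accounting attributes each lost site to its *first* failing
criterion in the fixed order depth-low, depth-high, MQ, MAF, missingness,
so counts always partition the removals — convenient and deterministic,
though it understates the marginal effect of later criteria. Whether
MAF/missingness should be assessed per whole cohort or per population is
genuinely ambiguous in routine practice; the default is per whole cohort,
with `per_population` switching to the stricter within-every-set rule.

## Window statistics

Windows are 40 kb advanced by 20 kb (both configurable); a window opens at
every step boundary while a full step remains, and the last window is
truncated at the chromosome end, so short chromosomes yield one window and
every base is covered. Windows with fewer than `min_snps` (default 10)
usable SNPs are masked: they are reported but excluded from quantile
thresholds and can never qualify as outliers. The 40-kb/20-kb window
geometry and the top-1% rule are the field's standard resequencing-scan
settings; the SNP floor is this package's own guard against ratio-of-sums
estimates built on a handful of sites.

* **F~ST~** is Weir & Cockerham (1984) for two populations of diploids with
  unequal sample sizes, using observed heterozygote counts; the window
  estimate is the ratio of sums Σa / Σ(a+b+c) ("weighted"), with
  `mean_of_ratios` exposed as an alternative. Negative estimates are kept
  (clamping could only matter in the lower tail, which the caller ignores).
  Sites monomorphic across both groups are sentinel-excluded.
* **θ~π~** per site is the unbiased `(n/(n−1))·2p̂(1−p̂)` with `n` the called
  chromosomes; the window value divides the per-site sum by the *full*
  window length (callable-site masking is out of scope), matching the
  convention of the common windowed-diversity tools. Consequently absolute
  π is sensitive to how much of a window is actually callable; ratios of
  the two groups' π, computed over the same windows, largely cancel this.
* **log₂ θ~π~ ratio** is `log2(π_control / π_focal)`, so a focal sweep is a
  large positive value. A focal-monomorphic window gives +∞: reported, kept
  out of threshold computation, but qualifying (it exceeds any threshold).
  Printed ratio conventions differ across tools and papers in sign; this
  orientation is fixed package-wide and stated in the column header.
* **D~xy~** per site is `p̂₁(1−p̂₂) + p̂₂(1−p̂₁)`, window-normalised like π.
* **Tajima's D** follows the classical 1989 statistic computed from S and
  the summed per-site mean pairwise differences; with missing data the
  sample size entering the constants is the modal called-chromosome count
  across the window's segregating sites. At n = 2 the numerator is
  identically zero while the variance constants vanish; the statistic is
  defined as exactly 0 there rather than 0/0.

## Outlier calling, segments, genes

Top-1% thresholds use the nearest-rank convention: the top set is the
⌊0.01·n⌋ largest unmasked values (minimum 1), the threshold is the smallest
member, and windows qualify by ≥ — consistent with thresholds being
printed as "F~ST~ ≥ x". Thresholds are recomputed per contrast, which is
why different contrasts realise different threshold pairs. Joint outliers
(both statistics ≥ their thresholds) are merged when overlapping *or*
book-ended: with step < window, a genuine sweep spans overlapping windows,
and contiguous reporting is the point of segments. Genes overlap a segment
by ≥ 1 bp (0-based half-open on both sides); containment rules are not
used. Concordance with a validator (XP-CLR or D~xy~ top-1% regions) is
|candidate ∩ validator| / |candidate|.

Allele-frequency trajectories order populations by altitude and flag a site
"altitude-increasing" when frequencies are non-decreasing along the
gradient, the total rise is ≥ `min_rise` (default 0.2 — an invented knob;
the phenomenon, frequencies rising with altitude, is what is being ranked)
and the top population is strictly above the bottom one; Spearman rank
correlation with altitude order is reported alongside.

## The XP-CLR-style scan

This is a documented reimplementation of the XP-CLR model class, not a
bit-compatible clone of any binary. At each grid point (default spacing
20 kb), up to `max_snps` (60) reference-polymorphic SNPs within
`window_radius` (100 kb) contribute. Under drift, the focal frequency given
the reference frequency `p` is Normal(p, ω·p(1−p)) on (0,1) with the tail
mass absorbed at the boundaries; ω is estimated genome-wide by method of
moments with binomial sampling variance subtracted, floored at 0.005
(below that the density is narrower than the 32-point midpoint quadrature
resolves — and such a scan would be uninformative anyway). Under a sweep of
strength `s` at the grid point, a lineage escapes hitchhiking with
probability `1 − exp(−r·d·ln(2N)/s)` (`r·d` the recombination distance,
`N` fixed at 10⁴ by default); non-escaping lineages are dragged to the
allele carried by the single sweeping haplotype, Bernoulli(p). The focal
sample's allele count enters through binomial sampling around the modelled
frequency. The score is `2·(max_s CLL − CLL(0))` over a logarithmic
selection grid on [0, 0.5] with 0 prepended; ties prefer smaller `s`, so
frequency-identical data give score exactly 0. Scores are non-negative by
construction. Because the study design this supports does not state XP-CLR
parameters or its outlier rule, the validator's outlier fraction is a
parameter (default: top 1% of grid scores, adjacent outlier points merged
to regions).

## The coalescent simulator and its scaling

`simulate_neutral_iwm()` is a Hudson-style structured coalescent with the
ms conventions throughout: time in units of 4N₀ generations, within-deme
pair coalescence at rate 2/x_i, per-lineage migration at rate M = 4N₀m
(split equally among other demes) while t < split time, a single ancestral
pool afterwards, and infinite-sites mutations at rate θ = 4N₀μ per lineage
per unit time, so E[S] = θ·a_{n−1}. The scaling is verified in the test
suite against an independent ms-compatible simulator (`mspms`), including
a site-frequency-spectrum chi-square comparison, rather than trusted from
documentation.

Within-locus recombination is deliberately not implemented (`rho > 0` is
rejected): every use in this package — F~ST~ calibration, window
statistics, the synthetic genome — simulates windows/blocks as independent
loci, which is also how ms is typically driven for windowed-F~ST~
calibration. Linkage where it scientifically matters (around planted
sweeps) comes from the forward simulator below. The cost of this choice is
fewer independent genealogies per window than real recombining sequence
would have; the synthetic genome therefore uses 10-kb blocks (about five
genealogies per 40-kb window) so that window statistics average over
several trees.

`calibrate_iwm_to_fst()` grid-searches (split_time × migration_rate),
simulating per-locus Weir–Cockerham F~ST~ distributions per cell
(haplotypes paired into diploids) and minimising either |mean difference|
or a summed quantile discrepancy. It returns the winning cell's full
neutral F~ST~ distribution and its nearest-rank 99th percentile — the
neutral envelope against which empirical top-1% windows are compared. No
fixed demographic parameterisation is assumed — real contrasts differ in
split depth and gene flow — hence a calibrator rather than hard-coded
models; a `converged` flag reports whether the grid could meet the target
at all.

## The forward sweep simulator

`simulate_sweep()` is a discrete-generation Wright–Fisher simulation with
genic selection: a parent is drawn with weight (1+s) per beneficial copy,
so 2Ns = 2·`n_diploids`·s; meiosis applies Poisson(r·L) crossovers and
Poisson(μ·L) new infinite-sites mutations at continuous bp positions. A
single beneficial copy is introduced and runs are conditioned on fixation
by restart (cap 10,000). `wf_trajectory()` exposes the same selection core
without haplotypes; at s = 0 it reproduces the neutral fixation probability
1/(2N). Founder haplotypes typically come from the coalescent simulator,
so the swept population carries realistic standing variation.

Choosing N and s separately matters even at fixed 2Ns: the per-lineage
escape probability scales like `1 − exp(−r·d·ln(2N)/s)`, so a fast sweep
(large s) hitchhikes essentially everything at small r·d while a slow sweep
at the same 2Ns lets recombination free the flanks. The diversity-trough
test therefore uses N = 500, s = 0.1 (the regime the hitchhiking
approximation describes), while the synthetic scan genome uses N = 100,
s = 0.5 — there the point is a compact, strong, cheap footprint.

## The synthetic scan genome

`simulate_scan_genome()` builds the study conditions for end-to-end tests:
10 chromosomes × 1 Mb; a two-deme IWM background (n = 20 + 20 chromosomes,
θ = 10 per 10-kb block ⇒ θ/bp = 0.001, split time 0.1 × 4N₀ generations,
no migration — a modest within-species baseline, mean neutral F~ST~ around
0.1); three hard sweeps (2Ns = 100) planted at the midpoints of
chromosomes 2, 5 and 8, each over an 80-kb region founded on eight
independent genealogies (so the fixed haplotype is a mosaic, as it would
be with recombination). Site depths are Poisson(30) and MQ constant 60
unless degraded generators are injected to exercise the filters. An 80-kb
sweep spans three fully-contained 40-kb windows; since the top-1% set on a
490-window genome holds four windows, a single locus cannot monopolise the
joint top set — recovering at least two of three planted loci is the
designed-for behaviour the acceptance checks measure.

What the generator does *not* emulate, and what passing tests therefore do
not show about real data: within-block linkage and LD decay, callable-site
heterogeneity (the π denominator issue above), non-equilibrium demography
beyond a single split, background selection, and — importantly for the
D~xy~ validator — locally adapted divergent haplotypes. A hard sweep of a
*random* founder haplotype leaves E[D~xy~] exactly unchanged (D~xy~ is
linear in the focal frequency), so on this generator D~xy~ support of
planted sweeps sits at chance level; on real data, where swept haplotypes
are often old and divergent, D~xy~ concordance can be high. The D~xy~
machinery is correspondingly tested for its contracts (formula, symmetry,
split-time monotonicity), not for sweep power.

## Numerical and degenerate-input choices

Quantile thresholds error on all-masked input; empty candidate gene sets
make concordance an error rather than NaN. Position collisions when scaling
relative coordinates to bp are resolved by shifting to the next free base,
preserving order and count. VCF I/O converts between 1-based VCF and
0-based half-open internal coordinates at the boundary; BED is native,
GFF3 is shifted. All randomness flows from explicit seeds; derived seeds
stay below 2³¹. Text outputs format numbers at full precision through a
locale-independent formatter, which is what makes re-runs byte-identical.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic data
at sizes chosen to make Monte-Carlo tolerances meaningful on a single CPU:
2,000 replicate loci for coalescent expectations, 150–300 loci per
calibration cell, 20 replicate 10-Mb genomes for sweep recovery, 50
replicates for the 1-Mb diversity-trough check. These sizes are the
package's stated study conditions; enlarging them tightens the Monte-Carlo
intervals but changes nothing structural.
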