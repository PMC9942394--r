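Package: sweepscan
Title: Selective-Sweep Scans from Windowed Population-Genetic Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects selective sweeps between populations sampled along an
    environmental gradient (e.g. altitude) from a multi-sample VCF. Computes
    Weir-Cockerham F_ST, nucleotide diversity (theta-pi), log2 theta-pi
    ratios, absolute divergence (Dxy) and Tajima's D in sliding genomic
    windows; calls candidate sweep regions as joint top-quantile outliers of
    F_ST and the diversity ratio; cross-validates candidates with an XP-CLR
    style composite-likelihood scan; annotates candidate segments with genes
    and reports cross-method and cross-contrast concordance and
    allele-frequency-altitude trajectories. Ships a coalescent
    isolation-with-migration simulator (ms conventions) for neutral F_ST
    calibration and a forward Wright-Fisher sweep simulator for power
    evaluation, both of which also generate the package's test data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
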