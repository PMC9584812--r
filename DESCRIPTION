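Package: hybridscan
Title: Quantifying Genome Introgression Between Hybridizing Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying hybridization and introgression between
    diverged populations from multi-sample variant data: ABBA-BABA D
    statistics with block-jackknife significance and f4-ratios for all
    population trios, phylogenetic-invariant hybridization tests with
    admixture-fraction (gamma) estimation at population and individual
    level, sliding-window admixture scans (fd, fdM, distance fraction),
    ancestry-diagnostic fixed-difference sites with per-sample hybrid
    indices and panel-based false discovery rates, windowed nucleotide
    diversity and per-site Weir-Cockerham Fst with outlier calling,
    topology weighting over group-labelled trees, and intersection of
    introgression windows with Fst outliers and gene annotation. Includes
    a Balding-Nichols admixture simulator with known per-individual
    ancestry truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
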