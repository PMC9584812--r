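# hybridscan

Population-genomic tools for detecting and quantifying **hybridization and
genome introgression** between diverged lineages — the situation faced, for
example, by wild polecat populations whose range overlaps feral domestic
ferrets: how much of each wild genome derives from the domesticated
lineage, where in the genome does that ancestry sit, and does any of it
look like it is under selection?

The package is aimed at analysts working from a multi-sample VCF plus a
sample-to-population map, and covers the standard introgression toolkit in
one tidyverse-native interface (data frames in, tibbles out):

* **Trio D statistics** (`dtrios_all()`, `d_statistic()`): Patterson's
  ABBA–BABA D from population allele frequencies,
  `D = Σ(ABBA − BABA) / Σ(ABBA + BABA)` with
  `ABBAᵢ = (1−p₁)p₂p₃(1−p_O)` and `BABAᵢ = p₁(1−p₂)p₃(1−p_O)`, a
  delete-one block jackknife for Z and p, and an f4-ratio admixture
  proportion from a seeded split of P3.
* **Invariant hybridization tests** (`hybrid_test()`,
  `individual_tests()`, `full_search()`): site-pattern masses for the
  quartet (outgroup, P1, hybrid, P2) give two linear invariants
  `d₁ = AABB − ABAB` and `d₂ = ABBA − ABAB` whose expectations are
  proportional to γ and 1 − γ, the fraction of the hybrid's genome drawn
  from each parent; `γ̂ = Σd₁ / (Σd₁ + Σd₂)` with a normal test of γ = 0.
  An F1 has γ = 0.5; a group of four with two F1s and two pure parentals
  has γ = 0.25.
* **Windowed admixture scans** (`scan_windows()`,
  `top_percentile_windows()`): D, f_d, f_dM and a distance-fraction
  statistic in SNP-count sliding windows; f_dM is symmetric about zero
  under no introgression, so the top percentile of positive windows marks
  candidate introgressed loci.
* **Diagnostic hybrid index** (`find_diagnostic_sites()`,
  `hybrid_index()`, `estimate_fdr()`): fixed-difference sites between two
  parental panels, per-sample parental-allele fractions (allele-copy
  counting), regional means, and a validation-panel false discovery rate.
* **Diversity and differentiation** (`windowed_pi()`, `per_site_fst()`,
  `fst_outliers()`): nucleotide diversity in 100 kb windows and per-site
  Weir–Cockerham Fst with top-percentile outlier calling.
* **Topology weighting** (`enumerate_topologies()`, `weight_tree()`):
  the 15 unrooted topologies of 5 groups, weighted per window tree by
  exact or Monte-Carlo one-tip-per-group subsampling.
* **Candidate intersection** (`adaptive_candidates()`): top-f_dM windows
  ∩ Fst outliers ∩ gene annotation, the screen for adaptively
  introgressed genes.
* **A simulator with known truth** (`sim_config()`,
  `simulate_genotypes()`): Balding–Nichols drift on the fixed tree
  ((P1,P2),P3),outgroup with per-individual admixture fractions, optional
  P3→P2 gene flow, QUAL scores and missingness — so every stage above is
  testable end to end without external data. `run_pipeline()` chains the
  whole analysis from one config.

## Worked example

Simulate the classic worked scenario — a putative hybrid population of
four diploids of which two are F1s (γ = 0.5) and two are pure P1 — then
test it at population and individual level:

```r
library(hybridscan)

cfg <- sim_config(n_sites = 50000, pop_sizes = c(P1 = 8, P2 = 8, OUT = 2),
                  gamma = c(0.5, 0.5, 0, 0), seed = 1)
sim <- simulate_genotypes(draw_population_frequencies(cfg), cfg)
popmap <- sim_population_map(sim$truth)

qp <- quartet_patterns(sim$geno, popmap, p1 = "P1", hybrid = "HYB",
                       p2 = "P2", outgroup = "OUT")
hybrid_test(qp)
#> Hybridization test: P1 = P1, H = HYB, P2 = P2 (out: OUT)
#>   Z = 11.726  p = 4.68e-32  gamma = 0.2857  (50000 sites)

individual_tests(sim$geno, popmap, "P1", "HYB", "P2", "OUT")
#> # A tibble: 4 × 9
#>   p1    hybrid p2          z        p   gamma n_sites significant low_confidence
#>   <chr> <chr>  <chr>   <dbl>    <dbl>   <dbl>   <int> <lgl>       <lgl>
#> 1 P1    HYB_1  P2    14.5    4.52e-48 0.519     50000 TRUE        FALSE
#> 2 P1    HYB_2  P2    11.8    3.08e-32 0.527     50000 TRUE        FALSE
#> 3 P1    HYB_3  P2     0.279  3.90e- 1 0.0123    50000 FALSE       FALSE
#> 4 P1    HYB_4  P2     0.0706 4.72e- 1 0.00313   50000 FALSE       FALSE
```

The population-level γ̂ ≈ 0.29 reflects the group's average P2 ancestry
(truth 0.25: two F1s at 0.5 and two pure P1 at 0); the individual tests
separate the two F1s (γ̂ ≈ 0.52, strongly significant) from the two pure
individuals (γ̂ ≈ 0, non-significant). `tidy()` and `glance()` turn any
fitted test object into a tibble; `plot_window_scan()`,
`plot_hybrid_index()` and `plot_topology_weights()` draw the standard
figures.

See `vignettes/introgression-methods.Rmd` for the statistical background,
parameter choices and limitations.

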