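---
title: "Statistical methods for quantifying introgression with hybridscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for quantifying introgression with hybridscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridscan)
```

hybridscan quantifies hybridization and introgression between diverged
populations from diploid genotype data. This vignette describes the
statistical models behind each component, the tunable parameters and their
defaults, what the built-in simulator does and does not emulate, and the
numerical conventions adopted where the design was genuinely open.

## Data model

All analyses run off a *genotype table* (`geno_tbl`): a tibble of variant
sites (contig, 1-based position, alleles, QUAL) carrying a sites × samples
matrix of alternate-allele dosages (0/1/2, `NA` = missing). Dosages come
from a VCF via `read_vcf()` (phasing is ignored; multi-allelic and non-SNP
records are read but flagged non-biallelic) or from the simulator. All
frequency-based statistics use only non-missing calls; nothing is imputed.

Positions are stored 1-based as printed in a VCF. Every *interval*
operation — scan windows, diversity windows, genes, BED intervals, merged
regions — uses 0-based half-open spans, with a point position `pos`
contained in `[start, end)` iff `start <= pos - 1 < end`. GFF input
(1-based closed) is converted on read. Fixing one conversion point
prevents off-by-one drift in the window/outlier/gene intersections.

## The synthetic admixture model

`sim_config()` + `draw_population_frequencies()` + `simulate_genotypes()`
generate data with known truth under a Balding–Nichols drift model on the
fixed population tree ((P1,P2),P3),outgroup. A branch with drift
coefficient F draws its allele frequency from a Beta distribution with
mean equal to the parent frequency p and variance p(1−p)F; F = 0 copies
the parent exactly. Per-individual genotypes are two Bernoulli draws from
the population frequency. An admixed individual with fraction γ draws each
allele copy's ancestry from P2 with probability γ (else P1) and then the
allele from the donor's frequency, so its expected dosage is
2(γp₂ + (1−γ)p₁) at every site — the mixture-linearity property the
estimators rely on. Locus-level gene flow replaces the P2 frequency with
the P3 frequency at a configurable fraction of sites (or at an explicit
site range, to emulate a localized introgressed segment).

Defaults, chosen once as a plausible diverged-populations regime and used
throughout the tests: ancestral frequencies Uniform(0.1, 0.9) (segregating
but not extreme); drift F = 0.1 on every branch including the internal
(P1,P2) branch — strong enough that the parents are clearly distinct,
weak enough that most sites stay polymorphic; QUAL ~ 30 + Gamma(2, 15);
no missingness; the outgroup fixed for the ancestral allele, making
"derived" unambiguous (a drifting outgroup is available via
`drift = c(OUT = ...)` for robustness checks); one contig with sites every
100 bp. Divergence magnitudes between real polecat-like and ferret-like
lineages are not published as drift coefficients, so F is a free,
configurable choice.

The simulator deliberately omits linkage (sites are independent),
recombination maps, selection and demography. Consequently the tests
demonstrate *estimator correctness under the model*, not robustness to LD
— which is why the D statistic uses a block jackknife (robust to linkage
on real data) even though simulated sites are exchangeable. The maternal
lineage of a hybrid is the ancestry of one randomly chosen allele copy, a
simplification standing in for cross direction.

## Trio D statistics

For populations (P1, P2, P3) and an outgroup O, per-site pattern masses
are computed from allele frequencies: ABBAᵢ = (1−p₁)p₂p₃(1−p_O), BABAᵢ =
p₁(1−p₂)p₃(1−p_O), and D = Σ(ABBAᵢ−BABAᵢ)/Σ(ABBAᵢ+BABAᵢ). Sites where the
outgroup is polymorphic are kept with the (1−p_O) weighting rather than
dropped. Significance uses a delete-one jackknife over `n_blocks = 20`
contiguous equal-site blocks (a common default; the estimate is
insensitive to the exact count), SE² = (m−1)/m · Σ(D₍₋ⱼ₎−D̄)², Z = D/SE and
a one-tailed normal p. Degenerate cases: Σ(ABBA+BABA) = 0 is an error;
zero jackknife variance (e.g. identical blocks) is flagged and returns no
Z rather than infinity.

**Orientation and test level.** Presentation tables orient each trio so
D ≥ 0 (swapping P1/P2), which makes the tabulated one-tailed p a
*selection-adjusted* quantity: under the null the oriented statistic is
folded, so its one-tailed p rejects at twice the nominal rate. When a
gene-flow direction is specified in advance, `d_statistic(...,
orient = FALSE)` keeps the signed statistic, whose one-tailed p holds its
nominal level exactly — the package's calibration tests verify a 5%
type-I rate this way. `dtrios_all()` picks each trio's P3 as the member
whose exclusion maximizes the shared-derived (BBAA) sister mass, then
orients P1/P2.

The f4-ratio estimates the admixture proportion as
f4(P1,P2;P3a,O)/f4(P1,P3b;P3a,O) with the P3 samples halved at random
(seeded, reproducible). With few P3 samples the denominator is noisy and
the ratio can exceed 1 when the assumed topology is wrong; it is reported
as computed, not clamped.

## Invariant hybridization tests and γ

For the ordered quartet (O, P1, H, P2), each taxon's probability of
showing the derived allele at a site is its group allele frequency (a
single individual's dosage/2 in individual mode). The 16 site-pattern
masses at a site are products of these probabilities, so they sum to
exactly 1 per usable site (a conservation law asserted in tests). Writing
m(·) for accumulated masses, the two invariants

* d₁ = m(AABB) − m(ABAB)
* d₂ = m(ABBA) − m(ABAB)

have expectations γ(A−B) and (1−γ)(A−B) under the drift-plus-mixture
model, where A and B depend only on the ancestral frequency law and drift
(derivable in closed form under Balding–Nichols). Hence

* γ̂ = Σd₁ / (Σd₁ + Σd₂), with γ̂ → 1 − γ̂ exactly under P1↔P2 exchange;
* Z = mean(d₁)/SE(mean(d₁)) over sites, standard normal when H carries no
  P2 ancestry, one-tailed p.

Following the usual reporting convention, only results that are
significant *and* have 0 < γ̂ < 1 count as hybridization evidence: a
population sister to P2 (γ̂ ≈ 1) or to P1 (γ̂ ≈ 0, non-significant) is
excluded. `full_search()` tests every directed arrangement (three hybrid
roles per unordered trio; P1/P2 symmetric) and corrects p-values across
arrangements with Bonferroni by default; because it is not stated whether
the reference workflow corrected across trios or filtered raw p,
`correction = "none"` exposes the other mode. Individuals with fewer than
half the population-level usable sites are flagged `low_confidence` rather
than dropped. An individual with no called genotypes is an error, never a
silent zero.

Correctness is defined by recovery, not by matching an external binary:
an F1 recovers γ̂ ≈ 0.5, a 2-F1 + 2-pure group recovers ≈ 0.25, γ̂ is
monotone across the γ grid, and the estimator agrees with an independent
least-squares mixture regression of the hybrid frequency on the
generator's true parental frequencies within ±0.05. (The least-squares
oracle must use the generator's true parental frequencies: with sample
frequencies from panels of 8 diploids, the shared sampling noise of p̂₁
biases that regression upward by ~0.1 at γ = 0.2, an attenuation-type
artifact of the oracle, not of the invariant estimator.)

## Windowed admixture scans

`scan_windows()` tiles each chromosome's usable SNPs into windows of
`window_snps = 1000` advancing by `step_snps = 500` (the 1,000-SNP window
is the conventional scan size; the step is unstated in common workflows,
so a 50% overlap is the default and both are parameters). The trailing
partial window is dropped. Per window:

* **D** restricted to the window (with step = window size the windows'
  ABBA/BABA sums concatenate exactly to the genome-wide D — a conservation
  property tested to 1e-12);
* **f_d**: Σ(ABBA−BABA) over Σ of the same with the dynamic donor
  p_D = max(p₂, p₃) substituted for both P2 and P3;
* **f_dM**: the symmetric extension. Per site the denominator is the f_d
  form when p₂ ≥ p₁ and the *negated* mirrored form (donor
  max(p₁, p₃) substituted around P2) otherwise. Algebraically the
  numerator is p₃(p₂−p₁)(1−p_O) and the denominator p_D(p_D−p₁)(1−p_O)
  (resp. p_DD(p_DD−p₂)(1−p_O)), so 0 ≤ |num| ≤ den per site and the
  window ratio is bounded in [−1, 1]; P3↔P1 sharing gives negative values
  and the statistic is symmetric about zero under no introgression.
* **d_f**: a distance-fraction estimator formulated from frequency-based
  distances, d_f = Σ(d_xy(P1,P3) − d_xy(P2,P3)) / Σ(d_xy(P1,P3) − π₃)
  with d_xy(X,Y) = p_X(1−p_Y) + p_Y(1−p_X) and π₃ = 2p₃(1−p₃): 1 when P2
  equals the donor, 0 under the null, negative for P1-sharing. It is
  reported for completeness; window *selection* always uses f_dM.

A window with a zero denominator records `NA` for that statistic but is
retained. Top-percentile selection is nearest-rank on the upper tail: the
k = ⌈n·pct/100⌉ largest defined values, ties at the threshold included,
restricted to positive values when the statistic's sign encodes direction.
The same rule drives Fst outlier calling, so "top 1%" of 100 distinct
windows is exactly 1 window.

## Diagnostic sites, hybrid index and FDR

A site is ancestry-diagnostic when every sample of panel A is called and
homozygous for one allele and every sample of panel B homozygous for the
other, the site is a biallelic SNP, and QUAL ≥ 30 (the conventional
quality floor, configurable). The panel-A allele need not be the
reference allele. A target sample's hybrid index is the fraction of its
allele copies at called diagnostic sites matching panel A — copy counting
(a heterozygote contributes 1 of 2) rather than genotype classing, because
the copy fraction is the unbiased estimator of genomic ancestry
(E[frac_A] = γ for simulated hybrids; bias < 0.01 at 10,000 sites in the
tests). Missing sites leave both numerator and denominator; a sample with
no called diagnostic sites is an error. Regional summaries are unweighted
means over samples with a region label. The validation FDR is discordant
allele copies over called copies on a presumed-pure panel — the same units
as the index. Note that panels define the sites: adding a panel sample can
only shrink the diagnostic set, and panel members score exactly 1 or 0 by
construction.

## Diversity and differentiation

Per-site diversity is πᵢ = 2·n_ref·n_alt/(n(n−1)) over called allele
counts; windows of 100 kb anchored at position 0 tile each chromosome, a
window's π is Σπᵢ divided by the window's true span (the trailing window
keeps its real length), and a population's summary is the mean over
windows. Using the genomic span as denominator treats unobserved
positions as invariant, the whole-genome convention; consequently mean π
is per-bp and halving/doubling the window span leaves the chromosome-wide
per-bp total unchanged.

Per-site Fst is the Weir–Cockerham (1984) two-population
variance-components estimator a/(a+b+c) computed from sample sizes,
allele frequencies and observed heterozygote proportions, with missing
calls excluded per site. Negative estimates are reported as-is (they are
informative about the estimator's null behavior); only undefined sites
(zero denominator) are excluded from percentile ranking. A Hudson-type
estimator (1 − H_w/H_b) is provided for robustness comparisons.

## Topology weighting

`enumerate_topologies()` builds all (2k−5)!! unrooted binary topologies
on k group labels (15 for five groups) by recursive subtree combination,
identifying each by a canonical split key (the sorted set of non-trivial
bipartitions, each normalized to the side not containing the
alphabetically first label) — insensitive to rooting, rotation and branch
lengths. The outgroup is simply one of the k groups; rooting is
presentation only.

`weight_tree()` scores a group-labelled tree by the fraction of
one-tip-per-group subsamples inducing each topology: exact enumeration
when the combination count is ≤ `max_exact = 10000` (a balance of
exactness and runtime; exact weights sum to 1 identically), seeded
Monte-Carlo otherwise (weights are sample proportions, converging to the
exact values as draws grow — verified at three sample sizes). A
combination whose pruned subtree is unresolved (input polytomy)
contributes equal fractional weight to every *compatible* binary topology
(those whose split set contains the polytomy's splits); a `discard` mode
drops such combinations instead.

`nj_window_tree()` provides a deterministic neighbor-joining window tree
on allele-sharing distances (mean |dosage difference|/2 over shared
called sites) so fully synthetic end-to-end runs have trees to weight; it
stands in for likelihood-based window-tree inference, which is out of
scope. An all-identical window returns a star tree flagged `star = TRUE`.

## Candidate intersection

`adaptive_candidates()` implements the adaptive-introgression screen:
top-percentile f_dM windows, top-percentile Fst outliers between the two
parental populations, windows retained only if they contain an outlier
(half-open containment: a point exactly at `start` is in, at `end` is
out), overlapping-or-adjacent windows merged into maximal regions (gap
tolerance 0 by default), and genes counted as candidates only when the
gene overlaps a merged region *and* contains an outlier position. The
stricter gene ∩ outlier ∩ window rule (rather than gene ∩ window alone)
is deliberate: it reproduces the situation where a region's outliers sit
near, but not inside, the closest gene, which should then report zero
genes with the neighbor visible via the signed nearest-outlier distance
in `mode = "gene-in-window"`.

## Pipeline and reproducibility

`run_pipeline()` chains simulate/read → filters (biallelic, QUAL ≥ 30,
optional LD pruning at r² ≤ 0.8 in 5 kb windows with greedy keep-first
retention and pairwise-complete Pearson r², optional ascertainment filter
requiring ≥ 3 alternate alleles plus both homozygote classes) → trio D →
hybridization tests → window scan → diagnostic index → π/Fst → candidate
intersection, writing one TSV per stage plus a JSON summary. Stages
lacking inputs (no hybrid group, no annotation) are skipped with a logged
notice. A single run seed is fanned out per stage through a fixed
stage-name hash, so any stage re-run from the saved intermediates (the
filtered VCF and popmap are written out) reproduces the full-run output
exactly. Identical configs produce byte-identical numeric outputs.

## Problem sizes and what the tests show

The recovery tests run at the study-design scale the estimators are meant
for: 50,000 independent biallelic sites, parental panels of 8 diploids,
drift F = 0.1, ten replicate seeds for the γ recoveries; ~100,000 sites /
200 windows for the null f_dM symmetry; 200 replicate null datasets for
the D-test calibration. These sizes make Monte-Carlo error comfortably
smaller than the stated tolerances (e.g. γ̂ within ±0.05) while keeping
the full suite under a minute. Passing them demonstrates correct
arithmetic, calibration and recovery under the simulator's assumptions —
independent sites, no selection, known panels; it does not by itself
demonstrate robustness to linkage, reference bias or population structure
in real data, for which the block jackknife, the LD pruning filter and
the validation-panel FDR are the package's mitigations.

## Known limitations

* The f4-ratio depends on a random halving of P3 and is unstable for
  small P3 panels; values above 1 indicate model violation, not bounded
  admixture.
* Individual-level γ̂ from dosage/2 frequencies is noisier than
  population-level γ̂ and mildly shrunken toward the population mean when
  the individual has substantial missingness (hence the low-confidence
  flag).
* The windowed scan's genomic spans depend on SNP density; SNP-count
  windows of fixed size have variable bp spans, so downstream span sums
  are data-dependent quantities.
* Topology weighting assumes the input trees are correct; uncertainty in
  tree inference is not propagated.
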