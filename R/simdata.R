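#' Simulation configuration for synthetic admixed populations
#'
#' Describes a four-lineage study design with known truth: two sister
#' populations `P1` and `P2`, a third population `P3`, an outgroup `OUT`
#' (fixed for the ancestral allele by default), and an optional group of
#' admixed individuals (`HYB`) whose genomes mix `P1` and `P2` ancestry in
#' per-individual proportions `gamma` (the fraction contributed by `P2`).
#' Population allele frequencies follow the Balding-Nichols drift model on
#' the fixed tree `((P1,P2),P3),OUT`: a branch with drift coefficient `F`
#' draws its frequency from a Beta distribution with mean equal to the
#' parent frequency `p` and variance `p(1-p)F`.
#'
#' @param n_sites Number of independent biallelic sites.
#' @param pop_sizes Named integer vector of diploid sample counts for
#'   `P1`, `P2`, `P3`, `OUT`. Populations with count 0 are omitted.
#' @param drift Named vector of drift coefficients `F` in `[0,1)` for
#'   branches `P12` (internal), `P1`, `P2`, `P3`, and optionally `OUT`.
#'   When `OUT` is absent the outgroup is fixed for the ancestral allele
#'   (frequency 0), so the alternate allele is unambiguously derived.
#' @param gamma Numeric vector of admixture fractions in `[0,1]`, one per
#'   admixed individual (fraction of ancestry drawn from `P2`). Names are
#'   used as sample ids; unnamed entries become `HYB_1`, `HYB_2`, ...
#' @param geneflow_rate Fraction in `[0,1]` of loci at which the `P2`
#'   frequency is replaced by the `P3` frequency, emulating P3->P2 gene
#'   flow (0 = null scenario).
#' @param geneflow_sites Optional integer site indices receiving the gene
#'   flow (a contiguous range emulates a localized introgressed segment);
#'   by default sites are drawn at random at rate `geneflow_rate`.
#' @param ancestral_freq Function `n -> n` draws of the ancestral allele
#'   frequency, with support strictly inside (0,1).
#' @param qual_law Function `n -> n` per-site quality scores.
#' @param missing_rate Probability in `[0,1)` that any genotype call is
#'   missing.
#' @param regions Optional named character vector mapping sample id to a
#'   region label (used by [aggregate_by_region()]).
#' @param chrom Contig name for the simulated sites.
#' @param pos_spacing Base-pair spacing between consecutive sites.
#' @param seed Integer seed; fully determines the output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_sites = 10000,
                       pop_sizes = c(P1 = 8, P2 = 8, P3 = 8, OUT = 2),
                       drift = c(P12 = 0.1, P1 = 0.1, P2 = 0.1, P3 = 0.1),
                       gamma = numeric(),
                       geneflow_rate = 0,
                       geneflow_sites = NULL,
                       ancestral_freq = function(n) stats::runif(n, 0.1, 0.9),
                       qual_law = function(n) 30 + stats::rgamma(n, shape = 2, scale = 15),
                       missing_rate = 0,
                       regions = NULL,
                       chrom = "chr1",
                       pos_spacing = 100,
                       seed = 1) {
  stopifnot(n_sites >= 0, missing_rate >= 0, missing_rate < 1,
            geneflow_rate >= 0, geneflow_rate <= 1)
  if (any(drift < 0) || any(drift >= 1)) {
    stop("drift coefficients F must lie in [0, 1)")
  }
  if (length(gamma) && (any(gamma < 0) || any(gamma > 1))) {
    stop("admixture fractions gamma must lie in [0, 1]")
  }
  pop_sizes <- pop_sizes[pop_sizes > 0]
  known <- c("P1", "P2", "P3", "OUT")
  if (!all(names(pop_sizes) %in% known)) {
    stop("pop_sizes names must be among ", paste(known, collapse = ", "))
  }
  if (!all(c("P1", "P2") %in% names(pop_sizes))) {
    stop("P1 and P2 must both have at least one sample")
  }
  if (length(gamma)) {
    nm <- names(gamma)
    if (is.null(nm)) nm <- rep("", length(gamma))
    nm[nm == ""] <- paste0("HYB_", seq_along(gamma))[nm == ""]
    names(gamma) <- nm
  }
  structure(list(n_sites = as.integer(n_sites), pop_sizes = pop_sizes,
                 drift = drift, gamma = gamma,
                 geneflow_rate = geneflow_rate,
                 geneflow_sites = geneflow_sites,
                 ancestral_freq = ancestral_freq, qual_law = qual_law,
                 missing_rate = missing_rate, regions = regions,
                 chrom = chrom, pos_spacing = pos_spacing,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Balding-Nichols draw: Beta with mean p and variance p(1-p)F.
bn_draw <- function(p, f) {
  if (f == 0) return(p)
  stats::rbeta(length(p), shape1 = p * (1 - f) / f,
               shape2 = (1 - p) * (1 - f) / f)
}

#' Draw per-population allele frequencies under the drift model
#'
#' Walks the fixed population tree `((P1,P2),P3),OUT` applying one
#' Balding-Nichols draw per branch. The outgroup frequency is fixed at 0
#' (all-ancestral) unless `drift["OUT"]` is supplied. When
#' `geneflow_rate > 0` (or `geneflow_sites` is set) the `P2` frequency at
#' the selected loci is replaced by the `P3` frequency, and those sites are
#' flagged in the `introgressed` column.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `chrom`, `pos`, `p_anc`, one frequency
#'   column per simulated population (`P1`, `P2`, `P3`, `OUT`), and
#'   `introgressed`.
#' @export
draw_population_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_sites
  p_anc <- config$ancestral_freq(n)
  if (n > 0 && (any(p_anc <= 0) || any(p_anc >= 1))) {
    stop("ancestral_freq must have support strictly inside (0, 1)")
  }
  dr <- function(br) if (br %in% names(config$drift)) config$drift[[br]] else 0
  p12 <- bn_draw(p_anc, dr("P12"))
  out <- tibble::tibble(chrom = rep(config$chrom, n),
                        pos = if (n) seq(1L, by = as.integer(config$pos_spacing),
                                         length.out = n) else integer(),
                        p_anc = p_anc,
                        P1 = bn_draw(p12, dr("P1")),
                        P2 = bn_draw(p12, dr("P2")))
  if ("P3" %in% names(config$pop_sizes)) out$P3 <- bn_draw(p_anc, dr("P3"))
  out$OUT <- if ("OUT" %in% names(config$drift)) {
    bn_draw(p_anc, dr("OUT"))
  } else {
    rep(0, n)
  }
  out$introgressed <- rep(FALSE, n)
  flow <- config$geneflow_sites
  if (is.null(flow) && config$geneflow_rate > 0) {
    flow <- sample.int(n, size = round(config$geneflow_rate * n))
  }
  if (length(flow)) {
    if (!"P3" %in% names(out)) stop("gene flow requires a P3 population")
    out$P2[flow] <- out$P3[flow]
    out$introgressed[flow] <- TRUE
  }
  out
}

#' Simulate diploid genotypes with known admixture truth
#'
#' Pure individuals draw two allele copies Bernoulli(population frequency)
#' per site. An admixed individual with fraction `gamma` first draws each
#' allele copy's ancestry (P2 with probability `gamma`, else P1) and then
#' the allele from the donor population's frequency, so its expected
#' alternate dosage is `2 * (gamma * p2 + (1 - gamma) * p1)` at every
#' site. Outgroup individuals are homozygous ancestral unless the outgroup
#' drifts. Per-site QUAL scores come from `config$qual_law` and genotypes
#' are masked missing independently at `config$missing_rate`.
#'
#' @param freqs Output of [draw_population_frequencies()].
#' @param config The same [sim_config()].
#' @return List with elements `geno` (a [geno_tbl()]) and `truth` (tibble
#'   with columns `sample`, `population`, `true_gamma`, `maternal_lineage`,
#'   `region`).
#' @export
simulate_genotypes <- function(freqs, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- nrow(freqs)
  pops <- names(config$pop_sizes)
  ids <- unlist(lapply(pops, function(p) {
    paste0(p, "_", seq_len(config$pop_sizes[[p]]))
  }))
  pop_of <- rep(pops, config$pop_sizes[pops])
  hyb <- names(config$gamma)
  if (any(hyb %in% ids)) stop("duplicate sample id between gamma and populations")
  all_ids <- c(ids, hyb)
  dos <- matrix(NA_integer_, nrow = n, ncol = length(all_ids),
                dimnames = list(NULL, all_ids))
  for (j in seq_along(ids)) {
    p <- freqs[[pop_of[j]]]
    dos[, j] <- stats::rbinom(n, 1, p) + stats::rbinom(n, 1, p)
  }
  maternal <- pop_of
  for (k in seq_along(hyb)) {
    g <- config$gamma[[k]]
    copy <- function() {
      anc2 <- stats::rbinom(n, 1, g) == 1L
      stats::rbinom(n, 1, ifelse(anc2, freqs$P2, freqs$P1))
    }
    dos[, length(ids) + k] <- copy() + copy()
    maternal <- c(maternal, if (stats::rbinom(1, 1, g) == 1L) "P2" else "P1")
  }
  if (config$missing_rate > 0 && length(dos)) {
    dos[stats::runif(length(dos)) < config$missing_rate] <- NA_integer_
  }
  sites <- tibble::tibble(chrom = freqs$chrom, pos = freqs$pos,
                          ref = rep("A", n), alt = rep("T", n),
                          qual = config$qual_law(n))
  contigs <- tibble::tibble(
    chrom = config$chrom,
    length = max(config$n_sites, 1L) * as.integer(config$pos_spacing))
  truth <- tibble::tibble(
    sample = all_ids,
    population = c(pop_of, rep("HYB", length(hyb))),
    true_gamma = c(ifelse(pop_of == "P1", 0,
                          ifelse(pop_of == "P2", 1, NA_real_)),
                   unname(config$gamma)),
    maternal_lineage = maternal,
    region = if (is.null(config$regions)) NA_character_ else
      unname(config$regions[all_ids]))
  list(geno = geno_tbl(sites, dos, contigs = contigs), truth = truth)
}

#' Population map for a simulated dataset
#'
#' @param truth Truth table from [simulate_genotypes()].
#' @return Tibble with columns `sample`, `population`, `role` suitable for
#'   every analysis function that takes a population map.
#' @export
sim_population_map <- function(truth) {
  role <- c(P1 = "P1", P2 = "P2", P3 = "P3", OUT = "outgroup",
            HYB = "hybrid")[truth$population]
  tibble::tibble(sample = truth$sample, population = truth$population,
                 role = unname(role))
}

#' Simulate a dataset and write it to disk
#'
#' Convenience wrapper producing the three files downstream analyses read:
#' a VCF, a population-map TSV (`sample`, `population`, `role`) and a
#' truth TSV.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory `geno`, `truth`, `popmap`
#'   and the file paths.
#' @export
simulate_dataset <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  freqs <- draw_population_frequencies(config)
  sim <- simulate_genotypes(freqs, config)
  popmap <- sim_population_map(sim$truth)
  paths <- list(vcf = file.path(dir, "simulated.vcf"),
                popmap = file.path(dir, "popmap.tsv"),
                truth = file.path(dir, "truth.tsv"))
  write_vcf(sim$geno, paths$vcf)
  readr::write_tsv(popmap, paths$popmap)
  readr::write_tsv(sim$truth, paths$truth)
  invisible(c(sim, list(popmap = popmap, paths = paths)))
}
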