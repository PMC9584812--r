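# Shared fixture builders: everything is generated in code at test time.

# Simulate a quartet dataset and return genotype table, truth and popmap.
quartet_sim <- function(n_sites, gamma = numeric(),
                        pop_sizes = c(P1 = 8, P2 = 8, OUT = 2),
                        seed = 1, ...) {
  cfg <- sim_config(n_sites = n_sites, pop_sizes = pop_sizes,
                    gamma = gamma, seed = seed, ...)
  sim <- simulate_genotypes(draw_population_frequencies(cfg), cfg)
  c(sim, list(popmap = sim_population_map(sim$truth), config = cfg))
}

# Build a geno_tbl directly from a dosage matrix (sites x samples).
make_gm <- function(dosage, chrom = "chr1", pos = NULL, ref = "A",
                    alt = "T", qual = 50, contigs = NULL) {
  n <- nrow(dosage)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  sites <- tibble::tibble(chrom = rep_len(chrom, n), pos = as.integer(pos),
                          ref = rep_len(ref, n), alt = rep_len(alt, n),
                          qual = rep_len(qual, n))
  geno_tbl(sites, dosage, contigs = contigs)
}

# Simple popmap for hand-built matrices: population = prefix before "_".
popmap_from_ids <- function(ids) {
  tibble::tibble(sample = ids, population = sub("_.*", "", ids),
                 role = NA_character_)
}

# Write a small VCF fixture and return its path.
write_vcf_fixture <- function(lines, dir = tempdir()) {
  path <- tempfile(fileext = ".vcf", tmpdir = dir)
  writeLines(lines, path)
  path
}
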