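#' Restrict a genotype table to biallelic SNP sites
#'
#' Keeps sites with exactly one alternate allele where both alleles are
#' single bases. Idempotent.
#'
#' @param gm A [geno_tbl()].
#' @return A filtered [geno_tbl()].
#' @export
filter_biallelic_snps <- function(gm) {
  subset_sites(gm, gm$biallelic)
}

#' Drop low-quality sites
#'
#' Removes sites whose QUAL is below `min_qual` (strictly less than; a site
#' at exactly the threshold is kept). The default threshold of 30 matches
#' routine variant-quality filtering practice.
#'
#' @param gm A [geno_tbl()].
#' @param min_qual Minimum QUAL to keep a site.
#' @return A filtered [geno_tbl()].
#' @export
filter_qual <- function(gm, min_qual = 30) {
  subset_sites(gm, !is.na(gm$qual) & gm$qual >= min_qual)
}

#' Greedy linkage-disequilibrium pruning
#'
#' Left-to-right within each chromosome: a site is dropped when its squared
#' Pearson correlation (over pairwise-complete dosage vectors) with any
#' already-retained site within `window_bp` exceeds `r2_max`. Earlier
#' positions win ties, so the result is deterministic and no retained pair
#' within a window has r-squared above the threshold. Defaults (r2 0.8,
#' 5 kb windows) match common pruning settings for diverged-population
#' panels.
#'
#' @param gm A [geno_tbl()] of biallelic sites.
#' @param r2_max Maximum allowed r-squared between retained sites.
#' @param window_bp Window, in base pairs, within which pairs are compared.
#' @return A pruned [geno_tbl()].
#' @export
ld_prune <- function(gm, r2_max = 0.8, window_bp = 5000) {
  n <- nrow(gm)
  if (n < 2) return(gm)
  keep <- logical(n)
  dos <- gm$dosage
  kept_idx <- integer(0)
  for (i in seq_len(n)) {
    cand <- kept_idx[gm$chrom[kept_idx] == gm$chrom[i] &
                       gm$pos[i] - gm$pos[kept_idx] <= window_bp]
    ok <- TRUE
    for (j in cand) {
      r <- suppressWarnings(
        stats::cor(dos[i, ], dos[j, ], use = "pairwise.complete.obs"))
      if (!is.na(r) && r * r > r2_max) { ok <- FALSE; break }
    }
    if (ok) { keep[i] <- TRUE; kept_idx <- c(kept_idx, i) }
  }
  subset_sites(gm, keep)
}

#' Ascertainment filter for informative sites
#'
#' Keeps a site only if the total alternate-allele count (over non-missing
#' calls) is at least `min_alt_alleles` and the site carries at least one
#' homozygous-alternate and one homozygous-reference call — the
#' ascertainment condition used when downstream tools require observed
#' fixed classes at every site.
#'
#' @param gm A [geno_tbl()] of biallelic sites.
#' @param min_alt_alleles Minimum total alternate allele count.
#' @return A filtered [geno_tbl()].
#' @export
ascertainment_filter <- function(gm, min_alt_alleles = 3) {
  dos <- gm$dosage
  alt_count <- rowSums(dos, na.rm = TRUE)
  has_hom_alt <- rowSums(dos == 2L, na.rm = TRUE) > 0
  has_hom_ref <- rowSums(dos == 0L, na.rm = TRUE) > 0
  subset_sites(gm, alt_count >= min_alt_alleles & has_hom_alt & has_hom_ref)
}
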