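#' Ancestry-diagnostic fixed-difference sites between two panels
#'
#' A site is diagnostic when every panel-A sample is called and homozygous
#' for one allele, every panel-B sample is called and homozygous for the
#' other allele, the site is a biallelic SNP, and its QUAL passes
#' `min_qual`. The common allele of a panel need not be the reference
#' allele; only within-panel fixation and a between-panel difference are
#' required.
#'
#' @param gm A [geno_tbl()].
#' @param panel_a,panel_b Character vectors of sample ids (non-overlapping).
#' @param min_qual Minimum QUAL for a diagnostic site.
#' @return Tibble of class `diagnostic_sites` with columns `chrom`, `pos`,
#'   `allele_a`, `allele_b` (allele strings) and `dosage_a` (the dosage
#'   value, 0 or 2, that panel A is fixed for). Panel ids and the QUAL
#'   filter are kept in attributes as provenance.
#' @export
find_diagnostic_sites <- function(gm, panel_a, panel_b, min_qual = 30) {
  if (length(intersect(panel_a, panel_b))) {
    stop("panels overlap: ", paste(intersect(panel_a, panel_b),
                                   collapse = ", "))
  }
  gm2 <- subset_samples(gm, c(panel_a, panel_b))
  da <- gm2$dosage[, panel_a, drop = FALSE]
  db <- gm2$dosage[, panel_b, drop = FALSE]
  fixed_a0 <- rowSums(da == 0L) == length(panel_a)   # NA-poisoning intended:
  fixed_a2 <- rowSums(da == 2L) == length(panel_a)   # any missing call fails
  fixed_b0 <- rowSums(db == 0L) == length(panel_b)
  fixed_b2 <- rowSums(db == 2L) == length(panel_b)
  fixed_a0[is.na(fixed_a0)] <- FALSE; fixed_a2[is.na(fixed_a2)] <- FALSE
  fixed_b0[is.na(fixed_b0)] <- FALSE; fixed_b2[is.na(fixed_b2)] <- FALSE
  keep <- gm$biallelic & !is.na(gm$qual) & gm$qual >= min_qual &
    ((fixed_a0 & fixed_b2) | (fixed_a2 & fixed_b0))
  dosage_a <- ifelse(fixed_a0, 0L, 2L)[keep]
  out <- tibble::tibble(chrom = gm$chrom[keep], pos = gm$pos[keep],
                        allele_a = ifelse(dosage_a == 0L, gm$ref[keep],
                                          gm$alt[keep]),
                        allele_b = ifelse(dosage_a == 0L, gm$alt[keep],
                                          gm$ref[keep]),
                        dosage_a = dosage_a)
  structure(out, panel_a = panel_a, panel_b = panel_b, min_qual = min_qual,
            class = c("diagnostic_sites", class(out)))
}

# Match diagnostic sites to rows of a genotype table by (chrom, pos).
diagnostic_rows <- function(gm, sites) {
  match(paste(sites$chrom, sites$pos),
        paste(gm$chrom, gm$pos))
}

#' Hybrid index: fraction of allele copies matching panel A
#'
#' For each target sample, looks up its genotype at every diagnostic site
#' and counts allele copies matching the panel-A allele (a heterozygote
#' contributes 1 of its 2 copies). Missing calls are excluded from both
#' numerator and denominator, so `frac_a` estimates the genomic ancestry
#' fraction without imputation. For a simulated hybrid with admixture
#' fraction `gamma` toward the panel-A lineage, `E[frac_a] = gamma`.
#'
#' @param gm A [geno_tbl()] containing the target samples.
#' @param sites A [find_diagnostic_sites()] result.
#' @param samples Samples to score (default: all samples in `gm`).
#' @return Tibble with columns `sample`, `n_sites_called`, `frac_a`,
#'   `frac_b` (= 1 - `frac_a`).
#' @export
hybrid_index <- function(gm, sites, samples = NULL) {
  if (is.null(samples)) samples <- sample_ids(gm)
  rows <- diagnostic_rows(gm, sites)
  if (anyNA(rows)) stop("diagnostic sites missing from genotype table")
  dos <- gm$dosage[rows, samples, drop = FALSE]
  # copies matching panel A: dosage itself when A is the alt allele,
  # 2 - dosage when A is the ref allele.
  a_copies <- dos
  flip <- sites$dosage_a == 0L
  a_copies[flip, ] <- 2L - dos[flip, , drop = FALSE]
  called <- colSums(!is.na(dos))
  if (any(called == 0)) {
    stop("no called diagnostic sites for sample(s): ",
         paste(samples[called == 0], collapse = ", "))
  }
  frac_a <- colSums(a_copies, na.rm = TRUE) / (2 * called)
  tibble::tibble(sample = samples, n_sites_called = unname(called),
                 frac_a = unname(frac_a), frac_b = 1 - unname(frac_a))
}

#' Mean hybrid index by region
#'
#' Unweighted per-region means of the panel-A/panel-B ancestry fractions.
#' Samples without a region label are dropped with a warning.
#'
#' @param results Output of [hybrid_index()].
#' @param metadata Tibble with columns `sample`, `region`.
#' @return Tibble with columns `region`, `n_samples`, `mean_frac_a`,
#'   `mean_frac_b`.
#' @export
aggregate_by_region <- function(results, metadata) {
  joined <- dplyr::left_join(results, metadata[, c("sample", "region")],
                             by = "sample")
  if (anyNA(joined$region)) {
    warning("dropping ", sum(is.na(joined$region)),
            " sample(s) without a region label")
    joined <- joined[!is.na(joined$region), , drop = FALSE]
  }
  dplyr::summarise(joined, n_samples = dplyr::n(),
                   mean_frac_a = mean(.data$frac_a),
                   mean_frac_b = mean(.data$frac_b),
                   .by = "region")
}

#' False discovery rate of a diagnostic site set on a validation panel
#'
#' Scores genotype calls of presumed-pure validation samples at the
#' diagnostic positions and counts allele copies that do not match the
#' expected panel's allele. The rate is discordant copies / called copies,
#' in the same allele-copy units as [hybrid_index()].
#'
#' @param validation A [geno_tbl()] of validation samples (calls restricted
#'   to, or at least covering, the diagnostic positions).
#' @param sites A [find_diagnostic_sites()] result.
#' @param expected_panel `"A"` or `"B"`: the panel the validation samples
#'   are presumed to belong to.
#' @return Tibble with columns `total_calls` (allele copies),
#'   `discordant_calls`, `rate`.
#' @export
estimate_fdr <- function(validation, sites, expected_panel = "A") {
  expected_panel <- match.arg(expected_panel, c("A", "B"))
  rows <- diagnostic_rows(validation, sites)
  present <- !is.na(rows)
  if (!any(present)) stop("no diagnostic sites present in validation data")
  dos <- validation$dosage[rows[present], , drop = FALSE]
  dos_a <- sites$dosage_a[present]
  a_copies <- dos
  flip <- dos_a == 0L
  a_copies[flip, ] <- 2L - dos[flip, , drop = FALSE]
  match_copies <- if (expected_panel == "A") a_copies else 2L - a_copies
  total <- 2 * sum(!is.na(dos))
  if (total == 0) stop("no called genotypes at diagnostic sites")
  discordant <- total - sum(match_copies, na.rm = TRUE)
  tibble::tibble(total_calls = total, discordant_calls = discordant,
                 rate = discordant / total)
}
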