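#' Genotype table
#'
#' The central container of the package: a tibble with one row per variant
#' site and a matrix column `dosage` holding per-sample alternate-allele
#' dosages. Columns:
#'
#' * `chrom`, `pos` — contig and 1-based position (as printed in a VCF).
#' * `ref`, `alt` — allele strings; multiple alternate alleles are
#'   comma-separated in `alt`.
#' * `qual` — per-site quality score (VCF QUAL).
#' * `biallelic` — `TRUE` iff the site has exactly one alternate allele and
#'   both alleles are single bases (a biallelic SNP).
#' * `dosage` — integer matrix (sites x samples, `NA` = missing call);
#'   column names are the sample ids.
#'
#' Chromosome lengths, when known (VCF contig headers or simulation
#' configuration), are kept in the `contigs` attribute as a tibble with
#' columns `chrom` and `length`.
#'
#' @param sites Tibble with columns `chrom`, `pos`, `ref`, `alt`, `qual`.
#' @param dosage Integer matrix, rows matching `sites`, named columns.
#' @param contigs Optional tibble with columns `chrom`, `length`.
#' @return A `geno_tbl` (subclass of tibble).
#' @export
geno_tbl <- function(sites, dosage, contigs = NULL) {
  stopifnot(is.data.frame(sites), is.matrix(dosage),
            nrow(sites) == nrow(dosage))
  if (is.null(colnames(dosage)) && ncol(dosage) > 0) {
    stop("dosage matrix must have sample ids as column names")
  }
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  if (any(sites$pos < 1)) stop("positions are 1-based and must be >= 1")
  sites <- tibble::as_tibble(sites)
  alt_split <- strsplit(as.character(sites$alt), ",", fixed = TRUE)
  n_alt <- lengths(alt_split)
  single_base <- nchar(sites$ref) == 1L &
    vapply(alt_split, function(a) all(nchar(a) == 1L), logical(1))
  sites$biallelic <- n_alt == 1L & single_base
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  storage.mode(dosage) <- "integer"
  sites$dosage <- dosage[ord, , drop = FALSE]
  structure(sites,
            contigs = contigs,
            class = c("geno_tbl", class(tibble::tibble())))
}

#' @export
print.geno_tbl <- function(x, ...) {
  cat(sprintf("# Genotype table: %d sites x %d samples\n",
              nrow(x), length(sample_ids(x))))
  NextMethod()
}

#' Sample ids of a genotype table
#' @param gm A [geno_tbl()].
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(gm) colnames(gm$dosage)

#' Contig lengths of a genotype table
#'
#' Returns the `contigs` attribute when present, otherwise infers each
#' contig's length as the largest observed position.
#' @param gm A [geno_tbl()].
#' @return Tibble with columns `chrom`, `length`.
#' @export
contig_lengths <- function(gm) {
  ct <- attr(gm, "contigs")
  if (!is.null(ct) && nrow(ct) > 0 && !anyNA(ct$length)) {
    return(tibble::as_tibble(ct))
  }
  dplyr::summarise(tibble::as_tibble(gm[, c("chrom", "pos")]),
                   length = max(.data$pos), .by = "chrom")
}

# Row-subset a geno_tbl keeping class and attributes.
subset_sites <- function(gm, keep) {
  out <- gm[keep, , drop = FALSE]
  attr(out, "contigs") <- attr(gm, "contigs")
  class(out) <- class(gm)
  out
}

# Column-subset (samples), preserving order requested.
subset_samples <- function(gm, samples) {
  missing <- setdiff(samples, sample_ids(gm))
  if (length(missing)) {
    stop("unknown sample id(s): ", paste(missing, collapse = ", "))
  }
  gm$dosage <- gm$dosage[, samples, drop = FALSE]
  gm
}
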