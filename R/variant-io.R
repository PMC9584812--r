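#' Read a VCF into a genotype table
#'
#' Parses a VCF (plain or gzipped) with `vcfR` and converts GT calls to
#' alternate-allele dosages. Phasing is ignored (`0|1` and `0/1` both give
#' dosage 1); any allele `.` marks the call missing. Multi-allelic and
#' non-SNP records are retained but flagged `biallelic = FALSE`; for them
#' the dosage counts non-reference alleles. Contig lengths are taken from
#' `##contig` header lines when present.
#'
#' @param path Path to a VCF file with a GT FORMAT field.
#' @param samples Optional character vector restricting (and ordering) the
#'   sample columns.
#' @return A [geno_tbl()].
#' @export
read_vcf <- function(path, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  contigs <- parse_contig_headers(v@meta)
  if (nrow(fix) == 0) {
    hdr <- unlist(strsplit(v@meta[length(v@meta)], "\t"))
    ids <- if (ncol(v@gt) > 1) colnames(v@gt)[-1] else character()
    if (!is.null(samples)) ids <- samples
    return(geno_tbl(tibble::tibble(chrom = character(), pos = integer(),
                                   ref = character(), alt = character(),
                                   qual = double()),
                    matrix(integer(), 0, length(ids),
                           dimnames = list(NULL, ids)),
                    contigs = contigs))
  }
  if (!"FORMAT" %in% colnames(v@gt) ||
      !all(grepl("GT", v@gt[, "FORMAT"]))) {
    stop("VCF records lack a GT FORMAT field: ", path)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(gt))
    if (length(missing)) stop("samples not in VCF: ",
                              paste(missing, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  }
  dos <- gt_to_dosage(gt)
  sites <- tibble::tibble(chrom = fix[, "CHROM"],
                          pos = as.integer(fix[, "POS"]),
                          ref = fix[, "REF"],
                          alt = ifelse(is.na(fix[, "ALT"]), ".", fix[, "ALT"]),
                          qual = suppressWarnings(as.numeric(fix[, "QUAL"])))
  geno_tbl(sites, dos, contigs = contigs)
}

parse_contig_headers <- function(meta) {
  ln <- grep("^##contig=", meta, value = TRUE)
  if (!length(ln)) return(NULL)
  id <- sub(".*ID=([^,>]+).*", "\\1", ln)
  len <- ifelse(grepl("length=", ln),
                as.numeric(sub(".*length=([0-9]+).*", "\\1", ln)), NA_real_)
  tibble::tibble(chrom = id, length = len)
}

# GT strings -> dosage; vectorised over the (few) unique GT values.
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  map <- vapply(u, function(g) {
    if (is.na(g)) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles != "0")
  }, integer(1))
  dos <- map[match(as.vector(gt), u)]
  matrix(as.integer(dos), nrow = nrow(gt),
         dimnames = list(NULL, colnames(gt)))
}

#' Write a genotype table as a VCF
#'
#' Emits a minimal standards-conformant VCF 4.2: contig headers, per-site
#' QUAL, and unphased GT calls (`0/0`, `0/1`, `1/1`, `./.`). Reading the
#' file back with [read_vcf()] reproduces the dosage matrix exactly.
#'
#' @param gm A [geno_tbl()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(gm, path) {
  ct <- contig_lengths(gm)
  if (nrow(gm) == 0 && is.null(attr(gm, "contigs"))) {
    ct <- tibble::tibble(chrom = character(), length = double())
  }
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", ct$chrom,
                   as.integer(ct$length)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_ids(gm)), collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  body <- character(nrow(gm))
  if (nrow(gm) > 0) {
    dos <- gm$dosage
    gt <- matrix(gt_code[dos + 1L], nrow = nrow(dos))
    gt[is.na(dos)] <- "./."
    body <- paste(gm$chrom, gm$pos, ".", gm$ref, gm$alt,
                  format(gm$qual, trim = TRUE, digits = 10), "PASS", ".",
                  "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    if (length(sample_ids(gm)) == 0) {
      body <- paste(gm$chrom, gm$pos, ".", gm$ref, gm$alt,
                    format(gm$qual, trim = TRUE, digits = 10), "PASS", ".",
                    sep = "\t")
    }
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a population map
#'
#' Tab-separated file mapping samples to populations, with an optional
#' third column giving the population role (`P1`, `P2`, `P3`, `hybrid`,
#' `outgroup`).
#'
#' @param path TSV path. A header line is detected and honoured.
#' @return Tibble with columns `sample`, `population`, `role`.
#' @export
read_population_map <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("^sample\\b", first)
  pm <- readr::read_tsv(path, col_names = has_header, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  if (!has_header) {
    names(pm)[1:2] <- c("sample", "population")
    if (ncol(pm) >= 3) names(pm)[3] <- "role"
  }
  if (!all(c("sample", "population") %in% names(pm))) {
    stop("population map needs columns sample, population: ", path)
  }
  if (!"role" %in% names(pm)) pm$role <- NA_character_
  if (anyDuplicated(pm$sample)) stop("duplicate sample ids in ", path)
  tibble::as_tibble(pm[, c("sample", "population", "role")])
}

#' Read protein-coding genes from a GFF3 annotation
#'
#' Keeps `gene` features; when the attributes carry a `gene_biotype` (or
#' `biotype`) key, only `protein_coding` genes are returned. Coordinates
#' are converted from GFF 1-based closed to 0-based half-open spans.
#'
#' @param path GFF3 path.
#' @return Tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`start`/`end` 0-based half-open).
#' @export
read_gff_genes <- function(path) {
  g <- ape::read.gff(path, na.strings = c(".", "?"), GFF3 = TRUE)
  g <- g[g$type == "gene", , drop = FALSE]
  attr_get <- function(attrs, key) {
    found <- grepl(paste0("(^|;)\\s*", key, "="), attrs)
    val <- rep(NA_character_, length(attrs))
    val[found] <- sub(paste0(".*(^|;)\\s*", key, "=([^;]+).*"), "\\2",
                      attrs[found])
    val
  }
  biotype <- attr_get(g$attributes, "gene_biotype")
  alt_bio <- attr_get(g$attributes, "biotype")
  biotype[is.na(biotype)] <- alt_bio[is.na(biotype)]
  if (any(!is.na(biotype))) {
    g <- g[is.na(biotype) | biotype == "protein_coding", , drop = FALSE]
  }
  id <- sub(".*(^|;)\\s*ID=([^;]+).*", "\\2", g$attributes)
  no_id <- !grepl("(^|;)\\s*ID=", g$attributes)
  id[no_id] <- paste0("gene_", seq_len(nrow(g)))[no_id]
  tibble::tibble(gene_id = id, chrom = as.character(g$seqid),
                 start = g$start - 1L, end = g$end,
                 strand = as.character(g$strand))
}

#' Read a BED file of genomic intervals
#'
#' BED is already 0-based half-open; coordinates are passed through.
#'
#' @param path BED path (3+ columns, no header).
#' @return Tibble with columns `chrom`, `start`, `end` (plus `name` when a
#'   fourth column exists). Empty files give an empty tibble.
#' @export
read_bed <- function(path) {
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer())
  if (file.size(path) == 0) return(empty)
  b <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       comment = "#")
  if (nrow(b) == 0) return(empty)
  names(b)[1:3] <- c("chrom", "start", "end")
  if (ncol(b) >= 4) names(b)[4] <- "name"
  tibble::as_tibble(b)
}

#' Read newline-delimited newick trees
#'
#' @param path File with one newick tree per line (e.g. per-window trees).
#' @return A list of `phylo` objects (`ape::multiPhylo`).
#' @export
read_window_trees <- function(path) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "phylo")) tr <- structure(list(tr), class = "multiPhylo")
  tr
}

#' Derive a tip-to-group mapping from suffixed tip labels
#'
#' Many window-tree files encode the group in the tip label (e.g.
#' `sample12_welsh`). This extracts the suffix after the last separator as
#' the group, in the named-vector form [weight_tree()] accepts.
#'
#' @param tips Character vector of tip labels.
#' @param sep Separator character (default `"_"`).
#' @return Named character vector `tip -> group`.
#' @export
tip_groups <- function(tips, sep = "_") {
  grp <- sub(paste0(".*\\", sep), "", tips)
  if (any(grp == tips)) {
    stop("tip label(s) without a group suffix: ",
         paste(tips[grp == tips], collapse = ", "))
  }
  stats::setNames(grp, tips)
}
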