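# Point-in-interval containment for 0-based half-open spans: a 1-based
# site position `pos` falls in [start, end) iff start <= pos - 1 < end.
point_in <- function(pos, start, end) (pos - 1) >= start & (pos - 1) < end

#' Retain scan windows containing outlier positions
#'
#' Filters window spans (0-based half-open) down to those containing at
#' least one outlier site (1-based positions), and annotates each outlier
#' with its containing window. An outlier exactly at a window's start
#' coordinate is contained; one at its end coordinate is not.
#'
#' @param windows Tibble with `chrom`, `start`, `end` (e.g. from
#'   [top_percentile_windows()]).
#' @param outliers Tibble with `chrom`, `pos` (e.g. from [fst_outliers()]).
#' @return List with `windows` (retained rows plus `window_id` and
#'   `n_outliers`) and `outliers` (contained outliers plus `window_id`).
#' @export
intersect_outliers_windows <- function(windows, outliers) {
  windows <- dplyr::mutate(windows, window_id = dplyr::row_number())
  hits <- purrr::map_dfr(seq_len(nrow(outliers)), function(i) {
    w <- windows[windows$chrom == outliers$chrom[i] &
                   point_in(outliers$pos[i], windows$start, windows$end), ,
                 drop = FALSE]
    if (!nrow(w)) return(NULL)
    dplyr::mutate(outliers[i, , drop = FALSE],
                  window_id = list(w$window_id))
  })
  if (nrow(hits) == 0) {
    return(list(windows = windows[0, , drop = FALSE],
                outliers = dplyr::mutate(outliers[0, , drop = FALSE],
                                         window_id = list())))
  }
  contained <- unique(unlist(hits$window_id))
  counts <- table(unlist(hits$window_id))
  windows <- windows[windows$window_id %in% contained, , drop = FALSE]
  windows$n_outliers <- as.integer(counts[as.character(windows$window_id)])
  list(windows = windows, outliers = hits)
}

#' Merge overlapping or adjacent windows into maximal regions
#'
#' Half-open spans on the same chromosome are merged when they overlap or
#' share a boundary coordinate (gap tolerance `gap`, default 0).
#'
#' @param windows Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param gap Maximum gap (bp) across which windows are still merged.
#' @return Tibble with `chrom`, `start`, `end`, `span`, `n_windows` and
#'   `window_id` (list column of merged source rows, when present).
#' @export
merge_windows <- function(windows, gap = 0) {
  if (!nrow(windows)) {
    return(tibble::tibble(chrom = character(), start = double(),
                          end = double(), span = double(),
                          n_windows = integer(), window_id = list()))
  }
  if (!"window_id" %in% names(windows)) {
    windows$window_id <- seq_len(nrow(windows))
  }
  windows <- dplyr::arrange(windows, .data$chrom, .data$start, .data$end)
  out <- list()
  cur <- NULL
  flush <- function(cur) tibble::tibble(
    chrom = cur$chrom, start = cur$start, end = cur$end,
    span = cur$end - cur$start, n_windows = length(cur$ids),
    window_id = list(cur$ids))
  for (i in seq_len(nrow(windows))) {
    r <- windows[i, ]
    if (!is.null(cur) && r$chrom == cur$chrom && r$start <= cur$end + gap) {
      cur$end <- max(cur$end, r$end)
      cur$ids <- c(cur$ids, r$window_id)
    } else {
      if (!is.null(cur)) out[[length(out) + 1]] <- flush(cur)
      cur <- list(chrom = r$chrom, start = r$start, end = r$end,
                  ids = r$window_id)
    }
  }
  out[[length(out) + 1]] <- flush(cur)
  dplyr::bind_rows(out)
}

#' Candidate genes in introgressed, differentiated regions
#'
#' Produces the per-scaffold candidate report: for each merged region, the
#' number of source windows, total span, contained outlier count, and the
#' protein-coding genes implicated. By default (`mode = "gene-in-outlier"`)
#' a gene is a candidate only when it overlaps a merged region *and* at
#' least one contained outlier position falls inside the gene span — a gene
#' merely inside an introgressed window, with the nearest outlier outside
#' it, does not count. `mode = "gene-in-window"` relaxes this to any
#' region-overlapping gene, reporting the signed distance to the nearest
#' contained outlier.
#'
#' @param regions Merged regions from [merge_windows()].
#' @param outliers Outlier positions contained in the source windows
#'   (tibble with `chrom`, `pos`).
#' @param genes Gene annotation tibble from [read_gff_genes()] (0-based
#'   half-open `start`, `end`).
#' @param mode `"gene-in-outlier"` (default) or `"gene-in-window"`.
#' @return List with `report` (per-chromosome tibble: `chrom`, `n_windows`,
#'   `span`, `n_outliers`, `n_genes`, `genes`) and `genes` (per-gene rows
#'   with the region coordinates and nearest-outlier distance, 0 when an
#'   outlier lies inside the gene).
#' @export
genes_in_candidates <- function(regions, outliers, genes,
                                mode = c("gene-in-outlier",
                                         "gene-in-window")) {
  mode <- match.arg(mode)
  overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
  gene_rows <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    g <- genes[genes$chrom == r$chrom &
                 overlap(genes$start, genes$end, r$start, r$end), ,
               drop = FALSE]
    if (!nrow(g)) return(NULL)
    o <- outliers[outliers$chrom == r$chrom &
                    point_in(outliers$pos, r$start, r$end), , drop = FALSE]
    dist <- vapply(seq_len(nrow(g)), function(j) {
      if (!nrow(o)) return(NA_real_)
      q <- o$pos - 1
      inside <- q >= g$start[j] & q < g$end[j]
      if (any(inside)) return(0)
      # positive: outlier past the gene end; negative: before its start
      signed <- ifelse(q >= g$end[j], q - g$end[j] + 1, q - g$start[j])
      signed[which.min(abs(signed))]
    }, double(1))
    dplyr::mutate(g, region_start = r$start, region_end = r$end,
                  nearest_outlier_distance = dist)
  })
  if (mode == "gene-in-outlier" && nrow(gene_rows)) {
    gene_rows <- gene_rows[!is.na(gene_rows$nearest_outlier_distance) &
                             gene_rows$nearest_outlier_distance == 0, ,
                           drop = FALSE]
  }
  report <- dplyr::summarise(
    regions,
    n_windows = sum(.data$n_windows),
    span = sum(.data$span),
    .by = "chrom")
  report$n_outliers <- vapply(report$chrom, function(ch) {
    rs <- regions[regions$chrom == ch, , drop = FALSE]
    sum(vapply(seq_len(nrow(rs)), function(i) {
      sum(outliers$chrom == ch &
            point_in(outliers$pos, rs$start[i], rs$end[i]))
    }, double(1)))
  }, double(1), USE.NAMES = FALSE) |> as.integer()
  report$n_genes <- vapply(report$chrom, function(ch) {
    sum(gene_rows$chrom == ch)
  }, integer(1), USE.NAMES = FALSE)
  report$genes <- vapply(report$chrom, function(ch) {
    paste(gene_rows$gene_id[gene_rows$chrom == ch], collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  list(report = report, genes = gene_rows)
}

#' End-to-end adaptive-introgression candidate detection
#'
#' Chains [top_percentile_windows()], [fst_outliers()],
#' [intersect_outliers_windows()], [merge_windows()] and
#' [genes_in_candidates()].
#'
#' @param window_stats Tibble from [scan_windows()].
#' @param fst_records Tibble from [per_site_fst()].
#' @param genes Tibble from [read_gff_genes()].
#' @param pct Upper percentile for both the window and outlier selections.
#' @param ... Passed to [genes_in_candidates()].
#' @return List: `top_windows`, `outliers`, `regions`, `report`, `genes`.
#' @export
adaptive_candidates <- function(window_stats, fst_records, genes, pct = 1,
                                ...) {
  top <- top_percentile_windows(window_stats, pct = pct)
  out <- fst_outliers(fst_records, pct = pct)
  ix <- intersect_outliers_windows(top, out)
  regions <- merge_windows(ix$windows)
  gc <- genes_in_candidates(regions, ix$outliers, genes, ...)
  list(top_windows = top, outliers = ix$outliers, regions = regions,
       report = gc$report, genes = gc$genes)
}
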