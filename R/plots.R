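#' Plot a windowed admixture scan along the genome
#'
#' @param stats Tibble from [scan_windows()].
#' @param statistic Column to plot (`"f_dM"` by default).
#' @param highlight Optional tibble of windows (e.g. from
#'   [top_percentile_windows()]) drawn in red.
#' @return A ggplot object.
#' @export
plot_window_scan <- function(stats, statistic = "f_dM", highlight = NULL) {
  mid <- (stats$start + stats$end) / 2
  p <- ggplot2::ggplot(dplyr::mutate(stats, mid = mid),
                       ggplot2::aes(x = .data$mid,
                                    y = .data[[statistic]])) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "window midpoint (bp)", y = statistic)
  if (!is.null(highlight) && nrow(highlight)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::mutate(highlight,
                           mid = (.data$start + .data$end) / 2),
      colour = "red")
  }
  p
}

#' Plot per-sample hybrid indices
#'
#' Stacked ancestry fractions per sample, optionally grouped by region.
#'
#' @param results Tibble from [hybrid_index()].
#' @param metadata Optional tibble with `sample`, `region` for faceting.
#' @return A ggplot object.
#' @export
plot_hybrid_index <- function(results, metadata = NULL) {
  long <- tidyr::pivot_longer(results, c("frac_a", "frac_b"),
                              names_to = "panel", values_to = "fraction")
  if (!is.null(metadata)) {
    long <- dplyr::left_join(long, metadata[, c("sample", "region")],
                             by = "sample")
  }
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$sample,
                                          y = .data$fraction,
                                          fill = .data$panel)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "ancestry fraction") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  if (!is.null(metadata)) {
    p <- p + ggplot2::facet_grid(~region, scales = "free_x",
                                 space = "free_x")
  }
  p
}

#' Plot topology weights across windows
#'
#' @param weights Tibble from [topology_weights()].
#' @param top_n Plot only the `top_n` topologies with the largest mean
#'   weight (default all).
#' @return A ggplot object.
#' @export
plot_topology_weights <- function(weights, top_n = NULL) {
  id_cols <- intersect(names(weights), c("window", "chrom", "start", "end"))
  long <- tidyr::pivot_longer(weights, -dplyr::all_of(id_cols),
                              names_to = "topology", values_to = "weight")
  if (!is.null(top_n)) {
    keep <- long |>
      dplyr::summarise(m = mean(.data$weight), .by = "topology") |>
      dplyr::arrange(dplyr::desc(.data$m)) |>
      utils::head(top_n)
    long <- dplyr::semi_join(long, keep, by = "topology")
  }
  x <- if ("start" %in% id_cols) "start" else "window"
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[x]], y = .data$weight,
                                     colour = .data$topology)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = x, y = "topology weight")
}
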