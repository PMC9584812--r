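#' Sliding-window admixture statistics (D, fd, fdM, distance fraction)
#'
#' Tiles the usable sites of each chromosome into windows of `window_snps`
#' SNPs advancing by `step_snps` (trailing windows shorter than
#' `window_snps` are dropped) and computes, per window:
#'
#' * `d` — Patterson's D restricted to the window.
#' * `f_d` — admixture fraction with the dynamic donor `pD = max(p2, p3)`
#'   substituted for both P2 and P3 in the denominator.
#' * `f_dM` — the symmetric extension of `f_d`: the denominator donor is
#'   chosen on the P2 side when `p2 >= p1` and on the P1 side otherwise, so
#'   sharing between P3 and P1 yields negative values and the statistic is
#'   symmetric about zero when there is no introgression.
#' * `d_f` — a distance-fraction estimator,
#'   `sum(dxy(P1,P3) - dxy(P2,P3)) / sum(dxy(P1,P3) - pi(P3))` with
#'   `dxy(X,Y) = pX(1-pY) + pY(1-pX)` and `pi(P3) = 2 p3 (1-p3)`: 1 when P2
#'   equals the donor P3, 0 under the null. Reported for completeness;
#'   window selection uses `f_dM`.
#'
#' A window with a zero denominator gets `NA` for that statistic but is
#' retained. Window genomic spans are `[pos of first SNP - 1, pos of last
#' SNP)` in 0-based half-open coordinates.
#'
#' @param freqs Frequency table from [population_frequencies()].
#' @param p1,p2,p3 Trio population column names (P3 the potential donor).
#' @param outgroup Outgroup column name.
#' @param window_snps Window size in usable SNPs.
#' @param step_snps Step between window starts, in SNPs.
#' @return Tibble with one row per window: `chrom`, `start`, `end`,
#'   `n_snps`, `d`, `f_d`, `f_dM`, `d_f`, `abba`, `baba`.
#' @export
scan_windows <- function(freqs, p1, p2, p3, outgroup, window_snps = 1000,
                         step_snps = 500) {
  stopifnot(window_snps >= 2, step_snps >= 1)
  f1 <- freqs[[p1]]; f2 <- freqs[[p2]]; f3 <- freqs[[p3]]
  fo <- freqs[[outgroup]]
  u <- !(is.na(f1) | is.na(f2) | is.na(f3) | is.na(fo))
  fr <- tibble::tibble(chrom = freqs$chrom[u], pos = freqs$pos[u],
                       p1 = f1[u], p2 = f2[u], p3 = f3[u], po = fo[u])
  num <- abba_mass(fr$p1, fr$p2, fr$p3, fr$po) -
    baba_mass(fr$p1, fr$p2, fr$p3, fr$po)
  hom <- abba_mass(fr$p1, fr$p2, fr$p3, fr$po) +
    baba_mass(fr$p1, fr$p2, fr$p3, fr$po)
  pd <- pmax(fr$p2, fr$p3)
  den_fd <- abba_mass(fr$p1, pd, pd, fr$po) - baba_mass(fr$p1, pd, pd, fr$po)
  # dynamic fdM denominator: donor on the P2 side when p2 >= p1, else the
  # mirrored (negated) form on the P1 side, so den >= |num| per site and
  # the window ratio is bounded in [-1, 1].
  pd1 <- pmax(fr$p1, fr$p3)
  den_fdm <- ifelse(fr$p2 >= fr$p1,
                    den_fd,
                    -(abba_mass(pd1, fr$p2, pd1, fr$po) -
                        baba_mass(pd1, fr$p2, pd1, fr$po)))
  dxy <- function(x, y) x * (1 - y) + y * (1 - x)
  df_num <- dxy(fr$p1, fr$p3) - dxy(fr$p2, fr$p3)
  df_den <- dxy(fr$p1, fr$p3) - 2 * fr$p3 * (1 - fr$p3)
  ratio_or_na <- function(a, b) if (b == 0) NA_real_ else a / b
  out <- list()
  for (ch in unique(fr$chrom)) {
    idx <- which(fr$chrom == ch)
    n <- length(idx)
    if (n < window_snps) next
    starts <- seq(1L, n - window_snps + 1L, by = step_snps)
    for (s in starts) {
      w <- idx[s:(s + window_snps - 1L)]
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = ch,
        start = fr$pos[w[1]] - 1L,
        end = fr$pos[w[length(w)]],
        n_snps = length(w),
        d = ratio_or_na(sum(num[w]), sum(hom[w])),
        f_d = ratio_or_na(sum(num[w]), sum(den_fd[w])),
        f_dM = ratio_or_na(sum(num[w]), sum(den_fdm[w])),
        d_f = ratio_or_na(sum(df_num[w]), sum(df_den[w])),
        abba = sum(abba_mass(fr$p1[w], fr$p2[w], fr$p3[w], fr$po[w])),
        baba = sum(baba_mass(fr$p1[w], fr$p2[w], fr$p3[w], fr$po[w])))
    }
  }
  if (!length(out)) stop("fewer usable sites than one window")
  dplyr::bind_rows(out)
}

# Nearest-rank upper-tail selection shared by window and Fst outliers:
# keep the k = ceiling(n * pct / 100) largest defined values, ties
# included.
top_tail <- function(values, pct) {
  defined <- which(!is.na(values))
  if (!length(defined)) stop("all values undefined")
  k <- max(1L, ceiling(length(defined) * pct / 100))
  thr <- sort(values[defined], decreasing = TRUE)[k]
  !is.na(values) & values >= thr
}

#' Top-percentile windows of an admixture scan
#'
#' Selects the windows whose statistic falls in the upper `pct` percent
#' (nearest-rank: the `ceiling(n * pct / 100)` largest defined values, ties
#' included), optionally restricted to positive values as is usual when the
#' statistic's sign encodes the direction of sharing.
#'
#' @param stats Window tibble from [scan_windows()].
#' @param statistic Column to rank on (default `f_dM`).
#' @param pct Upper percentile, in percent.
#' @param positive_only Drop non-positive values?
#' @return The selected rows of `stats`.
#' @export
top_percentile_windows <- function(stats, statistic = "f_dM", pct = 1,
                                   positive_only = TRUE) {
  stopifnot(nrow(stats) > 0, statistic %in% names(stats))
  keep <- top_tail(stats[[statistic]], pct)
  if (positive_only) keep <- keep & !is.na(stats[[statistic]]) &
      stats[[statistic]] > 0
  stats[keep, , drop = FALSE]
}
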