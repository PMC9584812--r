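#' Windowed nucleotide diversity
#'
#' Per-site diversity is `pi_i = 2 * n_ref * n_alt / (n * (n - 1))` over
#' the population's called allele counts (`n` alleles; sites with fewer
#' than 2 called alleles are skipped). Windows of `window_bp` tile each
#' chromosome from position 0 without overlap; a window's diversity is the
#' sum of its per-site values divided by the window's span in bp, so
#' invariant positions dilute the estimate as in whole-genome practice.
#' The trailing partial window is included with its true span. Chromosome
#' lengths come from [contig_lengths()].
#'
#' @param gm A [geno_tbl()] of biallelic sites.
#' @param popmap Population map tibble.
#' @param population Population to summarise.
#' @param window_bp Window span in base pairs (default 100 kb).
#' @return Tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   `n_snps`, `pi`; the mean over windows is in the `mean_pi` attribute.
#' @export
windowed_pi <- function(gm, popmap, population, window_bp = 100000) {
  ids <- intersect(popmap$sample[popmap$population == population],
                   sample_ids(gm))
  if (!length(ids)) stop("population has no samples: ", population)
  d <- gm$dosage[, ids, drop = FALSE]
  n_alt <- rowSums(d, na.rm = TRUE)
  n_all <- 2 * rowSums(!is.na(d))
  pi_site <- ifelse(n_all >= 2,
                    2 * (n_all - n_alt) * n_alt / (n_all * (n_all - 1)), 0)
  ct <- contig_lengths(gm)
  out <- purrr::map_dfr(seq_len(nrow(ct)), function(i) {
    ch <- ct$chrom[i]
    len <- ct$length[i]
    starts <- seq(0, max(0, len - 1), by = window_bp)
    ends <- pmin(starts + window_bp, len)
    on_ch <- gm$chrom == ch
    idx <- findInterval(gm$pos[on_ch] - 1L, starts)
    tibble::tibble(chrom = ch, start = starts, end = ends,
                   n_snps = tabulate(idx, nbins = length(starts)),
                   pi = as.vector(tapply(pi_site[on_ch], factor(idx,
                        levels = seq_along(starts)), sum, default = 0)) /
                     (ends - starts))
  })
  out$pi[is.na(out$pi)] <- 0
  attr(out, "mean_pi") <- mean(out$pi)
  out
}

#' Mean nucleotide diversity per population
#'
#' Convenience wrapper over [windowed_pi()] for every population in the
#' map: the population summary is the mean of the window values.
#'
#' @inheritParams windowed_pi
#' @param populations Populations to include (default: all).
#' @return Tibble with columns `population`, `n_samples`, `n_windows`,
#'   `mean_pi`, sorted by `mean_pi`.
#' @export
pi_summary <- function(gm, popmap, populations = NULL,
                       window_bp = 100000) {
  if (is.null(populations)) populations <- unique(popmap$population)
  purrr::map_dfr(populations, function(p) {
    w <- windowed_pi(gm, popmap, p, window_bp)
    tibble::tibble(population = p,
                   n_samples = sum(popmap$population == p &
                                     popmap$sample %in% sample_ids(gm)),
                   n_windows = nrow(w), mean_pi = attr(w, "mean_pi"))
  }) |> dplyr::arrange(.data$mean_pi)
}

#' Per-site two-population Fst
#'
#' Weir & Cockerham's (1984) variance-components estimator
#' `theta = a / (a + b + c)` from the two populations' allele frequencies,
#' sample sizes and observed heterozygote proportions at each site
#' (missing calls excluded). Negative estimates are reported as-is;
#' sites with a zero denominator are `NA`. A Hudson-style estimator
#' (`1 - Hw/Hb`) is available for robustness comparisons.
#'
#' @param gm A [geno_tbl()] of biallelic sites.
#' @param popmap Population map tibble.
#' @param pop_a,pop_b The two populations (each needs >= 2 samples).
#' @param estimator `"wc"` (Weir-Cockerham, default) or `"hudson"`.
#' @return Tibble with columns `chrom`, `pos`, `fst`.
#' @export
per_site_fst <- function(gm, popmap, pop_a, pop_b,
                         estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  ids <- lapply(c(pop_a, pop_b), function(p) {
    out <- intersect(popmap$sample[popmap$population == p], sample_ids(gm))
    if (length(out) < 2) stop("population needs >= 2 samples: ", p)
    out
  })
  stats_of <- function(id) {
    d <- gm$dosage[, id, drop = FALSE]
    n <- rowSums(!is.na(d))                    # diploid individuals called
    p <- rowSums(d, na.rm = TRUE) / (2 * n)
    h <- rowSums(d == 1L, na.rm = TRUE) / n    # observed het proportion
    list(n = n, p = p, h = h)
  }
  s1 <- stats_of(ids[[1]]); s2 <- stats_of(ids[[2]])
  ok <- s1$n >= 1 & s2$n >= 1
  fst <- rep(NA_real_, nrow(gm))
  if (estimator == "wc") {
    r <- 2
    n1 <- s1$n[ok]; n2 <- s2$n[ok]
    p1 <- s1$p[ok]; p2 <- s2$p[ok]
    h1 <- s1$h[ok]; h2 <- s2$h[ok]
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2v <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- nbar / nc * (s2v - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2v - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2v -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    denom <- a + b + cc
    v <- ifelse(denom == 0, NA_real_, a / denom)
  } else {
    p1 <- s1$p[ok]; p2 <- s2$p[ok]
    n1 <- 2 * s1$n[ok]; n2 <- 2 * s2$n[ok]
    hw <- (p1 * (1 - p1) * n1 / (n1 - 1) + p2 * (1 - p2) * n2 / (n2 - 1)) / 2
    hb <- p1 * (1 - p2) + p2 * (1 - p1)
    v <- ifelse(hb == 0, NA_real_, 1 - hw / hb)
  }
  fst[ok] <- v
  tibble::tibble(chrom = gm$chrom, pos = gm$pos, fst = fst)
}

#' Top-percentile Fst outlier sites
#'
#' Nearest-rank upper-tail selection over the defined Fst values (the
#' `ceiling(n * pct / 100)` largest, ties at the threshold included);
#' undefined (`NA`) sites never rank.
#'
#' @param records Tibble from [per_site_fst()].
#' @param pct Upper percentile, in percent.
#' @return The outlier rows of `records`.
#' @export
fst_outliers <- function(records, pct = 1) {
  records[top_tail(records$fst, pct), , drop = FALSE]
}
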