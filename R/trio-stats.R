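#' Per-population alternate-allele frequencies
#'
#' Frequency = alternate allele count / called allele count, computed from
#' non-missing calls only. A population with zero called alleles at a site
#' yields `NA` there; downstream statistics treat a site as usable only
#' when every population they need is non-missing.
#'
#' @param gm A [geno_tbl()] (biallelic sites recommended).
#' @param popmap Tibble with columns `sample`, `population` (see
#'   [read_population_map()]).
#' @param populations Populations to tabulate (default: all in `popmap`).
#' @return Tibble with `chrom`, `pos` and one frequency column per
#'   population.
#' @export
population_frequencies <- function(gm, popmap, populations = NULL) {
  if (is.null(populations)) populations <- unique(popmap$population)
  out <- tibble::tibble(chrom = gm$chrom, pos = gm$pos)
  for (p in populations) {
    ids <- intersect(popmap$sample[popmap$population == p], sample_ids(gm))
    if (!length(ids)) stop("population has no samples in the data: ", p)
    d <- gm$dosage[, ids, drop = FALSE]
    called <- 2 * rowSums(!is.na(d))
    f <- rowSums(d, na.rm = TRUE) / called
    f[called == 0] <- NA_real_
    out[[p]] <- f
  }
  out
}

abba_mass <- function(p1, p2, p3, po) (1 - p1) * p2 * p3 * (1 - po)
baba_mass <- function(p1, p2, p3, po) p1 * (1 - p2) * p3 * (1 - po)

# Split n sites into m contiguous blocks of near-equal size.
block_index <- function(n, m) {
  m <- max(1L, min(m, n))
  sort(rep_len(seq_len(m), n))
}

#' Patterson's D for one oriented population trio
#'
#' Computes the ABBA-BABA D statistic from population allele frequencies:
#' per usable site `ABBA = (1-p1) p2 p3 (1-pO)` and
#' `BABA = p1 (1-p2) p3 (1-pO)`, with
#' `D = sum(ABBA - BABA) / sum(ABBA + BABA)`. Polymorphic outgroup sites
#' are retained with the `(1 - pO)` weighting. Significance comes from a
#' delete-one block jackknife over `n_blocks` contiguous site blocks; the
#' reported p-value is one-tailed.
#'
#' With `orient = TRUE` (the presentation convention) P1 and P2 are swapped
#' if needed so that D >= 0; because that choice looks at the data, use
#' `orient = FALSE` (signed D for the trio as given) when testing a
#' pre-specified gene-flow direction at a nominal level.
#'
#' @param freqs Frequency table from [population_frequencies()].
#' @param p1,p2,p3 Population column names forming the trio.
#' @param outgroup Outgroup population column name.
#' @param n_blocks Number of jackknife blocks.
#' @param orient Swap P1/P2 so that D >= 0?
#' @return Object of class `d_stat`; see [tidy.d_stat()].
#' @export
d_statistic <- function(freqs, p1, p2, p3, outgroup, n_blocks = 20,
                        orient = TRUE) {
  f1 <- freqs[[p1]]; f2 <- freqs[[p2]]; f3 <- freqs[[p3]]
  fo <- freqs[[outgroup]]
  usable <- !(is.na(f1) | is.na(f2) | is.na(f3) | is.na(fo))
  f1 <- f1[usable]; f2 <- f2[usable]; f3 <- f3[usable]; fo <- fo[usable]
  n <- length(f1)
  if (n == 0) stop("no usable sites for trio (", p1, ",", p2, ",", p3, ")")
  abba <- abba_mass(f1, f2, f3, fo)
  baba <- baba_mass(f1, f2, f3, fo)
  denom <- sum(abba) + sum(baba)
  if (denom == 0) stop("D undefined: sum(ABBA + BABA) is zero")
  d <- (sum(abba) - sum(baba)) / denom
  swapped <- FALSE
  if (orient && d < 0) {
    tmp <- p1; p1 <- p2; p2 <- tmp
    tmp <- abba; abba <- baba; baba <- tmp
    d <- -d
    swapped <- TRUE
  }
  blk <- block_index(n, n_blocks)
  m <- max(blk)
  num_b <- vapply(split(abba - baba, blk), sum, double(1))
  den_b <- vapply(split(abba + baba, blk), sum, double(1))
  d_jack <- (sum(num_b) - num_b) / (sum(den_b) - den_b)
  se <- sqrt((m - 1) / m * sum((d_jack - mean(d_jack))^2))
  degenerate <- !is.finite(se) || se == 0
  z <- if (degenerate) NA_real_ else d / se
  p <- if (degenerate) NA_real_ else stats::pnorm(z, lower.tail = FALSE)
  structure(list(p1 = p1, p2 = p2, p3 = p3, outgroup = outgroup,
                 d = d, z = z, p = p, se = se,
                 abba = sum(abba), baba = sum(baba),
                 n_sites = n, n_blocks = m, swapped = swapped,
                 zero_variance = degenerate),
            class = "d_stat")
}

#' @export
print.d_stat <- function(x, ...) {
  cat(sprintf("ABBA-BABA D: (%s, %s; %s | %s)\n", x$p1, x$p2, x$p3,
              x$outgroup))
  cat(sprintf("  D = %.5f  Z = %s  p = %s  (%d sites, %d blocks%s)\n",
              x$d, format(x$z, digits = 4), format(x$p, digits = 4),
              x$n_sites, x$n_blocks,
              if (x$zero_variance) ", zero jackknife variance" else ""))
  invisible(x)
}

#' @rdname d_statistic
#' @param x A `d_stat` object.
#' @param ... Unused.
#' @export
tidy.d_stat <- function(x, ...) {
  tibble::tibble(p1 = x$p1, p2 = x$p2, p3 = x$p3, outgroup = x$outgroup,
                 d = x$d, z = x$z, p = x$p, abba = x$abba, baba = x$baba)
}

#' @rdname d_statistic
#' @export
glance.d_stat <- function(x, ...) {
  tibble::tibble(n_sites = x$n_sites, n_blocks = x$n_blocks,
                 se = x$se, swapped = x$swapped,
                 zero_variance = x$zero_variance)
}

# f4(A,B; C,D) from per-sample dosage columns: mean (pA-pB)(pC-pD).
f4_from_freq <- function(fa, fb, fc, fd) {
  u <- !(is.na(fa) | is.na(fb) | is.na(fc) | is.na(fd))
  mean((fa[u] - fb[u]) * (fc[u] - fd[u]))
}

#' f4-ratio estimate of the admixture proportion
#'
#' Ratio of `f4(P1, P2; P3a, O)` to `f4(P1, P3b; P3a, O)` where the P3
#' samples are randomly halved (seeded) into P3a and P3b. Under a simple
#' admixture model the ratio estimates the fraction of P2's ancestry
#' derived from P3; the estimate can exceed 1 when the model's assumptions
#' fail.
#'
#' @param gm A [geno_tbl()].
#' @param popmap Population map tibble.
#' @param p1,p2,p3 Trio population labels (P3 must have >= 2 samples).
#' @param outgroup Outgroup population label.
#' @param seed Seed for the P3 split.
#' @return Numeric f4-ratio with the split recorded in attributes.
#' @export
f4_ratio <- function(gm, popmap, p1, p2, p3, outgroup, seed = 1) {
  ids3 <- intersect(popmap$sample[popmap$population == p3], sample_ids(gm))
  if (length(ids3) < 2) stop("f4-ratio needs >= 2 samples in P3")
  set.seed(seed)
  a <- sort(sample(ids3, ceiling(length(ids3) / 2)))
  b <- setdiff(ids3, a)
  freq_of <- function(ids) {
    d <- gm$dosage[, ids, drop = FALSE]
    called <- 2 * rowSums(!is.na(d))
    f <- rowSums(d, na.rm = TRUE) / called
    f[called == 0] <- NA_real_
    f
  }
  pf <- population_frequencies(gm, popmap, c(p1, p2, outgroup))
  f3a <- freq_of(a); f3b <- freq_of(b)
  num <- f4_from_freq(pf[[p1]], pf[[p2]], f3a, pf[[outgroup]])
  den <- f4_from_freq(pf[[p1]], f3b, f3a, pf[[outgroup]])
  structure(num / den, p3_half_a = a, p3_half_b = b)
}

#' D statistics and f4-ratios for all population trios
#'
#' Runs [d_statistic()] (oriented so D >= 0) and [f4_ratio()] for every
#' unordered trio of non-outgroup populations against a fixed outgroup,
#' sorted by D descending.
#'
#' @param gm A [geno_tbl()].
#' @param popmap Population map tibble.
#' @param outgroup Outgroup population label.
#' @param n_blocks Jackknife blocks per trio.
#' @param seed Seed for the f4-ratio P3 split.
#' @return Tibble with one row per trio: `p1`, `p2`, `p3`, `d`, `z`, `p`,
#'   `f4_ratio`, `abba`, `baba`, `n_sites`, `n_blocks`.
#' @export
dtrios_all <- function(gm, popmap, outgroup, n_blocks = 20, seed = 1) {
  pops <- setdiff(unique(popmap$population), outgroup)
  pops <- intersect(pops, popmap$population[popmap$sample %in% sample_ids(gm)])
  if (length(pops) < 3) stop("need at least 3 non-outgroup populations")
  freqs <- population_frequencies(gm, popmap, c(pops, outgroup))
  trios <- utils::combn(sort(pops), 3, simplify = FALSE)
  rows <- purrr::map(trios, function(tr) {
    # Arrangement: P3 is the member whose exclusion maximises the BBAA
    # (shared-derived-in-sisters) mass, i.e. P1,P2 are the apparent
    # sisters; P1/P2 are then oriented so D >= 0.
    bbaa <- vapply(1:3, function(k) {
      p3 <- tr[k]; rest <- tr[-k]
      u <- stats::complete.cases(freqs[, c(rest, p3, outgroup)])
      sum(freqs[[rest[1]]][u] * freqs[[rest[2]]][u] *
            (1 - freqs[[p3]][u]) * (1 - freqs[[outgroup]][u]))
    }, double(1))
    k <- which.max(bbaa)
    best <- d_statistic(freqs, tr[-k][1], tr[-k][2], tr[k], outgroup,
                        n_blocks = n_blocks)
    f4 <- tryCatch(
      as.numeric(f4_ratio(gm, popmap, best$p1, best$p2, best$p3, outgroup,
                          seed = seed)),
      error = function(e) NA_real_)
    dplyr::mutate(tidy(best), f4_ratio = f4, n_sites = best$n_sites,
                  n_blocks = best$n_blocks)
  })
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(d))
}
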