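# Site-pattern machinery for the quartet (outgroup, P1, hybrid, P2).
#
# For each site, every group has a probability of showing the derived
# (alternate, "B") allele -- its allele frequency, or dosage/2 for a single
# individual. The mass of a 4-letter pattern such as ABBA is the product
# over taxa of that probability (for "B") or its complement (for "A"), so
# the 16 pattern masses at a site sum to exactly 1 and total pattern mass
# equals the number of usable sites.

pattern_names <- local({
  g <- expand.grid(o = c("A", "B"), p1 = c("A", "B"),
                   h = c("A", "B"), p2 = c("A", "B"),
                   stringsAsFactors = FALSE)
  paste0(g$o, g$p1, g$h, g$p2)
})

pattern_masses <- function(qo, q1, qh, q2) {
  m <- matrix(NA_real_, nrow = length(qo), ncol = 16,
              dimnames = list(NULL, pattern_names))
  probs <- list(qo, q1, qh, q2)
  for (k in seq_len(16)) {
    letters4 <- strsplit(pattern_names[k], "")[[1]]
    col <- rep(1, length(qo))
    for (t in 1:4) {
      col <- col * if (letters4[t] == "B") probs[[t]] else 1 - probs[[t]]
    }
    m[, k] <- col
  }
  m
}

#' Site-pattern masses for a hybridization quartet
#'
#' Tabulates frequency-weighted site-pattern masses for the ordered quartet
#' (outgroup, P1, hybrid, P2). The hybrid taxon is either a population
#' (group allele frequencies) or, when `hybrid_sample` is given, a single
#' individual (dosage / 2). Sites where any of the four taxa is entirely
#' missing are excluded.
#'
#' @param gm A [geno_tbl()] of biallelic sites.
#' @param popmap Population map tibble.
#' @param p1,p2 Parental population labels.
#' @param hybrid Putative hybrid population label (ignored when
#'   `hybrid_sample` is given).
#' @param outgroup Outgroup population label.
#' @param hybrid_sample Optional single sample id to test as the hybrid.
#' @return Object of class `quartet_patterns`: per-site mass matrix
#'   (sites x 16 patterns), totals, labels and usable-site count.
#' @export
quartet_patterns <- function(gm, popmap, p1, hybrid, p2, outgroup,
                             hybrid_sample = NULL) {
  freqs <- population_frequencies(gm, popmap, c(p1, p2, outgroup))
  if (is.null(hybrid_sample)) {
    fh <- population_frequencies(gm, popmap, hybrid)[[hybrid]]
    hybrid_label <- hybrid
  } else {
    if (!hybrid_sample %in% sample_ids(gm)) {
      stop("unknown hybrid sample: ", hybrid_sample)
    }
    fh <- gm$dosage[, hybrid_sample] / 2
    hybrid_label <- hybrid_sample
    if (all(is.na(fh))) {
      stop("hybrid individual has no called genotypes: ", hybrid_sample)
    }
  }
  u <- !(is.na(freqs[[p1]]) | is.na(freqs[[p2]]) |
           is.na(freqs[[outgroup]]) | is.na(fh))
  if (!any(u)) stop("no usable sites for quartet")
  m <- pattern_masses(freqs[[outgroup]][u], freqs[[p1]][u], fh[u],
                      freqs[[p2]][u])
  structure(list(per_site = m, totals = colSums(m), n_sites = sum(u),
                 p1 = p1, hybrid = hybrid_label, p2 = p2,
                 outgroup = outgroup),
            class = "quartet_patterns")
}

#' @export
print.quartet_patterns <- function(x, ...) {
  cat(sprintf("Quartet site patterns (%s; %s, %s, %s): %d usable sites\n",
              x$outgroup, x$p1, x$hybrid, x$p2, x$n_sites))
  print(round(x$totals, 2))
  invisible(x)
}

#' Invariant-based hybridization test with gamma estimation
#'
#' Under the hybrid-speciation model for the quartet (outgroup, P1, H, P2),
#' the two linear pattern-mass invariants `d1 = AABB - ABAB` and
#' `d2 = ABBA - ABAB` have expectations proportional to `gamma` and
#' `1 - gamma` respectively, where `gamma` is the fraction of the hybrid's
#' ancestry contributed by P2 (0.5 for an F1). The estimator is
#' `gamma_hat = sum(d1) / (sum(d1) + sum(d2))`; the test statistic is
#' `Z = mean(d1) / SE(mean(d1))` over sites, which is standard normal when
#' H carries no P2 ancestry, with a one-tailed p-value. Swapping P1 and P2
#' maps `gamma_hat` to `1 - gamma_hat` exactly.
#'
#' Following the usual reporting convention, a result counts as evidence of
#' hybridization only when it is significant *and* `0 < gamma_hat < 1`.
#'
#' @param counts A [quartet_patterns()] object.
#' @param alpha Significance level used for the `significant` flag.
#' @return Object of class `gamma_test` with fields `z`, `p`, `gamma`,
#'   labels, `n_sites`, `significant`, `flagged` (undefined invariant
#'   denominator). See [tidy.gamma_test()].
#' @export
hybrid_test <- function(counts, alpha = 0.05) {
  stopifnot(inherits(counts, "quartet_patterns"))
  m <- counts$per_site
  d1 <- m[, "AABB"] - m[, "ABAB"]
  d2 <- m[, "ABBA"] - m[, "ABAB"]
  s1 <- sum(d1); s2 <- sum(d2)
  n <- counts$n_sites
  flagged <- (s1 + s2) == 0
  gamma <- if (flagged) NA_real_ else s1 / (s1 + s2)
  se <- stats::sd(d1) / sqrt(n)
  z <- if (!is.finite(se) || se == 0) 0 else mean(d1) / se
  p <- stats::pnorm(z, lower.tail = FALSE)
  structure(list(p1 = counts$p1, hybrid = counts$hybrid, p2 = counts$p2,
                 outgroup = counts$outgroup, z = z, p = p, gamma = gamma,
                 n_sites = n, alpha = alpha,
                 significant = !is.na(p) && p < alpha,
                 flagged = flagged),
            class = "gamma_test")
}

#' @export
print.gamma_test <- function(x, ...) {
  cat(sprintf("Hybridization test: P1 = %s, H = %s, P2 = %s (out: %s)\n",
              x$p1, x$hybrid, x$p2, x$outgroup))
  cat(sprintf("  Z = %.3f  p = %.3g  gamma = %.4f  (%d sites)%s\n",
              x$z, x$p, x$gamma, x$n_sites,
              if (x$flagged) "  [undefined invariant denominator]" else ""))
  invisible(x)
}

#' @rdname hybrid_test
#' @param x A `gamma_test` object.
#' @param ... Unused.
#' @export
tidy.gamma_test <- function(x, ...) {
  tibble::tibble(p1 = x$p1, hybrid = x$hybrid, p2 = x$p2, z = x$z, p = x$p,
                 gamma = x$gamma)
}

#' @rdname hybrid_test
#' @export
glance.gamma_test <- function(x, ...) {
  tibble::tibble(n_sites = x$n_sites, alpha = x$alpha,
                 significant = x$significant, flagged = x$flagged)
}

#' Per-individual hybridization tests
#'
#' Fixes the parental populations and the outgroup, then tests each member
#' of the putative hybrid population one at a time (its dosage / 2 standing
#' in for the hybrid allele frequency). Individuals whose callable quartet
#' sites are fewer than half of the population-level usable sites are
#' flagged `low_confidence`.
#'
#' @param gm A [geno_tbl()] of biallelic sites.
#' @param popmap Population map tibble.
#' @param p1,p2 Parental population labels.
#' @param hybrid Hybrid population label whose members are tested.
#' @param outgroup Outgroup population label.
#' @param alpha Significance level.
#' @return Tibble with one row per individual: `p1`, `hybrid`, `p2`, `z`,
#'   `p`, `gamma`, `n_sites`, `significant`, `low_confidence`.
#' @export
individual_tests <- function(gm, popmap, p1, hybrid, p2, outgroup,
                             alpha = 0.05) {
  ids <- intersect(popmap$sample[popmap$population == hybrid],
                   sample_ids(gm))
  if (!length(ids)) stop("hybrid population has no samples: ", hybrid)
  pop_sites <- quartet_patterns(gm, popmap, p1, hybrid, p2, outgroup)$n_sites
  purrr::map_dfr(ids, function(id) {
    qp <- quartet_patterns(gm, popmap, p1, hybrid, p2, outgroup,
                           hybrid_sample = id)
    ht <- hybrid_test(qp, alpha = alpha)
    dplyr::mutate(tidy(ht), n_sites = ht$n_sites,
                  significant = ht$significant,
                  low_confidence = qp$n_sites < 0.5 * pop_sites)
  })
}

#' Test all population arrangements for hybridization
#'
#' Enumerates every directed arrangement (P1, H, P2) over the candidate
#' (non-outgroup) populations -- each unordered trio contributes three
#' arrangements, one per hybrid role, with P1/P2 symmetric -- runs
#' [hybrid_test()] on each, applies a multiple-testing correction, and
#' sorts by p then Z descending.
#'
#' @param gm A [geno_tbl()] of biallelic sites.
#' @param popmap Population map tibble.
#' @param outgroup Outgroup population label.
#' @param alpha Significance level applied to corrected p-values.
#' @param correction Multiple-testing method (any [stats::p.adjust()]
#'   method; `"bonferroni"` by default, `"none"` for raw p filtering).
#' @param filter Keep only significant arrangements with
#'   `0 < gamma_hat < 1` (the reporting convention)? When `FALSE` all
#'   arrangements are returned with a `kept` column.
#' @return Tibble of arrangements: `p1`, `hybrid`, `p2`, `z`, `p`, `p_adj`,
#'   `gamma`, `n_sites`, `kept`.
#' @export
full_search <- function(gm, popmap, outgroup, alpha = 0.05,
                        correction = "bonferroni", filter = TRUE) {
  pops <- sort(setdiff(unique(popmap$population), outgroup))
  if (length(pops) < 3) stop("need at least 3 candidate populations")
  trios <- utils::combn(pops, 3, simplify = FALSE)
  arr <- purrr::map_dfr(trios, function(tr) {
    purrr::map_dfr(1:3, function(k) {
      tibble::tibble(p1 = tr[-k][1], hybrid = tr[k], p2 = tr[-k][2])
    })
  })
  res <- purrr::pmap_dfr(arr, function(p1, hybrid, p2) {
    qp <- quartet_patterns(gm, popmap, p1, hybrid, p2, outgroup)
    ht <- hybrid_test(qp, alpha = alpha)
    dplyr::mutate(tidy(ht), n_sites = ht$n_sites, flagged = ht$flagged)
  })
  res$p_adj <- stats::p.adjust(res$p, method = correction)
  res$kept <- !res$flagged & res$p_adj < alpha &
    !is.na(res$gamma) & res$gamma > 0 & res$gamma < 1
  res <- dplyr::arrange(res, p, dplyr::desc(z))
  res <- dplyr::select(res, -"flagged")
  if (filter) dplyr::filter(res, .data$kept) else res
}
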