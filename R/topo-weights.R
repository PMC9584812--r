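# --- canonical topology keys -------------------------------------------
# Two unrooted trees on the same tip set are topologically identical iff
# they induce the same set of non-trivial bipartitions. The key normalizes
# each split to the side not containing the alphabetically first tip and
# serializes the sorted split set; it is insensitive to rooting, tip
# order and branch lengths.
canon_key <- function(tree) {
  tips <- tree$tip.label
  k <- length(tips)
  ref <- sort(tips)[1]
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (cl in parts) {
    lab <- tips[cl]
    if (ref %in% lab) lab <- setdiff(tips, lab)
    s <- length(lab)
    if (s >= 2 && k - s >= 2) {
      keys <- c(keys, paste(sort(lab), collapse = "+"))
    }
  }
  paste(sort(unique(keys)), collapse = "|")
}

# Non-trivial splits as a character set (used for polytomy compatibility).
split_set <- function(tree) {
  key <- canon_key(tree)
  if (key == "") character(0) else strsplit(key, "|", fixed = TRUE)[[1]]
}

rooted_shapes <- function(labels) {
  if (length(labels) == 1) return(labels)
  out <- character(0)
  rest <- labels[-1]
  for (sz in 0:(length(rest) - 1)) {
    for (pick in utils::combn(seq_along(rest), sz, simplify = FALSE)) {
      a <- c(labels[1], rest[pick])
      b <- if (sz == 0) rest else rest[-pick]
      for (ta in rooted_shapes(a)) {
        for (tb in rooted_shapes(b)) {
          out <- c(out, paste0("(", ta, ",", tb, ")"))
        }
      }
    }
  }
  out
}

#' Enumerate unrooted binary topologies over group labels
#'
#' All `(2k - 5)!!` distinct unrooted bifurcating topologies on `k` labels
#' (15 for five groups), built by recursive subtree combination and
#' identified by canonical split keys.
#'
#' @param groups Character vector of `k >= 3` group labels, or a single
#'   integer `k` (labels then default to `G1 ... Gk`).
#' @return A `topology_set`: tibble with columns `topology` (`T1`, ...),
#'   `newick`, `key`.
#' @export
enumerate_topologies <- function(groups) {
  if (is.numeric(groups) && length(groups) == 1) {
    groups <- paste0("G", seq_len(groups))
  }
  groups <- sort(as.character(groups))
  k <- length(groups)
  if (k < 3) stop("need at least 3 groups")
  newicks <- paste0("(", rooted_shapes(groups[-k]), ",", groups[k], ");")
  keys <- vapply(newicks,
                 function(s) canon_key(ape::read.tree(text = s)),
                 character(1), USE.NAMES = FALSE)
  stopifnot(!anyDuplicated(keys))
  out <- tibble::tibble(topology = paste0("T", seq_along(newicks)),
                        newick = newicks, key = keys)
  structure(out, groups = groups,
            class = c("topology_set", class(out)))
}

normalize_group_map <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("tip", "group") %in% names(groups)))
    return(stats::setNames(as.character(groups$group),
                           as.character(groups$tip)))
  }
  stopifnot(!is.null(names(groups)))
  groups
}

#' Topology weights of one group-labelled tree
#'
#' The weight of a group topology is the fraction of one-tip-per-group
#' subtrees of `tree` that induce it. When the number of combinations
#' (product of group sizes) is at most `max_exact` all combinations are
#' enumerated (weights sum to 1 exactly); otherwise `n_samples` seeded
#' Monte-Carlo draws are used. A combination whose pruned tree is
#' unresolved (input polytomy) is either split equally among the binary
#' topologies compatible with it (`polytomy = "split"`, default) or
#' dropped (`polytomy = "discard"`).
#'
#' @param tree A `phylo` whose tips are assigned to groups.
#' @param topologies A [enumerate_topologies()] result over the group
#'   labels.
#' @param groups Named character vector `tip -> group`, or a tibble with
#'   columns `tip`, `group`. Every tree tip must be mapped and every group
#'   must have at least one tip.
#' @param max_exact Combination-count threshold for exact enumeration.
#' @param n_samples Monte-Carlo draws when above `max_exact`.
#' @param seed Seed for Monte-Carlo sampling.
#' @param polytomy `"split"` or `"discard"`.
#' @return Named numeric vector of weights (one per topology, summing to 1
#'   over used combinations), with attributes `n_combinations` and `exact`.
#' @export
weight_tree <- function(tree, topologies, groups, max_exact = 10000,
                        n_samples = 1000, seed = 1,
                        polytomy = c("split", "discard")) {
  polytomy <- match.arg(polytomy)
  gmap <- normalize_group_map(groups)
  unknown <- setdiff(tree$tip.label, names(gmap))
  if (length(unknown)) {
    stop("tips without a group: ", paste(unknown, collapse = ", "))
  }
  glabels <- attr(topologies, "groups")
  tips_by_group <- lapply(glabels, function(g) {
    t <- intersect(names(gmap)[gmap == g], tree$tip.label)
    if (!length(t)) stop("group has no tips in tree: ", g)
    t
  })
  names(tips_by_group) <- glabels
  n_comb <- prod(lengths(tips_by_group))
  exact <- n_comb <= max_exact
  combos <- if (exact) {
    as.matrix(expand.grid(tips_by_group, stringsAsFactors = FALSE))
  } else {
    set.seed(seed)
    vapply(tips_by_group, function(t) sample(t, n_samples, replace = TRUE),
           character(n_samples))
  }
  cand_splits <- lapply(topologies$newick,
                        function(s) split_set(ape::read.tree(text = s)))
  counts <- stats::setNames(numeric(nrow(topologies)), topologies$topology)
  used <- 0
  for (i in seq_len(nrow(combos))) {
    sub <- ape::keep.tip(tree, combos[i, ])
    sub$tip.label <- unname(gmap[sub$tip.label])
    key <- canon_key(sub)
    hit <- match(key, topologies$key)
    if (!is.na(hit)) {
      counts[hit] <- counts[hit] + 1
      used <- used + 1
    } else if (polytomy == "split") {
      sp <- split_set(sub)
      compat <- vapply(cand_splits, function(cs) all(sp %in% cs), logical(1))
      if (any(compat)) {
        counts[compat] <- counts[compat] + 1 / sum(compat)
        used <- used + 1
      }
    }
  }
  if (used == 0) stop("no resolvable combinations in tree")
  structure(counts / used, n_combinations = nrow(combos), exact = exact)
}

#' Topology weights across a set of window trees
#'
#' @param trees A `multiPhylo` (or list of `phylo`), e.g. from
#'   [read_window_trees()] or [nj_window_tree()].
#' @param topologies A [enumerate_topologies()] result.
#' @param groups Tip-to-group mapping (see [weight_tree()]).
#' @param windows Optional tibble of window coordinates (`chrom`, `start`,
#'   `end`), one row per tree, prepended to the output.
#' @param ... Passed to [weight_tree()].
#' @return Tibble with one row per tree: window columns (or `window` index)
#'   plus one weight column per topology.
#' @export
topology_weights <- function(trees, topologies, groups, windows = NULL,
                             ...) {
  rows <- purrr::map(seq_along(trees), function(i) {
    w <- weight_tree(trees[[i]], topologies, groups, ...)
    tibble::as_tibble(as.list(w))
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(windows)) {
    stopifnot(nrow(windows) == length(trees))
    out <- dplyr::bind_cols(tibble::as_tibble(windows), out)
  } else {
    out <- dplyr::bind_cols(tibble::tibble(window = seq_along(trees)), out)
  }
  out
}

#' Neighbor-joining tree for a genomic window
#'
#' Builds a tree on all samples from pairwise allele-sharing distances
#' (mean absolute dosage difference / 2 over sites called in both samples)
#' with neighbor joining. A stand-in for likelihood-based window trees in
#' fully synthetic end-to-end runs. When all samples are identical the
#' star tree is returned with attribute `star = TRUE`.
#'
#' @param gm A [geno_tbl()] of biallelic sites.
#' @param chrom,start,end Optional window (0-based half-open span on
#'   `pos - 1`); default is all sites.
#' @return A `phylo`.
#' @export
nj_window_tree <- function(gm, chrom = NULL, start = NULL, end = NULL) {
  keep <- rep(TRUE, nrow(gm))
  if (!is.null(chrom)) keep <- keep & gm$chrom == chrom
  if (!is.null(start)) keep <- keep & gm$pos - 1L >= start
  if (!is.null(end)) keep <- keep & gm$pos - 1L < end
  dos <- gm$dosage[keep, , drop = FALSE]
  if (nrow(dos) < 1) stop("no variant sites in window")
  ids <- colnames(dos)
  if (length(ids) < 4) stop("need at least 4 samples")
  n <- length(ids)
  dm <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dd <- abs(dos[, i] - dos[, j]) / 2
      dm[i, j] <- dm[j, i] <- mean(dd, na.rm = TRUE)
    }
  }
  dm[is.nan(dm)] <- 0
  if (all(dm == 0)) {
    tr <- ape::stree(n, type = "star", tip.label = ids)
    attr(tr, "star") <- TRUE
    return(tr)
  }
  ape::nj(stats::as.dist(dm))
}
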