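test_that("topology enumeration matches the double-factorial count", {
  expect_equal(nrow(enumerate_topologies(4)), 3)
  ts5 <- enumerate_topologies(5)
  expect_equal(nrow(ts5), 15)
  expect_false(anyDuplicated(ts5$key) > 0)
  expect_error(enumerate_topologies(2), "at least 3")
  # canonical keys are parse-stable: re-reading the newick gives the same key
  rekeys <- vapply(ts5$newick, function(s)
    hybridscan:::canon_key(ape::read.tree(text = s)), character(1),
    USE.NAMES = FALSE)
  expect_identical(rekeys, ts5$key)
})

test_that("enumeration agrees with an independent tree generator", {
  labs <- c("A", "B", "C", "D", "E")
  ours <- enumerate_topologies(labs)
  ext <- phangorn::allTrees(5, rooted = FALSE, tip.label = labs)
  ext_keys <- vapply(ext, hybridscan:::canon_key, character(1))
  expect_setequal(ours$key, ext_keys)
})

test_that("a single combination puts all weight on the tree's own topology", {
  ts <- enumerate_topologies(c("A", "B", "C", "D", "E"))
  tr <- ape::read.tree(text = "(((a1,b1),c1),(d1,e1));")
  gmap <- c(a1 = "A", b1 = "B", c1 = "C", d1 = "D", e1 = "E")
  w <- weight_tree(tr, ts, gmap)
  expect_equal(sum(w), 1)
  expect_equal(sum(w == 1), 1)
  relabelled <- tr
  relabelled$tip.label <- unname(gmap[relabelled$tip.label])
  key <- hybridscan:::canon_key(relabelled)
  expect_equal(unname(w[ts$topology[ts$key == key]]), 1)
})

test_that("a split group yields the hand-enumerated 0.5/0.5 weights", {
  # group A has tips on opposite sides of the tree: the 2 combinations
  # induce different topologies, each with weight one half
  tr <- ape::read.tree(text = "(((a1,b1),c1),((a2,d1),e1));")
  gmap <- c(a1 = "A", a2 = "A", b1 = "B", c1 = "C", d1 = "D", e1 = "E")
  ts <- enumerate_topologies(c("A", "B", "C", "D", "E"))
  w <- weight_tree(tr, ts, gmap)
  expect_equal(sum(w), 1)
  expect_equal(sort(w[w > 0]), c(0.5, 0.5), ignore_attr = TRUE)
  expect_equal(attr(w, "n_combinations"), 2)
  expect_true(attr(w, "exact"))
})

test_that("exact mode equals brute-force enumeration by an independent oracle", {
  tr <- ape::read.tree(text = "(((a1,a2),(a3,b1)),((b2,c1),(c2,d1)),e1);")
  gmap <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B", c1 = "C",
            c2 = "C", d1 = "D", e1 = "E")
  ts <- enumerate_topologies(c("A", "B", "C", "D", "E"))
  w <- weight_tree(tr, ts, gmap)
  # oracle: explicit loops + RF distance to each candidate topology
  cands <- lapply(ts$newick, function(s) ape::read.tree(text = s))
  tally <- setNames(numeric(15), ts$topology)
  combos <- expand.grid(A = c("a1", "a2", "a3"), B = c("b1", "b2"),
                        C = c("c1", "c2"), D = "d1", E = "e1",
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    sub <- ape::keep.tip(tr, unlist(combos[i, ]))
    sub$tip.label <- unname(gmap[sub$tip.label])
    hit <- which(vapply(cands, function(cd)
      phangorn::RF.dist(ape::unroot(sub), ape::unroot(cd)) == 0,
      logical(1)))
    tally[hit] <- tally[hit] + 1
  }
  expect_equal(unclass(w), tally / nrow(combos), ignore_attr = TRUE)
  expect_equal(sum(w), 1)
})

test_that("Monte-Carlo weights converge to the exact weights", {
  tr <- ape::read.tree(text = "(((a1,a2),(a3,b1)),((b2,c1),(c2,d1)),e1);")
  gmap <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B", c1 = "C",
            c2 = "C", d1 = "D", e1 = "E")
  ts <- enumerate_topologies(c("A", "B", "C", "D", "E"))
  we <- weight_tree(tr, ts, gmap)
  for (n in c(300, 1000, 3000)) {
    wm <- weight_tree(tr, ts, gmap, max_exact = 1, n_samples = n, seed = 4)
    expect_false(attr(wm, "exact"))
    expect_equal(sum(wm), 1)
    se <- sqrt(pmax(we * (1 - we), 0.25 / n) / n)
    expect_true(all(abs(wm - we) <= 3 * se + 1e-9))
  }
})

test_that("input polytomies split weight among compatible topologies", {
  tr <- ape::read.tree(text = "((a1,b1,c1),(d1,e1));")
  gmap <- c(a1 = "A", b1 = "B", c1 = "C", d1 = "D", e1 = "E")
  ts <- enumerate_topologies(c("A", "B", "C", "D", "E"))
  w <- weight_tree(tr, ts, gmap)
  expect_equal(sum(w), 1)
  expect_equal(sort(unique(round(w[w > 0], 10))), 1 / 3)
  expect_equal(sum(w > 0), 3)
  wd <- expect_error(weight_tree(tr, ts, gmap, polytomy = "discard"),
                     "no resolvable")
})

test_that("unmapped tips and empty groups are rejected", {
  tr <- ape::read.tree(text = "(((a1,b1),c1),(d1,e1));")
  ts <- enumerate_topologies(c("A", "B", "C", "D", "E"))
  expect_error(weight_tree(tr, ts, c(a1 = "A")), "without a group")
  gmap <- c(a1 = "A", b1 = "B", c1 = "C", d1 = "D", e1 = "D")
  expect_error(weight_tree(tr, ts, gmap), "no tips")
})

test_that("neighbor joining recovers additive distances and flags stars", {
  set.seed(91)
  ref <- ape::rtree(8)
  dm <- stats::cophenetic(ref)
  rec <- ape::nj(stats::as.dist(dm))
  expect_equal(phangorn::RF.dist(ape::unroot(ref), ape::unroot(rec)), 0)
  # strong two-clade signal from the generator
  sim <- quartet_sim(500, pop_sizes = c(P1 = 3, P2 = 3, OUT = 2), seed = 92,
                     drift = c(P12 = 0, P1 = 0.4, P2 = 0.4))
  tr <- nj_window_tree(sim$geno)
  key_split <- hybridscan:::split_set(tr)
  expect_true(any(grepl("P2_1", key_split) & grepl("P2_2", key_split) |
                    grepl("P1_1", key_split) & grepl("P1_2", key_split)))
  # permuting sample order leaves the unrooted topology unchanged
  perm <- rev(sample_ids(sim$geno))
  gm2 <- hybridscan:::subset_samples(sim$geno, perm)
  tr2 <- nj_window_tree(gm2)
  expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(tr2)), 0)
  # identical samples -> star tree flagged
  dosu <- matrix(1L, 10, 4, dimnames = list(NULL, paste0("s_", 1:4)))
  star <- nj_window_tree(make_gm(dosu))
  expect_true(isTRUE(attr(star, "star")))
})

test_that("hybrid-with-donor topology weight rises with gamma", {
  ts <- enumerate_topologies(c("P1", "P2", "P3", "OUT", "HYB"))
  cherry <- grepl("OUT+P1+P3", ts$key, fixed = TRUE)
  expect_equal(sum(cherry), 3)
  wvals <- vapply(c(0.2, 0.5, 0.8), function(g) {
    cfg <- sim_config(n_sites = 3000,
                      pop_sizes = c(P1 = 3, P2 = 3, P3 = 2, OUT = 1),
                      gamma = rep(g, 2), seed = 33)
    sim <- simulate_genotypes(draw_population_frequencies(cfg), cfg)
    tr <- nj_window_tree(sim$geno)
    gmap <- setNames(sim$truth$population, sim$truth$sample)
    sum(weight_tree(tr, ts, gmap)[cherry])
  }, double(1))
  expect_true(all(diff(wvals) >= 0))
  expect_gt(wvals[3], wvals[1])
})

test_that("weights tabulate across multiple window trees", {
  trs <- structure(list(
    ape::read.tree(text = "(((a1,b1),c1),(d1,e1));"),
    ape::read.tree(text = "(((a1,c1),b1),(d1,e1));")), class = "multiPhylo")
  gmap <- c(a1 = "A", b1 = "B", c1 = "C", d1 = "D", e1 = "E")
  ts <- enumerate_topologies(c("A", "B", "C", "D", "E"))
  tw <- topology_weights(trs, ts, gmap,
                         windows = tibble::tibble(chrom = "chr1",
                                                  start = c(0, 50),
                                                  end = c(50, 100)))
  expect_equal(nrow(tw), 2)
  expect_equal(rowSums(tw[, ts$topology]), c(1, 1), ignore_attr = TRUE)
  expect_false(identical(tw[1, ts$topology], tw[2, ts$topology]))
})
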