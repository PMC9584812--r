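test_that("pattern masses conserve the usable-site total exactly", {
  sim <- quartet_sim(500, gamma = 0.4, seed = 14,
                     pop_sizes = c(P1 = 4, P2 = 4, OUT = 2))
  qp <- quartet_patterns(sim$geno, sim$popmap, "P1", "HYB", "P2", "OUT")
  expect_equal(sum(qp$totals), qp$n_sites)
  expect_true(all(qp$per_site >= 0))
})

test_that("pattern masses equal brute-force enumeration over allele draws", {
  sim <- quartet_sim(100, gamma = 0.5, seed = 15,
                     pop_sizes = c(P1 = 3, P2 = 3, OUT = 1))
  pm <- sim$popmap
  qp <- quartet_patterns(sim$geno, pm, "P1", "HYB", "P2", "OUT")
  # independent oracle: enumerate the 16 states per site explicitly
  f <- population_frequencies(sim$geno, pm, c("P1", "P2", "OUT", "HYB"))
  states <- expand.grid(o = 0:1, p1 = 0:1, h = 0:1, p2 = 0:1)
  oracle <- setNames(numeric(16), paste0(
    ifelse(states$o == 1, "B", "A"), ifelse(states$p1 == 1, "B", "A"),
    ifelse(states$h == 1, "B", "A"), ifelse(states$p2 == 1, "B", "A")))
  pr <- function(q, s) ifelse(s == 1, q, 1 - q)
  for (i in seq_len(nrow(f))) {
    for (k in seq_len(16)) {
      oracle[k] <- oracle[k] +
        pr(f$OUT[i], states$o[k]) * pr(f$P1[i], states$p1[k]) *
        pr(f$HYB[i], states$h[k]) * pr(f$P2[i], states$p2[k])
    }
  }
  expect_equal(qp$totals[names(oracle)], oracle, tolerance = 1e-12)
})

test_that("degenerate frequency patterns land on the forced pattern", {
  dos <- rbind(c(0L, 0L, 2L, 2L))
  colnames(dos) <- c("OUT_1", "P1_1", "HYB_1", "P2_1")
  gm <- make_gm(dos)
  pm <- tibble::tibble(sample = colnames(dos),
                       population = c("OUT", "P1", "HYB", "P2"),
                       role = NA)
  qp <- quartet_patterns(gm, pm, "P1", "HYB", "P2", "OUT")
  expect_equal(unname(qp$totals["AABB"]), 1)
  expect_equal(sum(qp$totals), 1)
  # monomorphic data: all mass on the constant pattern
  dos2 <- matrix(0L, 5, 4, dimnames = list(NULL, colnames(dos)))
  qp2 <- quartet_patterns(make_gm(dos2), pm, "P1", "HYB", "P2", "OUT")
  expect_equal(unname(qp2$totals["AAAA"]), 5)
})

test_that("swapping the parents maps gamma to 1 - gamma exactly", {
  sim <- quartet_sim(5000, gamma = 0.3, seed = 16)
  a <- hybrid_test(quartet_patterns(sim$geno, sim$popmap,
                                    "P1", "HYB", "P2", "OUT"))
  b <- hybrid_test(quartet_patterns(sim$geno, sim$popmap,
                                    "P2", "HYB", "P1", "OUT"))
  expect_equal(a$gamma, 1 - b$gamma, tolerance = 1e-12)
})

test_that("a hybrid group of pure P1 copies shows no hybridization", {
  sim <- quartet_sim(20000, gamma = c(0, 0), seed = 18)
  ht <- hybrid_test(quartet_patterns(sim$geno, sim$popmap,
                                     "P1", "HYB", "P2", "OUT"))
  expect_true(!ht$significant || abs(ht$gamma) < 0.05)
})

test_that("the invariant estimator agrees with a least-squares mixture oracle", {
  # oracle: regress the hybrid group's observed frequency on the known
  # simulated parental frequencies (truth from the generator), which gives
  # an unbiased least-squares estimate of the mixture fraction
  for (g in c(0.2, 0.5, 0.8)) {
    sim <- quartet_sim(30000, gamma = rep(g, 3), seed = 40 + round(10 * g))
    truth_freqs <- draw_population_frequencies(sim$config)
    fh <- population_frequencies(sim$geno, sim$popmap, "HYB")$HYB
    ht <- hybrid_test(quartet_patterns(sim$geno, sim$popmap,
                                       "P1", "HYB", "P2", "OUT"))
    gamma_ls <- sum((fh - truth_freqs$P1) * (truth_freqs$P2 - truth_freqs$P1),
                    na.rm = TRUE) /
      sum((truth_freqs$P2 - truth_freqs$P1)^2, na.rm = TRUE)
    expect_lt(abs(ht$gamma - gamma_ls), 0.05)
  }
})

test_that("gamma estimates are monotone in the simulated admixture fraction", {
  grid <- seq(0.1, 0.9, by = 0.1)
  est <- vapply(seq_along(grid), function(i) {
    sim <- quartet_sim(50000, gamma = grid[i], seed = 300 + i)
    hybrid_test(quartet_patterns(sim$geno, sim$popmap,
                                 "P1", "HYB", "P2", "OUT"))$gamma
  }, double(1))
  expect_equal(cor(est, grid, method = "spearman"), 1)
})

test_that("individual tests recover per-individual gamma within 0.07", {
  sim <- quartet_sim(50000, gamma = c(0.5, 0.2, 0), seed = 21)
  it <- individual_tests(sim$geno, sim$popmap, "P1", "HYB", "P2", "OUT")
  expect_equal(it$hybrid, c("HYB_1", "HYB_2", "HYB_3"))
  expect_lt(max(abs(it$gamma - c(0.5, 0.2, 0))), 0.07)
  expect_false(any(it$low_confidence))
})

test_that("identical individuals give identical results; all-missing errors", {
  dos <- cbind(P1_1 = c(0L, 2L, 0L, 1L), P1_2 = c(0L, 2L, 1L, 1L),
               P2_1 = c(2L, 0L, 2L, 1L), P2_2 = c(2L, 0L, 1L, 1L),
               HYB_1 = c(1L, 1L, 1L, 1L), HYB_2 = c(1L, 1L, 1L, 1L),
               HYB_3 = rep(NA_integer_, 4), OUT_1 = c(0L, 0L, 0L, 0L))
  gm <- make_gm(dos)
  pm <- popmap_from_ids(colnames(dos))
  expect_error(individual_tests(gm, pm, "P1", "HYB", "P2", "OUT"),
               "no called genotypes")
  pm2 <- pm[pm$sample != "HYB_3", ]
  gm2 <- hybridscan:::subset_samples(gm, pm2$sample)
  it <- individual_tests(gm2, pm2, "P1", "HYB", "P2", "OUT")
  expect_equal(it$gamma[1], it$gamma[2])
  expect_equal(it$z[1], it$z[2])
})

test_that("the full search tests 12 arrangements for 4 populations", {
  sim <- quartet_sim(8000, pop_sizes = c(P1 = 4, P2 = 4, P3 = 4, OUT = 2),
                     gamma = rep(0.5, 3), seed = 11)
  fs <- full_search(sim$geno, sim$popmap, "OUT", filter = FALSE)
  expect_equal(nrow(fs), 12)
  # each unordered trio appears in all 3 hybrid roles
  trio_key <- apply(fs[, c("p1", "hybrid", "p2")], 1,
                    function(r) paste(sort(r), collapse = "-"))
  expect_true(all(table(trio_key) == 3))
  # the true hybrid population tops the filtered table
  kept <- full_search(sim$geno, sim$popmap, "OUT")
  expect_gt(nrow(kept), 0)
  expect_equal(kept$hybrid[1], "HYB")
  expect_setequal(c(kept$p1[1], kept$p2[1]), c("P1", "P2"))
  expect_true(all(kept$gamma > 0 & kept$gamma < 1))
})

test_that("the corrected full search stays clean under the null", {
  clean <- vapply(1:10, function(s) {
    sim <- quartet_sim(4000, pop_sizes = c(P1 = 4, P2 = 4, P3 = 4, OUT = 2),
                       gamma = c(0, 0), seed = 100 + s)
    nrow(full_search(sim$geno, sim$popmap, "OUT")) == 0
  }, logical(1))
  expect_gte(sum(clean), 9)
})
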