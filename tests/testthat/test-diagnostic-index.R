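# 6-sample panel fixture: 2 panel-A, 2 panel-B, 2 targets.
panel_fixture <- function() {
  dos <- rbind(
    c(0L, 0L, 2L, 2L, 1L, 0L),   # diagnostic (A ref-fixed), QUAL ok
    c(2L, 2L, 0L, 0L, 1L, 2L),   # diagnostic with A alt-fixed
    c(0L, 1L, 2L, 2L, 1L, 0L),   # het in panel A -> excluded
    c(0L, 0L, 2L, 2L, 1L, 0L),   # QUAL 29 -> excluded
    c(0L, 0L, 0L, 0L, 1L, 0L),   # no between-panel difference
    c(0L, NA, 2L, 2L, 1L, 0L))   # missing panel call -> excluded
  colnames(dos) <- c("A_1", "A_2", "B_1", "B_2", "T_1", "T_2")
  make_gm(dos, qual = c(50, 50, 50, 29, 50, 50))
}

test_that("diagnostic sites require fixed opposite homozygotes and QUAL", {
  gm <- panel_fixture()
  ds <- find_diagnostic_sites(gm, c("A_1", "A_2"), c("B_1", "B_2"))
  expect_equal(nrow(ds), 2)
  expect_equal(ds$pos, c(100L, 200L))
  expect_equal(ds$allele_a, c("A", "T"))  # ref-fixed then alt-fixed panel A
  expect_equal(ds$allele_b, c("T", "A"))
  expect_error(find_diagnostic_sites(gm, c("A_1", "B_1"), c("B_1", "B_2")),
               "overlap")
})

test_that("panel members score exactly 1 and 0; adding samples only shrinks the set", {
  gm <- panel_fixture()
  ds <- find_diagnostic_sites(gm, c("A_1", "A_2"), c("B_1", "B_2"))
  hi <- hybrid_index(gm, ds, c("A_1", "A_2", "B_1", "B_2"))
  expect_equal(hi$frac_a, c(1, 1, 0, 0))
  expect_equal(hi$frac_a + hi$frac_b, rep(1, 4))
  # nested panels: with fewer panel samples the set can only be larger
  ds_small <- find_diagnostic_sites(gm, "A_1", c("B_1", "B_2"))
  expect_true(all(paste(ds$chrom, ds$pos) %in%
                    paste(ds_small$chrom, ds_small$pos)))
  expect_gte(nrow(ds_small), nrow(ds))
})

test_that("hybrid index counts allele copies over called sites", {
  # 10 diagnostic sites: target has 3 hom-A, 2 het, 5 hom-B -> fracA = 0.4
  target <- c(2L, 2L, 2L, 1L, 1L, 0L, 0L, 0L, 0L, 0L)
  dos <- cbind(A_1 = rep(2L, 10), A_2 = rep(2L, 10),
               B_1 = rep(0L, 10), B_2 = rep(0L, 10), T_1 = target)
  gm <- make_gm(dos)
  ds <- find_diagnostic_sites(gm, c("A_1", "A_2"), c("B_1", "B_2"))
  expect_equal(nrow(ds), 10)
  hi <- hybrid_index(gm, ds, "T_1")
  expect_equal(hi$frac_a, (3 * 2 + 2) / 20)
  # missing calls drop out of numerator and denominator
  dos2 <- dos; dos2[1:2, "T_1"] <- NA
  hi2 <- hybrid_index(make_gm(dos2), ds, "T_1")
  expect_equal(hi2$n_sites_called, 8)
  expect_equal(hi2$frac_a, (1 * 2 + 2) / 16)
  dos3 <- dos; dos3[, "T_1"] <- NA
  expect_error(hybrid_index(make_gm(dos3), ds, "T_1"), "no called")
})

test_that("the index is unbiased for simulated hybrids across the gamma grid", {
  n <- 10000
  set.seed(55)
  for (g in c(0.1, 0.5, 0.9)) {
    target <- rbinom(n, 2, g)
    dos <- cbind(A_1 = rep(2L, n), A_2 = rep(2L, n),
                 B_1 = rep(0L, n), B_2 = rep(0L, n),
                 T_1 = as.integer(target))
    gm <- make_gm(dos)
    ds <- find_diagnostic_sites(gm, c("A_1", "A_2"), c("B_1", "B_2"))
    hi <- hybrid_index(gm, ds, "T_1")
    expect_lt(abs(hi$frac_a - g), 0.01)
  }
})

test_that("an F1 from the generator scores one half at diagnostic sites", {
  n <- 20000
  cfg <- sim_config(n_sites = n, pop_sizes = c(P1 = 2, P2 = 2, OUT = 1),
                    gamma = 0.5, seed = 61)
  freqs <- draw_population_frequencies(cfg)
  freqs$P1 <- rep(1, n)  # fixed difference: P1 alt, P2 ref
  freqs$P2 <- rep(0, n)
  sim <- simulate_genotypes(freqs, cfg)
  ds <- find_diagnostic_sites(sim$geno, c("P1_1", "P1_2"),
                              c("P2_1", "P2_2"))
  hi <- hybrid_index(sim$geno, ds, "HYB_1")
  expect_lt(abs(hi$frac_a - 0.5), 3 * sqrt(0.25 / (2 * n)))
})

test_that("regional aggregation averages sample fractions", {
  res <- tibble::tibble(sample = c("s1", "s2", "s3", "s4"),
                        n_sites_called = 10L,
                        frac_a = c(0.2, 0.4, 0.7, 0.9),
                        frac_b = 1 - c(0.2, 0.4, 0.7, 0.9))
  md <- tibble::tibble(sample = c("s1", "s2", "s3", "s4"),
                       region = c("wales", "wales", "england", NA))
  expect_warning(agg <- aggregate_by_region(res, md), "without a region")
  expect_equal(agg$mean_frac_a[agg$region == "wales"], 0.3)
  expect_equal(agg$n_samples[agg$region == "england"], 1)
  expect_equal(agg$mean_frac_a[agg$region == "england"], 0.7)
})

test_that("regional means follow a simulated gamma gradient", {
  gammas <- c(a1 = 0.1, a2 = 0.15, b1 = 0.45, b2 = 0.5, c1 = 0.85, c2 = 0.9)
  n <- 5000
  cfg <- sim_config(n_sites = n, pop_sizes = c(P1 = 2, P2 = 2, OUT = 1),
                    gamma = gammas, seed = 71)
  freqs <- draw_population_frequencies(cfg)
  freqs$P1 <- rep(0, n); freqs$P2 <- rep(1, n)
  sim <- simulate_genotypes(freqs, cfg)
  ds <- find_diagnostic_sites(sim$geno, c("P2_1", "P2_2"),
                              c("P1_1", "P1_2"))
  hi <- hybrid_index(sim$geno, ds, names(gammas))
  md <- tibble::tibble(sample = names(gammas),
                       region = rep(c("r1", "r2", "r3"), each = 2))
  agg <- aggregate_by_region(hi, md)
  agg <- agg[order(agg$region), ]
  expect_true(all(diff(agg$mean_frac_a) > 0))
})

test_that("FDR counts discordant allele copies on a validation panel", {
  gm <- panel_fixture()
  ds <- find_diagnostic_sites(gm, c("A_1", "A_2"), c("B_1", "B_2"))
  # the panel itself is concordant by construction
  fdr0 <- estimate_fdr(hybridscan:::subset_samples(gm, c("A_1", "A_2")), ds)
  expect_equal(fdr0$rate, 0)
  # hand case: 50 sites x 1 sample = 100 copies, one discordant het
  dos <- cbind(A_1 = rep(2L, 50), A_2 = rep(2L, 50),
               B_1 = rep(0L, 50), B_2 = rep(0L, 50), V_1 = rep(2L, 50))
  dos[1, "V_1"] <- 1L
  gm2 <- make_gm(dos)
  ds2 <- find_diagnostic_sites(gm2, c("A_1", "A_2"), c("B_1", "B_2"))
  fdr <- estimate_fdr(hybridscan:::subset_samples(gm2, "V_1"), ds2)
  expect_equal(fdr$total_calls, 100)
  expect_equal(fdr$discordant_calls, 1)
  expect_equal(fdr$rate, 0.01)
  expect_error(estimate_fdr(
    make_gm(cbind(V_1 = rep(NA_integer_, 50))), ds2), "no called")
})

test_that("injected genotype error is recovered as the FDR", {
  n <- 20000
  eps <- 0.005
  set.seed(81)
  v <- rep(2L, n)
  flip <- runif(n) < eps
  v[flip] <- 0L  # miscalled genotype: both allele copies wrong
  dos <- cbind(A_1 = rep(2L, n), A_2 = rep(2L, n),
               B_1 = rep(0L, n), B_2 = rep(0L, n), V_1 = v)
  gm <- make_gm(dos)
  ds <- find_diagnostic_sites(gm, c("A_1", "A_2"), c("B_1", "B_2"))
  fdr <- estimate_fdr(hybridscan:::subset_samples(gm, "V_1"), ds)
  expect_lt(abs(fdr$rate - eps), 0.002)
})
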