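# Derive a per-stage seed from the run seed so stages are independently
# reproducible: run_seed + a fixed hash of the stage name, kept inside the
# 32-bit integer range.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) * 1009L
  as.integer((as.numeric(seed) + h) %% (2^31 - 1))
}

#' Run the full introgression-analysis pipeline
#'
#' Orchestrates simulate/read -> site filters -> trio D statistics ->
#' invariant hybridization tests (population and individual) -> windowed
#' admixture scan with top-percentile selection -> diagnostic hybrid index
#' -> nucleotide diversity and Fst with outliers -> optional topology
#' weighting and gene intersection, writing one TSV per stage plus a
#' machine-readable JSON summary into `out_dir`. Given the same `config`
#' (including its seed) the numeric outputs are identical between runs.
#' Stages whose inputs are absent (e.g. no hybrid population, no gene
#' annotation) are skipped with a logged notice.
#'
#' @param config Nested list (or path to a YAML file) with entries:
#'   `simulate` (arguments to [sim_config()]), or `vcf` + `popmap` paths;
#'   `outgroup`; optional `trio` (`p1`, `p2`, `p3`); `filters`
#'   (`min_qual`, `biallelic`, `ld_r2`, `ld_window`, `ascertainment`);
#'   `hybrid_tests` (`alpha`, `correction`); `window` (`window_snps`, `step_snps`,
#'   `pct`); `diagnostics` (`panel_a`, `panel_b` population labels);
#'   `fst` (`pop_a`, `pop_b`, `pct`); `pi` (`window_bp`); `gff` path;
#'   `seed`.
#' @param out_dir Output directory.
#' @return Invisibly, a named list with every stage's tibble and the
#'   summary.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML config requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed %||% 1L
  log_msg <- function(...) message("[pipeline] ", sprintf(...))
  results <- list()
  emit <- function(name, tbl) {
    results[[name]] <<- tbl
    readr::write_tsv(tbl, file.path(out_dir, paste0(name, ".tsv")))
  }
  jsonlite::write_json(config[setdiff(names(config), "simulate")],
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null")

  if (!is.null(config$simulate)) {
    log_msg("simulating dataset")
    sc_args <- config$simulate
    sc_args$seed <- sc_args$seed %||% stage_seed(seed, "simulate")
    sc <- do.call(sim_config, sc_args)
    sim <- simulate_genotypes(draw_population_frequencies(sc), sc)
    gm <- sim$geno
    popmap <- sim_population_map(sim$truth)
    emit("truth", sim$truth)
  } else {
    log_msg("reading %s", config$vcf)
    gm <- read_vcf(config$vcf)
    popmap <- read_population_map(config$popmap)
  }
  emit("popmap", popmap)

  fl <- config$filters %||% list()
  if (fl$biallelic %||% TRUE) gm <- filter_biallelic_snps(gm)
  gm <- filter_qual(gm, fl$min_qual %||% 30)
  if (!is.null(fl$ld_r2)) {
    gm <- ld_prune(gm, r2_max = fl$ld_r2, window_bp = fl$ld_window %||% 5000)
  }
  if (isTRUE(fl$ascertainment)) gm <- ascertainment_filter(gm)
  log_msg("%d sites after filtering", nrow(gm))
  write_vcf(gm, file.path(out_dir, "filtered.vcf"))

  outgroup <- config$outgroup %||% "OUT"
  pops <- setdiff(unique(popmap$population), outgroup)
  summary <- list(n_sites = nrow(gm), n_samples = length(sample_ids(gm)),
                  seed = seed)

  if (length(pops) >= 3) {
    log_msg("trio D statistics")
    dt <- dtrios_all(gm, popmap, outgroup,
                     seed = stage_seed(seed, "dtrios"))
    emit("dtrios", dt)
    summary$top_trio_d <- dt$d[1]
  } else log_msg("skipping trio stage: fewer than 3 populations")

  hybrid_pop <- intersect("HYB", pops)
  if (!length(hybrid_pop)) {
    hybrid_pop <- popmap$population[popmap$role %in% "hybrid"][1]
    hybrid_pop <- hybrid_pop[!is.na(hybrid_pop)]
  }
  hy <- config$hybrid_tests %||% list()
  trio <- config$trio %||% list(p1 = "P1", p2 = "P2", p3 = "P3")
  if (length(hybrid_pop) == 1 &&
      all(c(trio$p1, trio$p2) %in% pops)) {
    log_msg("hybridization tests (population and individual)")
    qp <- quartet_patterns(gm, popmap, trio$p1, hybrid_pop, trio$p2,
                           outgroup)
    ht <- hybrid_test(qp, alpha = hy$alpha %||% 0.05)
    emit("hybrid_test_population", dplyr::mutate(tidy(ht), n_sites = ht$n_sites))
    emit("hybrid_test_individual",
         individual_tests(gm, popmap, trio$p1, hybrid_pop, trio$p2,
                          outgroup, alpha = hy$alpha %||% 0.05))
    summary$population_gamma <- ht$gamma
  } else {
    log_msg("skipping hybridization stage: no hybrid population")
  }

  wcfg <- config$window %||% list()
  if (all(unlist(trio) %in% pops)) {
    freqs <- population_frequencies(gm, popmap, c(unlist(trio), outgroup))
    n_usable <- sum(stats::complete.cases(
      freqs[, c(trio$p1, trio$p2, trio$p3, outgroup)]))
    wsize <- wcfg$window_snps %||% 1000
    if (n_usable >= wsize) {
      log_msg("windowed admixture scan")
      ws <- scan_windows(freqs, trio$p1, trio$p2, trio$p3, outgroup,
                         window_snps = wsize,
                         step_snps = wcfg$step_snps %||% max(1, wsize %/% 2))
      emit("window_scan", ws)
      top <- top_percentile_windows(ws, pct = wcfg$pct %||% 1)
      emit("top_windows", top)
      summary$mean_fdM <- mean(ws$f_dM, na.rm = TRUE)
    } else log_msg("skipping window scan: fewer sites than one window")
  }

  dg <- config$diagnostics %||%
    (if (length(hybrid_pop) == 1) list(panel_a = trio$p1, panel_b = trio$p2))
  if (!is.null(dg) && length(hybrid_pop) == 1) {
    log_msg("diagnostic hybrid index")
    panel_a <- popmap$sample[popmap$population == dg$panel_a]
    panel_b <- popmap$sample[popmap$population == dg$panel_b]
    sites <- find_diagnostic_sites(gm, panel_a, panel_b)
    if (nrow(sites) > 0) {
      targets <- popmap$sample[popmap$population == hybrid_pop]
      hi <- hybrid_index(gm, sites, targets)
      emit("hybrid_index", hi)
      summary$n_diagnostic_sites <- nrow(sites)
    } else log_msg("skipping hybrid index: no diagnostic sites")
  } else log_msg("skipping diagnostics stage: no hybrid population")

  log_msg("nucleotide diversity")
  emit("pi", pi_summary(gm, popmap, pops,
                        window_bp = (config$pi %||% list())$window_bp %||%
                          100000))

  fcfg <- config$fst %||% list(pop_a = trio$p1, pop_b = trio$p2)
  if (all(c(fcfg$pop_a, fcfg$pop_b) %in% pops)) {
    log_msg("per-site Fst and outliers")
    fst <- per_site_fst(gm, popmap, fcfg$pop_a, fcfg$pop_b)
    emit("fst", fst)
    outl <- fst_outliers(fst, pct = fcfg$pct %||% 1)
    emit("fst_outliers", outl)
    if (!is.null(config$gff) && !is.null(results$top_windows)) {
      log_msg("intersecting windows, outliers and genes")
      genes <- read_gff_genes(config$gff)
      ad <- adaptive_candidates(results$window_scan, fst, genes,
                                pct = fcfg$pct %||% 1)
      emit("candidate_report", ad$report)
    }
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  results$summary <- summary
  invisible(results)
}
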