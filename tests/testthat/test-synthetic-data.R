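test_that("sim config validates feasibility", {
  expect_error(sim_config(n_probes_epic = 100, fraction_450k = 0.5,
                          studies = list(list(id = "A", arm = "exposure",
                                              platform = "HM450",
                                              n_hits = 60,
                                              dmr_fraction = 0))),
               "universe holds 50")
  expect_error(sim_config(planted = list(list(a = "F1", b = "ZZ", k = 2))),
               "unknown study")
  expect_error(sim_config(planted = list(list(a = "F1", b = "F3",
                                              k = 400))),
               "exceeds")
  expect_error(sim_config(fraction_450k = 0), "fraction_450k")
})

test_that("simulated manifest has exact platform counts and block genes", {
  cfg <- sim_config(n_probes_epic = 1000, fraction_450k = 0.6,
                    genes_total = 50, probes_per_gene = 10,
                    chrom_count = 4, studies = list(), planted = list(),
                    seed = 7)
  m <- simulate_manifest(cfg)
  expect_equal(sum(m$on_450k), 600L)
  expect_true(all(m$on_epic == 1L))
  expect_identical(m, simulate_manifest(cfg))  # same seed, same file
  expect_false(identical(m, simulate_manifest(sim_config(
    n_probes_epic = 1000, fraction_450k = 0.6, genes_total = 50,
    probes_per_gene = 10, chrom_count = 4, studies = list(),
    planted = list(), seed = 8))))
  # deterministic positions: spacing * index within chromosome
  for (ch in unique(m$chrom)) {
    pos <- m$pos[m$chrom == ch]
    expect_equal(pos, cfg$probe_spacing * seq_along(pos))
  }
  # block assignment: every gene's probes are consecutive in position
  ann <- m[nzchar(m$gene_symbols), ]
  genes <- unlist(lapply(ann$gene_symbols, strsplit, split = ";"))
  for (g in sample(unique(unlist(genes)), 10)) {
    rows <- unname(which(vapply(m$gene_symbols, function(s) {
      g %in% strsplit(s, ";", fixed = TRUE)[[1]]
    }, logical(1))))
    expect_equal(rows, seq(min(rows), max(rows)))
    expect_length(unique(m$chrom[rows]), 1L)
  }
})

test_that("planted exact overlap is recovered through the full pipeline", {
  cfg <- sim_config(seed = 31)
  m <- load_manifest(simulate_manifest(cfg))
  sim <- simulate_studies(cfg, m)
  rep <- suppressMessages(run_all(list(studies = sim$studies,
                                       manifest = m,
                                       universe = "manifest")))
  ov <- rep$overlaps[["F1|F3|cpg"]]
  expect_equal(ov$overlap_k, 17L)
  expect_identical(ov$shared_ids, sort(sim$truth$planted[["F1-F3"]]))
  # the three-way Venn isolates the planted region
  venn <- rep$venns[["exposure.cpg"]]
  f1f3 <- grep("F1.*F3|F3.*F1", names(venn$regions))
  f1f3 <- setdiff(f1f3, grep("F2", names(venn$regions)))
  expect_equal(unname(venn$regions[f1f3]), 17L)
})

test_that("DMR delivery round-trips: expansion plus explicit rows = truth", {
  for (seed in c(5, 6)) {
    cfg <- sim_config(seed = seed)
    m <- load_manifest(simulate_manifest(cfg))
    sim <- simulate_studies(cfg, m)
    for (sid in names(sim$studies)) {
      st <- sim$studies[[sid]]
      expanded <- expand_dmrs(st$dmrs, m, st$platform)$probe_id
      got <- union(expanded, st$cpg_hits$probe_id)
      expect_setequal(got, sim$truth$study_hits[[sid]])
    }
    # dmr_fraction = 1 emits no explicit probe rows at all
    expect_equal(nrow(sim$studies$F1$cpg_hits), 0L)
    expect_gt(nrow(sim$studies$F1$dmrs), 0L)
    # emitted DMR runs respect the cap
    expect_true(all(lengths(sim$truth$dmr_probes$F1) <= cfg$dmr_max_run))
  }
})

test_that("study substreams are stable when other studies are added", {
  base <- sim_config(seed = 12)
  extra <- base$studies
  extra[[length(extra) + 1]] <- list(id = "X9", arm = "outcome",
                                     platform = "EPIC", n_hits = 50,
                                     dmr_fraction = 0,
                                     endpoint = "nausea")
  cfg2 <- sim_config(studies = extra, seed = 12)
  m <- load_manifest(simulate_manifest(base))
  s1 <- simulate_studies(base, m)
  s2 <- simulate_studies(cfg2, m)
  for (sid in names(s1$studies)) {
    expect_setequal(s1$truth$study_hits[[sid]],
                    s2$truth$study_hits[[sid]])
  }
})

test_that("null simulation shows no planted overlap beyond chance", {
  # rho = 1 draws are independent: mean overlap tracks K n / N
  N <- 2000; K <- 120; n <- 150
  reps <- 400
  set.seed(77)
  ks <- replicate(reps, {
    length(intersect(sample.int(N, K), sample.int(N, n)))
  })
  mu <- K * n / N
  v <- mu * (N - K) * (N - n) / (N * (N - 1))
  expect_lt(abs(mean(ks) - mu), 3 * sqrt(v / reps))
  # and the pipeline-level calibration stays at its nominal level
  cal <- null_calibration(N, K, n, replicates = 400, alpha = 0.05,
                          seed = 3)
  expect_lte(cal$rate, cal$bound)
})

test_that("rejection rate grows with the planted enrichment factor", {
  rates <- vapply(c(1, 2, 4, 8), function(rho) {
    null_calibration(1000, 60, 80, replicates = 300, alpha = 0.05,
                     seed = 19, rho = rho)$rate
  }, numeric(1))
  # allow one Monte-Carlo inversion
  expect_lte(sum(diff(rates) < 0), 1)
  expect_gt(rates[4], rates[1])
})

test_that("simulated gene sets are reproducible and detectably planted", {
  cfg <- sim_config(planted_enriched_terms = 1, n_terms = 30,
                    term_size_range = c(5, 15), seed = 23)
  m <- load_manifest(simulate_manifest(cfg))
  sim <- simulate_studies(cfg, m)
  query <- sim$truth$genes$F3
  gs <- simulate_gene_sets(cfg, m, query = query)
  gs2 <- simulate_gene_sets(cfg, m, query = query)
  expect_identical(gs$collection, gs2$collection)
  res <- suppressMessages(ora(query, gs$collection))
  expect_identical(res$term_id[1], gs$truth$enriched)
  # the planted term separates clearly from the random ones
  expect_lt(res$p_raw[1], min(res$p_raw[-1]) / 10)
  expect_error(simulate_gene_sets(cfg, m), "query")
  # with no planted terms, random queries are rarely significant
  cfg0 <- sim_config(n_terms = 20, term_size_range = c(5, 15), seed = 29)
  gs0 <- simulate_gene_sets(cfg0, m)
  set.seed(41)
  pool <- sort(unique(unlist(m$table$gene_list)))
  n_sig <- sum(replicate(40, {
    res0 <- suppressMessages(suppressWarnings(
      ora(sample(pool, 12), gs0$collection)))
    nrow(significant_terms(res0, category = "KEGG", alpha = 0.05 / 20))
  }) > 0)
  expect_lte(n_sig / 40, 0.10)
})

test_that("written simulations reload into an identical analysis", {
  cfg <- sim_config(seed = 3)
  mdf <- simulate_manifest(cfg)
  m <- load_manifest(mdf)
  sim <- simulate_studies(cfg, m)
  dir <- tempfile()
  cfg_path <- write_simulation(sim, mdf, dir)
  catalog <- yaml::read_yaml(cfg_path)
  rep_mem <- suppressMessages(run_all(list(studies = sim$studies,
                                           manifest = m,
                                           universe = "manifest")))
  rep_file <- suppressMessages(run_all(list(studies = catalog$studies,
                                            manifest = catalog$manifest,
                                            base_dir = dir,
                                            universe = "manifest")))
  for (key in names(rep_mem$overlaps)) {
    expect_equal(rep_mem$overlaps[[key]]$overlap_k,
                 rep_file$overlaps[[key]]$overlap_k, label = key)
    expect_equal(rep_mem$overlaps[[key]]$p_upper,
                 rep_file$overlaps[[key]]$p_upper)
  }
})
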