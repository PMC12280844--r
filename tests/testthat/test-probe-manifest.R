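test_that("manifest round-trips probe fields and rejects duplicates", {
  df <- tiny_manifest_df()
  m <- load_manifest(write_tsv_fixture(df))
  expect_equal(nrow(m$table), 8L)
  row <- m$table["cg00000003", ]
  expect_equal(row$chrom, "chr1")
  expect_equal(row$pos, 200L)
  expect_identical(row$gene_list[[1]], c("GENEA", "GENEB"))
  expect_true(row$on_450k)

  dup <- rbind(df, df[1, ])
  expect_error(load_manifest(dup), "cg00000001")

  df$pos[2] <- NA
  expect_message(m2 <- load_manifest(df), "skipped 1")
  expect_equal(nrow(m2$table), 7L)

  bad <- tiny_manifest_df()
  bad$on_450k[4] <- 0L; bad$on_epic[4] <- 0L
  expect_error(load_manifest(bad), "no platform membership")
})

test_that("DMR expansion respects closed bounds, platform and dedup", {
  m <- tiny_manifest()
  # probes at chr1: 100, 150, 200, 300 -- DMR 120-210 contains 150, 200
  got <- expand_dmrs(data.frame(chrom = "chr1", start = 120, end = 210),
                     m, "EPIC")
  expect_identical(got$probe_id, c("cg00000002", "cg00000003"))
  expect_identical(unique(got$source), "dmr_derived")

  # boundary containment is inclusive on both ends
  got2 <- expand_dmrs(data.frame(chrom = "chr1", start = 150, end = 200),
                      m, "EPIC")
  expect_identical(got2$probe_id, c("cg00000002", "cg00000003"))

  # two overlapping DMRs over the same probes dedup to unique probes
  dmrs <- data.frame(chrom = "chr1", start = c(90, 140), end = c(160, 210))
  got3 <- expand_dmrs(dmrs, m, "EPIC")
  expect_identical(got3$probe_id,
                   c("cg00000001", "cg00000002", "cg00000003"))

  # platform filter: cg00000004 (chr1:300) is EPIC-only
  wide <- data.frame(chrom = "chr1", start = 1, end = 1000)
  expect_false("cg00000004" %in% expand_dmrs(wide, m, "HM450")$probe_id)
  expect_true("cg00000004" %in% expand_dmrs(wide, m, "EPIC")$probe_id)

  # unknown chromosome contributes nothing, counted
  expect_message(
    none <- expand_dmrs(data.frame(chrom = "chrX", start = 1, end = 10),
                        m, "EPIC"),
    "absent")
  expect_equal(nrow(none), 0L)
  expect_equal(attr(none, "n_unmapped_dmrs"), 1L)

  # empty-chromosome interval query
  expect_equal(nrow(expand_dmrs(data.frame(chrom = "chr2", start = 1,
                                           end = 1), m, "EPIC")), 0L)
})

test_that("DMR direction propagates to effect sign, conflicts become NA", {
  m <- tiny_manifest()
  dmrs <- data.frame(chrom = "chr1", start = c(90, 190), end = c(160, 210),
                     direction = c("hyper", "hypo"))
  got <- expand_dmrs(dmrs, m, "EPIC")
  eff <- stats::setNames(got$effect, got$probe_id)
  expect_equal(unname(eff[c("cg00000001", "cg00000002")]), c(1, 1))
  expect_equal(unname(eff["cg00000003"]), -1)
  # same probe under opposing DMRs
  conf <- data.frame(chrom = "chr1", start = c(90, 90), end = c(160, 160),
                     direction = c("hyper", "hypo"))
  expect_true(all(is.na(expand_dmrs(conf, m, "EPIC")$effect)))
})

test_that("expansion equals a brute-force scan on a simulated manifest", {
  cfg <- sim_config(n_probes_epic = 400, fraction_450k = 0.6,
                    genes_total = 30, probes_per_gene = 8,
                    chrom_count = 3, studies = list(), planted = list(),
                    seed = 11)
  mdf <- simulate_manifest(cfg)
  m <- load_manifest(mdf)
  set.seed(42)
  dmrs <- data.frame(
    chrom = sample(paste0("chr", 1:3), 25, replace = TRUE),
    start = sample.int(15000, 25))
  dmrs$end <- dmrs$start + sample.int(500, 25)
  for (pf in c("HM450", "EPIC")) {
    got <- expand_dmrs(dmrs, m, pf)$probe_id
    flag <- if (pf == "HM450") mdf$on_450k else mdf$on_epic
    want <- character(0)          # exhaustive double loop
    for (i in seq_len(nrow(mdf))) {
      for (j in seq_len(nrow(dmrs))) {
        if (flag[i] == 1L && mdf$chrom[i] == dmrs$chrom[j] &&
            mdf$pos[i] >= dmrs$start[j] && mdf$pos[i] <= dmrs$end[j]) {
          want <- c(want, mdf$probe_id[i])
          break
        }
      }
    }
    expect_identical(got, sort(unique(want)))
  }
})

test_that("expansion is invariant to DMR order and interval splitting", {
  m <- tiny_manifest()
  dmrs <- data.frame(chrom = c("chr1", "chr2"), start = c(100, 50),
                     end = c(300, 200))
  shuffled <- dmrs[2:1, ]
  split2 <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                       start = c(100, 201, 50), end = c(200, 300, 200))
  a <- expand_dmrs(dmrs, m, "EPIC")
  expect_identical(a, expand_dmrs(shuffled, m, "EPIC"),
                   ignore_attr = TRUE)
  expect_identical(a$probe_id, expand_dmrs(split2, m, "EPIC")$probe_id)
})

test_that("gene derivation unions annotations and distributes over union", {
  m <- tiny_manifest()
  expect_identical(as.character(genes_from_probes("cg00000003", m)),
                   c("GENEA", "GENEB"))
  expect_length(genes_from_probes(character(0), m), 0L)
  # unannotated probe contributes nothing
  expect_length(genes_from_probes("cg00000005", m), 0L)
  # missing probe skipped and counted
  expect_message(g <- genes_from_probes(c("cg00000006", "cg99999999"), m),
                 "absent")
  expect_equal(attr(g, "n_missing"), 1L)
  expect_identical(as.character(g), "GENEC")
  # distributivity over arbitrary bipartitions
  all_ids <- tiny_manifest_df()$probe_id
  set.seed(7)
  for (i in 1:5) {
    a <- sample(all_ids, 4); b <- sample(all_ids, 3)
    expect_setequal(genes_from_probes(union(a, b), m),
                    union(genes_from_probes(a, m),
                          genes_from_probes(b, m)))
  }
})

test_that("universe sizes follow the minimum-array rule", {
  expect_equal(universe_size(c("HM450", "EPIC"), "cpg"), 431312L)
  expect_equal(universe_size(c("EPIC", "EPIC"), "gene"), 27364L)
  expect_equal(universe_size("HM450", "gene"), 21231L)
  expect_error(universe_size(c("HM450", "27K"), "cpg"), "27K")
  # monotone: adding a study can never increase the universe
  set.seed(3)
  for (i in 1:20) {
    pf <- sample(c("HM450", "EPIC"), sample(1:3, 1), replace = TRUE)
    extra <- sample(c("HM450", "EPIC"), 1)
    for (lvl in c("cpg", "gene")) {
      expect_lte(universe_size(c(pf, extra), lvl),
                 universe_size(pf, lvl))
    }
  }
})

test_that("manifest-derived universes count cg probes and genes per platform", {
  u <- manifest_universe(tiny_manifest())
  expect_equal(unname(u$cpg["HM450"]), 6)
  expect_equal(unname(u$cpg["EPIC"]), 8)
  expect_equal(unname(u$gene["EPIC"]), 4)   # GENEA..GENED
  # 450k probes 1,2,3,5,6,8 still reach all four genes (GENEB via the
  # multi-gene probe cg00000003, GENEC via cg00000006)
  expect_equal(unname(u$gene["HM450"]), 4)
})

test_that("redundancy rate is the excess fraction of expanded probes", {
  expect_equal(redundancy_rate(sprintf("cg%08d", 1:110), 100), 10 / 110)
  expect_equal(redundancy_rate(sprintf("cg%08d", 1:50), 50), 0)
  expect_equal(redundancy_rate(sprintf("cg%08d", 1:40), 50), 0)
  expect_message(na <- redundancy_rate(character(0), 10), "not applicable")
  expect_true(is.na(na))
  # construction oracle: plant 5% extra over the declared count
  declared <- 950
  expanded <- sprintf("cg%08d", 1:1000)  # 50 extra of 1000 = 5%
  expect_equal(redundancy_rate(expanded, declared), 0.05)
})
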