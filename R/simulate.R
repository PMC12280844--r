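# Synthetic universe with planted structure: a scaled EPIC-like probe
# manifest containing a 450K-like subset, per-study hit lists with an
# exactly-planted (or enrichment-factor) cross-study overlap, DMRs
# covering runs of consecutive probes, and gene-set collections with
# optional planted enrichment.

# Internal: derive a reproducible 32-bit substream seed from the root
# seed and a label, so adding a study never perturbs earlier draws.
derive_seed <- function(root, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(root) * 48271 + h * 7919) %% 2147483563)
}

# Internal: run f() under a substream seed, restoring the caller's RNG
# state afterwards.
with_substream <- function(root, label, f) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(derive_seed(root, label))
  f()
}

#' Configuration of the synthetic universe and planted signal
#'
#' Defaults emulate the study conditions at 1/100 scale: an EPIC-like
#' universe of 7537 probes of which 4313 form the 450K-like subset
#' (matching [default_universe()]`(scale = 100)`), 274 genes in
#' contiguous probe blocks, three exposure hit lists (1343, 442 and 204
#' CpGs scaled to 134, 44, 20) on HM450 and four outcome hit lists
#' (HFS and thrombocytopenia endpoints: 368, 1376, 288, 509) on EPIC,
#' and a planted exposure-outcome-free overlap of exactly 17 probes
#' between the first and third exposure lists. DMRs are maximal runs of
#' consecutive truth probes capped at `dmr_max_run`.
#'
#' @param n_probes_epic EPIC-like universe size.
#' @param fraction_450k Fraction of probes flagged on the 450K-like
#'   subset (exact count by construction).
#' @param genes_total Number of genes annotated in contiguous blocks.
#' @param probes_per_gene Mean probes per gene block.
#' @param chrom_count Number of chromosomes.
#' @param probe_spacing Distance in bp between adjacent probes.
#' @param multi_gene_frac Probability that a block's first probe is also
#'   annotated to the previous gene (semicolon-joined), emulating
#'   multi-gene manifest rows.
#' @param studies List of per-study specs: `id`, `arm`, `platform`,
#'   `n_hits`, `dmr_fraction`, optional `endpoint`.
#' @param planted List of planted pair specs `list(a =, b =, k =)` for
#'   an exact overlap or `list(a =, b =, rho =)` for an expected
#'   enrichment factor relative to the null expectation K*n/N.
#' @param dmr_max_run Cap on the number of probes per emitted DMR.
#' @param n_terms,term_size_range,planted_enriched_terms,planted_term_fraction
#'   Gene-set simulation: number of random terms, their size range, how
#'   many terms are planted to contain `planted_term_fraction` of a
#'   designated query list.
#' @param seed Root seed; all substreams derive from it.
#' @return An `epimeet_sim_config` list.
#' @export
sim_config <- function(n_probes_epic = 7537,
                       fraction_450k = 4313 / 7537,
                       genes_total = 274,
                       probes_per_gene = 25,
                       chrom_count = 5,
                       probe_spacing = 100,
                       multi_gene_frac = 0.02,
                       studies = list(
                         list(id = "F1", arm = "exposure", platform = "HM450",
                              n_hits = 134, dmr_fraction = 1,
                              endpoint = "serum_folate"),
                         list(id = "F2", arm = "exposure", platform = "HM450",
                              n_hits = 44, dmr_fraction = 0.5,
                              endpoint = "dietary_folate"),
                         list(id = "F3", arm = "exposure", platform = "HM450",
                              n_hits = 20, dmr_fraction = 1,
                              endpoint = "dietary_folate"),
                         list(id = "T1h", arm = "outcome", platform = "EPIC",
                              n_hits = 368, dmr_fraction = 0.3,
                              endpoint = "HFS"),
                         list(id = "T2h", arm = "outcome", platform = "EPIC",
                              n_hits = 1376, dmr_fraction = 0.3,
                              endpoint = "HFS"),
                         list(id = "T1t", arm = "outcome", platform = "EPIC",
                              n_hits = 288, dmr_fraction = 0.3,
                              endpoint = "thrombocytopenia"),
                         list(id = "T3t", arm = "outcome", platform = "EPIC",
                              n_hits = 509, dmr_fraction = 0.3,
                              endpoint = "thrombocytopenia")),
                       planted = list(list(a = "F1", b = "F3", k = 17)),
                       dmr_max_run = 10,
                       n_terms = 50,
                       term_size_range = c(5, 40),
                       planted_enriched_terms = 0,
                       planted_term_fraction = 0.8,
                       seed = 1L) {
  cfg <- list(n_probes_epic = as.integer(n_probes_epic),
              fraction_450k = fraction_450k, genes_total = genes_total,
              probes_per_gene = probes_per_gene,
              chrom_count = chrom_count, probe_spacing = probe_spacing,
              multi_gene_frac = multi_gene_frac, studies = studies,
              planted = planted, dmr_max_run = dmr_max_run,
              n_terms = n_terms, term_size_range = term_size_range,
              planted_enriched_terms = planted_enriched_terms,
              planted_term_fraction = planted_term_fraction,
              seed = as.integer(seed))
  if (cfg$n_probes_epic < 1 || cfg$fraction_450k <= 0 ||
      cfg$fraction_450k > 1) {
    stop("need n_probes_epic >= 1 and fraction_450k in (0, 1]",
         call. = FALSE)
  }
  ids <- vapply(studies, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate study id in sim config",
                               call. = FALSE)
  n450 <- round(cfg$fraction_450k * cfg$n_probes_epic)
  for (s in studies) {
    cap <- if (s$platform == "HM450") n450 else cfg$n_probes_epic
    if (s$n_hits > cap) {
      stop("study '", s$id, "' asks for ", s$n_hits,
           " hits but its platform universe holds ", cap, call. = FALSE)
    }
  }
  sizes <- stats::setNames(vapply(studies, function(s) s$n_hits, 0), ids)
  for (p in cfg$planted) {
    if (!all(c(p$a, p$b) %in% ids)) {
      stop("planted pair references unknown study", call. = FALSE)
    }
    if (!is.null(p$k) && p$k > min(sizes[c(p$a, p$b)])) {
      stop("planted k=", p$k, " exceeds the smaller list size of pair ",
           p$a, "-", p$b, call. = FALSE)
    }
  }
  structure(cfg, class = "epimeet_sim_config")
}

#' Simulate an array manifest with block gene annotation
#'
#' Probes are laid out deterministically (`probe_spacing * index` within
#' each chromosome); a uniformly random subset of exact size
#' `round(fraction_450k * n_probes_epic)` is flagged `on_450k` (all
#' probes are `on_epic`). Genes are assigned to runs of consecutive
#' probes with mean block size `probes_per_gene` (Poisson-distributed,
#' never crossing a chromosome boundary, with small random gaps);
#' probes left after the last gene are unannotated. Reproducible under
#' the config seed.
#'
#' @param config An `epimeet_sim_config`.
#' @return A manifest data.frame (`probe_id`, `chrom`, `pos`, `strand`,
#'   `gene_symbols`, `on_450k`, `on_epic`) suitable for
#'   [load_manifest()] or [write_manifest()].
#' @export
simulate_manifest <- function(config) {
  stopifnot(inherits(config, "epimeet_sim_config"))
  n <- config$n_probes_epic
  per <- ceiling(n / config$chrom_count)
  chrom_idx <- rep(seq_len(config$chrom_count), each = per)[seq_len(n)]
  within <- stats::ave(seq_len(n), chrom_idx, FUN = seq_along)
  with_substream(config$seed, "manifest", function() {
    on450 <- logical(n)
    on450[sample.int(n, round(config$fraction_450k * n))] <- TRUE
    strand <- sample(c("+", "-"), n, replace = TRUE)
    gene <- character(n)
    sizes <- 1L + stats::rpois(config$genes_total,
                               max(0, config$probes_per_gene - 1))
    gaps <- stats::rpois(config$genes_total, 0.5)
    multi <- stats::runif(config$genes_total) < config$multi_gene_frac
    i <- 1L
    for (g in seq_len(config$genes_total)) {
      if (i > n) break
      last_of_chrom <- max(which(chrom_idx == chrom_idx[i]))
      end <- min(i + sizes[g] - 1L, last_of_chrom)
      name <- sprintf("G%04d", g)
      gene[i:end] <- name
      # occasional multi-gene probe at the block boundary
      if (multi[g] && g > 1L && i > 1L && chrom_idx[i - 1L] == chrom_idx[i] &&
          nzchar(gene[i - 1L]) && !grepl(";", gene[i - 1L], fixed = TRUE)) {
        gene[i] <- paste(gene[i - 1L], name, sep = ";")
      }
      i <- end + 1L + gaps[g]
    }
    data.frame(probe_id = sprintf("cg%08d", seq_len(n)),
               chrom = paste0("chr", chrom_idx),
               pos = within * config$probe_spacing,
               strand = strand, gene_symbols = gene,
               on_450k = as.integer(on450), on_epic = 1L,
               stringsAsFactors = FALSE)
  })
}

#' Write a manifest data.frame as delimited text
#' @param manifest_df Data frame from [simulate_manifest()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(manifest_df, path) {
  utils::write.table(manifest_df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Internal: manifest-ordered probe ids of one platform.
platform_ids <- function(manifest, platform) {
  manifest$table$probe_id[platform_mask(manifest, platform)]
}

#' Simulate per-study hit lists with planted cross-study overlap
#'
#' For each planted pair, either exactly `k` shared probes are drawn
#' from the joint platform universe, or (in `rho` mode) an extra
#' Poisson((rho - 1) K n / N) shared probes are planted so the expected
#' total overlap is about `rho` times the null expectation (`rho = 1`
#' plants nothing: the pure null). Remaining hits are drawn uniformly
#' without replacement from the study's platform universe, excluding
#' every planted id and — for exact-`k` pairs — the partner's
#' already-drawn hits, so the planted count is recovered exactly.
#' Per-study draws use substreams of the root seed, so adding a study
#' leaves earlier studies' lists unchanged. A `dmr_fraction` of each
#' study's hits is delivered as DMRs covering maximal runs of
#' consecutive same-platform probes (capped at `dmr_max_run`) instead
#' of explicit probe rows; gene hit lists are derived from the full
#' truth probe set through the manifest.
#'
#' @param config An `epimeet_sim_config`.
#' @param manifest A `probe_manifest`, or the data.frame from
#'   [simulate_manifest()].
#' @return List with `studies` (named list of `epimeet_study`),
#'   `truth` (planted ids per pair, full truth probe/gene sets and DMR
#'   memberships per study) and `config`.
#' @export
simulate_studies <- function(config, manifest) {
  stopifnot(inherits(config, "epimeet_sim_config"))
  if (!inherits(manifest, "probe_manifest")) {
    manifest <- load_manifest(manifest)
  }
  ids <- vapply(config$studies, `[[`, "", "id")
  spec <- stats::setNames(config$studies, ids)
  pf_ids <- lapply(stats::setNames(EPIMEET_PLATFORMS, EPIMEET_PLATFORMS),
                   platform_ids, manifest = manifest)

  # -- plant shared probes per configured pair ------------------------
  planted <- list()
  for (p in config$planted) {
    key <- paste(p$a, p$b, sep = "-")
    joint <- intersect(pf_ids[[spec[[p$a]]$platform]],
                       pf_ids[[spec[[p$b]]$platform]])
    k <- if (!is.null(p$k)) p$k else {
      N <- length(joint)
      lambda <- max(0, (p$rho - 1)) * spec[[p$a]]$n_hits *
        spec[[p$b]]$n_hits / N
      min(with_substream(config$seed, paste0("plant.n.", key),
                         function() stats::rpois(1L, lambda)),
          spec[[p$a]]$n_hits, spec[[p$b]]$n_hits)
    }
    if (k > length(joint)) {
      stop("planted overlap ", k, " exceeds the joint universe of pair ",
           key, call. = FALSE)
    }
    planted[[key]] <- with_substream(config$seed, paste0("plant.", key),
                                     function() sample(joint, k))
  }
  all_planted <- unique(unlist(planted, use.names = FALSE))
  exact_pairs <- Filter(function(p) !is.null(p$k), config$planted)

  # -- draw each study's truth probe set ------------------------------
  truth_hits <- list()
  effects <- list()
  for (sid in ids) {
    s <- spec[[sid]]
    own_keys <- vapply(config$planted, function(p) {
      if (sid %in% c(p$a, p$b)) paste(p$a, p$b, sep = "-") else NA_character_
    }, "")
    own <- unique(unlist(planted[own_keys[!is.na(own_keys)]],
                         use.names = FALSE))
    # exact-k partners already drawn: exclude their hits entirely
    partner_hits <- unique(unlist(lapply(exact_pairs, function(p) {
      other <- setdiff(c(p$a, p$b), sid)
      if (sid %in% c(p$a, p$b) && other %in% names(truth_hits)) {
        truth_hits[[other]]
      }
    }), use.names = FALSE))
    pool <- setdiff(pf_ids[[s$platform]],
                    unique(c(all_planted, partner_hits)))
    fill_n <- s$n_hits - length(own)
    if (fill_n < 0) {
      stop("study '", sid, "': planted ids exceed its list size",
           call. = FALSE)
    }
    if (fill_n > length(pool)) {
      stop("study '", sid, "': platform universe too small after ",
           "exclusions", call. = FALSE)
    }
    fill <- with_substream(config$seed, paste0("study.", sid),
                           function() sample(pool, fill_n))
    hits <- c(own, fill)
    truth_hits[[sid]] <- hits
    effects[[sid]] <- with_substream(
      config$seed, paste0("effect.", sid),
      function() stats::setNames(stats::rnorm(length(hits), 0, 0.05),
                                 hits))
  }

  # -- emit DMRs over runs of consecutive truth probes ----------------
  studies <- list()
  truth_dmrs <- list()
  truth_genes <- list()
  for (sid in ids) {
    s <- spec[[sid]]
    hits <- truth_hits[[sid]]
    eff <- effects[[sid]]
    pids <- pf_ids[[s$platform]]
    pchrom <- manifest$table$chrom[match(pids, manifest$table$probe_id)]
    idx <- sort(match(hits, pids))
    brk <- c(TRUE, diff(idx) != 1L | pchrom[idx[-1L]] != pchrom[idx[-length(idx)]])
    runs <- split(idx, cumsum(brk))
    # cap run length
    runs <- unlist(lapply(runs, function(ii) {
      split(ii, (seq_along(ii) - 1L) %/% config$dmr_max_run)
    }), recursive = FALSE, use.names = FALSE)
    target <- round(s$dmr_fraction * length(hits))
    order_runs <- with_substream(config$seed, paste0("dmr.", sid),
                                 function() sample(seq_along(runs)))
    selected <- logical(length(runs))
    got <- 0L
    for (r in order_runs) {
      if (got >= target) break
      selected[r] <- TRUE
      got <- got + length(runs[[r]])
    }
    if (s$dmr_fraction >= 1) selected[] <- TRUE
    dmr_rows <- lapply(runs[selected], function(ii) {
      probes <- pids[ii]
      pos <- manifest$table$pos[match(probes, manifest$table$probe_id)]
      data.frame(chrom = pchrom[ii[1L]], start = min(pos), end = max(pos),
                 direction = if (mean(eff[probes]) >= 0) "hyper" else "hypo",
                 stringsAsFactors = FALSE)
    })
    dmr_df <- if (length(dmr_rows)) do.call(rbind, dmr_rows) else NULL
    if (!is.null(dmr_df)) rownames(dmr_df) <- NULL
    dmr_probes <- unname(lapply(runs[selected], function(ii) pids[ii]))
    explicit <- setdiff(hits, unlist(dmr_probes, use.names = FALSE))
    cpg_df <- if (length(explicit)) {
      data.frame(probe_id = explicit, effect = unname(eff[explicit]),
                 source = "dmp", is_cpg = TRUE, stringsAsFactors = FALSE)
    } else NULL
    genes <- genes_from_probes(hits, manifest)
    gene_df <- if (length(genes)) {
      gl <- manifest$table$gene_list[match(hits, manifest$table$probe_id)]
      gmap <- data.frame(gene = unlist(gl, use.names = FALSE),
                         effect = rep(unname(eff[hits]), lengths(gl)),
                         stringsAsFactors = FALSE)
      agg <- tapply(gmap$effect, gmap$gene, mean)
      data.frame(symbol = genes, effect = as.numeric(agg[genes]),
                 stringsAsFactors = FALSE)
    } else NULL
    studies[[sid]] <- new_study(
      study_id = sid, arm = s$arm, endpoint = s$endpoint %||% NA_character_,
      platform = s$platform, sample_size = s$sample_size %||% NA_integer_,
      cpg_hits = cpg_df, dmrs = dmr_df, gene_hits = gene_df,
      log = list(simulated = TRUE))
    truth_dmrs[[sid]] <- dmr_probes
    truth_genes[[sid]] <- genes
  }
  list(studies = studies,
       truth = list(planted = planted, study_hits = truth_hits,
                    dmr_probes = truth_dmrs, genes = truth_genes,
                    effects = effects),
       config = config)
}

#' Simulate a gene-set collection with optional planted enrichment
#'
#' Draws `n_terms` random terms from the manifest's annotated genes.
#' When `planted_enriched_terms > 0` and a query list is supplied, the
#' planted terms are constructed to contain `planted_term_fraction` of
#' the query (filled up with random non-query genes) so an
#' over-representation analysis can detect them.
#'
#' @param config An `epimeet_sim_config`.
#' @param manifest A `probe_manifest` or manifest data.frame (source of
#'   the gene pool).
#' @param query Optional character vector of query gene symbols to
#'   plant against.
#' @param category Collection category label (see [load_gmt()]).
#' @return List with `collection` (a `gene_set_collection`) and `truth`
#'   (`enriched`: planted term ids).
#' @export
simulate_gene_sets <- function(config, manifest, query = NULL,
                               category = "custom") {
  stopifnot(inherits(config, "epimeet_sim_config"))
  if (!inherits(manifest, "probe_manifest")) {
    manifest <- load_manifest(manifest)
  }
  pool <- sort(unique(unlist(manifest$table$gene_list, use.names = FALSE)))
  lo <- config$term_size_range[1L]
  hi <- config$term_size_range[2L]
  if (hi > length(pool)) {
    stop("term size range exceeds the gene pool (", length(pool), ")",
         call. = FALSE)
  }
  n_planted <- config$planted_enriched_terms
  if (n_planted > 0L && is.null(query)) {
    stop("planted enriched terms need a designated query list",
         call. = FALSE)
  }
  query <- normalize_gene_symbol(query %||% character(0))
  terms <- with_substream(config$seed, "genesets", function() {
    out <- vector("list", config$n_terms)
    for (t in seq_len(config$n_terms)) {
      size <- sample(lo:hi, 1L)
      if (t <= n_planted) {
        n_from_query <- min(round(config$planted_term_fraction * size),
                            length(query))
        members <- c(sample(query, n_from_query),
                     sample(setdiff(pool, query), size - n_from_query))
      } else {
        members <- sample(pool, size)
      }
      out[[t]] <- list(name = sprintf("simulated term %d", t),
                       genes = sort(members))
    }
    names(out) <- sprintf("T%04d", seq_len(config$n_terms))
    out
  })
  collection <- structure(list(category = category, terms = terms),
                          class = "gene_set_collection")
  list(collection = collection,
       truth = list(enriched = names(terms)[seq_len(n_planted)]))
}

#' Write a gene-set collection as a GMT file
#' @param collection A `gene_set_collection`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$terms), function(id) {
    t <- collection$terms[[id]]
    paste(c(id, t$name, t$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated data set to disk
#'
#' Emits the manifest, per-study CpG/DMR/gene hit-list files, a catalog
#' YAML config consumable by [run_all()], and `truth.json`.
#'
#' @param sim Result of [simulate_studies()].
#' @param manifest_df Manifest data.frame (from [simulate_manifest()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path of the catalog config file.
#' @export
write_simulation <- function(sim, manifest_df, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_manifest(manifest_df, file.path(dir, "manifest.tsv"))
  descs <- list()
  for (sid in names(sim$studies)) {
    s <- sim$studies[[sid]]
    d <- list(id = sid, arm = s$arm, platform = s$platform)
    if (!is.na(s$endpoint)) d$endpoint <- s$endpoint
    if (nrow(s$cpg_hits)) {
      f <- sprintf("%s_cpg.tsv", sid)
      utils::write.table(s$cpg_hits[, c("probe_id", "effect")],
                         file.path(dir, f), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      d$cpg_file <- f
    }
    if (nrow(s$dmrs)) {
      f <- sprintf("%s_dmr.tsv", sid)
      utils::write.table(s$dmrs, file.path(dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      d$dmr_file <- f
    }
    if (nrow(s$gene_hits)) {
      f <- sprintf("%s_gene.tsv", sid)
      utils::write.table(s$gene_hits, file.path(dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      d$gene_file <- f
    }
    descs[[length(descs) + 1L]] <- d
  }
  cfg_path <- file.path(dir, "catalog.yaml")
  yaml::write_yaml(list(manifest = "manifest.tsv", studies = descs),
                   cfg_path)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(cfg_path)
}

#' Empirical null calibration of the overlap test
#'
#' Draws two independent uniform random subsets of sizes `K` and `n`
#' from a universe of size `N` per replicate, computes the upper-tail
#' overlap probability, and returns the rejection rate at `alpha`.
#' With `rho > 1`, an extra Poisson((rho - 1) K n / N) shared ids are
#' planted per replicate, giving an expected overlap of about
#' `rho K n / N` (power mode). The test statistic is discrete, so under
#' the null the rate is expected at or below
#' `alpha + 3 sqrt(alpha (1 - alpha) / replicates)`.
#'
#' @param N,K,n Universe and set sizes.
#' @param replicates Number of replicates (>= 1).
#' @param alpha Nominal level.
#' @param seed Seed for the replicate draws.
#' @param rho Overlap enrichment factor (1 = null).
#' @return List with `rate`, `alpha`, `replicates`, `se`, `bound`
#'   (`alpha + 3 se`) and the vector of `p_values`.
#' @export
#' @examples
#' null_calibration(400, 30, 40, replicates = 200, seed = 1)$rate
null_calibration <- function(N, K, n, replicates = 2000, alpha = 0.05,
                             seed = 1L, rho = 1) {
  stopifnot(replicates >= 1, alpha > 0, alpha <= 1, rho >= 0)
  p <- with_substream(seed, "calibration", function() {
    vapply(seq_len(replicates), function(i) {
      extra <- if (rho > 1) {
        min(stats::rpois(1L, (rho - 1) * K * n / N), K, n)
      } else 0L
      shared <- if (extra > 0) sample.int(N, extra) else integer(0)
      rest <- setdiff(seq_len(N), shared)
      a <- c(shared, sample(rest, K - extra))
      b <- c(shared, sample(rest, n - extra))
      k <- length(intersect(a, b))
      if (k == 0L) 1 else hypergeom_upper_tail(N, K, n, k)
    }, numeric(1))
  })
  se <- sqrt(alpha * (1 - alpha) / replicates)
  list(rate = mean(p <= alpha), alpha = alpha, replicates = replicates,
       se = se, bound = alpha + 3 * se, p_values = p)
}
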