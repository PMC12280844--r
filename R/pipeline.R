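# meet-in-the-middle orchestration: catalog -> expansion -> overlaps ->
# enrichment -> report bundle.

# Internal: display label for an outcome hit list, Table-2 style:
# "HFS (T1)" when an endpoint is recorded, else the study id.
record_label <- function(rec) {
  if (is.na(rec$endpoint) || !nzchar(rec$endpoint)) rec$study_id
  else sprintf("%s (%s)", rec$endpoint, rec$study_id)
}

# Internal: merge explicit CpG hits with DMR-derived probes, explicit
# rows winning on conflict; counts the redundantly re-extracted probes.
merge_cpg_hits <- function(explicit, derived) {
  redundant <- intersect(derived$probe_id, explicit$probe_id)
  add <- derived[!derived$probe_id %in% explicit$probe_id, , drop = FALSE]
  out <- rbind(explicit, add)
  rownames(out) <- NULL
  attr(out, "n_redundant") <- length(redundant)
  out
}

# Internal: prepare one study for analysis — expand its DMRs, merge hit
# sets, derive genes through the manifest.
prepare_study <- function(rec, manifest) {
  derived <- NULL
  if (nrow(rec$dmrs)) {
    if (is.null(manifest)) {
      stop("study '", rec$study_id,
           "' has DMRs but no manifest was supplied", call. = FALSE)
    }
    derived <- expand_dmrs(rec$dmrs, manifest, rec$platform)
  }
  cpg_all <- if (is.null(derived)) rec$cpg_hits
             else merge_cpg_hits(rec$cpg_hits, derived)
  genes <- rec$gene_hits$symbol
  n_unannotated <- 0L
  if (!is.null(manifest) && nrow(cpg_all)) {
    derived_genes <- genes_from_probes(cpg_all$probe_id, manifest)
    n_unannotated <- attr(derived_genes, "n_missing")
    genes <- union(genes, derived_genes)
  }
  gene_eff <- stats::setNames(rec$gene_hits$effect, rec$gene_hits$symbol)
  list(
    record = rec,
    label = record_label(rec),
    cpg_all = cpg_all,
    cpg_set = sort(cpg_all$probe_id[cpg_all$is_cpg]),
    cpg_effects = stats::setNames(cpg_all$effect, cpg_all$probe_id),
    gene_set = sort(unique(genes)),
    gene_effects = gene_eff,
    log = c(rec$log,
            n_dmr_derived = if (is.null(derived)) 0L else nrow(derived),
            n_redundant = attr(cpg_all, "n_redundant") %||% 0L,
            n_probes_unannotated = n_unannotated)
  )
}

#' Run the full meet-in-the-middle analysis
#'
#' Loads the study catalog and manifest, expands DMRs to probes, derives
#' gene lists, tests every exposure-by-outcome pair for CpG- and
#' gene-level overlap under the minimum-array universe rule, decomposes
#' 2-3 study groups into Venn regions, runs over-representation
#' analysis per study against each supplied collection, overlap-tests
#' significant pathway sets between arms, and tallies cross-arm pathway
#' commonality. Deterministic given its inputs.
#'
#' @param config A list (or path to a YAML file) with fields:
#'   \describe{
#'     \item{studies}{catalog config, list of descriptors, or list of
#'       `epimeet_study` records (at least one exposure and one
#'       outcome).}
#'     \item{manifest}{path / data.frame / `probe_manifest`; optional
#'       when no study carries DMRs.}
#'     \item{universe}{optional per-platform overrides of
#'       [default_universe()], or the string `"manifest"` to count both
#'       levels from the loaded manifest (see [manifest_universe()]).}
#'     \item{alpha}{significance level, default 0.05.}
#'     \item{collections}{named list, category -> GMT path or
#'       `gene_set_collection`.}
#'     \item{background}{`"auto"` (collection genes, intersected with
#'       the platform's annotated genes when a manifest is present) or
#'       a fixed number.}
#'     \item{term_universe}{optional fixed pathway-test universe;
#'       default: terms with at least one background gene.}
#'     \item{out_dir}{when set, [render_tables()] is called on the
#'       result.}
#'   }
#' @return A `meet_report` bundle: processed studies, all
#'   `overlap_result`s, per-level overlap matrices, Venn
#'   decompositions, shared ids with concordance labels, enrichment
#'   tables, pathway overlaps, the pathway-commonality map and tally,
#'   and a run log.
#' @export
run_all <- function(config) {
  if (is.character(config)) {
    base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
    config$base_dir <- config$base_dir %||% base_dir
  }
  alpha <- config$alpha %||% 0.05
  stopifnot(alpha > 0, alpha < 1)
  base_dir <- config$base_dir %||% "."

  manifest <- config$manifest
  if (!is.null(manifest) && !inherits(manifest, "probe_manifest")) {
    if (is.character(manifest) && !file.exists(manifest)) {
      manifest <- file.path(base_dir, manifest)
    }
    manifest <- load_manifest(manifest)
  }
  universe <- if (identical(config$universe, "manifest")) {
    if (is.null(manifest)) {
      stop("universe = \"manifest\" requires a manifest", call. = FALSE)
    }
    manifest_universe(manifest)
  } else {
    merge_universe(config$universe)
  }

  studies <- config$studies
  if (length(studies) && inherits(studies[[1L]], "epimeet_study")) {
    recs <- studies
    names(recs) <- vapply(recs, `[[`, "", "study_id")
  } else {
    recs <- load_catalog(studies, base_dir = base_dir)
  }
  arms <- vapply(recs, `[[`, "", "arm")
  if (!any(arms == "exposure") || !any(arms == "outcome")) {
    stop("catalog needs at least one exposure and one outcome study",
         call. = FALSE)
  }
  prepped <- lapply(recs, prepare_study, manifest = manifest)
  exposures <- prepped[arms == "exposure"]
  outcomes <- prepped[arms == "outcome"]

  # -- pairwise overlaps at cpg and gene level ------------------------
  overlaps <- list()
  shared_rows <- list()
  for (o in outcomes) {
    for (e in exposures) {
      for (level in c("cpg", "gene")) {
        set_e <- if (level == "cpg") e$cpg_set else e$gene_set
        set_o <- if (level == "cpg") o$cpg_set else o$gene_set
        N <- universe_size(c(e$record$platform, o$record$platform),
                           level, universe)
        res <- pairwise_overlap(set_e, set_o, N, level,
                                labels = c(e$record$study_id,
                                           o$record$study_id))
        key <- paste(e$record$study_id, o$record$study_id, level,
                     sep = "|")
        overlaps[[key]] <- res
        if (res$overlap_k > 0) {
          eff_e <- if (level == "cpg") e$cpg_effects else e$gene_effects
          eff_o <- if (level == "cpg") o$cpg_effects else o$gene_effects
          conc <- effect_concordance(res$shared_ids, eff_e, eff_o)
          shared_rows[[key]] <- data.frame(
            level = level, exposure = e$record$study_id,
            outcome = o$label, id = res$shared_ids,
            effect_exposure = as.numeric(eff_e[res$shared_ids]),
            effect_outcome = as.numeric(eff_o[res$shared_ids]),
            concordance = unname(conc), stringsAsFactors = FALSE)
        }
      }
    }
  }

  # within-arm comparisons: every exposure pair; outcome pairs sharing
  # an endpoint (profiles of the same toxicity across studies)
  same_arm_pairs <- list()
  if (length(exposures) >= 2L) {
    cmb <- utils::combn(seq_along(exposures), 2L)
    for (j in seq_len(ncol(cmb))) {
      same_arm_pairs[[length(same_arm_pairs) + 1L]] <-
        list(exposures[[cmb[1L, j]]], exposures[[cmb[2L, j]]])
    }
  }
  if (length(outcomes) >= 2L) {
    cmb <- utils::combn(seq_along(outcomes), 2L)
    for (j in seq_len(ncol(cmb))) {
      a <- outcomes[[cmb[1L, j]]]; b <- outcomes[[cmb[2L, j]]]
      if (!is.na(a$record$endpoint) && !is.na(b$record$endpoint) &&
          a$record$endpoint == b$record$endpoint) {
        same_arm_pairs[[length(same_arm_pairs) + 1L]] <- list(a, b)
      }
    }
  }
  for (pair in same_arm_pairs) {
    a <- pair[[1L]]; b <- pair[[2L]]
    for (level in c("cpg", "gene")) {
      set_a <- if (level == "cpg") a$cpg_set else a$gene_set
      set_b <- if (level == "cpg") b$cpg_set else b$gene_set
      N <- universe_size(c(a$record$platform, b$record$platform),
                         level, universe)
      overlaps[[paste(a$record$study_id, b$record$study_id, level,
                      sep = "|")]] <-
        pairwise_overlap(set_a, set_b, N, level,
                         labels = c(a$record$study_id, b$record$study_id))
    }
  }

  matrices <- lapply(c(cpg = "cpg", gene = "gene"), function(level) {
    rows <- lapply(outcomes, function(o) {
      row <- data.frame(endpoint = o$label, stringsAsFactors = FALSE)
      for (e in exposures) {
        res <- overlaps[[paste(e$record$study_id, o$record$study_id,
                               level, sep = "|")]]
        row[[paste0(e$record$study_id, ".k")]] <- res$overlap_k
        row[[paste0(e$record$study_id, ".p")]] <- format_p(res$p_upper)
      }
      row
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })

  # -- Venn decompositions per arm (2-3 hit lists) --------------------
  venns <- list()
  for (arm_name in c("exposure", "outcome")) {
    grp <- prepped[arms == arm_name]
    if (length(grp) >= 2L && length(grp) <= 3L) {
      for (level in c(cpg = "cpg", gene = "gene")) {
        sets <- lapply(grp, function(s) {
          if (level == "cpg") s$cpg_set else s$gene_set
        })
        names(sets) <- vapply(grp, `[[`, "", "label")
        venns[[paste(arm_name, level, sep = ".")]] <- multiway_venn(sets)
      }
    }
  }

  # -- enrichment + pathway-level overlap -----------------------------
  collections <- config$collections
  enrich <- list()
  path_overlaps <- list()
  commonality <- list()
  tally <- list()
  if (!is.null(collections)) {
    for (cat in names(collections)) {
      coll <- collections[[cat]]
      if (is.character(coll)) {
        path <- if (file.exists(coll)) coll else file.path(base_dir, coll)
        coll <- load_gmt(path, category = cat)
      }
      coll_genes <- collection_genes(coll)
      bg_for <- function(s) {
        bg_cfg <- config$background %||% "auto"
        if (is.numeric(bg_cfg)) return(bg_cfg)
        if (!is.null(manifest)) {
          pf_genes <- sort(unique(unlist(
            manifest$table$gene_list[platform_mask(manifest,
                                                   s$record$platform)],
            use.names = FALSE)))
          intersect(coll_genes, pf_genes)
        } else coll_genes
      }
      backgrounds <- lapply(prepped, bg_for)
      names(backgrounds) <- names(prepped)
      sig_ids <- list()
      for (sid in names(prepped)) {
        res <- ora(prepped[[sid]]$gene_set, coll, backgrounds[[sid]])
        sig <- significant_terms(res, category = cat, alpha = alpha)
        enrich[[paste(sid, cat, sep = ".")]] <-
          list(results = res, significant = sig)
        sig_ids[[sid]] <- sig$term_id
      }
      # pathway overlap only between studies that each have >=1
      # significant term
      for (o in outcomes) {
        for (e in exposures) {
          se <- sig_ids[[e$record$study_id]]
          so <- sig_ids[[o$record$study_id]]
          if (length(se) == 0L || length(so) == 0L) next
          tu <- config$term_universe
          if (is.null(tu)) {
            bg_pair <- union(backgrounds[[e$record$study_id]],
                             backgrounds[[o$record$study_id]])
            tu <- sum(vapply(coll$terms, function(t) {
              any(t$genes %in% bg_pair)
            }, logical(1)))
          }
          key <- paste(e$record$study_id, o$record$study_id, cat,
                       sep = "|")
          path_overlaps[[key]] <- pathway_overlap(
            se, so, tu, labels = c(e$record$study_id, o$record$study_id))
        }
      }
      # commonality: term significant in >=1 exposure and the outcome
      # hit lists it is shared with
      cmap <- list()
      exp_terms <- unique(unlist(
        sig_ids[vapply(prepped, function(s) s$record$arm, "")[names(sig_ids)]
                == "exposure"], use.names = FALSE))
      for (term in exp_terms) {
        hits <- vapply(outcomes, function(o) {
          term %in% sig_ids[[o$record$study_id]]
        }, logical(1))
        if (any(hits)) {
          cmap[[term]] <- vapply(outcomes[hits], `[[`, "", "label")
        }
      }
      commonality[[cat]] <- cmap
      tally[[cat]] <- tally_pathway_events(cmap)
    }
  }

  bundle <- structure(
    list(studies = prepped, overlaps = overlaps, matrices = matrices,
         venns = venns,
         shared_ids = if (length(shared_rows)) {
           out <- do.call(rbind, shared_rows); rownames(out) <- NULL; out
         } else NULL,
         enrichment = enrich, pathway_overlaps = path_overlaps,
         commonality = commonality, tally = tally, alpha = alpha,
         universe = universe,
         log = lapply(prepped, `[[`, "log")),
    class = "meet_report")
  if (!is.null(config$out_dir)) {
    render_tables(bundle, config$out_dir)
  }
  bundle
}

#' @export
print.meet_report <- function(x, ...) {
  cat(sprintf("<meet_report> %d studies, %d pairwise overlaps, alpha=%g\n",
              length(x$studies), length(x$overlaps), x$alpha))
  for (level in names(x$matrices)) {
    cat("--", level, "level overlaps --\n")
    print(x$matrices[[level]], row.names = FALSE)
  }
  if (length(x$tally)) {
    for (cat_ in names(x$tally)) {
      t <- x$tally[[cat_]]
      cat(sprintf("%s: %d overlap event(s) across %d distinct pathway(s)\n",
                  cat_, t$n_events, t$n_distinct))
    }
  }
  invisible(x)
}

#' Tally cross-arm pathway commonality events
#'
#' Given a map from pathway id to the set of (endpoint, study) outcome
#' hit lists it is shared with, counts the total number of overlap
#' events (sum of the set sizes) and the number of distinct pathways
#' (keys).
#'
#' @param per_pathway_commonality Named list; each element a character
#'   vector (or data.frame) of outcome occurrences, non-empty.
#' @return List with `n_events` and `n_distinct`.
#' @export
#' @examples
#' tally_pathway_events(list(hsa04510 = c("HFS (T1)", "HFS (T2)")))
tally_pathway_events <- function(per_pathway_commonality) {
  m <- per_pathway_commonality
  if (length(m) == 0L) return(list(n_events = 0L, n_distinct = 0L))
  sizes <- vapply(m, function(v) {
    if (is.data.frame(v)) nrow(unique(v)) else length(unique(v))
  }, integer(1))
  if (any(sizes == 0L)) {
    stop("commonality map contains an empty event set", call. = FALSE)
  }
  list(n_events = as.integer(sum(sizes)), n_distinct = length(m))
}

#' Write the report bundle to TSV/JSON files
#'
#' Emits `overlap_cpg.tsv` and `overlap_gene.tsv` (outcome endpoints by
#' exposure studies; per exposure a `k` column and a display-rounded
#' `p` column, untestable cells rendered `0` / `—`),
#' `overlap_pathway.tsv`, `shared_ids.tsv`, `venn.json`,
#' `enrichment_<study>_<category>.tsv`, full-precision
#' `overlaps.json`, and `run_manifest.json` with the audit counts.
#' Output is byte-deterministic given an identical bundle.
#'
#' @param bundle A `meet_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
render_tables <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "meet_report"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2L) != 0L) {
    stop("cannot write to output directory: ", out_dir, call. = FALSE)
  }
  written <- character(0)
  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    written <<- c(written, path)
  }
  jsonf <- function(x, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    written <<- c(written, path)
  }
  for (level in names(bundle$matrices)) {
    tsv(bundle$matrices[[level]], sprintf("overlap_%s.tsv", level))
  }
  if (length(bundle$pathway_overlaps)) {
    rows <- lapply(names(bundle$pathway_overlaps), function(key) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
      df <- as.data.frame(bundle$pathway_overlaps[[key]])
      df$p_display <- format_p(df$p_upper)
      cbind(collection = parts[3L], df)
    })
    tsv(do.call(rbind, rows), "overlap_pathway.tsv")
  }
  if (!is.null(bundle$shared_ids)) tsv(bundle$shared_ids, "shared_ids.tsv")
  if (length(bundle$venns)) {
    jsonf(lapply(bundle$venns, function(v) {
      list(labels = v$labels, regions = as.list(v$regions))
    }), "venn.json")
  }
  for (key in names(bundle$enrichment)) {
    tsv(bundle$enrichment[[key]]$results,
        sprintf("enrichment_%s.tsv", gsub("[^A-Za-z0-9_.-]", "_", key)))
  }
  jsonf(lapply(bundle$overlaps, function(r) unclass(r)), "overlaps.json")
  jsonf(list(alpha = bundle$alpha,
             universe = lapply(bundle$universe, as.list),
             study_log = bundle$log,
             tally = bundle$tally),
        "run_manifest.json")
  invisible(written)
}
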