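#' Load an array manifest
#'
#' Reads a probe manifest (delimited text, header
#' `probe_id, chrom, pos, strand, gene_symbols, on_450k, on_epic`;
#' `gene_symbols` semicolon-separated, platform flags 0/1) and indexes
#' it for O(1) probe lookup and fast per-chromosome interval queries
#' (via GenomicRanges). Positions are 1-based; probes are point
#' features, strand is carried but ignored by containment tests.
#'
#' @param x Path to a manifest file, or an equivalent data.frame.
#' @return An object of class `probe_manifest`: list with the parsed
#'   `table` (including a `gene_list` list-column of normalized
#'   symbols), a `GRanges` index `gr`, and `n_skipped` rows dropped for
#'   missing coordinates.
#' @export
load_manifest <- function(x) {
  tab <- if (is.character(x)) read_delim_auto(x) else as.data.frame(x)
  need <- c("probe_id", "chrom", "pos", "strand", "gene_symbols",
            "on_450k", "on_epic")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("manifest lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab$probe_id <- as.character(tab$probe_id)
  dup <- tab$probe_id[duplicated(tab$probe_id)]
  if (length(dup)) {
    stop("duplicate probe id in manifest: ", dup[1L], call. = FALSE)
  }
  tab$pos <- suppressWarnings(as.integer(tab$pos))
  keep <- !is.na(tab$pos) & !is.na(tab$chrom) & nzchar(as.character(tab$chrom))
  n_skipped <- sum(!keep)
  if (n_skipped) {
    message("manifest: skipped ", n_skipped, " row(s) with missing coordinates")
  }
  tab <- tab[keep, , drop = FALSE]
  if (any(tab$pos < 1L)) stop("manifest position < 1", call. = FALSE)
  tab$chrom <- as.character(tab$chrom)
  tab$on_450k <- as.logical(as.integer(tab$on_450k))
  tab$on_epic <- as.logical(as.integer(tab$on_epic))
  if (any(!tab$on_450k & !tab$on_epic)) {
    stop("manifest probe with no platform membership: ",
         tab$probe_id[which(!tab$on_450k & !tab$on_epic)[1L]],
         call. = FALSE)
  }
  gene_symbols <- as.character(tab$gene_symbols)
  gene_symbols[is.na(gene_symbols)] <- ""
  tab$gene_list <- lapply(gene_symbols, normalize_gene_symbol)
  rownames(tab) <- tab$probe_id
  gr <- GenomicRanges::GRanges(tab$chrom,
                               IRanges::IRanges(tab$pos, tab$pos))
  structure(list(table = tab, gr = gr, n_skipped = n_skipped),
            class = "probe_manifest")
}

#' @export
print.probe_manifest <- function(x, ...) {
  cat(sprintf("<probe_manifest> %d probes on %d chromosome(s); %d on 450K, %d on EPIC\n",
              nrow(x$table), length(unique(x$table$chrom)),
              sum(x$table$on_450k), sum(x$table$on_epic)))
  invisible(x)
}

# Internal: logical mask of manifest probes on a platform.
platform_mask <- function(manifest, platform) {
  platform <- match.arg(platform, EPIMEET_PLATFORMS)
  if (platform == "HM450") manifest$table$on_450k else manifest$table$on_epic
}

#' Expand DMRs to their constituent CpG probes
#'
#' Maps each differentially methylated region (1-based, closed on both
#' ends) to the manifest probes it contains on the requested platform.
#' Results are deduplicated across overlapping DMRs; a DMR direction
#' (`hyper`/`hypo`), when present, propagates to the probe effect sign
#' (+1/-1; conflicting directions across overlapping DMRs yield `NA`).
#' DMRs on chromosomes absent from the manifest contribute nothing and
#' are counted.
#'
#' @param dmrs data.frame with columns `chrom`, `start`, `end` and
#'   optionally `direction`.
#' @param manifest A `probe_manifest`.
#' @param platform `"HM450"` or `"EPIC"`.
#' @return data.frame of CpG hits (`probe_id`, `effect`, `source =
#'   "dmr_derived"`, `is_cpg`), with attribute `n_unmapped_dmrs`.
#' @export
expand_dmrs <- function(dmrs, manifest, platform) {
  stopifnot(inherits(manifest, "probe_manifest"))
  mask <- platform_mask(manifest, platform)
  empty <- data.frame(probe_id = character(0), effect = numeric(0),
                      source = character(0), is_cpg = logical(0),
                      stringsAsFactors = FALSE)
  if (is.null(dmrs) || nrow(dmrs) == 0L) {
    attr(empty, "n_unmapped_dmrs") <- 0L
    return(empty)
  }
  if (any(dmrs$start > dmrs$end)) stop("DMR with start > end", call. = FALSE)
  known <- dmrs$chrom %in% unique(manifest$table$chrom)
  n_unmapped <- sum(!known)
  if (n_unmapped) {
    message("expand_dmrs: ", n_unmapped,
            " DMR(s) on chromosome(s) absent from the manifest")
  }
  dmrs <- dmrs[known, , drop = FALSE]
  if (nrow(dmrs) == 0L) {
    attr(empty, "n_unmapped_dmrs") <- n_unmapped
    return(empty)
  }
  q <- GenomicRanges::GRanges(dmrs$chrom,
                              IRanges::IRanges(dmrs$start, dmrs$end))
  hits <- IRanges::findOverlaps(q, manifest$gr, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  on_pf <- mask[si]
  qi <- qi[on_pf]; si <- si[on_pf]
  if (length(si) == 0L) {
    attr(empty, "n_unmapped_dmrs") <- n_unmapped
    return(empty)
  }
  dir <- if ("direction" %in% names(dmrs)) dmrs$direction[qi]
         else rep(NA_character_, length(qi))
  sign <- ifelse(is.na(dir), NA_real_, ifelse(dir == "hyper", 1, -1))
  ids <- manifest$table$probe_id[si]
  # dedup across overlapping DMRs; conflicting direction -> NA effect
  eff <- tapply(sign, ids, function(s) {
    s <- unique(s[!is.na(s)])
    if (length(s) == 1L) s else NA_real_
  })
  uid <- sort(unique(ids))
  out <- data.frame(probe_id = uid,
                    effect = as.numeric(eff[uid]),
                    source = "dmr_derived",
                    is_cpg = startsWith(uid, "cg"),
                    stringsAsFactors = FALSE)
  attr(out, "n_unmapped_dmrs") <- n_unmapped
  out
}

#' Derive gene symbols from a probe set
#'
#' Union of the manifest gene annotations over the given probes.
#' Unannotated probes contribute nothing; probes absent from the
#' manifest are skipped and counted (attribute `n_missing`).
#'
#' @param probes Character vector of probe ids.
#' @param manifest A `probe_manifest`.
#' @return Sorted character vector of normalized gene symbols, with
#'   attribute `n_missing`.
#' @export
genes_from_probes <- function(probes, manifest) {
  stopifnot(inherits(manifest, "probe_manifest"))
  probes <- unique(as.character(probes))
  idx <- match(probes, manifest$table$probe_id)
  n_missing <- sum(is.na(idx))
  if (n_missing) {
    message("genes_from_probes: ", n_missing,
            " probe(s) absent from the manifest")
  }
  genes <- unlist(manifest$table$gene_list[idx[!is.na(idx)]],
                  use.names = FALSE)
  genes <- sort(unique(as.character(genes %||% character(0))))
  attr(genes, "n_missing") <- n_missing
  genes
}

#' Universe size for a set of studies under the minimum-array rule
#'
#' The population size of a cross-study overlap test is the smallest
#' probe (or annotated-gene) count among the platforms used by the
#' studies being compared — any probe outside the smallest array cannot
#' be observed in every study.
#'
#' @param studies List of `epimeet_study` records, or a character vector
#'   of platform names.
#' @param level `"cpg"` or `"gene"`.
#' @param universe Universe table as returned by [default_universe()].
#' @return A positive integer count.
#' @export
#' @examples
#' universe_size(c("HM450", "EPIC"), "cpg")
#' universe_size(c("EPIC", "EPIC"), "gene")
universe_size <- function(studies, level = c("cpg", "gene"),
                          universe = default_universe()) {
  level <- match.arg(level)
  platforms <- if (is.character(studies)) studies
               else vapply(studies, `[[`, "", "platform")
  if (length(platforms) == 0L) stop("no studies supplied", call. = FALSE)
  unknown <- setdiff(platforms, names(universe[[level]]))
  if (length(unknown)) {
    stop("platform(s) missing from universe table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  as.integer(min(universe[[level]][platforms]))
}

#' Universe sizes computed from a loaded manifest
#'
#' Counts, per platform, the `cg` probes and the distinct annotated
#' gene symbols actually present in a manifest. Used in place of the
#' shipped constants when the analysis should be self-consistent with
#' the manifest at hand (e.g. simulated universes), via
#' `universe = "manifest"` in [run_all()].
#'
#' @param manifest A `probe_manifest`.
#' @return A universe table shaped like [default_universe()].
#' @export
manifest_universe <- function(manifest) {
  stopifnot(inherits(manifest, "probe_manifest"))
  tab <- manifest$table
  is_cg <- startsWith(tab$probe_id, "cg")
  count_genes <- function(mask) {
    length(unique(unlist(tab$gene_list[mask], use.names = FALSE)))
  }
  list(cpg = c(HM450 = sum(tab$on_450k & is_cg),
               EPIC = sum(tab$on_epic & is_cg)),
       gene = c(HM450 = count_genes(tab$on_450k),
                EPIC = count_genes(tab$on_epic)))
}

#' Redundancy of DMR-derived probe extraction
#'
#' When DMRs are expanded against a full manifest, probes that the
#' source study had excluded (QC, non-CpG, ...) are extracted
#' redundantly. Against a declared per-study CpG count this returns
#' `max(0, |expanded| - declared) / |expanded|`.
#'
#' @param expanded Character vector of expanded probe ids (deduplicated
#'   internally).
#' @param declared_count The study's declared number of CpGs (positive).
#' @return Fraction in `[0, 1]`, or `NA` (with a message) when the
#'   expanded set is empty.
#' @export
#' @examples
#' redundancy_rate(sprintf("cg%08d", 1:110), 100)
redundancy_rate <- function(expanded, declared_count) {
  stopifnot(is.numeric(declared_count), length(declared_count) == 1L,
            declared_count > 0)
  n <- length(unique(expanded))
  if (n == 0L) {
    message("redundancy_rate: empty expanded set, not applicable")
    return(NA_real_)
  }
  max(0, n - declared_count) / n
}
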