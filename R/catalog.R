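#' Normalize a gene-symbol annotation string
#'
#' Array manifests annotate multi-gene probes as semicolon-separated
#' symbol lists, often with inconsistent case and stray whitespace. This
#' splits on `;`, trims, upper-cases, drops empty tokens and
#' deduplicates, preserving first-occurrence order. Idempotent.
#'
#' @param raw Character vector of raw annotation strings (each may hold
#'   several `;`-separated symbols). `NA` contributes nothing.
#' @return Character vector of zero or more normalized symbols.
#' @export
#' @examples
#' normalize_gene_symbol("Sept9")
#' normalize_gene_symbol("HOXA4;HOXA4;hoxa5")
#' normalize_gene_symbol(" ; ")
normalize_gene_symbol <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  raw <- raw[!is.na(raw)]
  toks <- unlist(strsplit(raw, ";", fixed = TRUE), use.names = FALSE)
  toks <- toupper(trimws(toks))
  unique(toks[nzchar(toks)])
}

#' Validate Illumina-style probe identifiers
#'
#' Accepts identifiers made of a lowercase `cg` or `ch` prefix followed
#' by at least eight digits. Everything else — upper-case variants, SNP
#' (`rs`) probes, malformed strings — is rejected with a reason; nothing
#' is raised.
#'
#' @param raw Character vector of candidate identifiers.
#' @return A data.frame with columns `probe_id`, `accepted` (logical) and
#'   `reason` (`""` when accepted).
#' @export
#' @examples
#' validate_probe_id(c("cg16651126", "CG16651126", "rs123456", "ch0012345678"))
validate_probe_id <- function(raw) {
  raw <- as.character(raw)
  ok <- grepl("^(cg|ch)[0-9]{8,}$", raw)
  reason <- character(length(raw))
  bad <- !ok
  reason[bad] <- "malformed identifier"
  reason[bad & grepl("^rs", raw)] <- "SNP (rs) probe"
  reason[bad & grepl("^(CG|CH)", raw)] <- "upper-case prefix"
  reason[bad & (is.na(raw) | !nzchar(raw))] <- "empty identifier"
  data.frame(probe_id = raw, accepted = ok, reason = reason,
             stringsAsFactors = FALSE)
}

# Internal: sniff the field separator of a delimited text file from its
# header line (tab wins over comma), then read it.
read_delim_auto <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    blank.lines.skip = TRUE)
}

# Internal: pick a (possibly renamed) column, erroring with the file path
# when a required column is absent.
pick_col <- function(df, want, mapping, path, required = TRUE) {
  name <- mapping[[want]] %||% want
  if (!name %in% names(df)) {
    if (required) {
      stop("column '", name, "' (", want, ") missing in ", path,
           call. = FALSE)
    }
    return(NULL)
  }
  df[[name]]
}

# Internal: coerce an effect column, erroring with 1-based data line
# numbers (header = line 1) on non-numeric entries.
parse_effect <- function(x, path) {
  if (is.null(x)) return(NULL)
  eff <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & nzchar(trimws(as.character(x))) & is.na(eff))
  if (length(bad)) {
    stop("unparseable effect value '", x[bad[1L]], "' at line ",
         bad[1L] + 1L, " of ", path, call. = FALSE)
  }
  eff[is.nan(eff) | is.infinite(eff)] <- NA_real_
  eff
}

# Internal constructor shared by load_study() and the simulator; enforces
# the StudyRecord invariants on already-parsed components.
new_study <- function(study_id, arm, endpoint = NA_character_,
                      platform, tissue = NA_character_,
                      sample_size = NA_integer_,
                      cpg_hits = NULL, dmrs = NULL, gene_hits = NULL,
                      log = list()) {
  arm <- match.arg(arm, c("exposure", "outcome"))
  if (!is.character(platform) || length(platform) != 1L ||
      !platform %in% EPIMEET_PLATFORMS) {
    stop("unsupported platform '", paste(platform, collapse = ","),
         "' for study '", study_id, "': must be one of ",
         paste(EPIMEET_PLATFORMS, collapse = ", "), call. = FALSE)
  }
  empty_cpg <- data.frame(probe_id = character(0), effect = numeric(0),
                          source = character(0), is_cpg = logical(0),
                          stringsAsFactors = FALSE)
  empty_gene <- data.frame(symbol = character(0), effect = numeric(0),
                           stringsAsFactors = FALSE)
  empty_dmr <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), direction = character(0),
                          stringsAsFactors = FALSE)
  cpg_hits <- cpg_hits %||% empty_cpg
  gene_hits <- gene_hits %||% empty_gene
  dmrs <- dmrs %||% empty_dmr
  stopifnot(!anyDuplicated(cpg_hits$probe_id),
            !anyDuplicated(gene_hits$symbol))
  if (nrow(dmrs) && any(dmrs$start > dmrs$end)) {
    stop("DMR with start > end in study '", study_id, "'", call. = FALSE)
  }
  structure(
    list(study_id = study_id, arm = arm, endpoint = endpoint,
         platform = platform, tissue = tissue,
         sample_size = sample_size, cpg_hits = cpg_hits, dmrs = dmrs,
         gene_hits = gene_hits, log = log),
    class = "epimeet_study")
}

#' @export
print.epimeet_study <- function(x, ...) {
  cat(sprintf("<epimeet_study> %s [%s, %s] endpoint=%s\n", x$study_id,
              x$arm, x$platform, x$endpoint))
  cat(sprintf("  %d CpG hits (%d non-cg), %d DMRs, %d gene hits\n",
              nrow(x$cpg_hits), sum(!x$cpg_hits$is_cpg), nrow(x$dmrs),
              nrow(x$gene_hits)))
  drops <- unlist(x$log)
  if (length(drops)) {
    cat("  log:", paste(names(drops), drops, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Load one study's hit lists into a validated record
#'
#' Reads the CpG, DMR and gene hit-list files named by a study
#' descriptor, validates and deduplicates them, and returns a uniform
#' study record. Files are tab- or comma-separated with a header row;
#' column names can be remapped through the descriptor. Duplicate
#' identifiers are removed silently with a logged count (extracted
#' supplementary tables commonly repeat rows); invalid probe identifiers
#' (e.g. `rs` SNP probes) are dropped and counted. Non-`cg` (`ch`)
#' probes are retained with `is_cpg = FALSE` and are excluded from
#' CpG-level overlap sets downstream.
#'
#' @param descriptor A list with fields `id`, `arm` (`"exposure"` or
#'   `"outcome"`), `platform` (`"HM450"` or `"EPIC"`), and at least one
#'   of `cpg_file`, `dmr_file`, `gene_file`; optional `endpoint`,
#'   `tissue`, `n` (sample size), `bed` (logical: DMR file uses 0-based
#'   half-open coordinates), and column mappings `cpg_cols`,
#'   `gene_cols`, `dmr_cols` (named lists, e.g.
#'   `list(probe_id = "cpg")`).
#' @param base_dir Directory that relative file paths are resolved
#'   against.
#' @return An object of class `epimeet_study` with components
#'   `cpg_hits` (probe_id, effect, source, is_cpg), `dmrs` (chrom,
#'   start, end, direction; 1-based closed intervals), `gene_hits`
#'   (symbol, effect) and a `log` of dropped/duplicated counts.
#' @export
load_study <- function(descriptor, base_dir = ".") {
  d <- descriptor
  if (is.null(d$id)) stop("study descriptor needs an 'id'", call. = FALSE)
  if (is.null(d$cpg_file) && is.null(d$dmr_file) && is.null(d$gene_file)) {
    stop("study '", d$id, "': descriptor names no hit-list file",
         call. = FALSE)
  }
  resolve <- function(p) {
    if (is.null(p)) NULL
    else if (file.exists(p)) p
    else file.path(base_dir, p)
  }
  log <- list()
  cpg_hits <- NULL
  if (!is.null(d$cpg_file)) {
    path <- resolve(d$cpg_file)
    df <- read_delim_auto(path)
    ids <- as.character(pick_col(df, "probe_id", d$cpg_cols, path))
    if (anyNA(ids) || any(!nzchar(ids))) {
      stop("missing probe_id at line ",
           which(is.na(ids) | !nzchar(ids))[1L] + 1L, " of ", path,
           call. = FALSE)
    }
    eff <- parse_effect(pick_col(df, "effect", d$cpg_cols, path,
                                 required = FALSE), path)
    v <- validate_probe_id(ids)
    log$cpg_invalid <- sum(!v$accepted)
    keep <- v$accepted
    ids <- ids[keep]
    eff <- if (is.null(eff)) rep(NA_real_, length(ids)) else eff[keep]
    dup <- duplicated(ids)
    log$cpg_duplicates <- sum(dup)
    cpg_hits <- data.frame(probe_id = ids[!dup], effect = eff[!dup],
                           source = "dmp",
                           is_cpg = startsWith(ids[!dup], "cg"),
                           stringsAsFactors = FALSE)
  }
  dmrs <- NULL
  if (!is.null(d$dmr_file)) {
    path <- resolve(d$dmr_file)
    df <- read_delim_auto(path)
    chrom <- as.character(pick_col(df, "chrom", d$dmr_cols, path))
    start <- suppressWarnings(as.integer(pick_col(df, "start", d$dmr_cols,
                                                  path)))
    end <- suppressWarnings(as.integer(pick_col(df, "end", d$dmr_cols,
                                                path)))
    bad <- which(is.na(start) | is.na(end) | !nzchar(chrom))
    if (length(bad)) {
      stop("unparseable DMR row at line ", bad[1L] + 1L, " of ", path,
           call. = FALSE)
    }
    if (isTRUE(d$bed)) start <- start + 1L  # 0-based half-open -> 1-based closed
    if (any(start > end)) {
      stop("DMR start > end at line ", which(start > end)[1L] + 1L,
           " of ", path, call. = FALSE)
    }
    dir <- pick_col(df, "direction", d$dmr_cols, path, required = FALSE)
    dir <- if (is.null(dir)) rep(NA_character_, length(chrom)) else {
      dir <- tolower(as.character(dir))
      dir[!dir %in% c("hyper", "hypo")] <- NA_character_
      dir
    }
    dmrs <- data.frame(chrom = chrom, start = start, end = end,
                       direction = dir, stringsAsFactors = FALSE)
  }
  gene_hits <- NULL
  if (!is.null(d$gene_file)) {
    path <- resolve(d$gene_file)
    df <- read_delim_auto(path)
    rawsym <- as.character(pick_col(df, "symbol", d$gene_cols, path))
    eff <- parse_effect(pick_col(df, "effect", d$gene_cols, path,
                                 required = FALSE), path)
    if (is.null(eff)) eff <- rep(NA_real_, length(rawsym))
    # one raw row may carry several ;-separated symbols
    per_row <- lapply(rawsym, normalize_gene_symbol)
    sym <- unlist(per_row, use.names = FALSE)
    eff <- rep(eff, lengths(per_row))
    log$gene_empty <- sum(lengths(per_row) == 0L)
    dup <- duplicated(sym)
    log$gene_duplicates <- sum(dup)
    gene_hits <- data.frame(symbol = sym[!dup], effect = eff[!dup],
                            stringsAsFactors = FALSE)
  }
  rec <- new_study(study_id = d$id, arm = d$arm %||% "exposure",
                   endpoint = d$endpoint %||% NA_character_,
                   platform = d$platform %||% "",
                   tissue = d$tissue %||% NA_character_,
                   sample_size = d$n %||% NA_integer_,
                   cpg_hits = cpg_hits, dmrs = dmrs,
                   gene_hits = gene_hits, log = log)
  dropped <- unlist(log)
  dropped <- dropped[dropped > 0]
  if (length(dropped)) {
    message("study '", d$id, "': ",
            paste(names(dropped), dropped, sep = "=", collapse = ", "))
  }
  rec
}

#' Load a study catalog from a config file or descriptor list
#'
#' The catalog config is a human-editable YAML file with a top-level
#' `studies:` sequence of study descriptors (see [load_study()]); file
#' paths are resolved relative to the config file's directory.
#'
#' @param config Path to a YAML file, or a list of descriptors / a list
#'   with a `studies` element.
#' @param base_dir Base directory for relative paths (defaults to the
#'   config file's directory).
#' @return A named list of `epimeet_study` records; study ids must be
#'   unique.
#' @export
load_catalog <- function(config, base_dir = NULL) {
  if (is.character(config)) {
    base_dir <- base_dir %||% dirname(config)
    config <- yaml::read_yaml(config)
  }
  base_dir <- base_dir %||% "."
  descs <- config$studies %||% config
  recs <- lapply(descs, load_study, base_dir = base_dir)
  ids <- vapply(recs, `[[`, "", "study_id")
  if (anyDuplicated(ids)) {
    stop("duplicate study_id in catalog: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  names(recs) <- ids
  recs
}
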