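#' Load a gene-set collection from a GMT file
#'
#' Standard GMT: one term per line, tab-separated as
#' `term_id <tab> description <tab> gene1 <tab> gene2 ...`. Member
#' symbols are normalized (see [normalize_gene_symbol()]); terms left
#' with no members are dropped with a message.
#'
#' @param path GMT file path.
#' @param category One of `"GO_BP"`, `"GO_CC"`, `"GO_MF"`, `"KEGG"`,
#'   `"custom"`. Determines the significance rule applied by
#'   [significant_terms()].
#' @return A `gene_set_collection`: list with `category` and `terms`
#'   (named list of `list(name =, genes =)`).
#' @export
load_gmt <- function(path, category = c("custom", "GO_BP", "GO_CC",
                                         "GO_MF", "KEGG")) {
  category <- match.arg(category)
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path, call. = FALSE)
    return(structure(list(category = category, terms = list()),
                     class = "gene_set_collection"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 2L)
  if (length(short)) {
    stop("malformed GMT line ", short[1L], " in ", path,
         " (need at least term id and description)", call. = FALSE)
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate term id in ", path, ": ", ids[duplicated(ids)][1L],
         call. = FALSE)
  }
  terms <- lapply(fields, function(f) {
    list(name = f[[2L]],
         genes = normalize_gene_symbol(f[-(1:2)]))
  })
  names(terms) <- ids
  empty <- vapply(terms, function(t) length(t$genes) == 0L, logical(1))
  if (any(empty)) {
    message("load_gmt: dropped ", sum(empty), " empty term(s)")
    terms <- terms[!empty]
  }
  structure(list(category = category, terms = terms),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> [%s] %d term(s), %d distinct gene(s)\n",
              x$category, length(x$terms),
              length(unique(unlist(lapply(x$terms, `[[`, "genes"))))))
  invisible(x)
}

# Internal: all genes annotated to >=1 term of a collection.
collection_genes <- function(collection) {
  sort(unique(unlist(lapply(collection$terms, `[[`, "genes"),
                     use.names = FALSE)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment `q_(i) = min(1, min_{j>=i} m p_(j) / j)` over
#' the sorted p-values, mapped back to input order (delegates to
#' [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same order and length.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation analysis against a gene-set collection
#'
#' For each term, tests whether the query list hits the term more often
#' than random draws from the background would: `p_raw =
#' P(X >= k)` with `X ~ Hypergeometric(N = |background|, K = |term ∩
#' background|, n = |query ∩ background|)`. The query is intersected
#' with the background first (dropped genes are counted); terms with no
#' background member are excluded. BH adjustment is applied across the
#' tested terms of this one run.
#'
#' @param query Character vector of gene symbols (normalized
#'   internally).
#' @param collection A `gene_set_collection`.
#' @param background Either a character vector of background gene
#'   symbols, a single number (fixed background size; term and query
#'   sizes are then used unintersected), or `NULL` to default to all
#'   genes annotated in the collection.
#' @return An `enrichment_result` data.frame sorted by `p_raw` (ties by
#'   term id) with columns `term_id`, `term_name`, `k_hits`, `K_term`,
#'   `n_query`, `N_bg`, `p_raw`, `q_bh`, `hit_genes`
#'   (semicolon-joined, sorted). Attributes: `category`,
#'   `n_query_dropped`, `n_terms_dropped`.
#' @export
ora <- function(query, collection, background = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- normalize_gene_symbol(query)
  if (is.null(background)) background <- collection_genes(collection)
  fixed_n <- is.numeric(background) && length(background) == 1L
  if (fixed_n) {
    N <- as.integer(background)
    if (N <= 0) stop("background size must be positive", call. = FALSE)
    q_in <- query
    n_dropped <- 0L
  } else {
    background <- normalize_gene_symbol(background)
    if (length(background) == 0L) {
      stop("background is empty", call. = FALSE)
    }
    N <- length(background)
    q_in <- intersect(query, background)
    n_dropped <- length(query) - length(q_in)
    if (n_dropped) {
      message("ora: dropped ", n_dropped,
              " query gene(s) outside the background")
    }
  }
  empty <- data.frame(term_id = character(0), term_name = character(0),
                      k_hits = integer(0), K_term = integer(0),
                      n_query = integer(0), N_bg = integer(0),
                      p_raw = numeric(0), q_bh = numeric(0),
                      hit_genes = character(0), stringsAsFactors = FALSE)
  if (length(q_in) == 0L) {
    warning("ora: empty query after background intersection", call. = FALSE)
    out <- empty
    attr(out, "category") <- collection$category
    attr(out, "n_query_dropped") <- n_dropped
    attr(out, "n_terms_dropped") <- 0L
    return(structure(out, class = c("enrichment_result", "data.frame")))
  }
  rows <- lapply(names(collection$terms), function(id) {
    term <- collection$terms[[id]]
    tg <- if (fixed_n) term$genes else intersect(term$genes, background)
    K <- length(tg)
    if (K == 0L) return(NULL)
    hit <- sort(intersect(tg, q_in))
    k <- length(hit)
    data.frame(term_id = id, term_name = term$name, k_hits = k,
               K_term = K, n_query = length(q_in), N_bg = N,
               p_raw = hypergeom_upper_tail(N, K, length(q_in), k),
               hit_genes = paste(hit, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  n_terms_dropped <- sum(vapply(rows, is.null, logical(1)))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    out <- empty
  } else {
    out <- do.call(rbind, rows)
    out$q_bh <- bh_adjust(out$p_raw)
    out <- out[order(out$p_raw, out$term_id),
               c("term_id", "term_name", "k_hits", "K_term", "n_query",
                 "N_bg", "p_raw", "q_bh", "hit_genes")]
    rownames(out) <- NULL
  }
  attr(out, "category") <- collection$category
  attr(out, "n_query_dropped") <- n_dropped
  attr(out, "n_terms_dropped") <- n_terms_dropped
  structure(out, class = c("enrichment_result", "data.frame"))
}

#' Filter enrichment results by the dual significance rule
#'
#' GO categories are filtered on the BH-adjusted value (`q_bh < alpha`);
#' KEGG and custom collections on the raw p-value (`p_raw < alpha`).
#' Both comparisons are strict. Non-significant terms with
#' `p_raw < near_miss` are attached as the `near_miss` attribute so
#' borderline pathways stay visible without changing the rule.
#'
#' @param results An `enrichment_result` (from [ora()]).
#' @param category Overrides the result's category attribute.
#' @param alpha Significance level (default 0.05).
#' @param near_miss Near-miss reporting threshold on `p_raw` (default
#'   0.10).
#' @return The significant subset (same columns), with attribute
#'   `near_miss`.
#' @export
significant_terms <- function(results, category = NULL, alpha = 0.05,
                              near_miss = 0.10) {
  category <- category %||% attr(results, "category") %||% "custom"
  use_bh <- startsWith(category, "GO")
  keep <- if (use_bh) results$q_bh < alpha else results$p_raw < alpha
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  nm <- results[!keep & results$p_raw < near_miss, , drop = FALSE]
  rownames(nm) <- NULL
  attr(out, "category") <- category
  attr(out, "near_miss") <- nm
  out
}

#' Pathway-level overlap between two studies' significant terms
#'
#' Hypergeometric overlap test on the significant term-id sets of two
#' studies, drawn from a universe of `term_universe` testable terms.
#'
#' @param sig_a,sig_b Character vectors of significant term ids.
#' @param term_universe Number of terms in the collection universe
#'   (at least `|sig_a U sig_b|`).
#' @param labels Length-2 labels for the result.
#' @return An `overlap_result` with `level = "pathway"`.
#' @export
pathway_overlap <- function(sig_a, sig_b, term_universe,
                            labels = c("A", "B")) {
  pairwise_overlap(sig_a, sig_b, term_universe, level = "pathway",
                   labels = labels)
}
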