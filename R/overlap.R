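#' Upper-tail hypergeometric probability P(X >= k)
#'
#' Probability of observing at least `k` shared items when sets of sizes
#' `K` and `n` are drawn without replacement from a universe of size
#' `N`: `sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`. Computed in
#' log space — the first term via `lchoose`, subsequent terms by the
#' ratio recurrence `t_{i+1}/t_i = (K-i)(n-i) / ((i+1)(N-K-n+i+1))` —
#' and summed with a log-sum-exp reduction, so the result is stable for
#' universes of millions of probes and absolute error stays below 1e-12.
#' The function is symmetric in `K` and `n`.
#'
#' @param N Universe size.
#' @param K,n Sizes of the two sets (each between 0 and `N`).
#' @param k Observed overlap, between 0 and `min(K, n)`; values at or
#'   below the lower support bound `max(0, K + n - N)` give exactly 1.
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' hypergeom_upper_tail(10, 3, 4, 2)         # 1/3
#' hypergeom_upper_tail(21231, 207, 24, 1)   # ~0.21
hypergeom_upper_tail <- function(N, K, n, k) {
  stopifnot(length(N) == 1L, length(K) == 1L, length(n) == 1L,
            length(k) == 1L)
  if (anyNA(c(N, K, n, k)) ||
      any(c(N, K, n, k) != floor(c(N, K, n, k)))) {
    stop("N, K, n, k must be non-negative integers", call. = FALSE)
  }
  if (K < 0 || n < 0 || K > N || n > N) {
    stop("need 0 <= K, n <= N", call. = FALSE)
  }
  kmax <- min(K, n)
  if (k < 0 || k > kmax) {
    stop("need 0 <= k <= min(K, n)", call. = FALSE)
  }
  kmin <- max(0, K + n - N)
  if (k <= kmin) return(1)
  i <- k:kmax
  lt <- numeric(length(i))
  lt[1L] <- lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n)
  if (length(i) > 1L) {
    j <- i[-length(i)]  # term index i -> i+1
    steps <- log(K - j) + log(n - j) - log(j + 1) - log(N - K - n + j + 1)
    lt[-1L] <- lt[1L] + cumsum(steps)
  }
  m <- max(lt)
  min(1, exp(m) * sum(exp(lt - m)))
}

#' Format a p-value for report display
#'
#' Mixed-precision rendering used in the report tables: `"—"` for
#' untestable (`NA`) entries, `"<0.001"` below 0.0005, two decimals
#' (half-up) at or above 0.10, three decimals otherwise. Machine output
#' always keeps full precision; this only affects display.
#'
#' @param p Numeric vector of p-values (`NA` = untestable).
#' @return Character vector.
#' @export
#' @examples
#' format_p(c(0.2096, 0.0104928, 4e-4, NA))
format_p <- function(p) {
  half_up <- function(x, d) {
    formatC(floor(x * 10^d + 0.5) / 10^d, format = "f", digits = d)
  }
  vapply(p, function(x) {
    if (is.na(x)) "—"
    else if (x < 5e-4) "<0.001"
    else if (x >= 0.10) half_up(x, 2L)
    else half_up(x, 3L)
  }, character(1))
}

#' Pairwise set overlap with hypergeometric tail probability
#'
#' Overlap of two deduplicated identifier sets by exact equality, with
#' the one-sided upper-tail probability of the observed (or larger)
#' overlap under random sampling from a universe of `universe_n`
#' identifiers. Zero-overlap comparisons are marked untestable
#' (`p_upper = NA`) rather than assigned p = 1.
#'
#' @param set_a,set_b Character vectors of identifiers.
#' @param universe_n Universe size; must be at least `|set_a U set_b|`.
#' @param level `"cpg"`, `"gene"` or `"pathway"`.
#' @param labels Length-2 character vector naming the sets.
#' @return An `overlap_result`: list with `level`, `study_a`, `study_b`,
#'   `size_a` (K), `size_b` (n), `overlap_k`, `universe_n` (N),
#'   `p_upper` (NA when untestable), `shared_ids` (sorted) and
#'   `testable`.
#' @export
pairwise_overlap <- function(set_a, set_b, universe_n,
                             level = c("cpg", "gene", "pathway"),
                             labels = c("A", "B")) {
  level <- match.arg(level)
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  union_n <- length(union(set_a, set_b))
  if (universe_n < union_n) {
    stop("universe (", universe_n, ") smaller than the union of the sets (",
         union_n, "): misconfigured universe", call. = FALSE)
  }
  shared <- sort(intersect(set_a, set_b))
  k <- length(shared)
  p <- if (k > 0) {
    hypergeom_upper_tail(universe_n, length(set_a), length(set_b), k)
  } else NA_real_
  structure(
    list(level = level, study_a = labels[1L], study_b = labels[2L],
         size_a = length(set_a), size_b = length(set_b), overlap_k = k,
         universe_n = as.integer(universe_n), p_upper = p,
         shared_ids = shared, testable = k > 0),
    class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> [%s] %s (K=%d) vs %s (n=%d), N=%d: k=%d, p=%s\n",
              x$level, x$study_a, x$size_a, x$study_b, x$size_b,
              x$universe_n, x$overlap_k, format_p(x$p_upper)))
  invisible(x)
}

#' @export
as.data.frame.overlap_result <- function(x, ...) {
  data.frame(level = x$level, study_a = x$study_a, study_b = x$study_b,
             size_a = x$size_a, size_b = x$size_b,
             overlap_k = x$overlap_k, universe_n = x$universe_n,
             p_upper = x$p_upper, testable = x$testable,
             shared_ids = paste(x$shared_ids, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Venn decomposition of two or three labeled sets
#'
#' Counts every elementary (exclusive) region of a 2- or 3-set Venn
#' diagram. Region names join the labels of the sets an element belongs
#' to with `&`. Region counts sum to the size of the union, and the
#' pairwise margins agree with [pairwise_overlap()].
#'
#' @param sets Named list of 2 or 3 character vectors (distinct names).
#' @return A `venn_decomposition`: list with `labels`, `regions` (named
#'   integer vector over all 2^m - 1 regions) and `members` (named list
#'   of sorted ids per region).
#' @export
#' @examples
#' multiway_venn(list(A = c("x", "y"), B = c("y", "z"), C = "z"))$regions
multiway_venn <- function(sets) {
  m <- length(sets)
  if (m < 2L || m > 3L) {
    stop("multiway_venn supports 2 or 3 sets, got ", m, call. = FALSE)
  }
  labels <- names(sets)
  if (is.null(labels) || anyDuplicated(labels) || any(!nzchar(labels))) {
    stop("sets must carry distinct non-empty names", call. = FALSE)
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  key <- apply(member, 1L, function(row) {
    paste(labels[row], collapse = "&")
  })
  region_names <- unlist(lapply(seq_len(m), function(sz) {
    utils::combn(labels, sz, FUN = paste, collapse = "&")
  }))
  counts <- table(factor(key, levels = region_names))
  members <- split(universe, factor(key, levels = region_names))
  structure(list(labels = labels,
                 regions = stats::setNames(as.integer(counts), region_names),
                 members = members),
            class = "venn_decomposition")
}

#' @export
print.venn_decomposition <- function(x, ...) {
  cat("<venn_decomposition>", paste(x$labels, collapse = ", "), "\n")
  for (r in names(x$regions)) {
    cat(sprintf("  %-12s %d\n", r, x$regions[[r]]))
  }
  invisible(x)
}

#' Effect-direction concordance over shared identifiers
#'
#' Labels each shared identifier `concordant` when both studies report
#' a finite non-zero effect of the same sign, `discordant` for opposite
#' signs, and `unknown` when either effect is missing or zero.
#'
#' @param shared Character vector of identifiers.
#' @param effects_a,effects_b Named numeric vectors (names are
#'   identifiers; e.g. regression coefficients, or +/-1 for a reported
#'   hyper-/hypomethylation direction).
#' @return Named character vector over `shared`.
#' @export
#' @examples
#' effect_concordance("HOXA4", c(HOXA4 = 0.08), c(HOXA4 = -0.016))
effect_concordance <- function(shared, effects_a, effects_b) {
  shared <- as.character(shared)
  a <- unname(effects_a[shared])
  b <- unname(effects_b[shared])
  lab <- rep("unknown", length(shared))
  both <- !is.na(a) & !is.na(b) & is.finite(a) & is.finite(b) &
    a != 0 & b != 0
  lab[both & sign(a) == sign(b)] <- "concordant"
  lab[both & sign(a) != sign(b)] <- "discordant"
  stats::setNames(lab, shared)
}
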