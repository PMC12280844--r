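---
title: "Meet-in-the-middle integration of EWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meet-in-the-middle integration of EWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimeet)
```

## The problem

A meet-in-the-middle design links an exposure to a clinical outcome
through molecular intermediates: if an exposure (say, folate status)
perturbs DNA methylation at certain CpG sites, and methylation at those
same sites associates with an outcome (say, a chemotherapy-induced
toxicity such as hand–foot syndrome), the shared sites are candidate
mechanistic links. Individual epigenome-wide association studies
(EWAS) publish only summary-level hit lists — differentially
methylated positions (DMPs), differentially methylated regions (DMRs),
and the gene symbols they annotate to — on either the Illumina 450K or
EPIC array. `epimeet` integrates such lists: it normalizes them into a
catalog, expands DMRs to their member probes against an array
manifest, and asks, for every exposure-by-outcome pair of lists,
whether they share more identifiers than chance sampling from a common
probe (or gene) universe would produce.

## The statistical model

Two deduplicated hit lists of sizes $K$ and $n$, drawn from a universe
of $N$ identifiers, share an overlap count
$X \sim \mathrm{Hypergeometric}(N, K, n)$ under the null of
independent lists. The reported quantity is the one-sided upper tail

$$P(X \ge k) \;=\; \sum_{i=k}^{\min(K,n)}
\frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

computed by `hypergeom_upper_tail()`. The convention is $P(X \ge k)$,
not $P(X > k)$ and not a two-sided test: recomputation of published
integration results is consistent only with this choice, and it is
fixed throughout the package. Comparisons with zero overlap are
reported *untestable* (rendered "—"), never assigned $p = 1$: a
zero-overlap cell carries no evidence for or against enrichment under
this one-sided convention. No multiple-testing correction is applied
across the pairwise comparisons; each is judged at a fixed
$\alpha = 0.05$, which mirrors how such integrative screens are
conventionally reported. The full-precision p-values are always kept
in machine output.

### The universe rule

$N$ is chosen by a *minimum-array* rule: the smallest post-QC probe
count among the platforms involved in a comparison, because a probe
absent from the smaller array can never be observed in both lists.
The shipped defaults are the published post-QC constants —

```{r}
default_universe()
```

— overridable per platform, or derivable from a loaded manifest with
`manifest_universe()` (used with simulated data, where the manifest is
the ground truth). Gene-level tests use the corresponding annotated
RefSeq symbol counts. Choosing a universe smaller than the union of
the two lists is rejected as a misconfiguration rather than silently
truncated.

### Numerical behaviour

The tail sum is evaluated in log space: the first term through
`lchoose`, subsequent terms through the ratio recurrence
$t_{i+1}/t_i = (K-i)(n-i)/\big((i+1)(N-K-n+i+1)\big)$, reduced with
log-sum-exp. This keeps absolute error below $10^{-12}$ for universes
up to $10^6$, verified in the test suite against `stats::phyper` and
against exhaustive enumeration of all parameter combinations with
$N \le 12$. Values of $k$ at or below the lower support bound
$\max(0, K+n-N)$ return exactly 1; the result is clamped to $[0, 1]$.

## From DMRs to probes and genes

DMR coordinates are 1-based and closed on both ends, matching hg19
annotation conventions; a `bed` flag on the reader converts 0-based
half-open inputs. Expansion queries the manifest's probe positions
with GenomicRanges interval overlap, filters by platform membership,
and deduplicates across overlapping DMRs. Probes are treated as point
features and strand is ignored. A DMR direction (`hyper`/`hypo`)
propagates to a $\pm 1$ effect sign on the derived probes; probes
covered by DMRs of opposing direction get `NA`. Because source studies
apply unknown probe-level QC, expansion against a full manifest can
re-extract probes a study had excluded; `redundancy_rate()` reports
the excess relative to a declared count, and the run log counts every
dropped, duplicated or unmapped identifier — no silent data loss.

Gene lists are the union of manifest annotations over a study's
probes (multi-gene probes contribute every symbol), merged with any
explicitly published gene list. Symbols are upper-cased, trimmed,
semicolon-split and deduplicated; `ch` (non-CpG) probes are retained
in the catalog but excluded from CpG-level overlap sets, since the
integration reasons about CpG sites.

## Enrichment and pathway-level overlap

`ora()` is a plain hypergeometric over-representation test of a gene
list against a GMT collection. The default background is every gene
annotated to at least one term of the collection, intersected with the
platform's annotated genes when a manifest is available; it can be
fixed to a constant. This choice is deliberately explicit because
hosted enrichment services use unpublished internal backgrounds, which
makes their exact term lists unreproducible — only the downstream
overlap logic is. Significance follows a dual rule: GO categories on
the Benjamini–Hochberg adjusted value ($q < 0.05$, strict), KEGG and
custom collections on the raw $p < 0.05$. BH is applied within one
(study, collection) run, never pooled across studies. Non-significant
terms with $p < 0.10$ are attached as a near-miss log so borderline
pathways stay visible without changing the rule.

Significant term sets are themselves overlap-tested between study
arms with the same hypergeometric machinery; the default term
universe is the number of terms with at least one background gene,
configurable because published pathway-overlap tables rarely state
the universe they used. `tally_pathway_events()` summarizes the
commonality map (pathway → outcome hit lists it is shared with) into
a total event count and a distinct-pathway count.

## The orchestrator

`run_all()` ties the modules together deterministically: load catalog
and manifest, expand, derive genes, test every exposure × outcome pair
at CpG and gene level, additionally test within-arm pairs (all
exposure pairs; outcome pairs sharing an endpoint, i.e. profiles of
the same toxicity from different studies), decompose 2–3 list groups
into Venn regions, run enrichment and pathway overlap, and emit
report tables. Each toxicity endpoint within a multi-endpoint study is
its own outcome hit list (its own catalog record), matching how such
results are tabulated. Display rounding is mixed-precision ("—" for
untestable, `<0.001` below 0.0005, two decimals at or above 0.10,
half-up, else three); shared identifiers are sorted lexicographically
so machine outputs are byte-deterministic.

## The synthetic-data generator

No raw hit lists are redistributable here, so the generator defines
the study conditions the package is tested under:

* an EPIC-like universe of 7537 probes with a uniformly random
  450K-like subset of exactly 4313 — the published post-QC constants
  scaled by 1/100 so the suite runs in seconds; gene universes scale
  to 212/274 in the same way;
* 274 genes annotated in contiguous probe blocks (mean 25 probes,
  Poisson sizes, occasional multi-gene boundary probes and small
  gaps), probe positions laid out deterministically at 100 bp spacing
  over 5 chromosomes;
* seven hit lists emulating the integration's shape: three exposure
  lists on the 450K-like platform (134, 44 and 20 probes — the
  published 1343/442/204 scaled by 1/10) and four outcome lists on the
  EPIC-like platform (368 and 1376 for one endpoint, 288 and 509 for
  another);
* a planted overlap of exactly 17 probes between the first and third
  exposure lists, the integration's headline region.

Draws are without replacement everywhere. A single root seed drives
per-study substreams (hashed from the study id), so adding a study
never perturbs earlier studies' lists. In exact-`k` mode the
non-planted fill of a pair excludes every planted id and the
partner's already-drawn hits, which makes closed-loop recovery exact:
the pipeline must report the planted count, not approximately it. In
`rho` mode, fills are independent and an extra
$\mathrm{Poisson}((\rho-1)Kn/N)$ shared ids are planted, so the
expected overlap is about $\rho$ times the null expectation and
$\rho = 1$ is the pure null — used by `null_calibration()`, which
verifies the test holds its level (the statistic is discrete, hence
conservative). DMRs are emitted over maximal runs of consecutive
same-platform truth probes, capped at 10 probes, so expansion plus
the explicit rows reconstructs the truth set exactly.

What the generator does **not** emulate: co-methylation correlation
between neighbouring probes, realistic effect-size distributions,
array chemistry or β-values, probe-level QC differences between
cohorts, and gene-length biases in annotation. Passing tests
therefore demonstrate the correctness of the set arithmetic, the
statistic and the plumbing under idealized sampling — not that the
biological signal in any real pair of cohorts would replicate.

## Problem sizes and runtime choices

The test suite runs the enumeration oracle over all $N \le 12$
(≈3000 cases), null calibration at 2000 replicates on the scaled
universe ($N = 4313$, $K = 130$, $n = 280$), and 20 consecutive seeds
of the closed-loop recovery; the whole suite completes in well under
a minute on one core. These sizes were chosen so that Monte-Carlo
standard errors are small relative to the asserted bounds
($3\sqrt{\alpha(1-\alpha)/2000} \approx 0.015$ at $\alpha = 0.05$)
while iteration stays fast.

## Known limitations

* Identifier-based matching only: no liftover between genome builds,
  no probe QC masks, no gene-ID mapping beyond symbol normalization.
* The hypergeometric null assumes uniform sampling of probes; probe
  density varies across genes and regions in real arrays, which an
  identifier-level integration cannot correct for.
* Venn decompositions support at most three sets.
* Enrichment is a plain hypergeometric ORA; modified statistics used
  by hosted services (e.g. EASE-adjusted counts) will rank borderline
  terms differently on identical inputs.
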