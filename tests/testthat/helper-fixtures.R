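# Shared fixtures, all built in code at test time.

# A small hand-written manifest: two chromosomes, mixed platform
# membership, multi-gene and unannotated probes.
tiny_manifest_df <- function() {
  data.frame(
    probe_id = sprintf("cg%08d", 1:8),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2", "chr2",
              "chr2"),
    pos = c(100L, 150L, 200L, 300L, 50L, 120L, 180L, 400L),
    strand = c("+", "-", "+", "+", "-", "+", "-", "+"),
    gene_symbols = c("GENEA", "GENEA", "GENEA;GENEB", "GENEB", "",
                     "genec", "GENEC", "GENED"),
    on_450k = c(1L, 1L, 1L, 0L, 1L, 1L, 0L, 1L),
    on_epic = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
    stringsAsFactors = FALSE)
}

tiny_manifest <- function() load_manifest(tiny_manifest_df())

# Write a delimited hit-list file and return its path.
write_tsv_fixture <- function(df, dir = tempdir()) {
  path <- tempfile(tmpdir = dir, fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

write_lines_fixture <- function(lines, dir = tempdir(), ext = ".txt") {
  path <- tempfile(tmpdir = dir, fileext = ext)
  writeLines(lines, path)
  path
}

# Exhaustive-enumeration oracle for the upper-tail overlap probability:
# for a universe 1..N with special items 1..K, enumerate every n-subset
# and count those containing at least k specials.
enum_upper_tail <- function(N, K, n, k) {
  if (n == 0L) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)
  mean(hits >= k)
}

# A 4-term collection over a 20-gene background, used across
# enrichment tests.
tiny_collection <- function(category = "custom") {
  lines <- c(
    "T1\tfirst term\tg1\tg2\tg3\tg4\tg5",
    "T2\tsecond term\tg6\tg7\tg8",
    "T3\tthird term\tg1\tg9\tg10\tg11",
    "T4\tfourth term\tg12\tg13")
  load_gmt(write_lines_fixture(lines, ext = ".gmt"), category = category)
}
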