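# Independent brute-force oracles and fixture builders used across the
# suite. Oracles deliberately avoid the package's own algorithms: region
# algebra is checked against per-base boolean arrays, clustering against an
# O(n^2) transitive closure, empirical p-values against a double loop, and
# PWM scanning against per-position rescoring.

library(data.table)

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- fixtures ----------------------------------------------------------

# The worked example: 10 SNV records at 4 positions (3, 1, 2, 4 records),
# consecutive start gaps of 10 bp <= the 25 bp window.
worked_example_variants <- function(base_pos = 101L, gaps = c(10L, 10L, 10L)) {
  pos <- base_pos + c(0L, cumsum(gaps))
  data.table(
    donor_id = paste0("D", 1:10),
    chrom = "chr1",
    pos1 = rep(pos, c(3L, 1L, 2L, 4L)),
    ref = "G", alt = "A", variant_class = "SNV")
}

random_variants <- function(n, chrom_len = 10000L, n_chroms = 1L,
                            n_donors = 20L) {
  data.table(
    donor_id = sprintf("D%02d", sample.int(n_donors, n, replace = TRUE)),
    chrom = paste0("chr", sample.int(n_chroms, n, replace = TRUE)),
    pos1 = sample.int(chrom_len, n, replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = "N", variant_class = "SNV")[, alt := ifelse(ref == "A", "C", "A")][]
}

random_intervals <- function(n, chrom_len = 10000L, max_len = 500L,
                             chrom = "chr1") {
  start <- sample.int(chrom_len - max_len, n, replace = TRUE) - 1L
  data.table(chrom = chrom, start = start,
             end = start + sample.int(max_len, n, replace = TRUE))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_str <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# ---- per-base region oracle (single toy chromosome) --------------------

base_mask <- function(intervals, chrom_len) {
  mask <- logical(chrom_len)
  if (!is.null(intervals) && nrow(intervals)) {
    for (i in seq_len(nrow(intervals))) {
      mask[(intervals$start[i] + 1L):intervals$end[i]] <- TRUE
    }
  }
  mask
}

region_set_mask <- function(rs, chrom_len) {
  base_mask(as.data.table(rs), chrom_len)
}

# ---- O(n^2) single-linkage chaining oracle -----------------------------
# transitive closure of the pairwise "within window" relation, computed as
# connected components of the full adjacency matrix (igraph) -- entirely
# independent of the package's sort-and-cut algorithm

oracle_clusters <- function(pos, window) {
  adj <- abs(outer(pos, pos, "-")) <= window
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  as.integer(igraph::components(g)$membership)
}

# cluster memberships as a canonical signature: sorted list of sorted
# position multisets
cluster_signature <- function(pos, cluster_id, min_records = 1L) {
  s <- split(pos, cluster_id)
  s <- s[vapply(s, length, 0L) >= min_records]
  unname(sort(vapply(s, function(p) paste(sort(p), collapse = ","), "")))
}

# ---- double-loop empirical p-value oracle ------------------------------

oracle_pvalues <- function(test_scores, null_scores) {
  vapply(test_scores, function(t) mean(null_scores >= t), 0)
}

# ---- naive PWM rescoring oracle ----------------------------------------

oracle_scan_count <- function(seq, pwm, threshold) {
  lo <- pwm_log_odds(pwm)
  L <- ncol(lo)
  score_at_pos <- function(s, j) {
    sub <- strsplit(substr(s, j, j + L - 1L), "")[[1]]
    idx <- match(sub, c("A", "C", "G", "T"))
    if (anyNA(idx)) return(-Inf)
    sum(lo[cbind(idx, seq_len(L))])
  }
  n <- 0L
  for (s in c(seq, revcomp_str(seq))) {
    for (j in seq_len(nchar(s) - L + 1L)) {
      if (score_at_pos(s, j) >= threshold) n <- n + 1L
    }
  }
  n
}

# ---- misc --------------------------------------------------------------

toy_gene_model <- function() {
  # two genes on chr1 (one per strand), one on chr2
  g <- data.table(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    tx_start = c(10000L, 30000L, 5000L),
    tx_end = c(20000L, 40000L, 9000L),
    exons = c("10000-10500,19000-20000", "30000-31000,39500-40000",
              "5000-5200"))
  f <- tempfile(fileext = ".tsv")
  fwrite(g, f, sep = "\t")
  read_gene_model(f)
}
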