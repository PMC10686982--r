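toy_genome <- c(chr1 = "ACGTACGTACGTACGTACGT")

test_that("extract_window anchors the variant at the requested index", {
  w <- extract_window(toy_genome, "chr1", pos1 = 10L, length = 11L,
                      anchor = 6L)
  expect_equal(w$seq, substr(toy_genome[["chr1"]], 5, 15))
  expect_equal(w$variant_offset, 5L)
  expect_equal(w$window_start, 4L)
  expect_equal(substr(w$seq, w$variant_offset + 1L, w$variant_offset + 1L),
               "C")  # base at pos1 = 10

  # 20-bp convention: variant at 1-based position 10
  w20 <- extract_window(toy_genome, "chr1", pos1 = 10L, length = 20L,
                        anchor = 10L)
  expect_equal(w20$variant_offset, 9L)
  expect_equal(nchar(w20$seq), 20L)

  expect_error(extract_window(toy_genome, "chr1", pos1 = 3L, length = 11L,
                              anchor = 6L), "off chromosome")
  expect_error(extract_window(toy_genome, "chr1", pos1 = 18L, length = 11L,
                              anchor = 6L), "off chromosome")
})

test_that("MUT windows substitute the alternate allele with reference checking", {
  w <- extract_window(toy_genome, "chr1", 10L, 11L, 6L, allele = "MUT",
                      ref = "C", alt = "T")
  expect_equal(substr(w$seq, 6, 6), "T")
  wt <- extract_window(toy_genome, "chr1", 10L, 11L, 6L, ref = "C")
  expect_equal(substr(wt$seq, 6, 6), "C")
  expect_error(extract_window(toy_genome, "chr1", 10L, 11L, 6L, ref = "G"),
               "mismatch")
  expect_error(extract_window(toy_genome, "chr1", 10L, 11L, 6L,
                              allele = "MUT", ref = "CC", alt = "C"),
               "length-preserving")
})

test_that("nearest_ets_offset reproduces the promoter-hotspot example on both strands", {
  # wild-type context CCGGAAGGCC; the recurrently mutated base is index 6,
  # the first base 3' of the GGAA core -> offset +4
  r <- nearest_ets_offset("CCGGAAGGCC", variant_offset = 6L)
  expect_equal(r[c("found", "offset", "strand", "motif_start")],
               list(found = TRUE, offset = 4L, strand = "+",
                    motif_start = 2L))
  # same sequence reverse-complemented: identical offset via TTCC
  r2 <- nearest_ets_offset("GGCCTTCCGG", variant_offset = 3L)
  expect_equal(r2$offset, 4L)
  expect_equal(r2$strand, "-")

  expect_false(nearest_ets_offset("ACACACACACA", variant_offset = 5L)$found)
  # inside the core counts as distance 0 -> offsets 0..3
  inside <- nearest_ets_offset("CCGGAAGGCC", variant_offset = 3L)
  expect_true(inside$offset %in% 0:3)
})

test_that("nearest_ets_offset is strand-involutive on random windows", {
  set.seed(41)
  n_checked <- 0L
  for (rep in 1:500) {
    seq <- random_dna(11L)
    v <- sample(0:10, 1)
    a <- nearest_ets_offset(seq, v)
    b <- nearest_ets_offset(revcomp_str(seq), 10L - v)
    expect_equal(a$found, b$found)
    if (a$found) {
      expect_equal(a$offset, b$offset)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 15L)  # the property was actually exercised
})

test_that("offset_histogram tallies found offsets and counts motif-less windows", {
  wins <- list("CCGGAAGGCC", "CCGGAAGGCC", "CCGGAAGGCC", "ACACACACAC")
  h <- offset_histogram(wins, variant_offsets = c(6L, 6L, 6L, 5L))
  expect_equal(h$counts, c("4" = 3L))
  expect_equal(h$n_no_motif, 1L)
  h0 <- offset_histogram(list())
  expect_equal(length(h0$counts), 0L)
})

test_that("consensus_counts aligns the first G of GGAA at position 5", {
  win <- structure(list(chrom = "chr1", window_start = 0L,
                        seq = "CCGGAAGGCCA", variant_offset = 6L,
                        allele = "WT"), class = "seq_window")
  m <- consensus_counts(list(win), align_G_at = 5L)
  expect_equal(dim(m), c(4L, 11L))
  expect_equal(unname(m["G", 5]), 1L)
  expect_equal(unname(m["G", 6]), 1L)
  expect_equal(unname(m["A", 7]), 1L)
  expect_equal(unname(m["A", 8]), 1L)
  m2 <- consensus_counts(list(win, win), align_G_at = 5L)
  expect_equal(m2, 2L * m)                 # linearity
  expect_true(all(colSums(m2) <= 2L))      # conservation
})

test_that("consensus-derived PWMs have the stated shape and self-score", {
  pwm <- pwm_from_consensus("CCGGAAGGCC")
  expect_equal(ncol(pwm$probs), 10L)
  expect_equal(unname(colSums(pwm$probs)), rep(1, 10), tolerance = 1e-12)
  expect_equal(rownames(pwm$probs)[apply(pwm$probs, 2, which.max)],
               strsplit("CCGGAAGGCC", "")[[1]])
  expect_equal(pwm_self_score(pwm), 10 * log2(0.997 / 0.25),
               tolerance = 1e-12)
  expect_error(pwm_from_consensus("CCGGAANGCC"), "ambiguity")

  # the four mutant 10-mers build equally well
  for (cons in c("CCAGAAGGCC", "CCGGAAAGCC", "CCGGAAGACC", "CCGGAAAACC")) {
    p <- pwm_from_consensus(cons)
    expect_equal(p$consensus, cons)
    expect_equal(pwm_self_score(p), 10 * log2(0.997 / 0.25),
                 tolerance = 1e-12)
  }
})

test_that("scan_pwm finds planted consensus occurrences on both strands", {
  pwm <- pwm_from_consensus("CCGGAAGGCC")
  set.seed(42)
  left <- "ATATATATATATATATAT"; right <- "TATATATATATATATATA"
  fwd <- paste0(left, "CCGGAAGGCC", right)
  genome <- c(chrF = fwd, chrR = revcomp_str(fwd))
  regions <- data.table(chrom = c("chrF", "chrR"), start = 0L,
                        end = nchar(fwd))

  hits <- scan_pwm(pwm, regions, genome)
  expect_equal(nrow(hits), 2L)
  f <- hits[chrom == "chrF"]
  expect_equal(list(f$start, f$end, f$strand), list(18L, 28L, "+"))
  r <- hits[chrom == "chrR"]
  expect_equal(r$strand, "-")
  expect_equal(r$start, nchar(fwd) - 28L)  # mirrored coordinates
  expect_equal(f$score, pwm_self_score(pwm))

  # threshold above the self-score -> nothing
  expect_equal(nrow(scan_pwm(pwm, regions, genome,
                             threshold_bits = pwm_self_score(pwm) + 0.1)),
               0L)
})

test_that("scan_pwm hit counts equal the naive rescoring oracle", {
  set.seed(43)
  pwm <- pwm_from_consensus("GGAA", p_consensus = 0.7)
  for (rep in 1:10) {
    seq <- random_dna(300L)
    thr <- runif(1, 0, pwm_self_score(pwm))
    hits <- scan_pwm(pwm, data.table(chrom = "c", start = 0L, end = 300L),
                     c(c = seq), threshold_bits = thr)
    expect_equal(nrow(hits), oracle_scan_count(seq, pwm, thr))
    if (nrow(hits)) {
      expect_lte(max(hits$score), pwm_self_score(pwm))  # self-score maximal
    }
  }
})

test_that("scan_pwm down-samples deterministically at max_instances", {
  pwm <- pwm_from_consensus("GG", p_consensus = 0.6)
  seq <- strrep("G", 200L)
  reg <- data.table(chrom = "c", start = 0L, end = 200L)
  all_hits <- scan_pwm(pwm, reg, c(c = seq), threshold_bits = 0)
  expect_gt(nrow(all_hits), 50L)
  s1 <- scan_pwm(pwm, reg, c(c = seq), threshold_bits = 0,
                 max_instances = 50L, seed = 9L)
  s2 <- scan_pwm(pwm, reg, c(c = seq), threshold_bits = 0,
                 max_instances = 50L, seed = 9L)
  expect_equal(nrow(s1), 50L)
  expect_equal(s1, s2)
})
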