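small_cfg <- function(seed = 101L, ...) {
  sim_config(genome_length = 3e4, n_donors = 20L, n_planted = 3L,
             seed = seed, ...)
}

test_that("all generators are deterministic under a fixed seed", {
  cfg <- small_cfg()
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$genome, b$genome)
  expect_equal(as.data.table(a$pmrr), as.data.table(b$pmrr))
  expect_equal(as.data.frame(a$track), as.data.frame(b$track))
  expect_equal(as.data.frame(a$variants), as.data.frame(b$variants))
  expect_equal(as.data.frame(a$truth), as.data.frame(b$truth))
  # and a different seed gives a different world
  c <- simulate_genome(small_cfg(seed = 102L))
  expect_false(identical(a$genome, c))
})

test_that("simulated genomes respect the configured GC content", {
  g1 <- simulate_genome(sim_config(genome_length = 5e4, gc = 1,
                                   n_planted = 0L, seed = 1L))
  expect_false(grepl("[AT]", g1[["chr1"]]))

  cfg <- sim_config(genome_length = 1e5, gc = 0.41, n_planted = 0L,
                    seed = 2L)
  g <- simulate_genome(cfg)
  obs <- mean(strsplit(g[["chr1"]], "")[[1]] %in% c("G", "C"))
  se <- sqrt(0.41 * 0.59 / 1e5)
  expect_lt(abs(obs - 0.41), 3 * se)

  # GGAA written at embed_ets anchors
  cfg2 <- sim_config(genome_length = 3e4, gc = 1, n_planted = 2L,
                     embed_ets = TRUE, seed = 3L)
  g2 <- simulate_genome(cfg2)
  for (p in cfg2$planted) {
    a <- min(p$positions)
    expect_equal(substr(g2[[p$chrom]], a, a + 3L), "GGAA")
  }
})

test_that("simulated regions hit the coverage target and contain planted spans", {
  cfg <- sim_config(genome_length = 1e5, seed = 5L)
  r <- simulate_regions(cfg)
  covered <- total_bases(r$pmrr)
  expect_gte(covered, 11000)
  expect_lte(covered, 13000)
  expect_equal(genome_fraction(r$pmrr, cfg$chrom_lengths), 0.12,
               tolerance = 0.01 / 0.12)
  spans <- data.table(
    chrom = vapply(cfg$planted, `[[`, "", "chrom"),
    start = vapply(cfg$planted, function(p) min(p$positions) - 1L, 0L),
    end = vapply(cfg$planted, function(p) max(p$positions), 0L))
  expect_true(all(region_overlaps(r$pmrr, spans)))
  # exons/blacklist are disjoint from the regulatory set and planted spans
  expect_equal(total_bases(region_subtract(r$exons, r$pmrr)),
               total_bases(r$exons))
  expect_false(any(region_overlaps(r$exons, spans)))
  expect_false(any(region_overlaps(r$blacklist, spans)))
  # infeasible fraction errors
  expect_error(simulate_regions(sim_config(genome_length = 1000,
                                           pmrr_fraction = 0.05,
                                           n_planted = 0L, seed = 1L)))
})

test_that("score track has the configured inside/outside fold", {
  cfg <- sim_config(genome_length = 1e5, seed = 6L)
  r <- simulate_regions(cfg)
  tr <- simulate_score_track(cfg, r$pmrr)
  expect_true(all(tr$score >= 0))
  mids <- tr[, .(chrom, start = as.integer(floor((start + end) / 2)))]
  mids[, end := start + 1L]
  inside <- region_overlaps(r$pmrr, mids)
  w <- tr$end - tr$start
  m_in <- sum(tr$score[inside] * w[inside]) / sum(w[inside])
  m_out <- sum(tr$score[!inside] * w[!inside]) / sum(w[!inside])
  expect_gt(sum(w[inside]), 1e4)
  expect_gt(sum(w[!inside]), 1e4)
  expect_lt(abs(m_in / m_out - 6.7), 0.15 * 6.7)

  # fold 1: the two sides are statistically indistinguishable
  cfg1 <- sim_config(genome_length = 1e5, funseq_fold_in = 1, seed = 7L)
  r1 <- simulate_regions(cfg1)
  tr1 <- simulate_score_track(cfg1, r1$pmrr)
  mids1 <- tr1[, .(chrom, start = as.integer(floor((start + end) / 2)))]
  mids1[, end := start + 1L]
  in1 <- region_overlaps(r1$pmrr, mids1)
  expect_gt(stats::t.test(tr1$score[in1], tr1$score[!in1])$p.value, 0.01)
})

test_that("planted-only worlds reproduce the worked example end to end", {
  planted <- list(list(chrom = "chr1", positions = c(101L, 111L, 121L, 131L),
                       counts = c(3L, 1L, 2L, 4L), embed_ets = FALSE))
  cfg <- sim_config(genome_length = 1e4, n_donors = 20L,
                    background_rate = 0, planted = planted, seed = 8L)
  sv <- simulate_variants(cfg, simulate_genome(cfg))
  expect_equal(nrow(sv$variants), 10L)
  expect_equal(sv$truth$D_expected, 10L)
  h <- merge_variants(sv$variants)
  expect_equal(as.data.frame(h[, .(D, G, donor_score)]),
               data.frame(D = 10L, G = 4L, donor_score = 25))
  # distinct donors at each position
  v <- sv$variants
  expect_true(all(v[, uniqueN(donor_id), by = pos1]$V1 ==
                    v[, .N, by = pos1]$N))

  # no plants, no background -> empty table
  cfg0 <- sim_config(genome_length = 1e4, background_rate = 0,
                     n_planted = 0L, seed = 9L)
  expect_equal(nrow(simulate_variants(cfg0, simulate_genome(cfg0))$variants),
               0L)

  # more donors required than the cohort has -> error
  cfg_bad <- sim_config(genome_length = 1e4, n_donors = 3L,
                        background_rate = 0, seed = 10L,
                        planted = list(list(chrom = "chr1",
                                            positions = 500L, counts = 5L)))
  expect_error(simulate_variants(cfg_bad, simulate_genome(cfg_bad)),
               "cohort")
})

test_that("background-only counts follow the binomial expectation", {
  cfg <- sim_config(genome_length = 5e4, n_donors = 50L,
                    background_rate = 2e-4, n_planted = 0L, seed = 11L)
  v <- simulate_variants(cfg, simulate_genome(cfg))$variants
  n_trials <- cfg$genome_length * cfg$n_donors
  expected <- n_trials * cfg$background_rate
  se <- sqrt(expected * (1 - cfg$background_rate))
  expect_lt(abs(nrow(v) - expected), 3 * se)
  expect_true(all(v$ref != v$alt))
  # deterministic truth spans are disjoint in every config
  cfg2 <- sim_config(seed = 12L)
  tr <- simulate_variants(cfg2, simulate_genome(cfg2))$truth
  setorder(tr, chrom, start)
  expect_true(all(tr[, start[-1L] >= end[-.N], by = chrom]$V1))
})

test_that("simulate_dataset writes the full plain-text file layout", {
  cfg <- small_cfg()
  dir <- file.path(tempdir(), "simout")
  sim <- simulate_dataset(cfg, outdir = dir)
  files <- c("genome.fa", "pmrr.bed", "exons.bed", "blacklist.bed",
             "funseq.bed", "variants.tsv", "truth.json")
  expect_true(all(file.exists(file.path(dir, files))))
  v <- read_variants(file.path(dir, "variants.tsv"), "ssm_tsv")
  expect_equal(nrow(v), nrow(sim$variants))
  g <- read_genome(file.path(dir, "genome.fa"))
  expect_equal(as.character(g[["chr1"]]), sim$genome[["chr1"]])
  tr <- read_score_track(file.path(dir, "funseq.bed"))
  expect_equal(as.data.frame(tr), as.data.frame(sim$track))
  truth <- data.table::as.data.table(
    jsonlite::fromJSON(file.path(dir, "truth.json")))
  expect_equal(truth$start, sim$truth$start)
})
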