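test_that("ssm_tsv dialect parses records, classifies alleles, keeps chroms verbatim", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "donor_id\tchrom\tpos1\tref\talt\tfunseq\tgerp",
    "D1\tchr1\t43824528\tG\tA\t1.2\t3.1",
    "D2\tchr1\t43824528\tGG\tAA\t0.8\tNA",
    "D3\t17\t100\tA\tAT\t0\t0",
    "D4\tchrX\t200\tACG\tA\t0\t0"), f)
  v <- read_variants(f, "ssm_tsv")
  expect_equal(nrow(v), 4L)
  expect_equal(v$variant_class, c("SNV", "MNV", "INS", "DEL"))
  expect_equal(v$pos1[1], 43824528L)
  expect_equal(v[2, .(donor_id, pos1, ref, alt)],
               data.table(donor_id = "D2", pos1 = 43824528L,
                          ref = "GG", alt = "AA"))
  expect_equal(v$chrom, c("chr1", "chr1", "17", "chrX"))  # verbatim
  expect_equal(v$funseq, c(1.2, 0.8, 0, 0))
})

test_that("ssm_tsv accepts ICGC header synonyms and empty bodies", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(paste("icgc_donor_id", "chromosome", "chromosome_start",
                     "reference_genome_allele", "mutated_to_allele",
                     sep = "\t"),
               "DO1\tchr2\t55\tC\tT"), f)
  v <- read_variants(f, "ssm_tsv")
  expect_equal(v$donor_id, "DO1")
  expect_equal(v$pos1, 55L)

  f2 <- tempfile(fileext = ".tsv")
  writeLines("donor_id\tchrom\tpos1\tref\talt", f2)
  expect_equal(nrow(read_variants(f2, "ssm_tsv")), 0L)
})

test_that("malformed variant rows error with their line number", {
  mk <- function(row) {
    f <- tempfile(fileext = ".tsv")
    writeLines(c("donor_id\tchrom\tpos1\tref\talt", "D1\tchr1\t10\tG\tA", row),
               f)
    f
  }
  expect_error(read_variants(mk("D2\tchr1\t0\tG\tA"), "ssm_tsv"), "line 3")
  expect_error(read_variants(mk("D2\tchr1\t5\tG\tG"), "ssm_tsv"),
               "line 3.*identical")
  expect_error(read_variants(mk("D2\tchr1\t5\tG\tZ"), "ssm_tsv"), "line 3")
  expect_error(read_variants(tempfile(), "ssm_tsv"), "not found")
  expect_error(read_variants(mk("x"), "bogus"))
})

test_that("vcf dialect splits multi-allelic rows and reads DONOR info", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t101\t.\tG\tA\t.\t.\tDONOR=DX",
    "chr1\t202\t.\tC\tA,T\t.\t.\t."), f)
  v <- read_variants(f, "vcf", donor_id = "fallback")
  expect_equal(nrow(v), 3L)
  expect_equal(v$donor_id, c("DX", "fallback", "fallback"))
  expect_equal(v$pos1, c(101L, 202L, 202L))
  expect_equal(v$alt, c("A", "A", "T"))
  expect_equal(v$variant_class, rep("SNV", 3))
})

test_that("variant footprints follow the 0-based half-open coordinate law", {
  v <- data.table(donor_id = "D", chrom = "c",
                  pos1 = c(100L, 100L, 100L, 100L),
                  ref = c("G", "GG", "A", "ACG"),
                  alt = c("A", "AA", "ATT", "A"),
                  variant_class = c("SNV", "MNV", "INS", "DEL"))
  fp <- variant_footprint(v)
  expect_equal(fp$start0, rep(99L, 4))
  expect_equal(fp$end0, c(100L, 101L, 100L, 102L))
})

test_that("read_bed parses BED3+ and errors with line numbers", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("track name=x", "chr1\t100\t200",
               paste("chr1", 500, 900, "feat", 0, "+", 500, 900, "0",
                     "2", "100,100", "0,300", sep = "\t")), f)
  b <- read_bed(f)
  expect_equal(b, data.table(chrom = c("chr1", "chr1"),
                             start = c(100L, 500L), end = c(200L, 900L)))

  f2 <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t200\t100"), f2)
  expect_error(read_bed(f2), "line 2")
  f3 <- tempfile(fileext = ".bed")
  writeLines("chr1\t100", f3)
  expect_error(read_bed(f3), "line 1")
})

test_that("score tracks look up positions and reject bad input", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t10\t1.5", "chr1\t20\t30\t2.5"), f)
  tr <- read_score_track(f)
  expect_equal(score_at(tr, "chr1", 5), 1.5)      # containment
  expect_equal(score_at(tr, "chr1", 10), 1.5)     # last base of [0,10)
  expect_true(is.na(score_at(tr, "chr1", 15)))    # gap
  expect_true(is.na(score_at(tr, "chr2", 5)))     # other chrom
  expect_equal(score_at(tr, c("chr1", "chr1"), c(25, 11)), c(2.5, NA))

  f2 <- tempfile(); writeLines(c("chr1\t0\t10\t1", "chr1\t5\t15\t1"), f2)
  expect_error(read_score_track(f2), "overlapping")
  f3 <- tempfile(); writeLines("chr1\t0\t10\t-1", f3)
  expect_error(read_score_track(f3), "non-negative")
})

test_that("hotspot tables round-trip and print the worked-example row", {
  v <- worked_example_variants()
  tr <- score_track(data.table(chrom = "chr1", start = 0L, end = 1000L,
                               score = 1.5))
  h <- call_hotspots(v, tr)
  f <- tempfile(fileext = ".tsv")
  write_hotspot_table(h, f)
  expect_match(readLines(f)[2], "10\t4\t25.0\t1.5\t37.5", fixed = TRUE)

  h2 <- read_hotspot_table(f)
  for (col in c("chrom", "start", "end", "D", "G", "donor_score",
                "mean_funseq", "hotspot_score")) {
    expect_equal(h2[[col]], h[[col]], info = col)
  }

  # empty table -> header only, still round-trips
  f0 <- tempfile(fileext = ".tsv")
  write_hotspot_table(h[0], f0)
  expect_equal(length(readLines(f0)), 1L)
  expect_equal(nrow(read_hotspot_table(f0)), 0L)
})

test_that("hotspot and variant tables round-trip on randomized inputs", {
  set.seed(42)
  for (rep in 1:5) {
    v <- random_variants(60)
    v[, funseq := round(runif(.N, 0, 5), 3)]
    f <- tempfile(fileext = ".tsv")
    write_variants(v, f)
    expect_equal(as.data.frame(read_variants(f, "ssm_tsv")),
                 as.data.frame(v))

    tr <- score_track(data.table(chrom = "chr1", start = 0L, end = 10000L,
                                 score = runif(1, 0.1, 3)))
    h <- test_hotspots(assign_compartments(
      call_hotspots(v, tr, min_count = 2L),
      region_set(random_intervals(5), "pMRR")))
    fh <- tempfile(fileext = ".tsv")
    write_hotspot_table(h, fh)
    h2 <- read_hotspot_table(fh)
    for (col in setdiff(names(h2), "variants")) {
      expect_equal(h2[[col]], h[[col]], info = col)
    }
  }
})
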