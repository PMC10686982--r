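#' Configuration of the synthetic benchmark world
#'
#' Describes a self-contained toy dataset emulating the real inputs of the
#' hotspot pipeline: a random genome, regulatory regions covering a fixed
#' genome fraction, a functional-score track elevated inside the
#' regulatory regions, and a multi-donor variant table of independent
#' background mutations plus planted recurrent hotspots. Defaults mirror
#' the melanoma cohort the pipeline was designed around: 183 donors,
#' regulatory regions covering ~12% of the genome, functional scores
#' 6.7-fold higher inside regulatory regions.
#'
#' Planted hotspots are either supplied explicitly or drawn once at
#' configuration time (seeded): `n_planted` hotspots, each with a total
#' record count drawn from `planted_records`, spread over 1--4 positions
#' with inter-position gaps of at most `window` bp so that merging chains
#' them into a single hotspot.
#'
#' @param genome_length Total genome length in bp (default 1e5).
#' @param n_chroms Number of equally sized chromosomes (default 1).
#' @param gc GC content of the background sequence (default 0.41).
#' @param pmrr_fraction Fraction of the genome covered by regulatory
#'   regions (default 0.12).
#' @param n_donors Cohort size (default 183).
#' @param background_rate Per-base per-donor mutation probability. The
#'   default, 3.7e-5, is the density of the melanoma whole-genome cohort
#'   the generator emulates (roughly 2.1e7 substitutions across 183
#'   donors and ~3.1 Gbp).
#' @param funseq_mean_out Mean functional score outside regulatory regions
#'   (default 0.5).
#' @param funseq_fold_in Fold elevation of the mean score inside
#'   regulatory regions (default 6.7).
#' @param n_planted Number of planted hotspots when `planted` is `NULL`
#'   (default 10).
#' @param planted_records Range (min, max) of total records per planted
#'   hotspot (default `c(5, 12)`).
#' @param planted Optional explicit list of planted hotspots; each element
#'   a list with `chrom`, `positions` (1-based, gaps <= `window`),
#'   `counts` (donors per position, total >= 3), `embed_ets` (logical).
#' @param embed_ets Write a GGAA 4-mer at each auto-generated planted
#'   hotspot anchor (default `FALSE`).
#' @param window Merge window the benchmark is built for (default 25).
#' @param score_tile Tile width of the simulated score track in bp
#'   (default 25).
#' @param seed Master seed; every generator derives its own stream from
#'   it, so any subset of the generators is reproducible (default 1).
#' @return A `sim_config` object (a list).
#' @export
sim_config <- function(genome_length = 1e5, n_chroms = 1L, gc = 0.41,
                       pmrr_fraction = 0.12, n_donors = 183L,
                       background_rate = 3.7e-5, funseq_mean_out = 0.5,
                       funseq_fold_in = 6.7, n_planted = 10L,
                       planted_records = c(5L, 12L), planted = NULL,
                       embed_ets = FALSE, window = 25L, score_tile = 25L,
                       seed = 1L) {
  stopifnot(genome_length >= 1000, n_chroms >= 1, gc >= 0, gc <= 1,
            pmrr_fraction > 0, pmrr_fraction < 1, n_donors >= 1,
            background_rate >= 0, funseq_mean_out > 0, funseq_fold_in > 0,
            window >= 0)
  per <- floor(genome_length / n_chroms)
  chrom_lengths <- setNames(c(rep(per, n_chroms - 1L),
                              genome_length - per * (n_chroms - 1L)),
                            paste0("chr", seq_len(n_chroms)))
  cfg <- list(genome_length = genome_length, n_chroms = as.integer(n_chroms),
              chrom_lengths = chrom_lengths, gc = gc,
              pmrr_fraction = pmrr_fraction, n_donors = as.integer(n_donors),
              background_rate = background_rate,
              funseq_mean_out = funseq_mean_out,
              funseq_fold_in = funseq_fold_in, window = as.integer(window),
              score_tile = as.integer(score_tile), seed = as.integer(seed))
  if (is.null(planted) && n_planted > 0L) {
    planted <- with_seed(sub_seed(seed, 0L), draw_planted(
      cfg, n_planted, planted_records, embed_ets))
  }
  cfg$planted <- lapply(planted, validate_planted, cfg = cfg)
  structure(cfg, class = "sim_config")
}

#' @noRd
sub_seed <- function(seed, k) (as.integer(seed) %% 1048576L) * 1024L + k

#' @noRd
validate_planted <- function(p, cfg) {
  stopifnot(!is.null(p$chrom), !is.null(p$positions), !is.null(p$counts))
  p$positions <- as.integer(p$positions)
  p$counts <- as.integer(p$counts)
  p$embed_ets <- isTRUE(p$embed_ets)
  if (length(p$positions) != length(p$counts)) {
    stop("planted hotspot: positions and counts differ in length",
         call. = FALSE)
  }
  if (sum(p$counts) < 3L) {
    stop("planted hotspot: total record count must be >= 3", call. = FALSE)
  }
  if (length(p$positions) > 1L &&
      any(diff(sort(p$positions)) > cfg$window)) {
    stop("planted hotspot: inter-position gaps must be <= the merge window",
         call. = FALSE)
  }
  p
}

#' @noRd
draw_planted <- function(cfg, n_planted, planted_records, embed_ets) {
  # anchors well separated so planted hotspots never chain into each other
  margin <- 2000L
  sep <- 2000L
  lens <- cfg$chrom_lengths
  slots <- data.table::rbindlist(lapply(names(lens), function(ch) {
    data.table::data.table(chrom = ch,
      pos = seq(margin, lens[[ch]] - margin, by = sep))
  }))
  if (nrow(slots) < n_planted) {
    stop("genome too small for ", n_planted, " planted hotspots",
         call. = FALSE)
  }
  picks <- slots[sort(sample.int(nrow(slots), n_planted))]
  lapply(seq_len(n_planted), function(i) {
    total <- sample(planted_records[1]:planted_records[2], 1L)
    k <- sample.int(min(4L, total), 1L)
    counts <- as.integer(table(factor(sample.int(k, total, replace = TRUE),
                                      levels = seq_len(k))))
    counts[counts == 0L] <- 1L  # keep every position supported
    gaps <- if (k > 1L) sample(5:cfg$window, k - 1L, replace = TRUE) else
      integer(0)
    list(chrom = picks$chrom[i],
         positions = picks$pos[i] + c(0L, cumsum(gaps)),
         counts = counts, embed_ets = embed_ets)
  })
}

#' Simulate a genome
#'
#' I.i.d. bases at the configured GC content; where a planted hotspot has
#' `embed_ets`, the 4-mer `GGAA` is written starting at its first planted
#' position after generation. Deterministic for a fixed config seed.
#'
#' @param config A [sim_config()].
#' @return Named character vector of chromosome sequences.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(sub_seed(config$seed, 1L), {
    p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
           G = config$gc / 2, T = (1 - config$gc) / 2)
    genome <- vapply(config$chrom_lengths, function(L) {
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
    }, "")
    for (pl in config$planted) {
      if (pl$embed_ets) {
        a <- min(pl$positions)
        substr(genome[[pl$chrom]], a, a + 3L) <- "GGAA"
      }
    }
    genome
  })
}

#' @noRd
place_intervals <- function(occupied, chrom, chrom_len, n, len_fun,
                            gap = 10L, max_tries = 2000L) {
  out <- vector("list", n)
  got <- 0L
  tries <- 0L
  occ <- occupied[occupied$chrom == chrom]
  while (got < n && tries < max_tries) {
    tries <- tries + 1L
    len <- len_fun()
    if (len >= chrom_len) next
    s <- sample.int(chrom_len - len, 1L) - 1L
    e <- s + len
    if (nrow(occ) == 0L || all(e + gap <= occ$start | s >= occ$end + gap)) {
      got <- got + 1L
      out[[got]] <- data.table::data.table(chrom = chrom, start = s, end = e)
      occ <- rbind(occ, out[[got]])
    }
  }
  if (got < n) {
    stop("could not place ", n, " intervals on ", chrom,
         ": genome too crowded", call. = FALSE)
  }
  data.table::rbindlist(out[seq_len(got)])
}

#' Simulate regulatory, exon and exclusion-list regions
#'
#' Random disjoint regulatory intervals totaling `pmrr_fraction` (within
#' 1% of the genome) of the genome; every planted hotspot lies inside a
#' regulatory interval. Small exon and exclusion-list sets are placed
#' outside the regulatory intervals and away from planted spans, so the
#' three sets are mutually disjoint.
#'
#' @param config A [sim_config()].
#' @return List of three [region_set()]s: `pmrr`, `exons`, `blacklist`.
#' @export
simulate_regions <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(sub_seed(config$seed, 2L), {
    lens <- config$chrom_lengths
    target <- round(config$pmrr_fraction * config$genome_length)
    if (target < 200L) {
      stop("pmrr_fraction infeasible for this genome length", call. = FALSE)
    }
    # one regulatory interval per planted hotspot, padded around its span
    seeded <- data.table::rbindlist(lapply(config$planted, function(p) {
      s <- max(0L, min(p$positions) - 1L - 150L)
      e <- min(lens[[p$chrom]], max(p$positions) + 150L)
      data.table::data.table(chrom = p$chrom, start = s, end = e)
    }))
    if (is.null(seeded) || nrow(seeded) == 0L) {
      seeded <- data.table::data.table(chrom = character(), start = integer(),
                                       end = integer())
    }
    pmrr <- data.table::copy(seeded)
    total <- sum(pmrr$end - pmrr$start)
    chroms <- rep(names(lens), length.out = max(1L, ceiling(
      (target - total) / 600) + 50L))
    i <- 1L
    while (total < target && i <= length(chroms)) {
      remaining <- target - total
      len <- as.integer(max(200, min(remaining, round(stats::rnorm(1, 600, 150)))))
      ch <- sample(names(lens), 1L)
      iv <- tryCatch(place_intervals(pmrr, ch, lens[[ch]], 1L,
                                     function() len),
                     error = function(e) NULL)
      if (!is.null(iv)) {
        pmrr <- rbind(pmrr, iv)
        total <- total + len
      }
      i <- i + 1L
    }
    if (abs(total - target) > 0.01 * config$genome_length) {
      stop("could not reach the requested regulatory fraction", call. = FALSE)
    }
    n_exons <- max(2L, round(config$genome_length / 2e4))
    n_bl <- max(1L, round(config$genome_length / 5e4))
    occ <- data.table::copy(pmrr)
    exons <- NULL
    bl <- NULL
    for (k in seq_len(n_exons)) {
      ch <- sample(names(lens), 1L)
      iv <- place_intervals(occ, ch, lens[[ch]], 1L,
                            function() sample(200:400, 1L))
      occ <- rbind(occ, iv)
      exons <- rbind(exons, iv)
    }
    for (k in seq_len(n_bl)) {
      ch <- sample(names(lens), 1L)
      iv <- place_intervals(occ, ch, lens[[ch]], 1L,
                            function() sample(150:300, 1L))
      occ <- rbind(occ, iv)
      bl <- rbind(bl, iv)
    }
    list(pmrr = region_set(pmrr, label = "pMRR"),
         exons = region_set(exons, label = "exon"),
         blacklist = region_set(bl, label = "excluded"))
  })
}

#' Simulate a functional score track
#'
#' Tiles the genome into `score_tile`-bp windows and draws each tile's
#' score from an exponential distribution: mean `funseq_mean_out` outside
#' the regulatory set, `funseq_mean_out * funseq_fold_in` inside (a tile
#' belongs to the regulatory side when its midpoint does).
#'
#' @param config A [sim_config()].
#' @param pmrr Regulatory [region_set()] (from [simulate_regions()]).
#' @return A [score_track()].
#' @export
simulate_score_track <- function(config, pmrr) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(sub_seed(config$seed, 3L), {
    tiles <- data.table::rbindlist(lapply(names(config$chrom_lengths),
      function(ch) {
        L <- config$chrom_lengths[[ch]]
        s <- seq(0L, L - 1L, by = config$score_tile)
        data.table::data.table(chrom = ch, start = s,
                               end = pmin(s + config$score_tile, L))
      }))
    mids <- tiles[, .(chrom, start = as.integer(floor((start + end) / 2)))]
    mids[, end := start + 1L]
    inside <- region_overlaps(pmrr, mids)
    mean_vec <- data.table::fifelse(inside,
      config$funseq_mean_out * config$funseq_fold_in, config$funseq_mean_out)
    tiles[, score := stats::rexp(.N, rate = 1 / mean_vec)]
    score_track(tiles)
  })
}

#' Simulate a multi-donor variant table with planted hotspots
#'
#' Background: every donor mutates every base independently with
#' probability `background_rate` (alternate base drawn uniformly from the
#' three non-reference bases). Planted: at each planted position, the
#' configured number of distinct donors (sampled without replacement)
#' receive an SNV. Rows are shuffled; a donor duplicated at a position
#' (background colliding with a plant) is deduplicated in favor of the
#' plant. Deterministic per config seed.
#'
#' @param config A [sim_config()].
#' @param genome Genome from [simulate_genome()].
#' @return A list: `variants` (table as from [read_variants()], plus a
#'   logical `planted` column) and `truth` (one row per planted hotspot:
#'   `chrom`, `start`, `end` 0-based span, `D_expected`, `G_expected`).
#' @export
simulate_variants <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(sub_seed(config$seed, 4L), {
    donors <- sprintf("D%03d", seq_len(config$n_donors))
    bg <- vector("list", config$n_donors)
    for (d in seq_len(config$n_donors)) {
      per_chrom <- lapply(names(config$chrom_lengths), function(ch) {
        L <- config$chrom_lengths[[ch]]
        n <- stats::rbinom(1L, L, config$background_rate)
        if (n == 0L) return(NULL)
        pos <- sort(sample.int(L, n))
        data.table::data.table(donor_id = donors[d], chrom = ch, pos1 = pos)
      })
      bg[[d]] <- data.table::rbindlist(Filter(Negate(is.null), per_chrom))
    }
    bg <- data.table::rbindlist(Filter(function(x) !is.null(x) && nrow(x),
                                       bg))
    if (nrow(bg)) bg[, planted := FALSE]
    pl <- data.table::rbindlist(lapply(config$planted, function(p) {
      if (max(p$counts) > config$n_donors) {
        stop("planted donor count exceeds the cohort size", call. = FALSE)
      }
      data.table::rbindlist(lapply(seq_along(p$positions), function(i) {
        data.table::data.table(
          donor_id = sample(donors, p$counts[i]),
          chrom = p$chrom, pos1 = p$positions[i], planted = TRUE)
      }))
    }))
    v <- data.table::rbindlist(list(pl, bg), use.names = TRUE, fill = TRUE)
    if (nrow(v) == 0L) {
      v <- data.table::data.table(donor_id = character(), chrom = character(),
        pos1 = integer(), ref = character(), alt = character(),
        variant_class = character(), planted = logical())
    } else {
      # planted rows first, so duplicates resolve in favor of the plant
      v <- unique(v, by = c("donor_id", "chrom", "pos1"))
      v[, ref := vapply(seq_len(.N), function(i) {
        substr(genome[[chrom[i]]], pos1[i], pos1[i])
      }, "")]
      v[, alt := vapply(ref, function(r) {
        sample(setdiff(DNA_BASES, r), 1L)
      }, "")]
      v[, variant_class := "SNV"]
      v <- v[sample.int(nrow(v))]
    }
    truth <- data.table::rbindlist(lapply(config$planted, function(p) {
      data.table::data.table(chrom = p$chrom,
        start = min(p$positions) - 1L, end = max(p$positions),
        D_expected = sum(p$counts), G_expected = length(p$positions))
    }))
    if (is.null(truth) || nrow(truth) == 0L) {
      truth <- data.table::data.table(chrom = character(), start = integer(),
        end = integer(), D_expected = integer(), G_expected = integer())
    }
    list(variants = v[], truth = truth[])
  })
}

#' Generate a complete synthetic benchmark dataset
#'
#' Runs all generators of a [sim_config()] and optionally writes the
#' standard file layout: `genome.fa`, `pmrr.bed`, `exons.bed`,
#' `blacklist.bed`, `funseq.bed`, `variants.tsv`, `truth.json`.
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory (created if needed).
#' @return A list: `genome`, `pmrr`, `exons`, `blacklist`, `track`,
#'   `variants`, `truth`, `config`.
#' @export
simulate_dataset <- function(config, outdir = NULL) {
  genome <- simulate_genome(config)
  regions <- simulate_regions(config)
  track <- simulate_score_track(config, regions$pmrr)
  sv <- simulate_variants(config, genome)
  out <- list(genome = genome, pmrr = regions$pmrr, exons = regions$exons,
              blacklist = regions$blacklist, track = track,
              variants = sv$variants, truth = sv$truth, config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome),
                                file.path(outdir, "genome.fa"))
    write_bed(regions$pmrr, file.path(outdir, "pmrr.bed"))
    write_bed(regions$exons, file.path(outdir, "exons.bed"))
    write_bed(regions$blacklist, file.path(outdir, "blacklist.bed"))
    data.table::fwrite(track, file.path(outdir, "funseq.bed"), sep = "\t",
                       col.names = FALSE)
    write_variants(sv$variants, file.path(outdir, "variants.tsv"))
    jsonlite::write_json(sv$truth, file.path(outdir, "truth.json"),
                         dataframe = "rows", digits = NA)
    out$outdir <- outdir
  }
  out
}
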