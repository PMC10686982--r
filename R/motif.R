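#' Read a genome FASTA
#'
#' Thin wrapper over `Biostrings::readDNAStringSet` that keeps only the
#' first word of each FASTA header as the chromosome name.
#'
#' @param path Path to a (plain-text) FASTA file.
#' @return A named `DNAStringSet`.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' @noRd
genome_seq <- function(genome, chrom) {
  if (is.character(genome)) {
    if (!chrom %in% names(genome)) {
      stop("chromosome not in genome: ", chrom, call. = FALSE)
    }
    return(toupper(genome[[chrom]]))
  }
  if (!chrom %in% names(genome)) {
    stop("chromosome not in genome: ", chrom, call. = FALSE)
  }
  toupper(as.character(genome[[chrom]]))
}

#' @noRd
revcomp_chr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Extract a variant-centered sequence window
#'
#' Cuts a fixed-length window out of the genome such that the variant base
#' sits at 1-based index `anchor` within the window: the conventions used
#' for motif analyses are an 11-bp window with the variant at position 6
#' (the center) and a 20-bp window with the variant at position 10. `MUT`
#' windows substitute the alternate allele (length-preserving alleles
#' only). Windows running off a chromosome end are an error; no clipping.
#'
#' @param genome A `DNAStringSet` (see [read_genome()]) or named character
#'   vector of chromosome sequences.
#' @param chrom Chromosome name.
#' @param pos1 1-based position of the (first) variant base.
#' @param length Window length in bp (default 11).
#' @param anchor 1-based index of the variant within the window
#'   (default 6).
#' @param allele `"WT"` (default) or `"MUT"`.
#' @param ref,alt Alleles, required for `allele = "MUT"` (must be equal
#'   length; `ref` is checked against the genome when given).
#' @return A `seq_window` object: list with `chrom`, `window_start`
#'   (0-based), `seq`, `variant_offset` (0-based index of the variant in
#'   `seq`), `allele`.
#' @export
extract_window <- function(genome, chrom, pos1, length = 11L, anchor = 6L,
                           allele = c("WT", "MUT"), ref = NULL, alt = NULL) {
  allele <- match.arg(allele)
  stopifnot(length >= 1L, anchor >= 1L, anchor <= length)
  chrseq <- genome_seq(genome, chrom)
  start0 <- (pos1 - 1L) - (anchor - 1L)
  if (start0 < 0L || start0 + length > nchar(chrseq)) {
    stop(sprintf("window [%d, %d) off chromosome %s (length %d)",
                 start0, start0 + length, chrom, nchar(chrseq)),
         call. = FALSE)
  }
  seq <- substr(chrseq, start0 + 1L, start0 + length)
  off <- anchor - 1L
  if (allele == "MUT") {
    if (is.null(alt)) stop("alt allele required for MUT windows", call. = FALSE)
    if (!is.null(ref) && nchar(alt) != nchar(ref)) {
      stop("MUT windows support length-preserving alleles only (SNV/MNV)",
           call. = FALSE)
    }
  }
  if (!is.null(ref)) {
    obs <- substr(seq, off + 1L, off + nchar(ref))
    if (obs != toupper(ref)) {
      stop(sprintf("reference mismatch at %s:%d: genome has %s, ref is %s",
                   chrom, pos1, obs, ref), call. = FALSE)
    }
  }
  if (allele == "MUT") {
    if (off + nchar(alt) > length) {
      stop("alt allele runs past the window end", call. = FALSE)
    }
    substr(seq, off + 1L, off + nchar(alt)) <- toupper(alt)
  }
  structure(list(chrom = chrom, window_start = start0, seq = seq,
                 variant_offset = off, allele = allele),
            class = "seq_window")
}

#' @export
print.seq_window <- function(x, ...) {
  marker <- paste0(strrep(" ", x$variant_offset), "^")
  cat(sprintf("<seq_window %s:%d %s>\n%s\n%s\n", x$chrom, x$window_start,
              x$allele, x$seq, marker))
  invisible(x)
}

#' @noRd
motif_hits_1d <- function(seq, motif) {
  m <- gregexpr(motif, seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

#' Strand-normalized offset of a variant to the nearest ETS core (GGAA)
#'
#' Finds every occurrence of the ETS core `GGAA` and of its reverse
#' complement `TTCC` in the window, and selects the occurrence closest to
#' the variant: distance 0 if the variant index lies inside the 4-mer,
#' otherwise the smaller gap to either motif edge. Equal-distance ties are
#' broken on the final oriented offset (the 3' flank wins) -- a rule that
#' is invariant under reverse complement, unlike a strand preference, which
#' would make the offset depend on which strand the window was read from;
#' equal-offset ties then prefer the plus-strand occurrence for reporting.
#' If the winner is a `TTCC` occurrence, the window is
#' rewritten as its reverse complement (variant index becomes
#' `len - 1 - index`) so the motif reads `GGAA`, and the offset is
#' reported on the re-oriented sequence. The offset is
#' `variant index - motif start`; offsets 0..3 mean "inside the core".
#'
#' @param window A `seq_window` (WT allele), or a character sequence if
#'   `variant_offset` is supplied.
#' @param variant_offset 0-based variant index when `window` is a plain
#'   sequence string.
#' @return A list: `found` (logical), and when found `offset` (integer),
#'   `strand` (`"+"`/`"-"`), `motif_start` (0-based, on the oriented
#'   sequence).
#' @examples
#' nearest_ets_offset("CCGGAAGGCC", variant_offset = 6)  # offset +4
#' @export
nearest_ets_offset <- function(window, variant_offset = NULL) {
  if (inherits(window, "seq_window")) {
    seq <- window$seq
    v <- window$variant_offset
  } else {
    seq <- toupper(as.character(window))
    if (is.null(variant_offset)) {
      stop("variant_offset required for plain sequences", call. = FALSE)
    }
    v <- as.integer(variant_offset)
  }
  len <- nchar(seq)
  dist_to <- function(s) {
    # occurrence covers [s, s+3]
    ifelse(v >= s & v <= s + 3L, 0L, pmin(abs(v - s), abs(v - (s + 3L))))
  }
  cand <- data.table::rbindlist(list(
    data.table::data.table(start = motif_hits_1d(seq, "GGAA"), strand = "+"),
    data.table::data.table(start = motif_hits_1d(seq, "TTCC"), strand = "-")
  ))
  if (nrow(cand) == 0L) return(list(found = FALSE))
  cand[, dist := dist_to(start)]
  # final oriented offset of each candidate: a minus-strand occurrence puts
  # the variant at len-1-v and the motif at len-4-start after flipping
  cand[, offset := data.table::fifelse(strand == "+", v - start,
                                       start + 3L - v)]
  # tie-break on the oriented offset (prefer the 3' flank), which is
  # invariant under reverse complement; strand order only disambiguates
  # equal-offset candidates for reporting
  data.table::setorder(cand, dist, -offset, strand, start)
  win <- cand[1]
  if (win$strand == "+") {
    list(found = TRUE, offset = win$offset, strand = "+",
         motif_start = win$start)
  } else {
    list(found = TRUE, offset = win$offset, strand = "-",
         motif_start = len - 4L - win$start)
  }
}

#' Histogram of variant offsets to the nearest ETS core
#'
#' Applies [nearest_ets_offset()] to a list of WT windows and tallies the
#' offsets of the windows in which a motif was found; windows without a
#' GGAA/TTCC occurrence are counted separately.
#'
#' @param windows List of `seq_window`s (or sequences paired with
#'   `variant_offsets`).
#' @param variant_offsets Optional integer vector for plain sequences.
#' @return A list: `counts` (named integer vector, names are offsets),
#'   `n_no_motif`.
#' @export
offset_histogram <- function(windows, variant_offsets = NULL) {
  res <- lapply(seq_along(windows), function(i) {
    nearest_ets_offset(windows[[i]], variant_offsets[i])
  })
  found <- vapply(res, `[[`, TRUE, "found")
  offs <- vapply(res[found], `[[`, 0L, "offset")
  counts <- table(offs)
  list(counts = setNames(as.integer(counts), names(counts)),
       n_no_motif = sum(!found))
}

DNA_BASES <- c("A", "C", "G", "T")

#' Per-position base counts of motif-aligned windows
#'
#' Re-orients each WT window so the ETS core reads `GGAA` on the forward
#' strand, shifts it so the first G of the core sits at 1-based position
#' `align_G_at`, and accumulates per-position base counts (a WebLogo-ready
#' count matrix). Bases shifted out of frame are dropped; windows without
#' a motif are skipped.
#'
#' @param windows List of `seq_window`s (typically 11 bp, WT).
#' @param align_G_at 1-based target position of the first G (default 5).
#' @param width Width of the count matrix; defaults to the first window's
#'   length.
#' @return A 4 x `width` integer matrix with rows A, C, G, T.
#' @export
consensus_counts <- function(windows, align_G_at = 5L, width = NULL) {
  if (!length(windows)) {
    width <- width %||% 11L
    return(matrix(0L, 4L, width, dimnames = list(DNA_BASES, NULL)))
  }
  first_seq <- if (inherits(windows[[1]], "seq_window")) {
    windows[[1]]$seq
  } else as.character(windows[[1]])
  width <- width %||% nchar(first_seq)
  counts <- matrix(0L, 4L, width, dimnames = list(DNA_BASES, NULL))
  for (w in windows) {
    hit <- nearest_ets_offset(w)
    if (!hit$found) next
    seq <- if (inherits(w, "seq_window")) w$seq else as.character(w)
    if (hit$strand == "-") seq <- revcomp_chr(seq)
    shift <- (align_G_at - 1L) - hit$motif_start
    chars <- strsplit(seq, "")[[1]]
    for (i in seq_along(chars)) {
      j <- i + shift  # 1-based target column
      if (j >= 1L && j <= width && chars[i] %in% DNA_BASES) {
        counts[chars[i], j] <- counts[chars[i], j] + 1L
      }
    }
  }
  counts
}

#' Position weight matrix from a consensus sequence
#'
#' Builds the zero-mismatch-style profile used by consensus-to-PWM tools:
#' each column assigns probability `p_consensus` to the consensus base and
#' `(1 - p_consensus)/3` to each of the other three bases.
#'
#' @param consensus DNA string over A/C/G/T (no ambiguity codes).
#' @param p_consensus Probability of the consensus base per column
#'   (default 0.997).
#' @return A `pwm` object: list with `probs` (4 x L matrix, rows A,C,G,T),
#'   `consensus`, `p_consensus`.
#' @export
pwm_from_consensus <- function(consensus, p_consensus = 0.997) {
  consensus <- toupper(consensus)
  if (grepl("[^ACGT]", consensus)) {
    stop("consensus must contain only A/C/G/T (no ambiguity codes)",
         call. = FALSE)
  }
  stopifnot(p_consensus > 0.25, p_consensus < 1)
  bases <- strsplit(consensus, "")[[1]]
  L <- length(bases)
  probs <- matrix((1 - p_consensus) / 3, 4L, L,
                  dimnames = list(DNA_BASES, NULL))
  probs[cbind(match(bases, DNA_BASES), seq_len(L))] <- p_consensus
  structure(list(probs = probs, consensus = consensus,
                 p_consensus = p_consensus), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm '%s', p_consensus = %g, self-score %.2f bits>\n",
              x$consensus, x$p_consensus, pwm_self_score(x)))
  print(round(x$probs, 4))
  invisible(x)
}

#' Log-odds score matrix of a PWM (base 2, uniform background)
#' @param pwm A [pwm_from_consensus()] object.
#' @return 4 x L matrix of bits.
#' @export
pwm_log_odds <- function(pwm) log2(pwm$probs / 0.25)

#' Self-score of a PWM's consensus sequence
#'
#' The maximum achievable scan score: `L * log2(p_consensus / 0.25)` for a
#' consensus-derived PWM (19.94 bits for a 10-mer at p = 0.997).
#'
#' @param pwm A [pwm_from_consensus()] object.
#' @return Score in bits.
#' @export
pwm_self_score <- function(pwm) {
  lo <- pwm_log_odds(pwm)
  bases <- strsplit(pwm$consensus, "")[[1]]
  sum(lo[cbind(match(bases, DNA_BASES), seq_along(bases))])
}

#' @noRd
revcomp_pwm_probs <- function(probs) {
  probs[c("T", "G", "C", "A"), rev(seq_len(ncol(probs))), drop = FALSE]
}

#' @noRd
scan_scores_1seq <- function(seq, log_odds) {
  L <- ncol(log_odds)
  n <- nchar(seq)
  if (n < L) return(numeric(0))
  code <- match(strsplit(seq, "")[[1]], DNA_BASES)
  npos <- n - L + 1L
  scores <- numeric(npos)
  for (l in seq_len(L)) {
    b <- code[l:(l + npos - 1L)]
    col <- log_odds[, l]
    s <- col[b]
    s[is.na(b)] <- -Inf  # N or other ambiguity never matches
    scores <- scores + s
  }
  scores
}

#' Scan regions for PWM matches on both strands
#'
#' Slides the PWM over every interval of `regions` on both strands and
#' reports positions whose log-odds score (base 2, uniform 0.25
#' background) reaches `threshold_bits`. When more than `max_instances`
#' hits are found they are uniformly down-sampled with `seed`.
#'
#' @param pwm A [pwm_from_consensus()] object.
#' @param regions A [region_set()] or `chrom`/`start`/`end` table.
#' @param genome A `DNAStringSet` or named character vector covering the
#'   regions.
#' @param threshold_bits Minimum score; default is the consensus
#'   self-score minus 1 bit (which tolerates no mismatch for a 10-mer at
#'   p_consensus 0.997).
#' @param max_instances Down-sampling cap (default 50000).
#' @param seed Seed for the down-sampling draw (default 1).
#' @return A `data.table` of hits: `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `score` (bits), sorted by position.
#' @export
scan_pwm <- function(pwm, regions, genome, threshold_bits = NULL,
                     max_instances = 50000L, seed = 1L) {
  threshold_bits <- threshold_bits %||% (pwm_self_score(pwm) - 1)
  ivs <- if (inherits(regions, "region_set")) {
    as.data.table(regions)
  } else {
    data.table::as.data.table(regions)[, .(chrom, start, end)]
  }
  lo_fwd <- pwm_log_odds(pwm)
  lo_rev <- log2(revcomp_pwm_probs(pwm$probs) / 0.25)
  L <- ncol(lo_fwd)
  hits <- vector("list", 2L * nrow(ivs))
  for (i in seq_len(nrow(ivs))) {
    chrseq <- genome_seq(genome, ivs$chrom[i])
    if (ivs$end[i] > nchar(chrseq)) {
      stop("region extends beyond chromosome ", ivs$chrom[i], call. = FALSE)
    }
    seq <- substr(chrseq, ivs$start[i] + 1L, ivs$end[i])
    for (str in c("+", "-")) {
      sc <- scan_scores_1seq(seq, if (str == "+") lo_fwd else lo_rev)
      k <- which(sc >= threshold_bits)
      if (length(k)) {
        hits[[2L * (i - 1L) + (str == "-") + 1L]] <- data.table::data.table(
          chrom = ivs$chrom[i], start = ivs$start[i] + k - 1L,
          end = ivs$start[i] + k - 1L + L, strand = str, score = sc[k])
      }
    }
  }
  out <- data.table::rbindlist(Filter(Negate(is.null), hits))
  if (nrow(out) == 0L) {
    return(data.table::data.table(chrom = character(), start = integer(),
      end = integer(), strand = character(), score = numeric()))
  }
  if (nrow(out) > max_instances) {
    keep <- with_seed(seed, sort(sample.int(nrow(out), max_instances)))
    out <- out[keep]
  }
  data.table::setorder(out, chrom, start, strand)
  out[]
}

#' Write PWM hits as BED6
#'
#' The BED score column is the hit score in bits times 100, as an integer.
#'
#' @param hits Hit table from [scan_pwm()].
#' @param path Output path.
#' @param name Feature name for column 4 (default "pwm_hit").
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path, name = "pwm_hit") {
  dt <- data.table::data.table(hits$chrom, hits$start, hits$end, name,
                               as.integer(round(hits$score * 100)),
                               hits$strand)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
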