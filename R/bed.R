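#' Read a BED3+ file of genomic intervals
#'
#' Reads the first three columns (chrom, start, end; 0-based half-open) of
#' a BED file; extra columns (BED6/BED12, ...) are ignored. Intervals are
#' returned in file order and are not merged -- build a [region_set()] for
#' set semantics.
#'
#' @param path Path to a BED file (plain text).
#' @return A `data.table` with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- which(!grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines))
  if (!length(keep)) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer()))
  }
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    stop_line(path, keep[which(nf < 3L)[1]], "BED line has fewer than 3 fields")
  }
  dt <- data.table::data.table(
    chrom = vapply(parts, `[`, "", 1L),
    start = suppressWarnings(as.integer(vapply(parts, `[`, "", 2L))),
    end = suppressWarnings(as.integer(vapply(parts, `[`, "", 3L))),
    line = keep
  )
  i <- which(is.na(dt$start) | is.na(dt$end))
  if (length(i)) stop_line(path, dt$line[i[1]], "non-integer BED coordinates")
  i <- which(dt$start < 0L)
  if (length(i)) stop_line(path, dt$line[i[1]], "negative BED start")
  i <- which(dt$start >= dt$end)
  if (length(i)) stop_line(path, dt$line[i[1]], "BED start must be < end")
  dt[, line := NULL]
  dt[]
}

#' Write intervals as BED3
#'
#' @param intervals A `data.table`/`data.frame` with `chrom`, `start`,
#'   `end`, or a [region_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  if (inherits(intervals, "region_set")) intervals <- as.data.table(intervals)
  dt <- data.table::as.data.table(intervals)[, .(chrom, start, end)]
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a per-position functional score track
#'
#' Reads a 4-column bedGraph-like file (chrom, start, end, score;
#' 0-based half-open) carrying pre-computed per-position functional-impact
#' scores (e.g. FunSeq2). Entries must be non-negative and non-overlapping
#' within a chromosome; the track is returned sorted.
#'
#' @param path Path to the 4-column track.
#' @return A `score_track` object (a keyed `data.table` with columns
#'   `chrom`, `start`, `end`, `score`).
#' @export
read_score_track <- function(path) {
  if (!file.exists(path)) stop("score track not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = FALSE, showProgress = FALSE,
                          col.names = c("chrom", "start", "end", "score")[1:4])
  if (ncol(dt) < 4L) stop(path, ": score track needs 4 columns", call. = FALSE)
  dt[, chrom := as.character(chrom)]
  score_track(dt)
}

#' Construct a score track from intervals and scores
#'
#' @param entries `data.table`/`data.frame` with columns `chrom`, `start`,
#'   `end`, `score`.
#' @return A `score_track` object.
#' @export
score_track <- function(entries) {
  dt <- data.table::as.data.table(entries)[, .(chrom = as.character(chrom),
    start = as.integer(start), end = as.integer(end),
    score = as.numeric(score))]
  if (any(is.na(dt$start) | is.na(dt$end) | dt$start >= dt$end)) {
    stop("score track intervals must satisfy 0 <= start < end", call. = FALSE)
  }
  if (any(is.na(dt$score) | dt$score < 0)) {
    stop("score track scores must be non-negative", call. = FALSE)
  }
  data.table::setorder(dt, chrom, start, end)
  ov <- dt[, any(start[-1L] < end[-.N]), by = chrom][V1 == TRUE]
  if (nrow(ov)) {
    stop("score track has overlapping entries on ", ov$chrom[1], call. = FALSE)
  }
  data.table::setattr(dt, "class", c("score_track", class(dt)))
  dt
}

#' Look up track scores at 1-based positions
#'
#' @param track A [score_track()].
#' @param chrom,pos1 Parallel vectors of chromosome names and 1-based
#'   positions.
#' @return Numeric vector of scores; `NA` where a position is covered by
#'   no track entry.
#' @export
score_at <- function(track, chrom, pos1) {
  stopifnot(inherits(track, "score_track"))
  q <- data.table::data.table(chrom = as.character(chrom),
                              pos0 = as.integer(pos1) - 1L,
                              idx = seq_along(chrom))
  out <- rep(NA_real_, nrow(q))
  for (ch in unique(q$chrom)) {
    tr <- track[chrom == ch]
    if (!nrow(tr)) next
    qi <- q[chrom == ch]
    j <- findInterval(qi$pos0, tr$start)
    hit <- j >= 1L & qi$pos0 < tr$end[pmax(j, 1L)]
    out[qi$idx[hit]] <- tr$score[j[hit]]
  }
  out
}
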