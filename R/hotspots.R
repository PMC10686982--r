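#' Merge variant records into hotspots
#'
#' Single-linkage chaining of variant records: within a chromosome, two
#' records belong to the same cluster when the gap between their start
#' positions is at most `window` bp (transitive, `bedtools merge`
#' semantics, so a hotspot may span more than `window` bp). Clusters with
#' fewer than `min_count` records are discarded -- those variants are
#' "isolated" and never become hotspots.
#'
#' `D` is the number of variant records in the hotspot (the default; a
#' donor mutated at two positions contributes twice) or the number of
#' distinct donors when `count = "donors"`. `G` is the number of distinct
#' mutated start positions; with `g_mode = "footprint"` each reference
#' base of an MNV/deletion counts as a mutated position instead.
#'
#' @param variants Variant table from [read_variants()].
#' @param window Maximum start-to-start gap (bp) chaining two records into
#'   one hotspot. Default 25.
#' @param min_count Minimum number of records for a cluster to be kept.
#'   Default 3.
#' @param count `"records"` (default) or `"donors"`: what `D` counts.
#' @param g_mode `"starts"` (default) or `"footprint"`: what `G` counts.
#' @return A `hotspot_table`: a `data.table` with one row per hotspot
#'   (`chrom`, `start`, `end` 0-based half-open footprint span, `D`, `G`,
#'   `donor_score`, and a `variants` list-column holding each hotspot's
#'   records), sorted by (chrom, start).
#' @examples
#' v <- data.table::data.table(
#'   donor_id = paste0("D", 1:10), chrom = "chr1",
#'   pos1 = rep(c(101L, 111L, 121L, 131L), c(3, 1, 2, 4)),
#'   ref = "G", alt = "A", variant_class = "SNV")
#' h <- merge_variants(v)
#' h[, .(D, G, donor_score)]  # D = 10, G = 4, donor score 10^2/4 = 25
#' @export
merge_variants <- function(variants, window = 25L, min_count = 3L,
                           count = c("records", "donors"),
                           g_mode = c("starts", "footprint")) {
  count <- match.arg(count)
  g_mode <- match.arg(g_mode)
  stopifnot(window >= 0, min_count >= 1)
  v <- variant_footprint(variants)
  if (nrow(v) == 0L) return(empty_hotspots())
  data.table::setorder(v, chrom, start0, donor_id)
  v[, cluster := cumsum(c(TRUE, diff(start0) > window)), by = chrom]
  h <- v[, {
    g <- if (g_mode == "footprint") {
      length(unique(unlist(Map(seq.int, start0, end0 - 1L))))
    } else {
      data.table::uniqueN(start0)
    }
    d <- if (count == "donors") data.table::uniqueN(donor_id) else .N
    list(start = min(start0), end = max(end0), D = d, G = g, n_records = .N,
         variants = list(data.table::copy(.SD)))
  }, by = .(chrom, cluster),
     .SDcols = intersect(c("donor_id", "chrom", "pos1", "ref", "alt",
                           "variant_class", "funseq", "gerp", "start0", "end0"),
                         names(v))]
  h <- h[n_records >= min_count]
  h[, cluster := NULL]
  h[, n_records := NULL]
  h[, donor_score := donor_score(D, G)]
  data.table::setorder(h, chrom, start)
  as_hotspot_table(h)
}

#' @noRd
empty_hotspots <- function() {
  as_hotspot_table(data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    D = integer(), G = integer(), variants = list(),
    donor_score = numeric()))
}

#' @noRd
as_hotspot_table <- function(dt) {
  if (!inherits(dt, "hotspot_table")) {
    data.table::setattr(dt, "class", c("hotspot_table", class(dt)))
  }
  dt
}

#' Donor score D^2/G
#'
#' Recurrence score of a hotspot: `D` squared over `G`, where `D` is the
#' number of donor variant records in the hotspot and `G` the number of
#' distinct mutated positions. Concentrating recurrence at few positions
#' is rewarded: 10 records at 4 positions score 10^2/4 = 25.
#'
#' @param D,G Integer vectors (recycled).
#' @return Numeric vector of donor scores.
#' @export
donor_score <- function(D, G) {
  # G <= D whenever D counts records; with donor counting a donor mutated
  # at several positions makes D < G legitimate, so only G >= 1 is enforced
  if (any(G < 1, na.rm = TRUE)) stop("G must be >= 1", call. = FALSE)
  as.numeric(D)^2 / as.numeric(G)
}

#' Attach mean functional scores to hotspots
#'
#' Looks up the per-variant functional-impact weight (e.g. a pre-computed
#' FunSeq2 score) at each record's start position and stores the
#' arithmetic mean over all `D` records as `mean_funseq`. Positions absent
#' from the track are imputed as 0 and counted in `n_missing_funseq`
#' (indels are looked up at their first reference base).
#'
#' @param hotspots A `hotspot_table` from [merge_variants()].
#' @param track A [score_track()], or `NULL` to use a `funseq` column
#'   already present on the variant records.
#' @return The hotspot table with `mean_funseq` and `n_missing_funseq`
#'   columns.
#' @export
attach_funseq <- function(hotspots, track = NULL) {
  h <- data.table::copy(hotspots)
  if (nrow(h) == 0L) {
    h[, `:=`(mean_funseq = numeric(0), n_missing_funseq = integer(0))]
    return(as_hotspot_table(h))
  }
  stats <- lapply(h$variants, function(v) {
    s <- if (is.null(track)) {
      if ("funseq" %in% names(v)) v$funseq else rep(NA_real_, nrow(v))
    } else {
      score_at(track, v$chrom, v$pos1)
    }
    miss <- is.na(s)
    s[miss] <- 0
    list(mean = mean(s), miss = sum(miss))
  })
  h[, mean_funseq := vapply(stats, `[[`, 0, "mean")]
  h[, n_missing_funseq := vapply(stats, function(x) as.integer(x$miss), 0L)]
  as_hotspot_table(h)
}

#' Combine donor and functional scores into hotspot scores
#'
#' The hotspot score is the product of the donor score (D^2/G) and the
#' mean functional score of the hotspot's records, weighing recurrence and
#' predicted functional consequence in one metric (e.g. donor score 25 at
#' mean weight 1.5 gives 1.5 * 25 = 37.5).
#'
#' @param hotspots A `hotspot_table`; if `mean_funseq` is absent,
#'   [attach_funseq()] is applied first (using `track`).
#' @param track Optional [score_track()] forwarded to [attach_funseq()].
#' @return The hotspot table with a `hotspot_score` column.
#' @export
score_hotspots <- function(hotspots, track = NULL) {
  h <- hotspots
  if (!"mean_funseq" %in% names(h) || !is.null(track)) {
    h <- attach_funseq(h, track)
  } else {
    h <- data.table::copy(h)
  }
  h[, hotspot_score := donor_score * mean_funseq]
  as_hotspot_table(h)
}

#' Call and score hotspots in one step
#'
#' Convenience wrapper: [merge_variants()] then [score_hotspots()].
#'
#' @inheritParams merge_variants
#' @param track Optional [score_track()] of functional weights.
#' @return A scored `hotspot_table`.
#' @export
call_hotspots <- function(variants, track = NULL, window = 25L,
                          min_count = 3L, count = c("records", "donors"),
                          g_mode = c("starts", "footprint")) {
  h <- merge_variants(variants, window = window, min_count = min_count,
                      count = count, g_mode = g_mode)
  score_hotspots(h, track)
}

hotspot_tsv_cols <- c("chrom", "start", "end", "n_variants", "n_positions",
                      "donor_score", "mean_funseq", "hotspot_score",
                      "compartment", "p_value", "q_value")

#' Write a hotspot table as TSV
#'
#' Persists the scored hotspot table (one row per hotspot; coordinates
#' 0-based half-open, BED-sortable) with columns `chrom`, `start`, `end`,
#' `n_variants` (D), `n_positions` (G), `donor_score`, `mean_funseq`,
#' `hotspot_score`, `compartment`, `p_value`, `q_value`. The per-record
#' `variants` list-column is not serialized. Round-trips through
#' [read_hotspot_table()].
#'
#' @param hotspots A `hotspot_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hotspot_table <- function(hotspots, path) {
  h <- data.table::as.data.table(hotspots)
  for (col in c("mean_funseq", "hotspot_score", "compartment", "p_value",
                "q_value")) {
    if (!col %in% names(h)) h[, (col) := NA]
  }
  out <- data.table::data.table(
    chrom = h$chrom, start = h$start, end = h$end,
    n_variants = h$D, n_positions = h$G,
    donor_score = format_score(h$donor_score),
    mean_funseq = format_score(as.numeric(h$mean_funseq)),
    hotspot_score = format_score(as.numeric(h$hotspot_score)),
    compartment = as.character(h$compartment %||% NA),
    p_value = format_score(as.numeric(h$p_value)),
    q_value = format_score(as.numeric(h$q_value)))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open for writing: ", path, call. = FALSE)
  })
  on.exit(close(con))
  writeLines(paste(hotspot_tsv_cols, collapse = "\t"), con)
  if (nrow(out)) {
    writeLines(do.call(paste, c(out, sep = "\t")), con)
  }
  invisible(path)
}

#' Read a hotspot table written by [write_hotspot_table()]
#'
#' @param path Path to the TSV.
#' @return A `hotspot_table` (without the `variants` list-column).
#' @export
read_hotspot_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                          showProgress = FALSE)
  miss <- setdiff(hotspot_tsv_cols, names(dt))
  if (length(miss)) {
    stop(path, ": not a hotspot table, missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  data.table::setnames(dt, c("n_variants", "n_positions"), c("D", "G"))
  for (col in c("donor_score", "mean_funseq", "hotspot_score", "p_value",
                "q_value")) {
    dt[, (col) := as.numeric(get(col))]
  }
  as_hotspot_table(dt)
}
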