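#' Genomic region sets
#'
#' A `region_set` is a labelled set of genomic bases: per chromosome, a
#' sorted list of disjoint 0-based half-open intervals. It is the container
#' for putative regulatory regions (the union of peak sets minus exons and
#' exclusion-listed intervals), exon models and exclusion lists, and backs
#' the compartment assignment of hotspots. Internally a reduced
#' `GenomicRanges::GRanges` holds the intervals.
#'
#' @param intervals A `data.table`/`data.frame` with `chrom`, `start`,
#'   `end` (0-based half-open), a `GRanges`, or `NULL` for an empty set.
#' @param label Free-text label (e.g. `"pMRR"`, `"exon"`, `"excluded"`).
#' @return A `region_set` object.
#' @examples
#' rs <- region_set(data.frame(chrom = "chr1", start = c(100, 150),
#'                             end = c(200, 250)))
#' total_bases(rs)  # 150: overlapping inputs are merged
#' @export
region_set <- function(intervals = NULL, label = "regions") {
  gr <- intervals_to_granges(intervals)
  structure(list(gr = GenomicRanges::reduce(gr), label = label),
            class = "region_set")
}

#' @noRd
intervals_to_granges <- function(x) {
  if (is.null(x)) {
    return(GenomicRanges::GRanges())
  }
  if (inherits(x, "region_set")) return(x$gr)
  if (inherits(x, "GRanges")) return(x)
  dt <- data.table::as.data.table(x)
  if (!all(c("chrom", "start", "end") %in% names(dt))) {
    stop("intervals need chrom/start/end columns", call. = FALSE)
  }
  if (nrow(dt) == 0L) return(GenomicRanges::GRanges())
  if (any(dt$start < 0L | dt$start >= dt$end)) {
    stop("intervals must satisfy 0 <= start < end", call. = FALSE)
  }
  GenomicRanges::GRanges(dt$chrom,
                         IRanges::IRanges(start = dt$start + 1L, end = dt$end))
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set '%s': %d intervals, %d chroms, %s bases>\n",
              x$label, length(x$gr),
              length(unique(as.character(GenomicRanges::seqnames(x$gr)))),
              format(total_bases(x), big.mark = ",")))
  invisible(x)
}

#' @export
as.data.table.region_set <- function(x, ...) {
  gr <- x$gr
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr))
}

#' @export
length.region_set <- function(x) length(x$gr)

#' Total number of bases covered by a region set
#' @param x A [region_set()].
#' @return Integer-valued numeric, the sum of interval lengths.
#' @export
total_bases <- function(x) {
  stopifnot(inherits(x, "region_set"))
  sum(as.numeric(BiocGenerics::width(x$gr)))
}

#' Chromosome names present in a region set
#' @param x A [region_set()].
#' @export
region_chroms <- function(x) {
  unique(as.character(GenomicRanges::seqnames(x$gr)))
}

#' Union of interval lists
#'
#' Merges any number of interval collections into one minimal disjoint
#' cover; overlapping and bookended (endpoint-sharing) intervals are
#' merged, matching `bedtools merge` semantics.
#'
#' @param ... Interval tables, `GRanges`, or `region_set`s.
#' @param label Label for the result.
#' @return A [region_set()].
#' @export
region_union <- function(..., label = "union") {
  parts <- lapply(list(...), intervals_to_granges)
  gr <- if (length(parts)) do.call(c, parts) else GenomicRanges::GRanges()
  structure(list(gr = GenomicRanges::reduce(gr), label = label),
            class = "region_set")
}

#' Base-wise set difference of two region sets
#'
#' @param a,b [region_set()]s (or anything [region_set()] accepts). The
#'   result covers exactly the bases in `a` and not in `b`.
#' @param label Label for the result.
#' @return A [region_set()].
#' @export
region_subtract <- function(a, b, label = NULL) {
  a <- if (inherits(a, "region_set")) a else region_set(a)
  bgr <- intervals_to_granges(b)
  lab <- label %||% a$label
  structure(list(gr = GenomicRanges::setdiff(a$gr, bgr, ignore.strand = TRUE),
                 label = lab), class = "region_set")
}

#' Does each query interval overlap a region set?
#'
#' A single shared base suffices (1-bp overlap rule, the
#' `bedtools intersect` default).
#'
#' @param region_set A [region_set()].
#' @param intervals Query intervals (`chrom`/`start`/`end` table).
#' @return Logical vector, one element per query interval.
#' @export
region_overlaps <- function(region_set, intervals) {
  stopifnot(inherits(region_set, "region_set"))
  q <- intervals_to_granges(intervals)
  IRanges::overlapsAny(q, region_set$gr)
}

#' Fraction of the genome covered by a region set
#'
#' @param region_set A [region_set()].
#' @param genome_sizes Named numeric vector of chromosome lengths (bp).
#' @return Covered bases / total bases, in `[0, 1]`.
#' @export
genome_fraction <- function(region_set, genome_sizes) {
  stopifnot(inherits(region_set, "region_set"))
  if (is.null(names(genome_sizes)) || any(!nzchar(names(genome_sizes)))) {
    stop("genome_sizes must be a named vector of chromosome lengths",
         call. = FALSE)
  }
  dt <- as.data.table(region_set)
  miss <- setdiff(unique(dt$chrom), names(genome_sizes))
  if (length(miss)) {
    stop("region set chromosome(s) absent from genome_sizes: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  over <- dt[end > genome_sizes[chrom]]
  if (nrow(over)) {
    stop(sprintf("region %s:%d-%d extends beyond chromosome length %d",
                 over$chrom[1], over$start[1], over$end[1],
                 genome_sizes[[over$chrom[1]]]), call. = FALSE)
  }
  total_bases(region_set) / sum(as.numeric(genome_sizes))
}

#' Build the putative regulatory region set
#'
#' The test compartment of the hotspot pipeline: the union of all peak
#' interval sets, minus exons, minus the exclusion list, in that order
#' (the order is fixed for reproducibility; set difference makes it
#' immaterial).
#'
#' @param peaks A list of interval tables (one per peak file), or a single
#'   table.
#' @param exons,blacklist Interval tables (or `region_set`s) to subtract;
#'   `NULL` for none.
#' @return A [region_set()] labelled `"pMRR"`.
#' @export
build_pmrr <- function(peaks, exons = NULL, blacklist = NULL) {
  if (!is.list(peaks) || is.data.frame(peaks)) peaks <- list(peaks)
  rs <- do.call(region_union, c(peaks, list(label = "pMRR")))
  if (!is.null(exons)) rs <- region_subtract(rs, exons)
  if (!is.null(blacklist)) rs <- region_subtract(rs, blacklist)
  rs
}
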