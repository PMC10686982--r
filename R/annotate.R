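#' Read a gene model
#'
#' Two plain-text encodings are supported:
#'
#' * a 6-column TSV with header `gene_id`, `chrom`, `strand`, `tx_start`,
#'   `tx_end`, `exons`, where `exons` lists 0-based half-open blocks as
#'   `"start-end,start-end,..."`;
#' * BED12, in which blocks are taken from blockStarts/blockSizes.
#'
#' The TSS is `tx_start` on the plus strand, `tx_end - 1` on minus.
#'
#' @param path Path to the gene model file.
#' @param format `"tsv"` or `"bed12"`.
#' @return A `data.table` with columns `gene_id`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`, `tss`, and list-columns `exon_start`,
#'   `exon_end`.
#' @export
read_gene_model <- function(path, format = c("tsv", "bed12")) {
  format <- match.arg(format)
  if (format == "tsv") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            showProgress = FALSE)
    need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end", "exons")
    miss <- setdiff(need, names(dt))
    if (length(miss)) {
      stop(path, ": gene model missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    blocks <- lapply(strsplit(as.character(dt$exons), ",", fixed = TRUE),
                     function(b) {
      if (!length(b) || identical(b, "")) return(matrix(integer(), 0, 2))
      m <- do.call(rbind, strsplit(b, "-", fixed = TRUE))
      matrix(as.integer(m), ncol = 2)
    })
    g <- dt[, .(gene_id = as.character(gene_id), chrom = as.character(chrom),
                strand = as.character(strand),
                tx_start = as.integer(tx_start), tx_end = as.integer(tx_end))]
  } else {
    raw <- data.table::fread(path, sep = "\t", header = FALSE,
                             showProgress = FALSE)
    if (ncol(raw) < 12L) stop(path, ": BED12 needs 12 columns", call. = FALSE)
    g <- raw[, .(gene_id = as.character(V4), chrom = as.character(V1),
                 strand = as.character(V6), tx_start = as.integer(V2),
                 tx_end = as.integer(V3))]
    blocks <- lapply(seq_len(nrow(raw)), function(i) {
      sizes <- as.integer(strsplit(sub(",$", "", raw$V11[i]), ",")[[1]])
      starts <- as.integer(strsplit(sub(",$", "", raw$V12[i]), ",")[[1]])
      cbind(g$tx_start[i] + starts, g$tx_start[i] + starts + sizes)
    })
  }
  if (any(!g$strand %in% c("+", "-"))) {
    stop(path, ": strand must be '+' or '-'", call. = FALSE)
  }
  g[, tss := data.table::fifelse(strand == "+", tx_start, tx_end - 1L)]
  g[, exon_start := lapply(blocks, function(m) m[, 1])]
  g[, exon_end := lapply(blocks, function(m) m[, 2])]
  bad <- vapply(seq_len(nrow(g)), function(i) {
    es <- g$exon_start[[i]]; ee <- g$exon_end[[i]]
    length(es) > 0 && (min(es) < g$tx_start[i] || max(ee) > g$tx_end[i])
  }, TRUE)
  if (any(bad)) {
    stop(path, ": exon blocks outside the transcript span for gene ",
         g$gene_id[which(bad)[1]], call. = FALSE)
  }
  g[]
}

feature_levels <- c("Promoter", "Exon", "Intron", "Downstream",
                    "Distal Intergenic")

#' Annotate intervals with genomic feature labels
#'
#' Assigns each interval the first matching label in the precedence order
#' Promoter > Exon > Intron > Downstream > Distal Intergenic (a 1-bp
#' overlap suffices). The promoter is the strand-oriented window
#' `[tss - promoter_up, tss + promoter_down]` around the TSS; Downstream
#' extends up to 3 kb past the strand-oriented gene end; UTRs are not
#' modelled separately and fall under Exon.
#'
#' @param intervals `chrom`/`start`/`end` table (0-based half-open), e.g.
#'   a `hotspot_table`.
#' @param genes A gene model from [read_gene_model()].
#' @param promoter_up,promoter_down Promoter extent upstream/downstream of
#'   the TSS in bp (default 3000 each).
#' @param downstream_bp Downstream window past the gene end (default 3000).
#' @return Character vector of labels, one per interval.
#' @export
annotate_feature <- function(intervals, genes, promoter_up = 3000L,
                             promoter_down = 3000L, downstream_bp = 3000L) {
  iv <- data.table::as.data.table(intervals)[, .(chrom, start, end)]
  mk_rs <- function(dt) {
    dt <- dt[start < end]
    dt[start < 0L, start := 0L]
    region_set(dt)
  }
  plus <- genes$strand == "+"
  prom <- mk_rs(data.table::data.table(
    chrom = genes$chrom,
    start = data.table::fifelse(plus, genes$tss - promoter_up,
                                genes$tss - promoter_down),
    end = data.table::fifelse(plus, genes$tss + promoter_down + 1L,
                              genes$tss + promoter_up + 1L)))
  exon <- mk_rs(data.table::data.table(
    chrom = rep(genes$chrom, lengths(genes$exon_start)),
    start = as.integer(unlist(genes$exon_start)),
    end = as.integer(unlist(genes$exon_end))))
  body <- mk_rs(genes[, .(chrom, start = tx_start, end = tx_end)])
  down <- mk_rs(data.table::data.table(
    chrom = genes$chrom,
    start = data.table::fifelse(plus, genes$tx_end,
                                genes$tx_start - downstream_bp),
    end = data.table::fifelse(plus, genes$tx_end + downstream_bp,
                              genes$tx_start)))
  out <- rep("Distal Intergenic", nrow(iv))
  out[region_overlaps(down, iv)] <- "Downstream"
  out[region_overlaps(body, iv)] <- "Intron"
  out[region_overlaps(exon, iv)] <- "Exon"
  out[region_overlaps(prom, iv)] <- "Promoter"
  out
}

#' Nearest gene by TSS distance
#'
#' For each interval, the gene (on the same chromosome) minimizing the
#' absolute distance between the interval midpoint and the gene TSS.
#' Distance is signed by gene strand: negative means the interval lies
#' upstream of the TSS. Intervals on chromosomes without genes get the
#' no-gene sentinel (`NA` id, `NA` distance).
#'
#' @param intervals `chrom`/`start`/`end` table.
#' @param genes A gene model from [read_gene_model()].
#' @return A `data.table` with `gene_id` and `tss_distance`, one row per
#'   interval.
#' @export
nearest_gene <- function(intervals, genes) {
  iv <- data.table::as.data.table(intervals)[, .(chrom, start, end)]
  iv[, mid := as.integer(floor((start + end) / 2))]
  out <- data.table::data.table(gene_id = rep(NA_character_, nrow(iv)),
                                tss_distance = rep(NA_integer_, nrow(iv)))
  for (i in seq_len(nrow(iv))) {
    cand <- genes[chrom == iv$chrom[i]]
    if (!nrow(cand)) next
    d <- abs(iv$mid[i] - cand$tss)
    j <- which.min(d)  # ties: first gene in model order
    signed <- if (cand$strand[j] == "+") iv$mid[i] - cand$tss[j] else
      cand$tss[j] - iv$mid[i]
    out[i, `:=`(gene_id = cand$gene_id[j], tss_distance = as.integer(signed))]
  }
  out[]
}

#' Frequencies of feature annotations
#'
#' @param labels Character vector of labels from [annotate_feature()] (or
#'   a `hotspot_table` carrying a `feature` column).
#' @return Named numeric vector of fractions summing to 1 (empty input
#'   gives an empty vector).
#' @export
annotation_frequencies <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$feature
  if (!length(labels)) return(setNames(numeric(0), character(0)))
  tab <- table(factor(labels, levels = feature_levels))
  tab <- tab[tab > 0]
  setNames(as.numeric(tab) / sum(tab), names(tab))
}
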