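#' Read somatic variant calls
#'
#' Parses a somatic variant table into the internal variant model: one row
#' per variant record, i.e. one donor's call at one site. Two dialects are
#' supported and must be declared (no sniffing):
#'
#' * `"ssm_tsv"` -- an ICGC simple-somatic-mutation-like delimited table
#'   with (at least) columns `donor_id`, `chrom`, `pos1`, `ref`, `alt`,
#'   mapped by header name. ICGC's own headers (`icgc_donor_id`,
#'   `chromosome`, `chromosome_start`, `reference_genome_allele`,
#'   `mutated_to_allele`) are accepted as synonyms. Optional `funseq` and
#'   `gerp` columns are carried through (`gerp` is display-only and never
#'   used in scoring).
#' * `"vcf"` -- a VCF 4.x file. Positions are taken from POS (1-based),
#'   alleles from REF/ALT; multi-allelic rows are split into one record
#'   per ALT allele. The donor id is read from a `DONOR=` key in INFO when
#'   present, otherwise from `donor_id`, otherwise the file's base name.
#'
#' Chromosome names are passed through verbatim: no "chr" normalization is
#' attempted, matching region files is the caller's responsibility (see
#' `strict_chroms` in [run_pipeline()]).
#'
#' @param path Path to the variant file.
#' @param dialect Either `"ssm_tsv"` or `"vcf"`.
#' @param donor_id Fallback donor id for the `"vcf"` dialect.
#' @return A `data.table` with columns `donor_id`, `chrom`, `pos1` (1-based
#'   position of the first altered base), `ref`, `alt`, `variant_class`
#'   (one of `SNV`, `MNV`, `INS`, `DEL`), and, when present in the input,
#'   `funseq` and `gerp`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("donor_id\tchrom\tpos1\tref\talt",
#'              "D1\tchr1\t43824528\tG\tA"), f)
#' read_variants(f, "ssm_tsv")
#' @export
read_variants <- function(path, dialect = c("ssm_tsv", "vcf"),
                          donor_id = NULL) {
  if (length(dialect) != 1L || !dialect %in% c("ssm_tsv", "vcf")) {
    dialect <- match.arg(dialect)
  }
  if (!file.exists(path)) stop("variant file not found: ", path, call. = FALSE)
  v <- switch(dialect,
    ssm_tsv = read_ssm_tsv(path),
    vcf = read_vcf_simple(path, donor_id = donor_id)
  )
  validate_variants(v, path = path)
  v[]
}

read_ssm_tsv <- function(path) {
  dt <- data.table::fread(path, header = TRUE, colClasses = list(character = 1L),
                          showProgress = FALSE)
  if (nrow(dt) == 0L && ncol(dt) == 0L) {
    stop(path, ": empty file with no header", call. = FALSE)
  }
  syn <- c(donor_id = "icgc_donor_id", chrom = "chromosome",
           pos1 = "chromosome_start", ref = "reference_genome_allele",
           alt = "mutated_to_allele")
  for (canon in names(syn)) {
    if (!canon %in% names(dt) && syn[[canon]] %in% names(dt)) {
      data.table::setnames(dt, syn[[canon]], canon)
    }
  }
  need <- c("donor_id", "chrom", "pos1", "ref", "alt")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop(path, ": missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  keep <- c(need, intersect(c("funseq", "gerp"), names(dt)))
  dt <- dt[, keep, with = FALSE]
  dt[, `:=`(donor_id = as.character(donor_id), chrom = as.character(chrom),
            ref = toupper(as.character(ref)), alt = toupper(as.character(alt)))]
  suppressWarnings(dt[, pos1 := as.integer(pos1)])
  dt[, variant_class := classify_variant(ref, alt)]
  data.table::setcolorder(dt, intersect(
    c("donor_id", "chrom", "pos1", "ref", "alt", "variant_class",
      "funseq", "gerp"), names(dt)))
  dt
}

read_vcf_simple <- function(path, donor_id = NULL) {
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#"))
  fallback <- donor_id %||% sub("\\.vcf(\\.gz)?$", "", basename(path))
  if (!length(body_idx)) {
    return(data.table::data.table(donor_id = character(), chrom = character(),
      pos1 = integer(), ref = character(), alt = character(),
      variant_class = character()))
  }
  recs <- vector("list", length(body_idx))
  for (k in seq_along(body_idx)) {
    i <- body_idx[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5L) stop_line(path, i, "VCF data row has fewer than 5 fields")
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) stop_line(path, i, "POS is not an integer")
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    don <- fallback
    if (length(f) >= 8L) {
      m <- regmatches(f[8], regexpr("(?:^|;)(?:DONOR|donor_id)=([^;]+)", f[8]))
      if (length(m)) don <- sub("^;?(?:DONOR|donor_id)=", "", m)
    }
    recs[[k]] <- data.table::data.table(
      donor_id = don, chrom = f[1], pos1 = pos,
      ref = toupper(f[4]), alt = toupper(alts))
  }
  dt <- data.table::rbindlist(recs)
  dt[, variant_class := classify_variant(ref, alt)]
  dt
}

#' Classify alleles into SNV / MNV / INS / DEL
#' @param ref,alt Character vectors of reference and alternate alleles.
#' @return Character vector of variant classes.
#' @export
classify_variant <- function(ref, alt) {
  lr <- nchar(ref)
  la <- nchar(alt)
  data.table::fcase(
    lr == 1L & la == 1L, "SNV",
    lr == la, "MNV",
    lr < la, "INS",
    default = "DEL"
  )
}

#' @noRd
validate_variants <- function(v, path = "<variants>") {
  bad <- function(cond, msg) {
    i <- which(cond)
    if (length(i)) {
      # +1 accounts for the header row of tabular dialects
      stop_line(path, i[1] + 1L, msg)
    }
  }
  bad(is.na(v$pos1) | v$pos1 < 1L, "position must be an integer >= 1")
  bad(is.na(v$ref) | is.na(v$alt) | v$ref == "" | v$alt == "",
      "ref and alt alleles are required")
  bad(v$ref == v$alt, "ref and alt alleles are identical")
  bad(grepl("[^ACGTN]", v$ref) | grepl("[^ACGTN]", v$alt),
      "alleles must be DNA strings over A/C/G/T/N")
  if ("funseq" %in% names(v)) {
    bad(!is.na(v$funseq) & v$funseq < 0, "funseq score must be non-negative")
  }
  invisible(v)
}

#' Write a variant table
#'
#' TSV writer paired with [read_variants()] (dialect `"ssm_tsv"`) so that
#' variant tables round-trip exactly.
#'
#' @param variants A variant `data.table` as returned by [read_variants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  cols <- intersect(c("donor_id", "chrom", "pos1", "ref", "alt",
                      "variant_class", "funseq", "gerp"), names(variants))
  data.table::fwrite(variants[, cols, with = FALSE], path, sep = "\t")
  invisible(path)
}

#' 0-based footprint of a variant record
#'
#' SNVs occupy `[pos1-1, pos1)`; MNVs and deletions span the reference
#' allele, `[pos1-1, pos1-1+nchar(ref))`; insertions are anchored at the
#' single base `[pos1-1, pos1)`.
#' @param variants A variant `data.table`.
#' @return The table with `start0`/`end0` footprint columns added.
#' @export
variant_footprint <- function(variants) {
  v <- data.table::copy(variants)
  v[, start0 := pos1 - 1L]
  v[, end0 := start0 + data.table::fifelse(variant_class == "INS", 1L, nchar(ref))]
  v[]
}
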