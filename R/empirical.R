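#' Assign hotspots to test / null / excluded compartments
#'
#' A hotspot whose footprint span overlaps (by at least 1 bp) the exon
#' model or the exclusion list is `"excluded"`; otherwise it is `"test"`
#' if it overlaps the regulatory region set, else `"null"`. By default
#' exon/exclusion overlap removes a hotspot from *both* compartments: a
#' null distribution meant to represent non-functional sequence should not
#' contain coding exons. Set `null_excludes = FALSE` for the literal
#' reading in which the null is everything outside the regulatory set.
#'
#' @param hotspots A `hotspot_table`.
#' @param pmrr Regulatory [region_set()].
#' @param exons,blacklist [region_set()]s (or `NULL`).
#' @param null_excludes Logical; see above. Default `TRUE`.
#' @param strict When `TRUE`, error if a hotspot chromosome is absent from
#'   every supplied region set (guards against chromosome-naming
#'   mismatches). Default `FALSE`.
#' @return The hotspot table with a `compartment` column.
#' @export
assign_compartments <- function(hotspots, pmrr, exons = NULL,
                                blacklist = NULL, null_excludes = TRUE,
                                strict = FALSE) {
  h <- data.table::copy(hotspots)
  if (nrow(h) == 0L) {
    h[, compartment := character(0)]
    return(as_hotspot_table(h))
  }
  if (strict) {
    known <- unique(unlist(lapply(
      Filter(Negate(is.null), list(pmrr, exons, blacklist)), region_chroms)))
    miss <- setdiff(unique(h$chrom), known)
    if (length(miss)) {
      stop("hotspot chromosome(s) absent from all region files: ",
           paste(miss, collapse = ", "),
           " (chromosome naming mismatch?)", call. = FALSE)
    }
  }
  spans <- h[, .(chrom, start, end)]
  in_test <- region_overlaps(pmrr, spans)
  in_bad <- rep(FALSE, nrow(h))
  for (rs in Filter(Negate(is.null), list(exons, blacklist))) {
    in_bad <- in_bad | region_overlaps(rs, spans)
  }
  if (!null_excludes) in_bad <- in_bad & !in_test
  h[, compartment := data.table::fifelse(in_bad, "excluded",
                       data.table::fifelse(in_test, "test", "null"))]
  as_hotspot_table(h)
}

#' Empirical p-values against a null score distribution
#'
#' For each test score `t`, the p-value is the proportion of null scores
#' greater than or equal to `t` (ties count). p may be exactly 0 when a
#' test score exceeds every null score; no pseudo-count is added. The null
#' is sorted once and queried by binary search.
#'
#' @param test_scores Numeric vector of test-compartment hotspot scores.
#' @param null_scores Numeric vector of null-compartment hotspot scores;
#'   must be non-empty.
#' @return Numeric vector of p-values, parallel to `test_scores`.
#' @examples
#' empirical_pvalues(3, c(1, 2, 3, 4, 5))  # 0.6: three of five >= 3
#' @export
empirical_pvalues <- function(test_scores, null_scores) {
  if (length(null_scores) == 0L) {
    stop("empty null compartment: no null hotspots to form the empirical ",
         "distribution; use a larger genome/simulation or relax exclusions",
         call. = FALSE)
  }
  if (anyNA(test_scores) || anyNA(null_scores)) {
    stop("scores must not contain NA", call. = FALSE)
  }
  ns <- sort(null_scores)
  m <- length(ns)
  # findInterval(..., left.open = TRUE) counts null scores strictly below t
  (m - findInterval(test_scores, ns, left.open = TRUE)) / m
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values: with order statistics `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, clipped to 1, returned in the
#' input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(pvalues)
  o <- order(pvalues)
  q_sorted <- rev(cummin(rev(pvalues[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Empirical testing of regulatory hotspots
#'
#' Computes empirical p-values for every `"test"` hotspot against the
#' `"null"` hotspot score distribution and BH-adjusts them. Null and
#' excluded hotspots receive `NA` p/q.
#'
#' @param hotspots A scored, compartment-assigned `hotspot_table`.
#' @return The hotspot table with `p_value` and `q_value` columns.
#' @export
test_hotspots <- function(hotspots) {
  h <- data.table::copy(hotspots)
  if (!"compartment" %in% names(h) || !"hotspot_score" %in% names(h)) {
    stop("hotspots must be scored and compartment-assigned first",
         call. = FALSE)
  }
  h[, `:=`(p_value = NA_real_, q_value = NA_real_)]
  it <- which(h$compartment == "test")
  if (length(it)) {
    p <- empirical_pvalues(h$hotspot_score[it],
                           h$hotspot_score[h$compartment == "null"])
    h[it, p_value := p]
    h[it, q_value := bh_fdr(p)]
  }
  as_hotspot_table(h)
}

#' Significant hotspots at an FDR threshold
#'
#' @param hotspots A tested `hotspot_table` (see [test_hotspots()]).
#' @param alpha FDR threshold on the q-value (default 0.05).
#' @return The subset with `q_value < alpha`, sorted by descending
#'   `hotspot_score`.
#' @export
significant_hotspots <- function(hotspots, alpha = 0.05) {
  h <- hotspots[!is.na(q_value) & q_value < alpha]
  data.table::setorder(h, -hotspot_score)
  as_hotspot_table(h)
}

#' Compartment score enrichment summary
#'
#' Takes the `top_n` highest-scoring hotspots of the test and of the null
#' compartment and reports the test/null ratios of the mean donor score,
#' mean functional score, and mean hotspot score.
#'
#' @param hotspots A scored, compartment-assigned `hotspot_table`.
#' @param top_n Number of top hotspots per compartment (default 10000).
#' @return A list with `n_test`, `n_null`, `top_n`, `fold_donor`,
#'   `fold_funseq`, `fold_hotspot` (folds are `NA` when either compartment
#'   is empty).
#' @export
compartment_summary <- function(hotspots, top_n = 10000L) {
  pick <- function(comp) {
    x <- hotspots[compartment == comp]
    data.table::setorder(x, -hotspot_score)
    head(x, top_n)
  }
  te <- pick("test")
  nu <- pick("null")
  fold <- function(col) {
    if (nrow(te) == 0L || nrow(nu) == 0L) return(NA_real_)
    mean(te[[col]]) / mean(nu[[col]])
  }
  list(n_test = sum(hotspots$compartment == "test"),
       n_null = sum(hotspots$compartment == "null"),
       top_n = as.integer(top_n),
       fold_donor = fold("donor_score"),
       fold_funseq = fold("mean_funseq"),
       fold_hotspot = fold("hotspot_score"))
}

#' Cohort prevalence of a mutation, in percent
#'
#' Fraction of donors in a cohort that carry a given hotspot mutation,
#' reported as a percentage rounded to `digits` decimals (e.g. 1 carrier
#' among 35 acral melanoma donors: 2.9%).
#'
#' @param n_carriers Number of donors carrying the mutation.
#' @param n_cohort Cohort size.
#' @param digits Decimals to round the percentage to (default 1).
#' @return Percentage in `[0, 100]`.
#' @export
cohort_prevalence <- function(n_carriers, n_cohort, digits = 1) {
  stopifnot(n_cohort > 0, n_carriers >= 0, n_carriers <= n_cohort)
  round(100 * n_carriers / n_cohort, digits)
}

#' Distinct donors with a record inside a genomic span
#'
#' @param variants A variant table.
#' @param chrom,start,end The query span (0-based half-open).
#' @return Character vector of donor ids.
#' @export
donors_in_span <- function(variants, chrom, start, end) {
  v <- variant_footprint(variants)
  qc <- chrom
  unique(v[chrom == qc & start0 < end & end0 > start, donor_id])
}
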