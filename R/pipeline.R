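#' Run the full hotspot discovery pipeline
#'
#' Orchestrates the stages end to end: build the regulatory region set
#' from peak/exon/exclusion BEDs, merge and score variants into hotspots,
#' assign compartments, compute empirical p- and q-values, and (when a
#' gene model is given) annotate features and nearest genes. Writes
#' `tested.tsv` (the full hotspot table), `summary.tsv` (compartment
#' enrichment summary), and `manifest.json` (tool version, parameters,
#' input digests) into `outdir`. Stage failures abort with the stage name.
#'
#' @param variants Path to the variant file.
#' @param peaks Character vector of peak BED paths.
#' @param exons,blacklist Optional BED paths.
#' @param score_track Path to the 4-column functional score track.
#' @param gene_model Optional gene model TSV path (see
#'   [read_gene_model()]).
#' @param outdir Output directory (created if needed).
#' @param dialect Variant dialect for [read_variants()].
#' @param window,min_count Merge parameters (defaults 25 bp, 3 records).
#' @param alpha FDR threshold reported in the summary (default 0.05).
#' @param top_n Top-N per compartment for the enrichment summary
#'   (default 10000).
#' @param promoter_up,promoter_down Promoter window for annotation.
#' @param null_excludes Exclude exon/blacklist-overlapping hotspots from
#'   the null compartment too (default `TRUE`).
#' @param strict_chroms Error when variant chromosomes are absent from all
#'   region files (default `TRUE`).
#' @param seed Seed recorded in the manifest (reserved for stages with
#'   randomness; the core pipeline is deterministic). Default 1.
#' @param quiet Suppress stage log lines on stderr.
#' @return Invisibly, a list with the tested `hotspots` table, the
#'   `summary`, and `outdir`.
#' @export
run_pipeline <- function(variants, peaks, exons = NULL, blacklist = NULL,
                         score_track, gene_model = NULL, outdir,
                         dialect = "ssm_tsv", window = 25L, min_count = 3L,
                         alpha = 0.05, top_n = 10000L, promoter_up = 3000L,
                         promoter_down = 3000L, null_excludes = TRUE,
                         strict_chroms = TRUE, seed = 1L, quiet = FALSE) {
  t0 <- Sys.time()
  log_stage <- function(...) {
    if (!quiet) {
      message(sprintf("[crvhotspot +%5.1fs] %s",
                      as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      sprintf(...)))
    }
  }
  stage <- function(name, expr) {
    log_stage("stage %s", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  inputs <- c(variants = variants, setNames(peaks, rep("peaks", length(peaks))),
              exons = exons, blacklist = blacklist,
              score_track = score_track, gene_model = gene_model)
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in)) {
    stop("missing input file(s): ",
         paste(sprintf("%s (%s)", missing_in, names(missing_in)),
               collapse = ", "), call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  exon_iv <- if (is.null(exons)) NULL else read_bed(exons)
  bl_iv <- if (is.null(blacklist)) NULL else read_bed(blacklist)
  pmrr <- stage("build-pmrr",
                build_pmrr(lapply(peaks, read_bed), exon_iv, bl_iv))
  exon_rs <- if (is.null(exon_iv)) NULL else region_set(exon_iv, "exon")
  bl_rs <- if (is.null(bl_iv)) NULL else region_set(bl_iv, "excluded")

  v <- stage("read-variants", read_variants(variants, dialect))
  track <- stage("read-score-track", read_score_track(score_track))
  h <- stage("call-hotspots",
             call_hotspots(v, track, window = window, min_count = min_count))
  h <- stage("assign-compartments",
             assign_compartments(h, pmrr, exon_rs, bl_rs,
                                 null_excludes = null_excludes,
                                 strict = strict_chroms))
  h <- stage("test-hotspots", test_hotspots(h))
  if (!is.null(gene_model)) {
    genes <- stage("read-gene-model", read_gene_model(gene_model))
    h <- stage("annotate", {
      hh <- data.table::copy(h)
      hh[, feature := annotate_feature(hh, genes, promoter_up, promoter_down)]
      ng <- nearest_gene(hh, genes)
      hh[, `:=`(nearest_gene = ng$gene_id, tss_distance = ng$tss_distance)]
      as_hotspot_table(hh)
    })
  }
  smry <- stage("summary", compartment_summary(h, top_n = top_n))

  tested_path <- file.path(outdir, "tested.tsv")
  write_hotspot_table(h, tested_path)
  if (!is.null(gene_model)) {
    extra <- data.table::as.data.table(h)[, .(feature, nearest_gene,
                                              tss_distance)]
    data.table::fwrite(cbind(data.table::fread(tested_path, sep = "\t"),
                             extra),
                       tested_path, sep = "\t", na = "NA", quote = FALSE)
  }
  smry_dt <- data.table::data.table(
    metric = c("n_test", "n_null", "top_n", "fold_donor", "fold_funseq",
               "fold_hotspot", "n_significant", "alpha"),
    value = c(smry$n_test, smry$n_null, smry$top_n, smry$fold_donor,
              smry$fold_funseq, smry$fold_hotspot,
              nrow(significant_hotspots(h, alpha)), alpha))
  data.table::fwrite(smry_dt, file.path(outdir, "summary.tsv"), sep = "\t")
  write_manifest(file.path(outdir, "manifest.json"),
                 subcommand = "run", inputs = inputs, seed = seed,
                 params = list(window = window, min_count = min_count,
                               alpha = alpha, top_n = top_n,
                               promoter_up = promoter_up,
                               promoter_down = promoter_down,
                               null_excludes = null_excludes,
                               dialect = dialect))
  log_stage("done: %d hotspots (%d test, %d null)", nrow(h), smry$n_test,
            smry$n_null)
  invisible(list(hotspots = h, summary = smry, outdir = outdir))
}

#' Write a run manifest
#'
#' JSON sidecar recording the package version, subcommand, parameter map,
#' md5 digests of all input files, seed and timestamp, so that a run can
#' be audited and reproduced.
#'
#' @param path Output JSON path.
#' @param subcommand Name of the invoking subcommand.
#' @param inputs Named character vector of input file paths.
#' @param params Named list of parameters.
#' @param seed The run seed.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, subcommand, inputs = character(),
                           params = list(), seed = NA_integer_) {
  digests <- if (length(inputs)) {
    stats::setNames(as.list(unname(tools::md5sum(inputs))),
                    sprintf("%s:%s", names(inputs), basename(inputs)))
  } else list()
  manifest <- list(
    tool = "crvhotspot",
    version = as.character(utils::packageVersion("crvhotspot")),
    subcommand = subcommand,
    parameters = params,
    input_md5 = digests,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
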