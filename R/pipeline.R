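# End-to-end orchestration of the analysis stages, mirroring the standard
# workflow funnel: array-metric sample QC -> raw-call filtering ->
# multi-caller consensus -> region exclusion -> CNV-count sample QC ->
# per-gene association + burden tables.

#' Pipeline parameters
#'
#' One object holding every stage threshold, with the study defaults:
#' 5 kb / 5 probes raw-call filters, 2-caller consensus, 100 kb
#' centromere/telomere buffers, 0.70 overlap fractions, 0.95 call rate,
#' 3 SD QC bands, 0.1% control-frequency rarity, adjusted-p 0.01 for the
#' rare report and 0.25 for overrepresentation.
#'
#' @param ... Named overrides of any default listed above.
#' @return A list of class `pipeline_params`.
#' @export
pipeline_params <- function(...) {
  defaults <- list(
    min_size_bp = 5000L, min_probes = 5L, quality_thresholds = NULL,
    strict_gt = FALSE, min_callers = 2L, buffer_bp = 100000L,
    segdup_max_frac = 0.70, ig_max_frac = 0.70,
    min_call_rate = 0.95, k_sd = 3,
    rare_control_freq = 0.001, p_adj_threshold = 0.01,
    ora_p_adj_threshold = 0.25, ora_min_overlap = 2L, alpha = 0.05
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown pipeline parameter(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  structure(modifyList(defaults, overrides), class = "pipeline_params")
}

#' Read pipeline parameters from a YAML config file
#'
#' @param path YAML file whose top-level keys are [pipeline_params()]
#'   names.
#' @return A `pipeline_params` object.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  vals <- yaml::read_yaml(path)
  do.call(pipeline_params, vals)
}

#' Run the full rare-CNV case-control pipeline
#'
#' Chains every stage on in-memory inputs and records the funnel of
#' samples and records surviving each stage. The stages are exactly the
#' exported stage functions; running them by hand with the same parameters
#' yields identical outputs.
#'
#' @param calls Raw calls of all callers (see [read_cnv_calls()]).
#' @param samples Sample manifest.
#' @param genes Gene models.
#' @param tracks List with `centromere`, `segdup`, `immunoglobulin` region
#'   tracks (unbuffered centromeres; buffering is applied here).
#' @param chrom_lengths Tibble `chrom`, `length`.
#' @param params A [pipeline_params()].
#' @param exclude_samples Character vector of externally determined sample
#'   exclusions (e.g. relatedness or sex checks computed elsewhere),
#'   removed before QC.
#' @return A list of class `cnv_pipeline`: stage outputs (`qc_array`,
#'   `filtered_calls`, `stringent`, `region_removed`, `qc_count`, `cnvs`,
#'   `samples`, `association`, `burden_cd_uc`, `burden_case_control`) and
#'   `funnel`, the per-stage record counts.
#' @export
run_cnv_pipeline <- function(calls, samples, genes, tracks, chrom_lengths,
                             params = pipeline_params(),
                             exclude_samples = character()) {
  validate_sample_manifest(samples)
  funnel <- list()
  note <- function(stage, n_samples, n_records) {
    funnel[[length(funnel) + 1]] <<- tibble(
      stage = stage, n_samples = n_samples, n_records = n_records
    )
  }
  note("input", nrow(samples), nrow(calls))

  samples0 <- filter(samples, !.data$sample_id %in% exclude_samples)
  qc_array <- array_metric_qc(samples0, params$min_call_rate, params$k_sd)
  samples1 <- semi_join(samples0, filter(qc_array, .data$passed),
                        by = "sample_id")
  calls1 <- filter(calls, .data$sample_id %in% samples1$sample_id)
  note("array_qc", nrow(samples1), nrow(calls1))

  filtered <- filter_raw_calls(calls1, params$min_size_bp,
                               params$min_probes,
                               params$quality_thresholds, params$strict_gt)
  note("call_filter", nrow(samples1), nrow(filtered))

  stringent <- merge_consensus(filtered, samples1, params$min_callers)
  note("consensus", nrow(samples1), nrow(stringent))

  buffered <- build_buffer_tracks(tracks$centromere, chrom_lengths,
                                  params$buffer_bp)
  rf <- apply_region_filters(
    stringent,
    list(centromere_telomere = buffered, segdup = tracks$segdup,
         immunoglobulin = tracks$immunoglobulin),
    params$segdup_max_frac, params$ig_max_frac
  )
  note("region_filter", nrow(samples1), nrow(rf$kept))

  qc_count <- cnv_count_qc(rf$kept, samples1, params$k_sd)
  samples2 <- semi_join(samples1, filter(qc_count, .data$passed),
                        by = "sample_id")
  cnvs <- filter(rf$kept, .data$sample_id %in% samples2$sample_id)
  note("cnv_count_qc", nrow(samples2), nrow(cnvs))

  assoc <- run_association(cnvs, genes, samples2,
                           rare_control_freq = params$rare_control_freq,
                           p_adj_threshold = params$p_adj_threshold,
                           alpha = params$alpha)
  note("association", nrow(samples2), nrow(assoc))

  has_cd_uc <- all(c("CD", "UC") %in%
                     samples2$subtype[samples2$cohort == "case"])
  burden_cd_uc <- if (has_cd_uc) {
    burden_table(cnvs, genes, samples2, "CD_vs_UC")
  } else {
    NULL
  }
  burden_cc <- if (all(c("case", "control") %in% samples2$cohort)) {
    burden_table(cnvs, genes, samples2, "case_vs_control")
  } else {
    NULL
  }

  structure(
    list(
      params = params, qc_array = qc_array, filtered_calls = filtered,
      stringent = stringent, region_removed = rf$removed,
      qc_count = qc_count, cnvs = cnvs, samples = samples2,
      association = assoc, burden_cd_uc = burden_cd_uc,
      burden_case_control = burden_cc,
      funnel = list_rbind(funnel)
    ),
    class = "cnv_pipeline"
  )
}

#' @export
print.cnv_pipeline <- function(x, ...) {
  cat("Rare-CNV case-control pipeline run\n")
  cat("Funnel (samples / records per stage):\n")
  print(as.data.frame(x$funnel), row.names = FALSE)
  sig <- significant_rare(x$association)
  cat(sprintf(
    "Association: %d gene x type tests, %d significant rare\n",
    nrow(x$association), nrow(sig)
  ))
  invisible(x)
}
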