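# Sample-level quality control.
#
# Two exclusion stages: array-metric QC before CNV analysis (call rate and
# per-batch LRR/BAF SD bands) and CNV-count outlier removal after consensus
# merging. Outlier statistics use the sample standard deviation (n - 1) and
# are computed once per batch on the full batch (single filter pass, no
# re-iteration after exclusions).

qc_decision_tbl <- function(sample_id, reasons) {
  tibble(
    sample_id = sample_id,
    passed = lengths(reasons) == 0,
    reasons = reasons
  )
}

#' Array-metric sample QC
#'
#' A sample fails if its genotype call rate is below `min_call_rate`, or if
#' its LRR SD (respectively BAF SD) falls outside
#' `[batch mean - k_sd * SD, batch mean + k_sd * SD]`, where mean and SD are
#' computed per analysis batch over all samples in that batch. All failing
#' reasons are recorded. In a batch of size one the SD is undefined and the
#' SD criteria pass with a warning.
#'
#' @param samples Sample manifest tibble (see [read_sample_manifest()]).
#' @param min_call_rate Minimum genotype call rate (default 0.95).
#' @param k_sd Width of the SD band in standard deviations (default 3).
#' @return Tibble `sample_id`, `passed`, `reasons` (list-column of failure
#'   codes among `low_call_rate`, `lrr_sd_outlier`, `baf_sd_outlier`), plus
#'   the per-batch bands used.
#' @export
array_metric_qc <- function(samples, min_call_rate = 0.95, k_sd = 3) {
  validate_sample_manifest(samples)
  if (k_sd < 0) abort("k_sd must be non-negative")
  bands <- samples |>
    group_by(.data$batch) |>
    summarise(
      batch_n = n(),
      lrr_mean = mean(.data$lrr_sd), lrr_band_sd = sd(.data$lrr_sd),
      baf_mean = mean(.data$baf_sd), baf_band_sd = sd(.data$baf_sd),
      .groups = "drop"
    )
  if (any(bands$batch_n < 2)) {
    warn(sprintf(
      "batch(es) of size 1 (%s): SD undefined, SD criteria pass by default",
      paste(bands$batch[bands$batch_n < 2], collapse = ", ")
    ))
  }
  df <- left_join(samples, bands, by = "batch") |>
    mutate(
      low_call_rate = .data$call_rate < min_call_rate,
      lrr_sd_outlier = .data$batch_n >= 2 &
        abs(.data$lrr_sd - .data$lrr_mean) > k_sd * .data$lrr_band_sd,
      baf_sd_outlier = .data$batch_n >= 2 &
        abs(.data$baf_sd - .data$baf_mean) > k_sd * .data$baf_band_sd
    )
  reasons <- pmap(
    list(df$low_call_rate, df$lrr_sd_outlier, df$baf_sd_outlier),
    function(cr, l, b) {
      c("low_call_rate", "lrr_sd_outlier", "baf_sd_outlier")[c(cr, l, b)]
    }
  )
  out <- qc_decision_tbl(df$sample_id, reasons)
  out$batch <- df$batch
  out$call_rate <- df$call_rate
  out$lrr_sd <- df$lrr_sd
  out$baf_sd <- df$baf_sd
  out
}

#' CNV-count sample QC
#'
#' After consensus merging, a sample is excluded if it contributed more
#' stringent CNVs than its batch mean plus `k_sd` standard deviations.
#' The filter is one-sided: an unusually low CNV count is not an exclusion.
#' Samples absent from `cnvs` count zero CNVs.
#'
#' @param cnvs Stringent CNV tibble (must contain `sample_id`), or a tibble
#'   with columns `sample_id` and `n_cnvs` of precomputed counts.
#' @param samples Sample manifest tibble; defines the batch of every sample.
#' @param k_sd Band width in standard deviations (default 3).
#' @return Tibble `sample_id`, `passed`, `reasons` (`cnv_count_outlier` when
#'   failing), `n_cnvs`, `batch`, and the batch threshold applied.
#' @export
cnv_count_qc <- function(cnvs, samples, k_sd = 3) {
  validate_sample_manifest(samples)
  if (nrow(samples) == 0) abort("empty sample manifest")
  if ("n_cnvs" %in% names(cnvs)) {
    counts <- select(as_tibble(cnvs), "sample_id", "n_cnvs")
  } else {
    stopifnot_cols(cnvs, "sample_id", "CNV table")
    counts <- count(as_tibble(cnvs), .data$sample_id, name = "n_cnvs")
  }
  unknown <- setdiff(counts$sample_id, samples$sample_id)
  if (length(unknown)) {
    abort(sprintf("CNV counts for sample(s) absent from the manifest: %s",
                  paste(unknown, collapse = ", ")))
  }
  df <- samples |>
    select("sample_id", "batch") |>
    left_join(counts, by = "sample_id") |>
    mutate(n_cnvs = replace_na(.data$n_cnvs, 0L)) |>
    group_by(.data$batch) |>
    mutate(
      batch_n = n(),
      upper = mean(.data$n_cnvs) +
        k_sd * if_else(.data$batch_n >= 2, sd(.data$n_cnvs), NA_real_)
    ) |>
    ungroup() |>
    mutate(fails = !is.na(.data$upper) & .data$n_cnvs > .data$upper)
  reasons <- map(df$fails, function(f) if (f) "cnv_count_outlier" else character(0))
  out <- qc_decision_tbl(df$sample_id, reasons)
  out$n_cnvs <- df$n_cnvs
  out$batch <- df$batch
  out$count_upper <- df$upper
  out
}

#' Flatten QC decisions into a report table
#'
#' @param decisions A QC decision tibble from [array_metric_qc()] or
#'   [cnv_count_qc()].
#' @return The same tibble with `reasons` collapsed to a comma-separated
#'   string, suitable for TSV export.
#' @export
qc_report <- function(decisions) {
  mutate(decisions,
         reasons = map_chr(.data$reasons, paste, collapse = ","))
}
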