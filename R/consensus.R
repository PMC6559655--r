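# Raw-call filtering and multi-caller consensus merging.
#
# A "stringent CNV" is a maximal connected component of same-type,
# same-sample raw calls (edge = >= 1 bp overlap, with transitive closure)
# supported by at least two distinct callers; its breakpoints are the
# outermost union of the member calls. Components are found with a line
# sweep per (sample, chrom, type) stratum: after sorting by start, a new
# component opens exactly where a call starts at or beyond the running
# maximum end (half-open intervals, so abutting calls do not overlap).

#' Filter raw CNV calls by size, probe content and quality
#'
#' A call is retained iff its length is at least `min_size_bp` (strictly
#' greater when `strict_gt = TRUE`), it spans at least `min_probes` probes,
#' and, when a quality threshold is configured for its caller, its quality
#' score is at or above that threshold.
#'
#' @param calls Raw-call tibble (see [read_cnv_calls()]).
#' @param min_size_bp Minimum length in bp (default 5000).
#' @param min_probes Minimum probe count (default 5).
#' @param quality_thresholds Optional named numeric vector of per-caller
#'   minimum quality scores; callers without an entry are not quality
#'   filtered.
#' @param strict_gt If `TRUE`, require length strictly greater than
#'   `min_size_bp` instead of the default inclusive boundary.
#' @return The retained calls, with attribute `filter_report`: a tibble of
#'   removal counts per criterion (a call failing several criteria counts
#'   once per criterion).
#' @export
filter_raw_calls <- function(calls, min_size_bp = 5000L, min_probes = 5L,
                             quality_thresholds = NULL, strict_gt = FALSE) {
  stopifnot_cols(calls, c("sample_id", "chrom", "start", "end", "cnv_type",
                          "n_probes", "quality", "caller"), "raw calls")
  validate_cnv_type(calls$cnv_type)
  if (min_size_bp < 0 || min_probes < 0) {
    abort("size/probe thresholds must be non-negative")
  }
  if (!is.null(quality_thresholds) && any(quality_thresholds < 0)) {
    abort("quality thresholds must be non-negative")
  }
  len <- calls$end - calls$start
  fail_size <- if (strict_gt) len <= min_size_bp else len < min_size_bp
  fail_probes <- calls$n_probes < min_probes
  fail_quality <- rep(FALSE, nrow(calls))
  if (!is.null(quality_thresholds)) {
    idx <- calls$caller %in% names(quality_thresholds)
    fail_quality[idx] <- is.na(calls$quality[idx]) |
      calls$quality[idx] < quality_thresholds[calls$caller[idx]]
  }
  keep <- !(fail_size | fail_probes | fail_quality)
  out <- calls[keep, ]
  attr(out, "filter_report") <- tibble(
    criterion = c("size", "probes", "quality"),
    n_removed = c(sum(fail_size), sum(fail_probes), sum(fail_quality))
  )
  out
}

# Connected components under the reciprocal-overlap linkage rule:
# union-find over pairs whose intersection covers >= frac of both calls.
reciprocal_components <- function(start, end, frac) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      ov <- min(end[i], end[j]) - max(start[i], start[j])
      if (ov >= frac * (end[i] - start[i]) &&
          ov >= frac * (end[j] - start[j]) && ov > 0) {
        parent[find(j)] <- find(i)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Merge filtered calls into stringent consensus CNVs
#'
#' Within each (sample, chromosome, CNV type) stratum, overlapping calls
#' (>= 1 bp, transitively) are grouped into connected components. Each
#' component supported by at least `min_callers` distinct callers emits one
#' stringent CNV spanning the outermost union `min(start)..max(end)`;
#' single-caller components are dropped. Deletions and duplications never
#' co-merge, and repeated calls from one caller never satisfy the
#' multi-caller requirement.
#'
#' @param calls Filtered raw-call tibble.
#' @param samples Optional sample manifest; when supplied, calls from
#'   samples absent from it are an error.
#' @param min_callers Minimum number of distinct supporting callers
#'   (default 2).
#' @param min_reciprocal_overlap Stricter matching rule: two calls are
#'   linked only when their intersection covers at least this fraction of
#'   **both** calls. The default 0 links any >= 1 bp overlap (the most
#'   permissive deterministic reading).
#' @return Tibble of stringent CNVs (`sample_id`, `chrom`, `start`, `end`,
#'   `cnv_type`, `length`, `n_callers`, `callers`, `max_probes`), sorted by
#'   (sample_id, chrom, start, end, cnv_type), with attribute `members`
#'   mapping every input call to its component (`component` = output row or
#'   NA for dropped components).
#' @export
merge_consensus <- function(calls, samples = NULL, min_callers = 2L,
                            min_reciprocal_overlap = 0) {
  if (min_reciprocal_overlap < 0 || min_reciprocal_overlap > 1) {
    abort("min_reciprocal_overlap must lie in [0, 1]")
  }
  stopifnot_cols(calls, c("sample_id", "chrom", "start", "end", "cnv_type",
                          "n_probes", "caller"), "raw calls")
  validate_cnv_type(calls$cnv_type)
  if (!is.null(samples)) {
    unknown <- setdiff(unique(calls$sample_id), samples$sample_id)
    if (length(unknown)) {
      abort(sprintf("calls from sample(s) absent from the manifest: %s",
                    paste(unknown, collapse = ", ")))
    }
  }
  if (nrow(calls) == 0) {
    out <- tibble(
      sample_id = character(), chrom = character(), start = integer(),
      end = integer(), cnv_type = character(), length = integer(),
      n_callers = integer(), callers = character(), max_probes = integer()
    )
    attr(out, "members") <- tibble(call_row = integer(), component = integer())
    return(out)
  }

  df <- as_tibble(calls) |>
    mutate(.call_row = row_number()) |>
    arrange(.data$sample_id, .data$chrom, .data$cnv_type, .data$start,
            .data$end)
  if (min_reciprocal_overlap == 0) {
    df <- df |>
      group_by(.data$sample_id, .data$chrom, .data$cnv_type) |>
      mutate(
        # new component where a call starts at/after everything seen so far
        .new = as.numeric(.data$start) >=
          lag(cummax(as.numeric(.data$end)), default = -Inf),
        .comp = cumsum(.data$.new)
      ) |>
      ungroup()
  } else {
    df <- df |>
      group_by(.data$sample_id, .data$chrom, .data$cnv_type) |>
      mutate(.comp = reciprocal_components(.data$start, .data$end,
                                           min_reciprocal_overlap)) |>
      ungroup()
  }

  comps <- df |>
    group_by(.data$sample_id, .data$chrom, .data$cnv_type, .data$.comp) |>
    summarise(
      start = min(.data$start),
      end = max(.data$end),
      n_callers = dplyr::n_distinct(.data$caller),
      callers = paste(sort(unique(.data$caller)), collapse = ","),
      max_probes = max(.data$n_probes),
      .groups = "drop"
    ) |>
    mutate(length = .data$end - .data$start)

  comps <- comps |>
    mutate(emit = .data$n_callers >= min_callers) |>
    arrange(.data$sample_id, .data$chrom, .data$start, .data$end,
            .data$cnv_type)
  comps$out_row <- NA_integer_
  comps$out_row[comps$emit] <- seq_len(sum(comps$emit))

  members <- df |>
    left_join(
      select(comps, "sample_id", "chrom", "cnv_type", ".comp", "out_row"),
      by = c("sample_id", "chrom", "cnv_type", ".comp")
    ) |>
    select(call_row = ".call_row", component = "out_row") |>
    arrange(.data$call_row)

  out <- comps |>
    filter(.data$emit) |>
    select("sample_id", "chrom", "start", "end", "cnv_type", "length",
           "n_callers", "callers", "max_probes")
  attr(out, "members") <- members
  out
}
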