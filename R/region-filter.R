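# Genomic-context exclusion filters for stringent CNVs.
#
# Rules: any (>= 1 bp) overlap with a buffered centromere/telomere track
# removes a CNV outright; fractional overlap with the segmental-duplication
# or immunoglobulin track removes a CNV only when the fraction of its length
# covered is strictly greater than the configured threshold (0.70).

#' Fraction of each CNV covered by a region track
#'
#' Computes (total bp of cnv intersected with the track) / (cnv length) for
#' every row of `cnvs`. The track is union-merged first, so the result is
#' invariant to how the track was split into sub-intervals.
#'
#' @param cnvs Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param track Region-track tibble (see [read_region_track()]).
#' @return Numeric vector in \[0, 1\], one value per CNV.
#' @export
overlap_fraction <- function(cnvs, track) {
  stopifnot_cols(cnvs, c("chrom", "start", "end"), "CNV table")
  if (nrow(cnvs) > 0 && any(cnvs$end <= cnvs$start)) {
    abort("zero- or negative-length CNV in overlap_fraction()")
  }
  track <- merge_intervals(track)
  intersect_widths(cnvs, track) / (cnvs$end - cnvs$start)
}

#' Build buffered centromere/telomere exclusion windows
#'
#' For each chromosome with a centromere annotation, emits the window
#' `[cen_start - buffer, cen_end + buffer)` clipped to
#' `[0, chrom_length)`; for every chromosome in the length table, emits the
#' telomere windows `[0, buffer)` and `[chrom_length - buffer,
#' chrom_length)`.
#'
#' @param centromeres Region-track tibble of centromere intervals.
#' @param chrom_lengths Tibble with `chrom` and `length` (bp).
#' @param buffer_bp Buffer size in bp (default 100 kb).
#' @return A union-merged region-track tibble.
#' @export
build_buffer_tracks <- function(centromeres, chrom_lengths,
                                buffer_bp = 100000L) {
  stopifnot_cols(chrom_lengths, c("chrom", "length"), "chromosome lengths")
  if (buffer_bp <= 0) abort("buffer_bp must be positive")
  missing <- setdiff(unique(centromeres$chrom), chrom_lengths$chrom)
  if (length(missing)) {
    abort(sprintf("centromere chromosome(s) missing a length: %s",
                  paste(missing, collapse = ", ")))
  }
  len <- setNames(chrom_lengths$length, chrom_lengths$chrom)
  cen <- centromeres |>
    mutate(
      start = pmax(0L, .data$start - buffer_bp),
      end = pmin(unname(len[.data$chrom]), .data$end + buffer_bp)
    )
  tel <- bind_rows(
    tibble(chrom = chrom_lengths$chrom, start = 0L,
           end = pmin(chrom_lengths$length, buffer_bp)),
    tibble(chrom = chrom_lengths$chrom,
           start = pmax(0L, chrom_lengths$length - buffer_bp),
           end = chrom_lengths$length)
  )
  out <- merge_intervals(bind_rows(
    select(cen, "chrom", "start", "end"), tel
  ))
  attr(out, "track_name") <- "centromere_telomere_buffer"
  out
}

#' Apply genomic-context exclusion rules to stringent CNVs
#'
#' A CNV is removed iff it overlaps the buffered centromere/telomere track
#' by at least one bp, or more than `segdup_max_frac` of its length lies in
#' the segmental-duplication track, or more than `ig_max_frac` of its length
#' lies in the immunoglobulin track. Every input CNV lands in exactly one of
#' kept/removed; removed CNVs carry all matching rules.
#'
#' @param cnvs Stringent CNV tibble.
#' @param tracks Named list with elements `centromere_telomere` (already
#'   buffered; see [build_buffer_tracks()]), `segdup` and `immunoglobulin`.
#'   A missing required track is a configuration error. A default
#'   immunoglobulin track covering the IGH/IGK/IGL loci (approximate hg19
#'   coordinates) ships with the package:
#'   `read_region_track(system.file("extdata", "immunoglobulin_hg19.bed",
#'   package = "rarecnv"), "immunoglobulin")`.
#' @param segdup_max_frac,ig_max_frac Strict fraction thresholds
#'   (default 0.70): a CNV at exactly the threshold is kept.
#' @return List with `kept` (input rows passing all rules) and `removed`
#'   (input rows plus `rules`, a comma-separated list of all matching rules,
#'   first match first).
#' @export
apply_region_filters <- function(cnvs, tracks,
                                 segdup_max_frac = 0.70,
                                 ig_max_frac = 0.70) {
  required <- c("centromere_telomere", "segdup", "immunoglobulin")
  missing <- setdiff(required, names(tracks))
  if (length(missing)) {
    abort(sprintf("missing required track(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (!(segdup_max_frac > 0 && segdup_max_frac <= 1) ||
      !(ig_max_frac > 0 && ig_max_frac <= 1)) {
    abort("fraction thresholds must lie in (0, 1]")
  }
  cnvs <- as_tibble(cnvs)
  if (nrow(cnvs) == 0) {
    return(list(kept = cnvs, removed = mutate(cnvs, rules = character(0))))
  }
  cen_bp <- intersect_widths(cnvs, merge_intervals(tracks$centromere_telomere))
  segdup_frac <- overlap_fraction(cnvs, tracks$segdup)
  ig_frac <- overlap_fraction(cnvs, tracks$immunoglobulin)

  hit <- cbind(
    centromere_telomere = cen_bp > 0,
    segdup_fraction = segdup_frac > segdup_max_frac,
    ig_fraction = ig_frac > ig_max_frac
  )
  removed_idx <- rowSums(hit) > 0
  rules <- apply(hit[removed_idx, , drop = FALSE], 1, function(r) {
    paste(colnames(hit)[r], collapse = ",")
  })
  list(
    kept = cnvs[!removed_idx, ],
    removed = mutate(cnvs[removed_idx, ], rules = unname(rules))
  )
}
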