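# Internal helpers shared across modules.
#
# All genomic intervals inside the package are 0-based, half-open [start, end):
# length = end - start. Conversion to the 1-based, closed convention used by
# IRanges/GenomicRanges happens only inside these helpers.

CNV_TYPES <- c("deletion", "duplication")
CALLER_IDS <- c("caller_A", "caller_B", "caller_C")

#' Normalize chromosome names to the canonical "chr*" form
#'
#' Adds a "chr" prefix where missing and resolves configured aliases
#' (e.g. `c(MT = "chrM")`). Normalization is idempotent.
#'
#' @param x Character vector of chromosome names.
#' @param aliases Named character vector mapping observed names to canonical
#'   ones; applied before prefixing.
#' @return Character vector of canonical names.
#' @export
normalize_chrom <- function(x, aliases = NULL) {
  x <- as.character(x)
  if (!is.null(aliases) && length(aliases)) {
    hit <- x %in% names(aliases)
    x[hit] <- unname(aliases[x[hit]])
  }
  pre <- !startsWith(x, "chr")
  x[pre] <- paste0("chr", x[pre])
  x
}

# tibble(chrom, start, end) [0-based half-open] -> GRanges (1-based closed)
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# GRanges -> tibble(chrom, start, end) in 0-based half-open coordinates
granges_to_tbl0 <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr)
  )
}

# Union-merge intervals per chromosome; overlapping or bookended ([a,b) [b,c))
# inputs collapse to disjoint sorted intervals. Fractions computed downstream
# are invariant to how a track was split into sub-intervals.
merge_intervals <- function(df) {
  if (nrow(df) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  gr <- GenomicRanges::reduce(as_granges0(df))
  arrange(granges_to_tbl0(gr), .data$chrom, .data$start)
}

# findOverlaps with the chromosome-universe mismatch warning silenced
# (querying e.g. a chr1-only CNV set against a chr2-only track is routine)
overlaps <- function(x, y) {
  suppressWarnings(GenomicRanges::findOverlaps(x, y))
}

# Total intersection width (bp) of each query interval with a track.
# `track` must already be union-merged so bp are not double counted.
intersect_widths <- function(query, track) {
  if (nrow(query) == 0) return(integer(0))
  if (nrow(track) == 0) return(rep(0L, nrow(query)))
  qg <- as_granges0(query)
  tg <- as_granges0(track)
  hits <- overlaps(qg, tg)
  if (length(hits) == 0) return(rep(0L, nrow(query)))
  qi <- S4Vectors::queryHits(hits)
  pieces <- GenomicRanges::pintersect(qg[qi], tg[S4Vectors::subjectHits(hits)])
  w <- tapply(BiocGenerics::width(pieces), qi, sum)
  out <- rep(0L, nrow(query))
  out[as.integer(names(w))] <- as.integer(w)
  out
}

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

validate_cnv_type <- function(x) {
  bad <- setdiff(unique(x), CNV_TYPES)
  if (length(bad)) {
    abort(sprintf("invalid cnv_type value(s): %s", paste(bad, collapse = ", ")))
  }
  invisible(x)
}

# Deterministic sub-seed per simulation component so that changing one rate
# does not reshuffle the random stream of another component.
component_seed <- function(seed, component) {
  offsets <- c(
    genome = 11L, manifest = 23L, placement = 37L, lengths = 53L,
    planting = 67L, dropout = 83L, jitter = 101L, fp = 127L, qc = 149L
  )
  off <- offsets[[component]]
  as.integer((as.numeric(seed) * 1009 + off * 9973) %% .Machine$integer.max)
}
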