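# Readers and writers for every external file the pipeline touches.
#
# Internal coordinate convention: 0-based, half-open everywhere (BED-native).
# Caller tables are declared 1-based inclusive by default (the PennCNV-style
# convention) and are converted at the boundary.

#' Column-mapping dialect for per-caller CNV tables
#'
#' CNV callers emit tab-separated tables with caller-specific column names,
#' coordinate conventions and copy-number encodings. A dialect maps those
#' onto the package's internal representation once, at read time.
#'
#' @param sample_id,chrom,start,end,state,n_probes,quality Column names in
#'   the input file holding the respective fields.
#' @param coords Coordinate convention of the input: `"1-based-inclusive"`
#'   (default; length = end - start + 1) or `"0-based-half-open"`.
#' @param deletion_states Integer copy-number states mapped to deletions
#'   (default 0 and 1).
#' @param duplication_min_state Minimum copy-number state mapped to
#'   duplications (default 3). State 2 (copy-neutral) is always skipped.
#' @param chrom_aliases Named character vector of chromosome-name aliases,
#'   see [normalize_chrom()].
#' @return A list of class `cnv_dialect`.
#' @export
cnv_dialect <- function(sample_id = "sample_id", chrom = "chrom",
                        start = "start", end = "end", state = "cn",
                        n_probes = "n_probes", quality = "quality",
                        coords = c("1-based-inclusive", "0-based-half-open"),
                        deletion_states = c(0L, 1L),
                        duplication_min_state = 3L,
                        chrom_aliases = NULL) {
  coords <- match.arg(coords)
  structure(
    list(
      columns = c(
        sample_id = sample_id, chrom = chrom, start = start, end = end,
        state = state, n_probes = n_probes, quality = quality
      ),
      coords = coords,
      deletion_states = as.integer(deletion_states),
      duplication_min_state = as.integer(duplication_min_state),
      chrom_aliases = chrom_aliases
    ),
    class = "cnv_dialect"
  )
}

#' Read one caller's raw CNV calls
#'
#' Parses a tab-separated caller output table into the internal raw-call
#' representation: coordinates normalized to 0-based half-open, copy-number
#' states mapped to deletion/duplication, chromosome names canonicalized.
#' Copy-neutral rows (state 2) are never calls and are always skipped;
#' malformed rows (non-positive length, unparseable fields) raise an error in
#' strict mode and are otherwise logged in the skip report.
#'
#' @param path Path to the caller table (TSV with header).
#' @param caller Caller identifier, one of `"caller_A"`, `"caller_B"`,
#'   `"caller_C"`.
#' @param dialect A [cnv_dialect()] describing the file.
#' @param strict If `TRUE` (default) malformed rows abort the read; if
#'   `FALSE` they are skipped and reported.
#' @return A tibble with columns `sample_id`, `chrom`, `start`, `end`,
#'   `cnv_type`, `n_probes`, `quality`, `caller`, carrying a `skip_report`
#'   attribute (tibble of row number + reason for every skipped row).
#' @export
read_cnv_calls <- function(path, caller, dialect = cnv_dialect(),
                           strict = TRUE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  caller <- match.arg(caller, CALLER_IDS)
  raw <- read_tsv(path, col_types = cols(.default = col_character()),
                  progress = FALSE)
  missing <- setdiff(unname(dialect$columns), names(raw))
  if (length(missing)) {
    abort(sprintf(
      "caller table %s lacks column(s) required by the dialect: %s",
      path, paste(missing, collapse = ", ")
    ))
  }
  cl <- dialect$columns
  df <- tibble(
    row = seq_len(nrow(raw)),
    sample_id = raw[[cl[["sample_id"]]]],
    chrom = normalize_chrom(raw[[cl[["chrom"]]]], dialect$chrom_aliases),
    start = suppressWarnings(as.numeric(raw[[cl[["start"]]]])),
    end = suppressWarnings(as.numeric(raw[[cl[["end"]]]])),
    state = suppressWarnings(as.integer(raw[[cl[["state"]]]])),
    n_probes = suppressWarnings(as.integer(raw[[cl[["n_probes"]]]])),
    quality = suppressWarnings(as.numeric(raw[[cl[["quality"]]]]))
  )
  if (dialect$coords == "1-based-inclusive") {
    df$start <- df$start - 1
  }

  reason <- rep(NA_character_, nrow(df))
  bad_field <- is.na(df$sample_id) | is.na(df$start) | is.na(df$end) |
    is.na(df$state) | is.na(df$n_probes)
  reason[bad_field] <- "unparseable field"
  neutral <- !bad_field & !(df$state %in% dialect$deletion_states) &
    df$state < dialect$duplication_min_state
  reason[neutral] <- "copy-neutral state"
  bad_span <- !bad_field & !neutral & df$end <= df$start
  reason[bad_span] <- "end <= start"
  bad_probe <- !bad_field & !neutral & !bad_span & df$n_probes < 1
  reason[bad_probe] <- "n_probes < 1"

  skipped <- tibble(row = df$row[!is.na(reason)],
                    reason = reason[!is.na(reason)])
  hard <- skipped$reason != "copy-neutral state"
  if (strict && any(hard)) {
    abort(sprintf(
      "malformed row(s) in %s: %s",
      path,
      paste(sprintf("row %d (%s)", skipped$row[hard], skipped$reason[hard]),
            collapse = "; ")
    ))
  }

  keep <- df[is.na(reason), ]
  out <- tibble(
    sample_id = keep$sample_id,
    chrom = keep$chrom,
    start = as.integer(keep$start),
    end = as.integer(keep$end),
    cnv_type = if_else(keep$state %in% dialect$deletion_states,
                       "deletion", "duplication"),
    n_probes = keep$n_probes,
    quality = keep$quality,
    caller = caller
  )
  attr(out, "skip_report") <- skipped
  out
}

#' Read a BED region track
#'
#' Reads a BED3+ file and union-merges its intervals per chromosome so that
#' overlap fractions are well defined. Unsorted input is allowed.
#'
#' @param path BED file path (an empty file yields an empty, valid track).
#' @param name Track name (e.g. `"segdup"`, `"immunoglobulin"`).
#' @param merge Union-merge intervals on load (default `TRUE`).
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open), sorted,
#'   with attribute `track_name`.
#' @export
read_region_track <- function(path, name = "custom", merge = TRUE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  gr <- rtracklayer::import(path, format = "BED")
  df <- granges_to_tbl0(gr)
  if (any(df$start < 0)) abort(sprintf("negative coordinates in %s", path))
  if (merge) df <- merge_intervals(df) else df <- arrange(df, .data$chrom, .data$start)
  attr(df, "track_name") <- name
  df
}

#' Read gene models from a BED4 file
#'
#' @param path BED file with the gene identifier in the name (4th) column.
#' @return Tibble `gene_id`, `chrom`, `start`, `end` (0-based half-open).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  gr <- rtracklayer::import(path, format = "BED")
  nm <- if ("name" %in% names(S4Vectors::mcols(gr))) {
    as.character(S4Vectors::mcols(gr)$name)
  } else {
    character(0)
  }
  df <- granges_to_tbl0(gr)
  if (nrow(df) > 0 && length(nm) != nrow(df)) {
    abort(sprintf("gene BED %s lacks a name column", path))
  }
  out <- tibble(gene_id = nm, chrom = df$chrom, start = df$start, end = df$end)
  if (anyDuplicated(out$gene_id)) {
    dup <- unique(out$gene_id[duplicated(out$gene_id)])
    abort(sprintf("duplicate gene_id(s): %s", paste(dup, collapse = ", ")))
  }
  if (nrow(out) > 0 && any(out$end <= out$start)) {
    abort(sprintf("gene with end <= start in %s", path))
  }
  arrange(out, .data$chrom, .data$start)
}

parse_rate <- function(x) {
  x <- str_trim(as.character(x))
  pct <- str_detect(x, "%$")
  v <- suppressWarnings(as.numeric(str_remove(x, "%$")))
  v[pct & !is.na(v)] <- v[pct & !is.na(v)] / 100
  v
}

#' Read the sample manifest
#'
#' The manifest is a TSV with columns `sample_id`, `cohort` (case/control),
#' `subtype` (CD/UC for cases, none for controls), `batch`, `call_rate`,
#' `lrr_sd`, `baf_sd`. Call rates may be given as proportions ("0.942") or
#' percentages ("94.2%"); both parse to the proportion.
#'
#' @param path Manifest TSV path.
#' @return Validated tibble of sample records.
#' @export
read_sample_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- read_tsv(path, col_types = cols(.default = col_character()),
                 progress = FALSE)
  stopifnot_cols(df, c("sample_id", "cohort", "subtype", "batch",
                       "call_rate", "lrr_sd", "baf_sd"), "sample manifest")
  out <- tibble(
    sample_id = df$sample_id,
    cohort = df$cohort,
    subtype = if_else(is.na(df$subtype) | df$subtype == "", "none",
                      df$subtype),
    batch = df$batch,
    call_rate = parse_rate(df$call_rate),
    lrr_sd = as.numeric(df$lrr_sd),
    baf_sd = as.numeric(df$baf_sd)
  )
  validate_sample_manifest(out)
}

#' Validate a sample manifest tibble
#'
#' Enforces unique sample ids, known cohort/subtype levels, the
#' subtype-iff-case rule, and metric ranges.
#'
#' @param samples Tibble of sample records.
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_sample_manifest <- function(samples) {
  stopifnot_cols(samples, c("sample_id", "cohort", "subtype", "batch",
                            "call_rate", "lrr_sd", "baf_sd"),
                 "sample manifest")
  if (anyDuplicated(samples$sample_id)) {
    dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
    abort(sprintf("duplicate sample_id(s): %s", paste(dup, collapse = ", ")))
  }
  if (!all(samples$cohort %in% c("case", "control"))) {
    abort("cohort must be 'case' or 'control'")
  }
  if (!all(samples$subtype %in% c("CD", "UC", "none"))) {
    abort("subtype must be 'CD', 'UC' or 'none'")
  }
  bad_ctl <- samples$cohort == "control" & samples$subtype != "none"
  if (any(bad_ctl)) {
    abort(sprintf("control sample(s) with a subtype: %s",
                  paste(samples$sample_id[bad_ctl], collapse = ", ")))
  }
  bad_case <- samples$cohort == "case" & !(samples$subtype %in% c("CD", "UC"))
  if (any(bad_case)) {
    abort(sprintf("case sample(s) without CD/UC subtype: %s",
                  paste(samples$sample_id[bad_case], collapse = ", ")))
  }
  if (any(!is.na(samples$call_rate) &
          (samples$call_rate < 0 | samples$call_rate > 1))) {
    abort("call_rate must lie in [0, 1]")
  }
  samples
}

#' Read a GMT gene-set library
#'
#' @param path GMT file: one set per line, tab-separated
#'   `set_id<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#'   within one set are deduplicated.
#' @param library_name Name recorded for the library (defaults to the file
#'   base name).
#' @return A list of class `gene_set_library` with elements `library_name`
#'   and `sets` (named list of `list(description=, members=)`).
#' @export
read_gmt <- function(path, library_name = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    abort(sprintf("GMT line(s) with fewer than 3 fields: %s",
                  paste(short, collapse = ", ")))
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate set id(s) in %s", path))
  }
  sets <- lapply(fields, function(f) {
    list(description = f[[2]], members = unique(f[-(1:2)]))
  })
  names(sets) <- ids
  structure(
    list(library_name = library_name %||% sub("\\.gmt$", "", basename(path)),
         sets = sets),
    class = "gene_set_library"
  )
}

#' Write a gene-set library to GMT
#'
#' @param library A `gene_set_library` as returned by [read_gmt()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(library, path) {
  lines <- vapply(names(library$sets), function(id) {
    s <- library$sets[[id]]
    paste(c(id, s$description, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

STRINGENT_COLS <- c("sample_id", "chrom", "start", "end", "cnv_type",
                    "length", "n_callers", "callers", "max_probes")

#' Write / read stringent CNV tables
#'
#' Stringent CNVs are written as a TSV with a fixed column order and a
#' stable (chrom, start, end, sample_id) sort so that outputs are
#' deterministic and `read_cnv_table(write_cnv_table(x))` round-trips.
#'
#' @param cnvs Tibble of stringent CNVs.
#' @param path Output TSV path.
#' @return `write_cnv_table()` the path invisibly; `read_cnv_table()` the
#'   tibble.
#' @export
write_cnv_table <- function(cnvs, path) {
  stopifnot_cols(cnvs, STRINGENT_COLS, "stringent CNV table")
  out <- arrange(select(as_tibble(cnvs), all_of(STRINGENT_COLS)),
                 .data$chrom, .data$start, .data$end, .data$sample_id)
  write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_cnv_table
#' @export
read_cnv_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- read_tsv(path, col_types = cols(
    sample_id = col_character(), chrom = col_character(),
    start = col_integer(), end = col_integer(), cnv_type = col_character(),
    length = col_integer(), n_callers = col_integer(),
    callers = col_character(), max_probes = col_integer()
  ), progress = FALSE)
  validate_cnv_type(df$cnv_type)
  df
}

ASSOC_COLS <- c("gene_id", "cnv_type", "case_carriers", "case_cd", "case_uc",
                "control_carriers", "n_cases", "n_controls", "or_cmle",
                "or_sample", "ci_low", "ci_high", "p_two_sided", "p_adj",
                "is_rare")

#' Write / read gene association tables
#'
#' @param results Association results (from [run_association()]).
#' @param path Output TSV path.
#' @return `write_association_table()` the path invisibly;
#'   `read_association_table()` the tibble.
#' @export
write_association_table <- function(results, path) {
  stopifnot_cols(results, ASSOC_COLS, "association table")
  out <- arrange(select(as_tibble(results), all_of(ASSOC_COLS)),
                 .data$cnv_type, .data$gene_id)
  write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_association_table
#' @export
read_association_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  read_tsv(path, col_types = cols(
    gene_id = col_character(), cnv_type = col_character(),
    case_carriers = col_integer(), case_cd = col_integer(),
    case_uc = col_integer(), control_carriers = col_integer(),
    n_cases = col_integer(), n_controls = col_integer(),
    or_cmle = col_double(), or_sample = col_double(),
    ci_low = col_double(), ci_high = col_double(),
    p_two_sided = col_double(), p_adj = col_double(),
    is_rare = readr::col_logical()
  ), progress = FALSE)
}

#' Write a region track or gene models to BED
#'
#' @param x Tibble with `chrom`, `start`, `end` and optionally `gene_id`.
#' @param path Output BED path.
#' @return The path, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot_cols(x, c("chrom", "start", "end"), "BED input")
  x <- arrange(as_tibble(x), .data$chrom, .data$start, .data$end)
  cols <- c("chrom", "start", "end")
  if ("gene_id" %in% names(x)) cols <- c(cols, "gene_id")
  write.table(x[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
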