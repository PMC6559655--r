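# Seeded synthetic CNV studies with known ground truth.
#
# The generator emulates the statistical structure of a SNP-array rare-CNV
# case-control study: a small case cohort against a large control cohort,
# three callers observing the same underlying CNVs with per-caller dropout,
# breakpoint jitter and caller-specific false positives, a length mixture
# dominated by sub-100 kb events, and a configurable set of planted
# case-enriched genic CNVs with exact carrier counts. Each random component
# (genome layout, manifest, placement, lengths, planting, dropout, jitter,
# false positives) draws from its own seeded stream, so changing one rate
# does not reshuffle the others.

#' Configuration for a synthetic CNV study
#'
#' Defaults describe the emulated study: 243 cases vs 2,988 controls, about
#' 18 true CNVs per sample, ~88% of events shorter than 100 kb, 65%
#' deletions, three callers with dropout, jitter and false positives.
#'
#' @param seed Master seed; every component stream derives from it.
#' @param n_cases,n_controls Cohort sizes.
#' @param n_chromosomes,chrom_length_bp Genome layout (equal-length
#'   chromosomes named chr1..chrN).
#' @param n_genes Number of gene models, placed outside excluded regions.
#' @param background_cnv_rate_per_sample Mean true CNVs per sample
#'   (Poisson).
#' @param length_mixture_weights Probabilities of the four length classes
#'   \[5-100 kb, 100-500 kb, 500 kb-1 Mb, >1 Mb\); lengths are log-uniform
#'   within a class.
#' @param deletion_fraction Probability a background event is a deletion.
#' @param caller_sensitivity Named per-caller emission probability for true
#'   events.
#' @param breakpoint_jitter_sd_bp SD of the rounded Gaussian endpoint
#'   jitter applied to every emitted call.
#' @param caller_fp_rate Mean false-positive calls per sample per caller
#'   (Poisson). False positives never overlap another call of the same
#'   sample and type, so they are single-caller by construction.
#' @param probe_density Probes per bp; `n_probes = floor(length * density)`.
#' @param n_batches Number of analysis batches in the manifest.
#' @param planted_signals Tibble with `gene_id`, `cnv_type`,
#'   `n_case_carriers`, `n_control_carriers`; gene ids refer to the
#'   generated gene models (`gene_0001`...). Background events avoid
#'   planted gene loci so the configured carrier counts are exact.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_cases = 243L, n_controls = 2988L,
                              n_chromosomes = 5L, chrom_length_bp = 3e7,
                              n_genes = 400L,
                              background_cnv_rate_per_sample = 18,
                              length_mixture_weights =
                                c(0.881, 0.108, 0.0075, 0.003),
                              deletion_fraction = 0.65,
                              caller_sensitivity = c(caller_A = 0.92,
                                                     caller_B = 0.95,
                                                     caller_C = 0.90),
                              breakpoint_jitter_sd_bp = 300,
                              caller_fp_rate = 2,
                              probe_density = 0.001,
                              n_batches = 4L,
                              planted_signals = NULL) {
  if (any(c(background_cnv_rate_per_sample, breakpoint_jitter_sd_bp,
            caller_fp_rate, probe_density) < 0)) {
    abort("rates must be non-negative")
  }
  if (!all(names(caller_sensitivity) %in% CALLER_IDS) ||
      any(caller_sensitivity <= 0 | caller_sensitivity > 1)) {
    abort("caller_sensitivity must be named probabilities in (0, 1]")
  }
  if (!is.null(planted_signals)) {
    stopifnot_cols(planted_signals,
                   c("gene_id", "cnv_type", "n_case_carriers",
                     "n_control_carriers"), "planted_signals")
    validate_cnv_type(planted_signals$cnv_type)
    if (any(planted_signals$n_case_carriers > n_cases) ||
        any(planted_signals$n_control_carriers > n_controls)) {
      abort("cannot plant more carriers than samples in a cohort")
    }
  }
  structure(
    list(
      seed = as.integer(seed), n_cases = as.integer(n_cases),
      n_controls = as.integer(n_controls),
      n_chromosomes = as.integer(n_chromosomes),
      chrom_length_bp = chrom_length_bp, n_genes = as.integer(n_genes),
      background_cnv_rate_per_sample = background_cnv_rate_per_sample,
      length_mixture_weights =
        length_mixture_weights / sum(length_mixture_weights),
      deletion_fraction = deletion_fraction,
      caller_sensitivity = caller_sensitivity,
      breakpoint_jitter_sd_bp = breakpoint_jitter_sd_bp,
      caller_fp_rate = caller_fp_rate,
      probe_density = probe_density,
      n_batches = as.integer(n_batches),
      planted_signals = planted_signals
    ),
    class = "simulation_config"
  )
}

# log-uniform draw within the configured length class per event
draw_lengths <- function(n, weights) {
  lo <- c(5e3, 1e5, 5e5, 1e6)
  hi <- c(1e5, 5e5, 1e6, 3e6)
  cls <- sample.int(4, n, replace = TRUE, prob = weights)
  round(exp(runif(n, log(lo[cls]), log(hi[cls]))))
}

# Uniform placement of intervals of the given lengths, avoiding a mask.
# Rejection sampling with a bounded number of redraw rounds; the returned
# tibble carries `.idx`, the index into `lengths` of each placed interval
# (unplaced leftovers after max_rounds are dropped).
place_intervals <- function(lengths, chroms_tbl, avoid = NULL,
                            max_rounds = 8L) {
  n <- length(lengths)
  if (n == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  .idx = integer()))
  }
  prob <- chroms_tbl$length / sum(chroms_tbl$length)
  out_chrom <- rep(NA_character_, n); out_start <- rep(NA_real_, n)
  out_len <- rep(NA_real_, n)
  todo <- seq_len(n)
  for (round in seq_len(max_rounds)) {
    if (!length(todo)) break
    ci <- sample.int(nrow(chroms_tbl), length(todo), replace = TRUE,
                     prob = prob)
    L <- chroms_tbl$length[ci]
    len <- pmin(lengths[todo], L - 1)
    st <- floor(runif(length(todo), 0, L - len))
    cand <- tibble(chrom = chroms_tbl$chrom[ci], start = st, end = st + len)
    ok <- rep(TRUE, length(todo))
    if (!is.null(avoid) && nrow(avoid) > 0) {
      ok <- intersect_widths(cand, avoid) == 0
    }
    out_chrom[todo[ok]] <- cand$chrom[ok]
    out_start[todo[ok]] <- cand$start[ok]
    out_len[todo[ok]] <- len[ok]
    todo <- todo[!ok]
  }
  placed <- which(!is.na(out_chrom))
  tibble(chrom = out_chrom[placed],
         start = as.integer(out_start[placed]),
         end = as.integer(out_start[placed] + out_len[placed]),
         .idx = placed)
}

# Mutually disjoint placement (used for gene models): redraw intervals that
# collide with an already accepted one for a few rounds.
place_disjoint_intervals <- function(lengths, chroms_tbl, avoid = NULL,
                                     max_rounds = 8L) {
  accepted <- NULL
  todo <- seq_along(lengths)
  for (round in seq_len(max_rounds)) {
    if (!length(todo)) break
    mask <- if (is.null(accepted)) avoid else {
      merge_intervals(bind_rows(avoid, accepted[, c("chrom", "start", "end")]))
    }
    pos <- place_intervals(lengths[todo], chroms_tbl, avoid = mask,
                           max_rounds = 2L)
    if (nrow(pos) == 0) next
    # keep a non-overlapping subset of this round's draws (greedy sweep)
    pos <- arrange(pos, .data$chrom, .data$start)
    ok <- unlist(lapply(split(seq_len(nrow(pos)), pos$chrom), function(i) {
      p <- pos[i, ]
      sel <- rep(FALSE, nrow(p))
      last_end <- -1
      for (j in seq_len(nrow(p))) {
        if (p$start[j] >= last_end) {
          sel[j] <- TRUE
          last_end <- p$end[j]
        }
      }
      i[sel]
    }), use.names = FALSE)
    got <- pos[sort(ok), ]
    got$.idx <- todo[got$.idx]
    accepted <- bind_rows(accepted, got)
    todo <- setdiff(todo, got$.idx)
  }
  if (is.null(accepted)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  .idx = integer()))
  }
  arrange(accepted, .data$chrom, .data$start)
}

# Per-gene planting margins: how far a planted CNV may extend beyond its
# target gene (at most 20 kb) without ever reaching a neighbouring gene,
# with a deterministic jitter allowance reserved on top. `w_start`/`w_end`
# is the hard clip window applied to jittered planted calls.
planted_margins <- function(genes, jitter_sd) {
  jit_allow <- ceiling(10 * jitter_sd)
  genes |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    mutate(
      left_gap = .data$start - lag(.data$end, default = -10L^9),
      right_gap = dplyr::lead(.data$start, default = 10L^9) - .data$end,
      hard_left = pmax(0, floor((.data$left_gap - 1000) / 2)),
      hard_right = pmax(0, floor((.data$right_gap - 1000) / 2)),
      margin_left = pmin(2e4, pmax(0, .data$hard_left - jit_allow)),
      margin_right = pmin(2e4, pmax(0, .data$hard_right - jit_allow)),
      w_start = .data$start - .data$margin_left - jit_allow,
      w_end = .data$end + .data$margin_right + jit_allow
    ) |>
    ungroup() |>
    select("gene_id", "margin_left", "margin_right", "w_start", "w_end")
}

# caller subset for planted events, conditioned on >= 2 supporting callers
draw_caller_sets <- function(n, sens) {
  subsets <- list(c(1, 2), c(1, 3), c(2, 3), c(1, 2, 3))
  w <- vapply(subsets, function(s) {
    prod(sens[s]) * prod(1 - sens[setdiff(1:3, s)])
  }, numeric(1))
  idx <- sample.int(length(subsets), n, replace = TRUE, prob = w / sum(w))
  subsets[idx]
}

#' Generate a complete synthetic CNV study
#'
#' Produces genome annotation (gene models, centromere / segmental
#' duplication / immunoglobulin tracks, chromosome lengths), a sample
#' manifest, three-caller raw call tables and the ground truth, fully
#' deterministically for a given configuration.
#'
#' @param config A [simulation_config()].
#' @return A list of class `cnv_study`: `config`, `manifest`, `genes`,
#'   `chrom_lengths`, `tracks` (list of region tracks), `calls` (raw calls
#'   of all callers, internal coordinates), and `truth` (list with the true
#'   CNV table and the planted expectation table).
#' @export
simulate_study <- function(config = simulation_config()) {
  cfg <- config
  chroms <- tibble(
    chrom = paste0("chr", seq_len(cfg$n_chromosomes)),
    length = cfg$chrom_length_bp
  )
  L <- cfg$chrom_length_bp

  # -- deterministic genome landmarks ------------------------------------
  centromere <- tibble(chrom = chroms$chrom,
                       start = as.integer(L / 2 - 5e5),
                       end = as.integer(L / 2 + 5e5))
  segdup <- tibble(chrom = chroms$chrom,
                   start = as.integer(0.25 * L),
                   end = as.integer(0.25 * L + 3e5))
  immunoglobulin <- tibble(chrom = chroms$chrom[min(2, nrow(chroms))],
                           start = as.integer(0.70 * L),
                           end = as.integer(0.70 * L + 2e5))
  # genes stay clear of all excluded context: the 100 kb buffers plus a
  # margin wide enough that a planted CNV (gene +- 20 kb plus jitter) can
  # never touch a buffered window
  gene_margin <- as.integer(1e5 + 2e4 + 10 * cfg$breakpoint_jitter_sd_bp)
  gene_avoid <- merge_intervals(bind_rows(
    mutate(centromere, start = .data$start - gene_margin,
           end = .data$end + gene_margin),
    tibble(chrom = chroms$chrom, start = 0L, end = gene_margin),
    tibble(chrom = chroms$chrom, start = as.integer(L - gene_margin),
           end = as.integer(L)),
    segdup, immunoglobulin
  ))

  set.seed(component_seed(cfg$seed, "genome"))
  gene_len <- round(exp(runif(cfg$n_genes, log(8e3), log(6e4))))
  gene_pos <- place_disjoint_intervals(gene_len, chroms, avoid = gene_avoid)
  genes <- tibble(gene_id = sprintf("gene_%04d", seq_len(nrow(gene_pos))),
                  chrom = gene_pos$chrom, start = gene_pos$start,
                  end = gene_pos$end)
  if (nrow(genes) < cfg$n_genes) {
    warn(sprintf("placed %d of %d genes", nrow(genes), cfg$n_genes))
  }

  # -- manifest -----------------------------------------------------------
  set.seed(component_seed(cfg$seed, "manifest"))
  n <- cfg$n_cases + cfg$n_controls
  subtype <- c(
    sample(rep(c("CD", "UC"), length.out = cfg$n_cases)),
    rep("none", cfg$n_controls)
  )
  manifest <- tibble(
    sample_id = c(sprintf("case_%04d", seq_len(cfg$n_cases)),
                  sprintf("control_%04d", seq_len(cfg$n_controls))),
    cohort = rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls)),
    subtype = subtype,
    batch = sprintf("batch_%02d", rep_len(seq_len(cfg$n_batches), n)),
    call_rate = round(runif(n, 0.965, 0.999), 4),
    lrr_sd = round(rnorm(n, 0.12, 0.012), 4),
    baf_sd = round(rnorm(n, 0.035, 0.004), 4)
  )
  validate_sample_manifest(manifest)

  # -- background event counts (drawn first so planting can prefer
  #    samples whose counts keep clear of the count-QC band) --------------
  set.seed(component_seed(cfg$seed, "placement"))
  n_events <- rpois(n, cfg$background_cnv_rate_per_sample)

  # -- planted events (exact carrier counts) ------------------------------
  planted <- cfg$planted_signals
  planted_cnvs <- NULL
  planted_avoid <- NULL
  if (!is.null(planted) && nrow(planted) > 0) {
    missing <- setdiff(planted$gene_id, genes$gene_id)
    if (length(missing)) {
      abort(sprintf("planted gene(s) not in the gene models: %s",
                    paste(missing, collapse = ", ")))
    }
    set.seed(component_seed(cfg$seed, "planting"))
    # carriers are drawn from samples that pass the array-metric QC bands
    # and carry at most an average background load, so planting never
    # interacts with either sample-QC filter
    qc <- suppressWarnings(array_metric_qc(manifest))
    eligible <- manifest$sample_id[
      qc$passed & n_events <= cfg$background_cnv_rate_per_sample
    ]
    pool <- function(cohort) {
      ids <- manifest$sample_id[manifest$cohort == cohort]
      pref <- intersect(ids, eligible)
      if (length(pref)) pref else ids
    }
    case_pool <- pool("case")
    control_pool <- pool("control")
    # planting margins per gene: reach toward a neighbouring gene is
    # capped so a planted CNV can only ever overlap its target gene
    margins <- planted_margins(genes, cfg$breakpoint_jitter_sd_bp)
    planted_cnvs <- list_rbind(pmap(planted, function(gene_id, cnv_type,
                                                      n_case_carriers,
                                                      n_control_carriers) {
      g <- genes[genes$gene_id == gene_id, ]
      m <- margins[margins$gene_id == gene_id, ]
      carriers <- c(sample(case_pool, n_case_carriers),
                    sample(control_pool, n_control_carriers))
      k <- length(carriers)
      if (k == 0) return(NULL)
      tibble(
        sample_id = carriers,
        chrom = g$chrom,
        start = as.integer(g$start - round(runif(k, 0, m$margin_left))),
        end = as.integer(g$end + round(runif(k, 0, m$margin_right))),
        cnv_type = cnv_type,
        origin = "planted",
        planted_gene = gene_id
      )
    }))
    # background events keep clear of planted loci (with a jitter margin)
    planted_avoid <- merge_intervals(
      genes |>
        filter(.data$gene_id %in% planted$gene_id) |>
        mutate(start = pmax(0L, .data$start - 50000L),
               end = .data$end + 50000L)
    )
  }

  # -- background events --------------------------------------------------
  sample_of_event <- rep(manifest$sample_id, n_events)
  total <- length(sample_of_event)
  set.seed(component_seed(cfg$seed, "lengths"))
  lens <- draw_lengths(total, cfg$length_mixture_weights)
  types <- if_else(runif(total) < cfg$deletion_fraction,
                   "deletion", "duplication")
  pos <- place_intervals(lens, chroms, avoid = planted_avoid)
  background_cnvs <- tibble(
    sample_id = sample_of_event[pos$.idx],
    chrom = pos$chrom, start = pos$start, end = pos$end,
    cnv_type = types[pos$.idx],
    origin = "background", planted_gene = NA_character_
  )

  truth_cnvs <- bind_rows(background_cnvs, planted_cnvs) |>
    arrange(.data$sample_id, .data$chrom, .data$start, .data$end)

  # -- caller emission (dropout) -----------------------------------------
  set.seed(component_seed(cfg$seed, "dropout"))
  sens <- cfg$caller_sensitivity[CALLER_IDS]
  is_planted <- truth_cnvs$origin == "planted"
  emitted <- vector("list", 3)
  planted_sets <- draw_caller_sets(sum(is_planted), sens)
  for (ci in 1:3) {
    take_bg <- !is_planted & runif(nrow(truth_cnvs)) < sens[ci]
    take_pl <- rep(FALSE, nrow(truth_cnvs))
    take_pl[is_planted] <- map_lgl(planted_sets, function(s) ci %in% s)
    take <- take_bg | take_pl
    emitted[[ci]] <- mutate(truth_cnvs[take, ], caller = CALLER_IDS[ci])
  }
  calls <- list_rbind(emitted)

  # -- breakpoint jitter and clipping ------------------------------------
  set.seed(component_seed(cfg$seed, "jitter"))
  if (cfg$breakpoint_jitter_sd_bp > 0 && nrow(calls) > 0) {
    calls$start <- calls$start +
      round(rnorm(nrow(calls), 0, cfg$breakpoint_jitter_sd_bp))
    calls$end <- calls$end +
      round(rnorm(nrow(calls), 0, cfg$breakpoint_jitter_sd_bp))
  }
  if (nrow(calls) > 0) {
    min_len <- max(5000, ceiling(5 / cfg$probe_density))
    gene_windows <- if (!is.null(planted)) {
      left_join(select(genes, "gene_id", g_start = "start", g_end = "end"),
                planted_margins(genes, cfg$breakpoint_jitter_sd_bp),
                by = "gene_id")
    } else {
      tibble(gene_id = character(), g_start = integer(), g_end = integer(),
             margin_left = numeric(), margin_right = numeric(),
             w_start = numeric(), w_end = numeric())
    }
    calls <- calls |>
      left_join(select(gene_windows, planted_gene = "gene_id", "g_start",
                       "g_end", "w_start", "w_end"),
                by = "planted_gene") |>
      mutate(across(c("start", "end", "g_start", "g_end", "w_start",
                      "w_end"), as.numeric)) |>
      mutate(
        lo_bound = dplyr::coalesce(.data$w_start, 0),
        hi_bound = dplyr::coalesce(.data$w_end, as.numeric(L)),
        lo_bound = pmax(.data$lo_bound, 0),
        hi_bound = pmin(.data$hi_bound, L),
        # planted calls stay inside their clip window and keep >= 1 bp
        # overlap with the target gene; all calls keep the minimum length
        start = pmax(.data$start, .data$lo_bound),
        end = pmin(.data$end, .data$hi_bound),
        start = if_else(!is.na(.data$g_start),
                        pmin(.data$start, .data$g_end - 1), .data$start),
        end = if_else(!is.na(.data$g_start),
                      pmax(.data$end, .data$g_start + 1), .data$end),
        end = if_else(.data$end - .data$start < min_len,
                      pmin(.data$start + min_len, .data$hi_bound),
                      .data$end),
        start = if_else(.data$end - .data$start < min_len,
                        pmax(.data$end - min_len, .data$lo_bound),
                        .data$start),
        start = as.integer(.data$start),
        end = as.integer(.data$end)
      ) |>
      select(-"g_start", -"g_end", -"w_start", -"w_end", -"lo_bound",
             -"hi_bound")
  }

  # -- caller-specific false positives -----------------------------------
  set.seed(component_seed(cfg$seed, "fp"))
  fp_calls <- NULL
  if (cfg$caller_fp_rate > 0) {
    n_fp <- rpois(n * 3, cfg$caller_fp_rate)
    fp_sample <- rep(rep(manifest$sample_id, 3), n_fp)
    fp_caller <- rep(rep(CALLER_IDS, each = n), n_fp)
    fp_total <- length(fp_sample)
    if (fp_total > 0) {
      fp_len <- draw_lengths(fp_total, cfg$length_mixture_weights)
      fp_type <- if_else(runif(fp_total) < cfg$deletion_fraction,
                         "deletion", "duplication")
      fp_pos <- place_intervals(fp_len, chroms, avoid = planted_avoid)
      fp_calls <- tibble(
        sample_id = fp_sample[fp_pos$.idx], chrom = fp_pos$chrom,
        start = fp_pos$start, end = fp_pos$end,
        cnv_type = fp_type[fp_pos$.idx],
        origin = "false_positive", planted_gene = NA_character_,
        caller = fp_caller[fp_pos$.idx]
      )
      # enforce the single-caller property: drop any false positive that
      # overlaps another call of the same sample and type (true-derived
      # calls of any caller, or another false positive)
      key <- function(d) paste(d$sample_id, d$cnv_type, d$chrom, sep = "|")
      n_true <- nrow(calls)
      g <- GenomicRanges::GRanges(
        c(key(calls), key(fp_calls)),
        IRanges::IRanges(c(calls$start, fp_calls$start) + 1,
                         c(calls$end, fp_calls$end))
      )
      hits <- suppressWarnings(GenomicRanges::findOverlaps(g, drop.self = TRUE))
      bad <- unique(S4Vectors::queryHits(hits))
      bad <- bad[bad > n_true] - n_true
      if (length(bad)) fp_calls <- fp_calls[-bad, ]
    }
  }

  all_calls <- bind_rows(calls, fp_calls) |>
    mutate(
      n_probes = as.integer(floor((.data$end - .data$start) *
                                    cfg$probe_density)),
      quality = round(runif(dplyr::n(), 20, 100), 1)
    ) |>
    arrange(.data$caller, .data$sample_id, .data$chrom, .data$start,
            .data$end) |>
    select("sample_id", "chrom", "start", "end", "cnv_type", "n_probes",
           "quality", "caller", "origin", "planted_gene")

  planted_expected <- if (!is.null(planted)) as_tibble(planted) else
    tibble(gene_id = character(), cnv_type = character(),
           n_case_carriers = integer(), n_control_carriers = integer())

  structure(
    list(
      config = cfg,
      manifest = manifest,
      genes = genes,
      chrom_lengths = chroms,
      tracks = list(centromere = centromere, segdup = segdup,
                    immunoglobulin = immunoglobulin),
      calls = all_calls,
      truth = list(cnvs = truth_cnvs, planted = planted_expected)
    ),
    class = "cnv_study"
  )
}

#' Plant array-metric and CNV-count QC outliers into a study
#'
#' Lowers the genotype call rate of `n_callrate_outliers` samples below the
#' QC threshold and adds `count_excess` extra, mutually disjoint,
#' all-caller CNVs to `n_count_outliers` samples so they exceed the batch
#' CNV-count band. The planted outliers are recorded in
#' `study$truth$qc_outliers`.
#'
#' @param study A `cnv_study` from [simulate_study()].
#' @param n_count_outliers,n_callrate_outliers Numbers of planted outliers
#'   (drawn from the case cohort).
#' @param call_rate_value Call rate assigned to call-rate outliers
#'   (default 0.90).
#' @param count_excess Extra stringent CNVs given to each count outlier;
#'   defaults to 12 standard deviations of the background count
#'   distribution.
#' @return The modified `cnv_study`.
#' @export
simulate_qc_outliers <- function(study, n_count_outliers = 0L,
                                 n_callrate_outliers = 0L,
                                 call_rate_value = 0.90,
                                 count_excess = NULL) {
  cfg <- study$config
  set.seed(component_seed(cfg$seed, "qc"))
  cases <- filter(study$manifest, .data$cohort == "case")
  # spread count outliers over distinct batches so a planted outlier never
  # inflates its own batch's count SD enough to mask itself
  by_batch <- split(cases$sample_id, cases$batch)
  by_batch <- lapply(by_batch, sample)
  count_ids <- character(0)
  i <- 0
  while (length(count_ids) < n_count_outliers) {
    b <- by_batch[[i %% length(by_batch) + 1]]
    pick <- setdiff(b, count_ids)[1]
    if (!is.na(pick)) count_ids <- c(count_ids, pick)
    i <- i + 1
    if (i > n_count_outliers * length(by_batch) + 10) break
  }
  callrate_ids <- sample(setdiff(cases$sample_id, count_ids),
                         n_callrate_outliers)

  if (n_callrate_outliers > 0) {
    study$manifest <- mutate(study$manifest, call_rate = if_else(
      .data$sample_id %in% callrate_ids, call_rate_value, .data$call_rate
    ))
  }
  if (n_count_outliers > 0) {
    rate <- cfg$background_cnv_rate_per_sample
    excess <- count_excess %||% ceiling(12 * sqrt(max(rate, 1)))
    # disjoint 10 kb slots in the clear zone between telomere buffer and
    # segmental duplication, far from centromeres and planted loci
    slot_w <- 2e4
    zone_lo <- 2e5
    n_slots <- floor((0.24 * cfg$chrom_length_bp - zone_lo) / slot_w)
    slots <- crossing(chrom = study$chrom_lengths$chrom,
                      slot = seq_len(n_slots)) |>
      mutate(start = as.integer(zone_lo + (.data$slot - 1) * slot_w),
             end = .data$start + 10000L)
    if (!is.null(study$truth$planted) && nrow(study$truth$planted) > 0) {
      avoid <- merge_intervals(
        filter(study$genes,
               .data$gene_id %in% study$truth$planted$gene_id) |>
          mutate(start = pmax(0L, .data$start - 50000L),
                 end = .data$end + 50000L)
      )
      slots <- slots[intersect_widths(slots, avoid) == 0, ]
    }
    if (nrow(slots) < excess * n_count_outliers) {
      abort("not enough disjoint slots to plant CNV-count outliers")
    }
    extra <- list_rbind(imap(setNames(count_ids, count_ids), function(sid, i) {
      off <- (match(sid, count_ids) - 1) * excess
      s <- slots[(off + 1):(off + excess), ]
      tibble(sample_id = sid, chrom = s$chrom, start = s$start, end = s$end,
             cnv_type = "deletion", origin = "qc_outlier",
             planted_gene = NA_character_)
    }))
    study$truth$cnvs <- bind_rows(study$truth$cnvs, extra)
    extra_calls <- crossing(caller = CALLER_IDS, extra) |>
      mutate(
        n_probes = as.integer(floor((.data$end - .data$start) *
                                      cfg$probe_density)),
        quality = 99
      ) |>
      select("sample_id", "chrom", "start", "end", "cnv_type", "n_probes",
             "quality", "caller", "origin", "planted_gene")
    study$calls <- bind_rows(study$calls, extra_calls)
  }
  study$truth$qc_outliers <- tibble(
    sample_id = c(count_ids, callrate_ids),
    kind = rep(c("cnv_count", "call_rate"),
               c(length(count_ids), length(callrate_ids)))
  )
  study
}

#' Write a synthetic study to disk in the pipeline's exchange formats
#'
#' Writes the manifest (TSV), gene models (BED4), region tracks (BED),
#' chromosome lengths (TSV), one raw-call TSV per caller in the default
#' 1-based-inclusive dialect (deletion encoded as copy number 1,
#' duplication as 3), and the truth table (TSV).
#'
#' @param study A `cnv_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_tsv(study$manifest, p("samples.tsv"), progress = FALSE)
  write_bed(study$genes |>
              select("chrom", "start", "end", "gene_id"), p("genes.bed"))
  write_bed(study$tracks$centromere, p("centromere.bed"))
  write_bed(study$tracks$segdup, p("segdup.bed"))
  write_bed(study$tracks$immunoglobulin, p("immunoglobulin.bed"))
  write_tsv(study$chrom_lengths, p("chrom_lengths.tsv"), progress = FALSE)
  for (ci in unique(study$calls$caller)) {
    d <- study$calls |>
      filter(.data$caller == ci) |>
      mutate(start = .data$start + 1L,
             cn = if_else(.data$cnv_type == "deletion", 1L, 3L)) |>
      select("sample_id", "chrom", "start", "end", "cn", "n_probes",
             "quality")
    write_tsv(d, p(paste0(ci, ".tsv")), progress = FALSE)
  }
  write_tsv(study$truth$cnvs, p("truth_cnvs.tsv"), progress = FALSE)
  write_tsv(study$truth$planted, p("truth_planted.tsv"), progress = FALSE)
  invisible(dir)
}

#' Read a synthetic study back from disk
#'
#' Inverse of [write_study()], exercising the package's format readers.
#'
#' @param dir Directory written by [write_study()].
#' @return A list with `manifest`, `genes`, `chrom_lengths`, `tracks` and
#'   `calls` in internal representation.
#' @export
read_study <- function(dir) {
  p <- function(...) file.path(dir, ...)
  calls <- list_rbind(map(CALLER_IDS, function(ci) {
    f <- p(paste0(ci, ".tsv"))
    if (!file.exists(f)) return(NULL)
    read_cnv_calls(f, ci, cnv_dialect())
  }))
  list(
    manifest = read_sample_manifest(p("samples.tsv")),
    genes = read_gene_models(p("genes.bed")),
    chrom_lengths = read_tsv(p("chrom_lengths.tsv"),
                             col_types = cols(chrom = col_character(),
                                              length = col_double()),
                             progress = FALSE),
    tracks = list(
      centromere = read_region_track(p("centromere.bed"), "centromere"),
      segdup = read_region_track(p("segdup.bed"), "segdup"),
      immunoglobulin = read_region_track(p("immunoglobulin.bed"),
                                         "immunoglobulin")
    ),
    calls = calls
  )
}
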