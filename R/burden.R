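# Stratified CNV burden comparison.
#
# Stringent CNVs are classified by type x length class x genic status and
# event counts in two sample groups are compared with an
# observed-vs-expected exact test: the expected split of the combined count
# follows the group sample sizes (rounded to the nearest integer, the
# complement by subtraction so the margin is preserved) and the observed and
# expected pairs form a 2x2 table for the two-tailed Fisher exact test.

LENGTH_CLASSES <- c("5-100kb", "100-500kb", "500kb-1Mb", ">1Mb")
LENGTH_BREAKS <- c(5e3, 1e5, 5e5, 1e6, Inf)

#' Classify CNVs by length bin and genic status
#'
#' Length bins are half-open upward: \[5 kb, 100 kb), \[100 kb, 500 kb),
#' \[500 kb, 1 Mb), \[1 Mb, Inf) — a CNV of exactly 100,000 bp falls in the
#' 100-500 kb class. A CNV is genic iff it overlaps at least one gene by at
#' least one bp. CNVs shorter than 5 kb (which the raw-call filter should
#' have removed upstream) trigger a warning and get an `NA` class.
#'
#' @param cnvs Stringent CNV tibble.
#' @param genes Gene-model tibble.
#' @return `cnvs` with added `length_class` (factor) and `genic` (logical).
#' @export
classify_cnv <- function(cnvs, genes) {
  cnvs <- as_tibble(cnvs)
  len <- cnvs$end - cnvs$start
  if (any(len < LENGTH_BREAKS[1])) {
    warn(sprintf("%d CNV(s) shorter than 5 kb reached classification",
                 sum(len < LENGTH_BREAKS[1])))
  }
  cls <- cut(len, breaks = LENGTH_BREAKS, labels = LENGTH_CLASSES,
             right = FALSE)
  genic <- rep(FALSE, nrow(cnvs))
  if (nrow(cnvs) > 0 && nrow(genes) > 0) {
    hits <- overlaps(as_granges0(cnvs), as_granges0(genes))
    genic[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  mutate(cnvs, length_class = cls, genic = genic)
}

#' Observed-versus-expected exact test for group CNV counts
#'
#' Splits the combined count `obs1 + obs2` into expected counts proportional
#' to the group sample sizes (`expected1 = round((obs1 + obs2) * n1 /
#' (n1 + n2))`, `expected2` by subtraction) and tests
#' `[[obs1, obs2], [expected1, expected2]]` with the two-tailed Fisher exact
#' test. Zero combined counts give p = 1. Vectorized over counts.
#'
#' @param obs1,obs2 Observed event counts in the two groups.
#' @param n1,n2 Group sample sizes (e.g. 120 CD vs 123 UC samples).
#' @return Numeric vector of two-tailed p-values.
#' @export
observed_vs_expected_test <- function(obs1, obs2, n1, n2) {
  if (any(c(n1, n2) <= 0)) abort("group sizes must be positive")
  k <- max(length(obs1), length(obs2))
  obs1 <- rep_len(obs1, k); obs2 <- rep_len(obs2, k)
  total <- obs1 + obs2
  e1 <- round(total * n1 / (n1 + n2))
  e2 <- total - e1
  p <- rep(1, k)
  nz <- total > 0
  if (any(nz)) {
    p[nz] <- fisher_p_two_sided(obs1[nz], obs2[nz], e1[nz], e2[nz])
  }
  p
}

#' Stratified CNV burden table
#'
#' Builds the full 3 (type: all/deletion/duplication) x 5 (length: any plus
#' four bins) x 3 (genic: all/genic/non-genic) grid of event counts per
#' group with the observed-vs-expected exact p-value per cell. Marginal
#' cells ("all"/"any") equal the sum of their partition cells by
#' construction.
#'
#' @param cnvs Stringent CNV tibble.
#' @param genes Gene-model tibble.
#' @param samples Sample manifest (defines the groups).
#' @param group_by `"CD_vs_UC"` (cases only, split by subtype) or
#'   `"case_vs_control"`.
#' @return A `cnv_burden` tibble: `cnv_type`, `length_class`, `genic_class`,
#'   `count_group1`, `count_group2`, `p_value`, with attributes `groups`
#'   (labels) and `group_sizes`.
#' @export
burden_table <- function(cnvs, genes, samples,
                         group_by = c("CD_vs_UC", "case_vs_control")) {
  group_by <- match.arg(group_by)
  validate_sample_manifest(samples)
  if (group_by == "CD_vs_UC") {
    grp <- samples |>
      filter(.data$cohort == "case") |>
      mutate(group = .data$subtype)
    labels <- c("CD", "UC")
  } else {
    grp <- mutate(samples, group = .data$cohort)
    labels <- c("case", "control")
  }
  sizes <- c(sum(grp$group == labels[1]), sum(grp$group == labels[2]))
  if (any(sizes == 0)) {
    abort(sprintf("empty group: %s", labels[which(sizes == 0)][1]))
  }
  df <- classify_cnv(cnvs, genes) |>
    inner_join(select(grp, "sample_id", "group"), by = "sample_id")

  type_levels <- c("all", "deletion", "duplication")
  length_levels <- c("any", LENGTH_CLASSES)
  genic_levels <- c("all", "genic", "non-genic")
  grid <- crossing(
    cnv_type = factor(type_levels, levels = type_levels),
    length_class = factor(length_levels, levels = length_levels),
    genic_class = factor(genic_levels, levels = genic_levels)
  )

  cell_counts <- function(type, lc, gc) {
    sel <- df
    if (type != "all") sel <- filter(sel, .data$cnv_type == type)
    if (lc != "any") sel <- filter(sel, .data$length_class == lc)
    if (gc == "genic") sel <- filter(sel, .data$genic)
    if (gc == "non-genic") sel <- filter(sel, !.data$genic)
    c(sum(sel$group == labels[1]), sum(sel$group == labels[2]))
  }
  counts <- pmap(grid, function(cnv_type, length_class, genic_class) {
    cell_counts(as.character(cnv_type), as.character(length_class),
                as.character(genic_class))
  })
  grid$count_group1 <- map_int(counts, function(x) as.integer(x[1]))
  grid$count_group2 <- map_int(counts, function(x) as.integer(x[2]))
  grid$p_value <- observed_vs_expected_test(
    grid$count_group1, grid$count_group2, sizes[1], sizes[2]
  )
  structure(grid, class = c("cnv_burden", class(grid)),
            groups = labels, group_sizes = sizes)
}
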