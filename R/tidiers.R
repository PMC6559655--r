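# broom-style tidiers and autoplot methods for the result classes.

#' @export
tidy.cnv_association <- function(x, ...) {
  as_tibble(x) |> arrange(.data$p_adj, .data$p_two_sided, .data$gene_id)
}

#' @export
glance.cnv_association <- function(x, ...) {
  tibble(
    m_tests = attr(x, "m_tests"),
    n_cases = attr(x, "n_cases"),
    n_controls = attr(x, "n_controls"),
    n_significant = sum(x$p_adj <= attr(x, "p_adj_threshold")),
    n_rare = sum(x$is_rare),
    n_significant_rare = nrow(significant_rare(x)),
    rare_control_freq = attr(x, "rare_control_freq"),
    p_adj_threshold = attr(x, "p_adj_threshold")
  )
}

#' Volcano-style plot of gene x type association results
#'
#' @param object A `cnv_association` from [run_association()].
#' @param ... Unused.
#' @return A ggplot: log2 conditional-MLE odds ratio (infinite estimates
#'   capped at the plot margin) against -log10 adjusted p, shaped by CNV
#'   type, rare gene x type pairs highlighted.
#' @export
autoplot.cnv_association <- function(object, ...) {
  thr <- attr(object, "p_adj_threshold") %||% 0.01
  df <- as_tibble(object) |>
    filter(!is.na(.data$or_cmle)) |>
    mutate(
      log2_or = log2(pmax(.data$or_cmle, 2^-10)),
      log2_or = pmin(.data$log2_or, 10),
      neg_log10_p = -log10(pmax(.data$p_adj, 1e-16))
    )
  ggplot(df, aes(x = .data$log2_or, y = .data$neg_log10_p,
                 shape = .data$cnv_type, colour = .data$is_rare)) +
    geom_point(alpha = 0.7) +
    geom_hline(yintercept = -log10(thr), linetype = "dashed") +
    scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red3"),
                        name = "rare") +
    labs(x = "log2 odds ratio (conditional MLE, capped)",
         y = "-log10 adjusted p", shape = "CNV type") +
    theme_minimal()
}

#' @export
print.cnv_association <- function(x, ...) {
  cat(sprintf(
    "Gene x CNV-type association: %d tests (%d cases, %d controls)\n",
    attr(x, "m_tests"), attr(x, "n_cases"), attr(x, "n_controls")
  ))
  NextMethod()
}

#' @export
tidy.cnv_burden <- function(x, ...) {
  groups <- attr(x, "groups")
  as_tibble(x) |>
    rename(!!paste0("count_", groups[1]) := "count_group1",
           !!paste0("count_", groups[2]) := "count_group2")
}

#' @export
glance.cnv_burden <- function(x, ...) {
  sizes <- attr(x, "group_sizes")
  tibble(
    group1 = attr(x, "groups")[1], group2 = attr(x, "groups")[2],
    n_group1 = sizes[1], n_group2 = sizes[2],
    total_cnvs = x$count_group1[x$cnv_type == "all" &
                                  x$length_class == "any" &
                                  x$genic_class == "all"] +
      x$count_group2[x$cnv_type == "all" & x$length_class == "any" &
                       x$genic_class == "all"],
    n_cells_p05 = sum(x$p_value < 0.05)
  )
}

#' Bar chart of the stratified CNV burden
#'
#' @param object A `cnv_burden` from [burden_table()].
#' @param ... Unused.
#' @return A ggplot of per-group event counts across length classes,
#'   faceted by CNV type and genic status.
#' @export
autoplot.cnv_burden <- function(object, ...) {
  groups <- attr(object, "groups")
  df <- as_tibble(object) |>
    filter(.data$length_class != "any", .data$genic_class != "all") |>
    tidyr::pivot_longer(c("count_group1", "count_group2"),
                        names_to = "group", values_to = "count") |>
    mutate(group = if_else(.data$group == "count_group1",
                           groups[1], groups[2]))
  ggplot(df, aes(x = .data$length_class, y = .data$count,
                 fill = .data$group)) +
    geom_col(position = "dodge") +
    facet_grid(genic_class ~ cnv_type) +
    labs(x = "CNV length class", y = "CNV count", fill = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 30, hjust = 1))
}

#' @export
tidy.cnv_ora <- function(x, ...) {
  as_tibble(x) |>
    mutate(member_hits = map_chr(.data$member_hits, paste, collapse = ",")) |>
    arrange(.data$library_name, .data$p_adj, .data$p)
}

#' @export
glance.cnv_ora <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$library_name) |>
    summarise(
      n_sets = n(),
      n_reported = sum(.data$reported),
      min_p_adj = if (n() > 0) min(.data$p_adj) else NA_real_,
      .groups = "drop"
    )
}

#' Dot plot of gene-set overrepresentation results
#'
#' @param object A `cnv_ora` from [run_ora()].
#' @param max_sets Sets shown per library, by ascending p (default 15).
#' @param ... Unused.
#' @return A ggplot of -log10 adjusted p per set, sized by query hits.
#' @export
autoplot.cnv_ora <- function(object, max_sets = 15, ...) {
  df <- as_tibble(object) |>
    group_by(.data$library_name) |>
    arrange(.data$p, .by_group = TRUE) |>
    filter(row_number() <= max_sets) |>
    ungroup() |>
    mutate(set_id = factor(.data$set_id, levels = rev(unique(.data$set_id))))
  ggplot(df, aes(x = -log10(pmax(.data$p_adj, 1e-16)), y = .data$set_id,
                 size = .data$hits, colour = .data$reported)) +
    geom_point() +
    facet_grid(library_name ~ ., scales = "free_y", space = "free_y") +
    scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "red3")) +
    labs(x = "-log10 adjusted p", y = NULL, colour = "reported") +
    theme_minimal()
}
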