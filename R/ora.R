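# Gene-set overrepresentation analysis against the CNV-overlapped
# background.
#
# For each set, the number of query genes falling in it is tested with the
# one-sided (enrichment) hypergeometric upper tail given the background
# size, the set size within the background and the query size — the
# standard overrepresentation reading of "Fisher's exact test". BH
# correction is applied within each library separately.

#' Gene-set overrepresentation analysis
#'
#' @param query_genes Character vector of query gene ids (e.g. genes
#'   associated at an adjusted-p threshold). Genes outside the background
#'   are dropped with a warning.
#' @param background_genes Character vector: all genes overlapped by at
#'   least one CNV in at least one sample.
#' @param libraries A `gene_set_library` (see [read_gmt()]) or a list of
#'   them.
#' @param p_adj_threshold Within-library BH threshold for the `reported`
#'   flag (default 0.25).
#' @param min_overlap Minimum query hits for the `reported` flag
#'   (default 2).
#' @param alternative `"greater"` (one-sided enrichment, default) or
#'   `"two.sided"` (full exact test).
#' @return A `cnv_ora` tibble: `library_name`, `set_id`, `description`,
#'   `hits`, `set_in_background`, `query_size`, `background_size`, `p`,
#'   `p_adj` (BH within library), `reported`, `member_hits` (list-column).
#' @export
run_ora <- function(query_genes, background_genes, libraries,
                    p_adj_threshold = 0.25, min_overlap = 2L,
                    alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (inherits(libraries, "gene_set_library")) libraries <- list(libraries)
  background <- unique(as.character(background_genes))
  if (length(background) == 0) abort("empty background gene set")
  query <- unique(as.character(query_genes))
  outside <- setdiff(query, background)
  if (length(outside)) {
    warn(sprintf("%d query gene(s) outside the background dropped",
                 length(outside)))
    query <- setdiff(query, outside)
  }
  n_bg <- length(background)
  n_q <- length(query)

  one_library <- function(lib) {
    rows <- imap(lib$sets, function(s, id) {
      members_bg <- intersect(s$members, background)
      member_hits <- intersect(members_bg, query)
      k <- length(member_hits)
      m <- length(members_bg)
      p <- if (alternative == "greater") {
        phyper(k - 1, m, n_bg - m, n_q, lower.tail = FALSE)
      } else {
        fisher_exact_2x2(k, n_q - k, m - k,
                         n_bg - n_q - (m - k))$p_two_sided
      }
      tibble(
        library_name = lib$library_name, set_id = id,
        description = s$description, hits = k, set_in_background = m,
        query_size = n_q, background_size = n_bg, p = p,
        member_hits = list(sort(member_hits))
      )
    })
    out <- list_rbind(rows)
    out$p_adj <- if (nrow(out)) bh_adjust(out$p) else numeric(0)
    out
  }

  res <- list_rbind(map(libraries, one_library)) |>
    mutate(reported = .data$hits >= min_overlap &
             .data$p_adj <= p_adj_threshold) |>
    relocate("member_hits", .after = "reported") |>
    arrange(.data$library_name, .data$p, .data$set_id)
  structure(res, class = c("cnv_ora", class(res)),
            p_adj_threshold = p_adj_threshold, min_overlap = min_overlap,
            alternative = alternative)
}
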