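# Fixtures built in code and independent oracles used across test files.

make_call <- function(sample_id = "s1", chrom = "chr1", start = 0L,
                      end = 10000L, cnv_type = "deletion", n_probes = 10L,
                      quality = 50, caller = "caller_A") {
  tibble::tibble(sample_id = sample_id, chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 cnv_type = cnv_type, n_probes = as.integer(n_probes),
                 quality = quality, caller = caller)
}

make_calls <- function(...) dplyr::bind_rows(...)

make_samples <- function(n_cases = 2, n_controls = 2, batch = "b1",
                         call_rate = 0.99, lrr_sd = 0.12, baf_sd = 0.03) {
  n <- n_cases + n_controls
  tibble::tibble(
    sample_id = c(sprintf("case_%03d", seq_len(n_cases)),
                  sprintf("control_%03d", seq_len(n_controls))),
    cohort = rep(c("case", "control"), c(n_cases, n_controls)),
    subtype = c(rep_len(c("CD", "UC"), n_cases), rep("none", n_controls)),
    batch = rep_len(batch, n),
    call_rate = rep_len(call_rate, n),
    lrr_sd = rep_len(lrr_sd, n),
    baf_sd = rep_len(baf_sd, n)
  )
}

rand_call_set <- function(n, n_samples = 3, span = 1000L, max_len = 120L) {
  tibble::tibble(
    sample_id = sample(sprintf("s%d", seq_len(n_samples)), n, replace = TRUE),
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = sample.int(span, n, replace = TRUE),
    len = sample.int(max_len, n, replace = TRUE),
    cnv_type = sample(c("deletion", "duplication"), n, replace = TRUE),
    n_probes = sample(5:50, n, replace = TRUE),
    quality = runif(n, 0, 100),
    caller = sample(c("caller_A", "caller_B", "caller_C"), n, replace = TRUE)
  ) |>
    dplyr::mutate(start = as.integer(start), end = as.integer(start + len)) |>
    dplyr::select(-"len")
}

# O(n^2) pairwise-overlap union-find oracle for consensus merging:
# independent of the package's line sweep.
brute_consensus <- function(calls, min_callers = 2) {
  strata <- split(calls, paste(calls$sample_id, calls$chrom, calls$cnv_type,
                               sep = "|"))
  out <- lapply(strata, function(d) {
    n <- nrow(d)
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i < j && d$start[i] < d$end[j] && d$start[j] < d$end[i]) {
          parent[find(i)] <- find(j)
        }
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    comp <- split(seq_len(n), roots)
    rows <- lapply(comp, function(idx) {
      if (length(unique(d$caller[idx])) < min_callers) return(NULL)
      tibble::tibble(
        sample_id = d$sample_id[1], chrom = d$chrom[1],
        start = min(d$start[idx]), end = max(d$end[idx]),
        cnv_type = d$cnv_type[1],
        n_callers = length(unique(d$caller[idx]))
      )
    })
    dplyr::bind_rows(rows)
  })
  empty <- tibble::tibble(
    sample_id = character(), chrom = character(), start = integer(),
    end = integer(), cnv_type = character(), n_callers = integer()
  )
  dplyr::bind_rows(empty, dplyr::bind_rows(out)) |>
    dplyr::arrange(sample_id, chrom, start, end, cnv_type)
}

# base-by-base overlap oracle on small coordinates
brute_overlap_fraction <- function(cnv_start, cnv_end, track) {
  bases <- seq.int(cnv_start, cnv_end - 1)
  covered <- rep(FALSE, length(bases))
  for (i in seq_len(nrow(track))) {
    covered <- covered | (bases >= track$start[i] & bases < track$end[i])
  }
  sum(covered) / (cnv_end - cnv_start)
}

# direct enumeration of the two-sided Fisher p over the hypergeometric
# support, written from the definition (independent of the package's path)
enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  N <- a + b + c + d
  supp <- max(0, c1 - (N - r1)):min(r1, c1)
  pk <- vapply(supp, function(k) {
    exp(lchoose(r1, k) + lchoose(N - r1, c1 - k) - lchoose(N, c1))
  }, numeric(1))
  pa <- pk[supp == a]
  min(1, sum(pk[pk <= pa * (1 + 1e-7)]))
}

# direct step-up formula for BH adjustment
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  out <- numeric(m)
  out[o] <- pmin(1, adj_sorted)
  out
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
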