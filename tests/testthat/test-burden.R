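test_that("length bins are half-open upward and genic needs only 1 bp", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 100000L,
                          end = 120000L)
  cnvs <- tibble::tibble(
    sample_id = "s1", chrom = "chr1",
    start = c(0L, 0L, 0L, 0L, 99999L),
    end = c(99999L, 100000L, 500000L, 1000001L, 100000L + 1L),
    cnv_type = "deletion"
  )
  cnvs$end[5] <- 100001L  # 1 bp inside the gene, length below 5 kb
  cls <- suppressWarnings(classify_cnv(cnvs, genes))
  expect_equal(as.character(cls$length_class)[1:4],
               c("5-100kb", "100-500kb", "500kb-1Mb", ">1Mb"))
  expect_true(cls$genic[5])
  expect_false(cls$genic[1])
  expect_warning(classify_cnv(cnvs[5, ], genes), "5 kb")
})

test_that("classification equals a brute-force bin assignment", {
  set.seed(3)
  genes <- tibble::tibble(gene_id = sprintf("g%d", 1:3), chrom = "chr1",
                          start = c(1e6, 3e6, 8e6),
                          end = c(1.2e6, 3.5e6, 8.1e6)) |>
    dplyr::mutate(dplyr::across(c(start, end), as.integer))
  st <- as.integer(sample.int(9e6, 50))
  cnvs <- tibble::tibble(
    sample_id = "s1", chrom = "chr1", start = st,
    end = st + as.integer(round(exp(runif(50, log(5e3), log(2e6))))),
    cnv_type = "duplication"
  )
  cls <- classify_cnv(cnvs, genes)
  len <- cnvs$end - cnvs$start
  want <- ifelse(len < 1e5, "5-100kb",
                 ifelse(len < 5e5, "100-500kb",
                        ifelse(len < 1e6, "500kb-1Mb", ">1Mb")))
  expect_equal(as.character(cls$length_class), want)
  want_genic <- vapply(seq_len(nrow(cnvs)), function(i) {
    any(cnvs$start[i] < genes$end & genes$start < cnvs$end[i])
  }, logical(1))
  expect_equal(cls$genic, want_genic)
})

test_that("observed-vs-expected test has the documented construction", {
  # proportional counts give p = 1, zero counts give p = 1
  expect_equal(observed_vs_expected_test(120, 123, 120, 123), 1)
  expect_equal(observed_vs_expected_test(0, 0, 120, 123), 1)
  # equals the two-sided exact test on the rounded-expected 2x2
  for (obs in list(c(30, 12), c(7, 6), c(100, 80))) {
    tot <- sum(obs)
    e1 <- round(tot * 120 / 243)
    expect_equal(
      observed_vs_expected_test(obs[1], obs[2], 120, 123),
      enum_fisher_p(obs[1], obs[2], e1, tot - e1)
    )
  }
  # symmetric under swapping the groups together with their sizes
  expect_equal(observed_vs_expected_test(35, 18, 120, 123),
               observed_vs_expected_test(18, 35, 123, 120))
  expect_error(observed_vs_expected_test(1, 1, 0, 10), "positive")
})

test_that("the burden grid conserves counts across every partition", {
  set.seed(19)
  s <- make_samples(n_cases = 30, n_controls = 40)
  genes <- tibble::tibble(gene_id = sprintf("g%d", 1:4), chrom = "chr1",
                          start = as.integer(seq(1e6, 7e6, by = 2e6))) |>
    dplyr::mutate(end = start + 300000L)
  st <- as.integer(sample.int(9e6, 300))
  cnvs <- tibble::tibble(
    sample_id = sample(s$sample_id, 300, TRUE), chrom = "chr1", start = st,
    end = st + as.integer(round(exp(runif(300, log(6e3), log(1.5e6))))),
    cnv_type = sample(c("deletion", "duplication"), 300, TRUE)
  )
  b <- burden_table(cnvs, genes, s, "case_vs_control")
  expect_equal(nrow(b), 3 * 5 * 3)
  cell <- function(t, l, g) {
    r <- b[b$cnv_type == t & b$length_class == l & b$genic_class == g, ]
    c(r$count_group1, r$count_group2)
  }
  # type partition: deletions + duplications = all, in every stratum
  for (l in c("any", "5-100kb", ">1Mb")) {
    for (g in c("all", "genic", "non-genic")) {
      expect_equal(cell("deletion", l, g) + cell("duplication", l, g),
                   cell("all", l, g))
    }
  }
  # length partition sums to "any"; genic partition sums to "all"
  lens <- c("5-100kb", "100-500kb", "500kb-1Mb", ">1Mb")
  expect_equal(Reduce(`+`, lapply(lens, function(l) cell("all", l, "all"))),
               cell("all", "any", "all"))
  expect_equal(cell("all", "any", "genic") + cell("all", "any", "non-genic"),
               cell("all", "any", "all"))
  # total in the top cell equals the number of events from grouped samples
  expect_equal(sum(cell("all", "any", "all")), 300)
  expect_s3_class(autoplot(b), "ggplot")
  g <- glance(b)
  expect_equal(g$total_cnvs, 300)
})

test_that("CD-vs-UC burden uses case samples only and errors when empty", {
  s <- make_samples(n_cases = 10, n_controls = 10)
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 0L,
                          end = 10000L)
  cnvs <- make_calls(
    make_call(sample_id = s$sample_id[1]),
    make_call(sample_id = s$sample_id[11])  # control event, excluded
  )
  b <- burden_table(cnvs, genes, s, "CD_vs_UC")
  top <- b[b$cnv_type == "all" & b$length_class == "any" &
             b$genic_class == "all", ]
  expect_equal(top$count_group1 + top$count_group2, 1L)
  s_uc_only <- dplyr::mutate(s, subtype = dplyr::if_else(cohort == "case",
                                                         "UC", subtype))
  expect_error(burden_table(cnvs, genes, s_uc_only, "CD_vs_UC"), "empty")
})

test_that("a planted short-deletion excess in one group is flagged", {
  set.seed(29)
  s <- make_samples(n_cases = 60, n_controls = 0)
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 5e6,
                          end = 5.1e6) |>
    dplyr::mutate(dplyr::across(c(start, end), as.integer))
  cd <- s$sample_id[s$subtype == "CD"]
  uc <- s$sample_id[s$subtype == "UC"]
  # balanced background in both subtypes, plus a strong CD-only excess of
  # short deletions
  bg_ids <- c(rep(cd, each = 4), rep(uc, each = 4))
  st <- as.integer(sample.int(8e6, length(bg_ids) + 120))
  cnvs <- tibble::tibble(
    sample_id = c(bg_ids, rep(cd, length.out = 120)),
    chrom = "chr1", start = st, end = st + 20000L,
    cnv_type = c(sample(c("deletion", "duplication"), length(bg_ids), TRUE),
                 rep("deletion", 120))
  )
  b <- burden_table(cnvs, genes, s, "CD_vs_UC")
  flagged <- b[b$cnv_type == "deletion" & b$length_class == "5-100kb" &
                 b$genic_class == "all", ]
  expect_lt(flagged$p_value, 0.05)
  expect_gt(flagged$count_group1, flagged$count_group2)
})

test_that("under uniform rates the null cell p-values are calibrated", {
  set.seed(61)
  hits <- 0; cells <- 0
  for (rep in 1:12) {
    s <- make_samples(n_cases = 40, n_controls = 0)
    st <- as.integer(sample.int(8e6, 400))
    cnvs <- tibble::tibble(
      sample_id = sample(s$sample_id, 400, TRUE),
      chrom = "chr1", start = st,
      end = st + as.integer(round(exp(runif(400, log(6e3), log(8e5))))),
      cnv_type = sample(c("deletion", "duplication"), 400, TRUE)
    )
    genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 1000000L,
                            end = 3000000L)
    b <- burden_table(cnvs, genes, s, "CD_vs_UC")
    ok <- !is.na(b$p_value) & (b$count_group1 + b$count_group2) > 0
    hits <- hits + sum(b$p_value[ok] < 0.05)
    cells <- cells + sum(ok)
  }
  rate <- hits / cells
  # exact tests are conservative; allow two MC standard errors above 0.05
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / cells))
})
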