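test_that("exact test matches enumeration and reference on small tables", {
  r <- fisher_exact_2x2(3, 2, 1, 4)
  expect_equal(r$p_two_sided, enum_fisher_p(3, 2, 1, 4))
  r2 <- fisher_exact_2x2(1, 1, 1, 1)
  expect_equal(r2$p_two_sided, 1)
  expect_equal(r2$or_cmle, 1, tolerance = 1e-4)
  # independent reference implementation agrees on p, OR and CI
  set.seed(4)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6), 2)
    mine <- fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ref <- fisher.test(tab)
    expect_equal(mine$p_two_sided, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$or_cmle, unname(ref$estimate), tolerance = 1e-6)
    expect_equal(mine$ci_low, ref$conf.int[1], tolerance = 1e-6)
    expect_equal(mine$ci_high, ref$conf.int[2], tolerance = 1e-6)
  }
})

test_that("degenerate carrier margins return p = 1 without error", {
  r <- fisher_exact_2x2(0, 10, 0, 20)
  expect_equal(r$p_two_sided, 1)
  expect_true(is.na(r$or_cmle))
  full <- fisher_exact_2x2(10, 0, 20, 0)
  expect_equal(full$p_two_sided, 1)
  expect_error(fisher_exact_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("exact test is transpose-consistent (row swap inverts the OR)", {
  set.seed(8)
  for (i in 1:15) {
    x <- rpois(4, 5) + c(1, 1, 1, 1)
    a <- fisher_exact_2x2(x[1], x[2], x[3], x[4], ci_tol = 1e-10)
    b <- fisher_exact_2x2(x[3], x[4], x[1], x[2], ci_tol = 1e-10)
    expect_equal(a$p_two_sided, b$p_two_sided, tolerance = 1e-10)
    expect_equal(a$or_cmle, 1 / b$or_cmle, tolerance = 1e-5)
    expect_equal(a$ci_low, 1 / b$ci_high, tolerance = 1e-5)
    expect_equal(a$ci_high, 1 / b$ci_low, tolerance = 1e-5)
  }
})

test_that("high-precision CI endpoints invert the one-sided tests", {
  tables <- list(c(12, 231, 1, 2987), c(5, 238, 2, 2986), c(7, 3, 2, 9),
                 c(4, 16, 9, 11))
  tail_at <- function(psi, a, b, c, d, lower) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c
    supp <- max(0, c1 - r2):min(r1, c1)
    w <- dhyper(supp, r1, r2, c1) * psi^supp
    w <- w / sum(w)
    if (lower) sum(w[supp <= a]) else sum(w[supp >= a])
  }
  for (t in tables) {
    r <- fisher_exact_2x2(t[1], t[2], t[3], t[4], ci_tol = 1e-10)
    expect_equal(tail_at(r$ci_low, t[1], t[2], t[3], t[4], lower = FALSE),
                 0.025, tolerance = 1e-6)
    expect_equal(tail_at(r$ci_high, t[1], t[2], t[3], t[4], lower = TRUE),
                 0.025, tolerance = 1e-6)
    expect_true(r$ci_low <= r$or_cmle && r$or_cmle <= r$ci_high)
  }
})

test_that("the cMLE solves the conditional score equation", {
  tables <- list(c(12, 231, 1, 2987), c(6, 4, 3, 7), c(2, 8, 5, 5))
  for (t in tables) {
    r <- fisher_exact_2x2(t[1], t[2], t[3], t[4], ci_tol = 1e-10)
    r1 <- t[1] + t[2]; r2 <- t[3] + t[4]; c1 <- t[1] + t[3]
    supp <- max(0, c1 - r2):min(r1, c1)
    w <- dhyper(supp, r1, r2, c1) * r$or_cmle^supp
    expect_equal(sum(supp * w / sum(w)), t[1], tolerance = 1e-5)
  }
})

test_that("BH adjustment equals the direct step-up formula", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(12)
  # large vector with ties
  p <- round(runif(5000), 3)
  expect_equal(bh_adjust(p), bh_oracle(p))
  # monotone in the sorted order, permutation-equivariant
  o <- order(p)
  expect_true(all(diff(bh_adjust(p)[o]) >= 0))
  perm <- sample(length(p))
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("carrier counting is per-sample with 1 bp overlap sensitivity", {
  s <- make_samples(n_cases = 3, n_controls = 3)
  genes <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "chr1",
                          start = c(1000L, 50000L), end = c(2000L, 60000L))
  cnvs <- make_calls(
    # overlaps gA by exactly 1 bp
    make_call(sample_id = s$sample_id[1], start = 1999L, end = 7000L),
    # two duplications from one sample over gB count once
    make_call(sample_id = s$sample_id[2], start = 49000L, end = 51000L,
              cnv_type = "duplication"),
    make_call(sample_id = s$sample_id[2], start = 55000L, end = 61000L,
              cnv_type = "duplication"),
    # control carrier at gA; ends right before gB starts (no overlap)
    make_call(sample_id = s$sample_id[4], start = 900L, end = 50000L)
  )
  del <- count_gene_carriers(cnvs, genes, s, "deletion")
  expect_equal(del$case_carriers[del$gene_id == "gA"], 1L)
  expect_equal(del$control_carriers[del$gene_id == "gA"], 1L)
  expect_false("gB" %in% del$gene_id)  # half-open: [.,50000) misses gB
  dup <- count_gene_carriers(cnvs, genes, s, "duplication")
  expect_equal(dup$case_carriers[dup$gene_id == "gB"], 1L)
  expect_equal(dup$case_cd + dup$case_uc, dup$case_carriers)
  expect_error(
    count_gene_carriers(make_call(sample_id = "ghost"), genes, s,
                        "deletion"),
    "ghost"
  )
})

test_that("carrier counts equal a per-base brute-force scan", {
  set.seed(41)
  s <- make_samples(n_cases = 4, n_controls = 4)
  genes <- tibble::tibble(gene_id = sprintf("g%d", 1:5), chrom = "chr1",
                          start = seq(0L, 4000L, by = 1000L)) |>
    dplyr::mutate(end = start + 600L)
  st <- sample.int(4500, 40)
  cnvs <- tibble::tibble(
    sample_id = sample(s$sample_id, 40, TRUE), chrom = "chr1",
    start = st, end = st + sample.int(500, 40),
    cnv_type = sample(c("deletion", "duplication"), 40, TRUE)
  )
  for (tp in c("deletion", "duplication")) {
    got <- count_gene_carriers(cnvs, genes, s, tp)
    for (g in seq_len(nrow(genes))) {
      gene_bases <- seq(genes$start[g], genes$end[g] - 1)
      carriers <- unique(cnvs$sample_id[
        cnvs$cnv_type == tp &
          vapply(seq_len(nrow(cnvs)), function(i) {
            any(seq(cnvs$start[i], cnvs$end[i] - 1) %in% gene_bases)
          }, logical(1))
      ])
      want_case <- sum(carriers %in% s$sample_id[s$cohort == "case"])
      want_ctl <- sum(carriers %in% s$sample_id[s$cohort == "control"])
      row <- got[got$gene_id == genes$gene_id[g], ]
      if (length(carriers) == 0) {
        expect_equal(nrow(row), 0)
      } else {
        expect_equal(row$case_carriers, want_case)
        expect_equal(row$control_carriers, want_ctl)
      }
    }
  }
})

test_that("association pools BH across both type universes and flags rarity", {
  s <- make_samples(n_cases = 5, n_controls = 5)
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                          start = c(0L, 100000L), end = c(10000L, 110000L))
  cnvs <- make_calls(
    make_call(sample_id = s$sample_id[1], start = 0L, end = 8000L),
    make_call(sample_id = s$sample_id[2], start = 0L, end = 8000L),
    make_call(sample_id = s$sample_id[1], start = 100000L, end = 108000L,
              cnv_type = "duplication"),
    make_call(sample_id = s$sample_id[6], start = 100000L, end = 108000L,
              cnv_type = "duplication")
  )
  assoc <- run_association(cnvs, genes, s)
  # universe size = |deletion universe| + |duplication universe|
  expect_equal(nrow(assoc), 2)
  expect_equal(attr(assoc, "m_tests"), 2)
  expect_equal(sort(paste(assoc$gene_id, assoc$cnv_type)),
               c("g1 deletion", "g2 duplication"))
  # pooled BH equals adjusting the combined p-vector
  expect_equal(assoc$p_adj, bh_oracle(assoc$p_two_sided))
  expect_equal(glance(assoc)$m_tests, 2)
  expect_s3_class(autoplot(assoc), "ggplot")
})

test_that("rarity is a strict threshold on the control carrier proportion", {
  rare_flag <- function(k) k / 2988 < 0.001
  expect_true(rare_flag(1))
  expect_true(rare_flag(2))
  expect_false(rare_flag(3))
  # through the full interface
  s <- make_samples(n_cases = 2, n_controls = 10)
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 0L,
                          end = 10000L)
  cnvs <- make_calls(
    make_call(sample_id = s$sample_id[1]),
    make_call(sample_id = s$sample_id[3])
  )
  # 1/10 controls = 10% is far above 0.1%: not rare
  assoc <- run_association(cnvs, genes, s)
  expect_false(assoc$is_rare)
  assoc2 <- run_association(cnvs, genes, s, rare_control_freq = 0.2)
  expect_true(assoc2$is_rare)
})

test_that("an empty universe warns and returns an empty result", {
  s <- make_samples()
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 0L,
                          end = 1000L)
  expect_warning(assoc <- run_association(make_call()[0, ], genes, s),
                 "empty")
  expect_equal(nrow(assoc), 0)
})

test_that("clinical subgroup tests pick the right method", {
  # 17 of 120 CD vs 23 of 123 UC carriers: no significant difference
  dat <- tibble::tibble(
    subtype = rep(c("CD", "UC"), c(120, 123)),
    carrier = c(rep(c(TRUE, FALSE), c(17, 103)),
                rep(c(TRUE, FALSE), c(23, 100)))
  )
  res <- subgroup_association(dat)
  expect_equal(res$method, "fisher_exact_2x2")
  expect_gt(res$p_value, 0.05)
  # identical carrier proportions give p = 1
  bal <- tibble::tibble(subtype = rep(c("CD", "UC"), each = 50),
                        carrier = rep(c(TRUE, FALSE), times = 50))
  expect_equal(subgroup_association(bal)$p_value, 1)
  # r x 2 with small cells: exact method, equal to the reference
  dat3 <- tibble::tibble(
    level = rep(c("A17", "A40", "A60"), c(8, 9, 7)),
    carrier = c(rep(TRUE, 3), rep(FALSE, 5), rep(TRUE, 1), rep(FALSE, 8),
                rep(TRUE, 4), rep(FALSE, 3))
  )
  res3 <- subgroup_association(dat3, feature = "level")
  expect_equal(res3$method, "fisher_exact_rx2")
  ref <- fisher.test(table(dat3$level, factor(dat3$carrier,
                                              levels = c(TRUE, FALSE))))
  expect_equal(res3$p_value, ref$p.value)
  expect_error(subgroup_association(dplyr::mutate(bal, subtype = "CD")),
               "two levels")
})
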