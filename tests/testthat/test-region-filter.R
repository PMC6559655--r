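test_that("overlap fractions follow the union-track definition", {
  cnv <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L)
  expect_equal(overlap_fraction(cnv, tibble::tibble(chrom = "chr1",
                                                    start = 0L, end = 100L)),
               1.0)
  expect_equal(overlap_fraction(cnv, tibble::tibble(chrom = "chr1",
                                                    start = 50L, end = 80L)),
               0.30)
  expect_equal(overlap_fraction(cnv, tibble::tibble(chrom = "chr2",
                                                    start = 0L, end = 100L)),
               0)
  expect_error(overlap_fraction(tibble::tibble(chrom = "chr1", start = 5L,
                                               end = 5L),
                                cnv), "length")
})

test_that("overlap fraction equals a base-by-base count on random toys", {
  set.seed(77)
  for (i in 1:25) {
    track <- tibble::tibble(
      chrom = "chr1",
      start = sort(sample.int(9000, 4)),
      len = sample.int(800, 4)
    ) |>
      dplyr::mutate(end = pmin(start + len, 10000L)) |>
      dplyr::select(-"len")
    s <- sample.int(9000, 1)
    cnv <- tibble::tibble(chrom = "chr1", start = s,
                          end = s + sample.int(900, 1))
    expect_equal(overlap_fraction(cnv, track),
                 brute_overlap_fraction(cnv$start, cnv$end, track))
  }
})

test_that("overlap fraction is invariant to splitting the track", {
  cnv <- tibble::tibble(chrom = "chr1", start = 10L, end = 110L)
  whole <- tibble::tibble(chrom = "chr1", start = 0L, end = 200L)
  split3 <- tibble::tibble(chrom = "chr1", start = c(0L, 50L, 120L),
                           end = c(60L, 120L, 200L))
  expect_equal(overlap_fraction(cnv, whole), overlap_fraction(cnv, split3))
})

test_that("buffer tracks clip at chromosome bounds with the right total", {
  cen <- tibble::tibble(chrom = "chr1", start = 4000000L, end = 5000000L)
  lens <- tibble::tibble(chrom = "chr1", length = 10000000L)
  buf <- build_buffer_tracks(cen, lens, buffer_bp = 100000L)
  expect_equal(buf$start, c(0L, 3900000L, 9900000L))
  expect_equal(buf$end, c(100000L, 5100000L, 10000000L))
  expect_equal(sum(buf$end - buf$start), 100000 + 1200000 + 100000)

  # acrocentric-like centromere clips at zero and fuses with the telomere
  cen0 <- tibble::tibble(chrom = "chr1", start = 50000L, end = 950000L)
  buf0 <- build_buffer_tracks(cen0, lens, buffer_bp = 100000L)
  expect_equal(buf0$start[1], 0L)
  expect_equal(buf0$end[1], 1050000L)

  expect_error(
    build_buffer_tracks(tibble::tibble(chrom = "chrZ", start = 1L,
                                       end = 2L), lens),
    "chrZ"
  )
})

make_filter_fixture <- function() {
  lens <- tibble::tibble(chrom = "chr1", length = 10000000L)
  cen <- tibble::tibble(chrom = "chr1", start = 4000000L, end = 5000000L)
  list(
    tracks = list(
      centromere_telomere = build_buffer_tracks(cen, lens),
      segdup = tibble::tibble(chrom = "chr1", start = 2000000L,
                              end = 2100000L),
      immunoglobulin = tibble::tibble(chrom = "chr1", start = 7000000L,
                                      end = 7050000L)
    ),
    lens = lens
  )
}

test_that("region rules: any buffered overlap removes, fractions are strict", {
  fx <- make_filter_fixture()
  cnvs <- tibble::tibble(
    sample_id = "s1", chrom = "chr1",
    start = c(99999L, 2000000L, 2000000L, 300000L),
    end = c(110000L, 2070000L, 2100000L, 320000L),
    cnv_type = "deletion"
  )
  # [99999,110000) touches the [0,100000) telomere window by exactly 1 bp
  # segdup overlaps: 70000/70000 = 1.0 (removed) vs exactly 0.70 (kept)
  cnvs$end[3] <- 2100000L; cnvs$start[3] <- 2000000L  # fraction 1 over 100kb
  cnvs2 <- tibble::tibble(
    sample_id = "s1", chrom = "chr1",
    start = 1970000L, end = 2070000L, cnv_type = "deletion"
  ) # overlap 70000 of length 100000 -> exactly 0.70, strict > keeps it
  res <- apply_region_filters(cnvs, fx$tracks)
  expect_true("centromere_telomere" %in% res$removed$rules)
  expect_true(cnvs$start[4] %in% res$kept$start)
  res2 <- apply_region_filters(cnvs2, fx$tracks)
  expect_equal(nrow(res2$kept), 1)
  expect_equal(overlap_fraction(cnvs2, fx$tracks$segdup), 0.70)

  # slightly more than 70% is removed with the segdup rule attributed
  cnvs3 <- dplyr::mutate(cnvs2, start = start + 10L)
  res3 <- apply_region_filters(cnvs3, fx$tracks)
  expect_equal(res3$removed$rules, "segdup_fraction")
})

test_that("kept and removed partition the input on randomized suites", {
  fx <- make_filter_fixture()
  set.seed(99)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    st <- sample.int(9900000L, n)
    cnvs <- tibble::tibble(
      sample_id = sprintf("s%d", sample(1:4, n, TRUE)), chrom = "chr1",
      start = st, end = st + sample.int(300000L, n), cnv_type = "deletion"
    ) |> dplyr::mutate(end = pmin(end, 10000000L))
    res <- apply_region_filters(cnvs, fx$tracks)
    expect_equal(nrow(res$kept) + nrow(res$removed), n)
    both <- dplyr::bind_rows(res$kept, res$removed[names(res$kept)])
    expect_equal(dplyr::arrange(both, start, end),
                 dplyr::arrange(cnvs, start, end))
  }
})

test_that("enlarging a track never rescues a removed CNV", {
  fx <- make_filter_fixture()
  set.seed(13)
  st <- sample.int(9000000L, 40)
  cnvs <- tibble::tibble(sample_id = "s1", chrom = "chr1", start = st,
                         end = pmin(st + sample.int(400000L, 40), 10000000L),
                         cnv_type = "duplication")
  res_small <- apply_region_filters(cnvs, fx$tracks)
  bigger <- fx$tracks
  bigger$segdup <- dplyr::mutate(bigger$segdup, start = start - 50000L,
                                 end = end + 50000L)
  bigger$centromere_telomere <- dplyr::mutate(
    bigger$centromere_telomere, end = end + 20000L
  )
  res_big <- apply_region_filters(cnvs, bigger)
  removed_small <- paste(res_small$removed$start, res_small$removed$end)
  removed_big <- paste(res_big$removed$start, res_big$removed$end)
  expect_true(all(removed_small %in% removed_big))
})

test_that("a missing track is a configuration error", {
  fx <- make_filter_fixture()
  cnvs <- tibble::tibble(sample_id = "s1", chrom = "chr1", start = 0L,
                         end = 10000L, cnv_type = "deletion")
  expect_error(apply_region_filters(cnvs, fx$tracks[c("segdup")]),
               "missing required track")
  expect_error(apply_region_filters(cnvs, fx$tracks, segdup_max_frac = 1.5),
               "fraction")
})

test_that("the shipped immunoglobulin default track loads and filters", {
  path <- system.file("extdata", "immunoglobulin_hg19.bed",
                      package = "rarecnv")
  ig <- read_region_track(path, "immunoglobulin")
  expect_equal(nrow(ig), 3)
  expect_setequal(ig$chrom, c("chr2", "chr14", "chr22"))
  # a CNV fully inside the IGH locus is removed by the fraction rule
  cnvs <- tibble::tibble(sample_id = "s1", chrom = c("chr14", "chr14"),
                         start = c(106100000L, 90000000L),
                         end = c(106200000L, 90100000L),
                         cnv_type = "duplication")
  tracks <- list(
    centromere_telomere = tibble::tibble(chrom = "chr1", start = 0L,
                                         end = 100000L),
    segdup = ig[0, ],
    immunoglobulin = ig
  )
  res <- apply_region_filters(cnvs, tracks)
  expect_equal(res$removed$rules, "ig_fraction")
  expect_equal(res$kept$start, 90000000L)
})
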