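toy_grid <- function(chrom_len = 100, seg_len = 10) {
  genome_grid(c(toy = chrom_len), seg_len)
}

test_that("segment averaging matches the per-basepair oracle exactly", {
  set.seed(61)
  for (i in 1:200) {
    chrom_len <- sample(40:100, 1)
    seg_len <- sample(c(5, 10, 25), 1)
    rec <- random_toy_records(chrom_len)
    grid <- toy_grid(chrom_len, seg_len)
    got <- suppressWarnings(segment_average_copy(rec, grid))
    expect_equal(got, brute_avg_copy(rec, chrom_len, seg_len),
                 tolerance = 1e-12)
  }
})

test_that("worked detectability examples hold", {
  g5 <- genome_grid(c(chrA = 5e6), 5e6)
  # 1 Mb subsection with 5 extra copies: average +1, detectable
  r1 <- tibble::tibble(sample_id = "s", chrom = "chrA", start = 1e6,
                       end = 2e6, copies = 7)
  d1 <- segment_average_copy(r1, g5)
  expect_equal(d1, 1)
  expect_true(flag_detectable(d1))
  # whole 5 Mb spanned by a single-copy gain: average +1, detectable
  r2 <- tibble::tibble(sample_id = "s", chrom = "chrA", start = 0,
                       end = 5e6, copies = 3)
  expect_equal(segment_average_copy(r2, g5), 1)
  # empty: zero deviation
  expect_equal(segment_average_copy(r1[0, ], g5), 0)
  expect_error(
    segment_average_copy(
      tibble::tibble(sample_id = "s", chrom = "chrA", start = 0, end = 6e6,
                     copies = 3), g5),
    "chromosome end")
})

test_that("a record spanning several segments contributes uniformly", {
  g <- genome_grid(c(chrA = 20e6), 5e6)
  r <- tibble::tibble(sample_id = "s", chrom = "chrA", start = 0, end = 15e6,
                      copies = 5)
  expect_equal(segment_average_copy(r, g), c(3, 3, 3, 0))
})

test_that("later records take precedence over earlier overlapping ones", {
  g <- genome_grid(c(chrA = 10), 10)
  r <- tibble::tibble(sample_id = "s", chrom = "chrA",
                      start = c(0, 0), end = c(10, 5), copies = c(4, 0))
  expect_warning(d <- segment_average_copy(r, g), "precedence")
  # first half overwritten to 0 copies (-2), second half stays +2
  expect_equal(d, (5 * (-2) + 5 * 2) / 10)
})

test_that("detectability flag is inclusive and symmetric", {
  expect_equal(flag_detectable(c(1, 0.99, -1.2, 0, -0.99)),
               c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(flag_detectable(c(0.5, -0.5), threshold = 0.5), c(TRUE, TRUE))
})

test_that("five-level discretisation applies the copy-state breakpoints", {
  x <- c(0.2, 0.7, 1.8, -0.6, -1.7, 0.5, -0.5, 1.5, -1.5, 0.49, -0.49)
  expect_equal(as.character(sax_discretize(x)),
               c("NEUTRAL", "AMP1", "AMP2PLUS", "DEL1", "DEL2", "AMP1",
                 "DEL1", "AMP2PLUS", "DEL2", "NEUTRAL", "NEUTRAL"))
  # order-preserving in avg_dev
  xs <- sort(runif(50, -3, 3))
  codes <- as.integer(sax_discretize(xs))
  expect_true(all(diff(codes) >= 0))
})

test_that("germline filtering removes only high-frequency reciprocal overlaps", {
  rec <- tibble::tibble(sample_id = "s", chrom = "chrA",
                        start = c(0, 2e6, 4e6), end = c(1e6, 3e6, 5e6),
                        copies = 4)
  res <- tibble::tibble(chrom = "chrA",
                        start = c(0, 2e6), end = c(1e6, 3e6),
                        af = c(0.05, 0.005))
  out <- filter_germline(rec, res)
  # only the AF = 5% equal-size overlap is removed
  expect_equal(out$start, c(2e6, 4e6))
  expect_identical(filter_germline(rec, res[0, ]), rec)
  # partial overlap below reciprocal threshold is kept
  res2 <- tibble::tibble(chrom = "chrA", start = 0, end = 4e5, af = 0.2)
  expect_equal(nrow(filter_germline(rec, res2)), 3)
  expect_error(filter_germline(
    tibble::tibble(sample_id = "s", chrom = "c", start = 5, end = 5, copies = 2),
    res), "malformed")
})

test_that("cohort detectable fractions count per-type events correctly", {
  g <- genome_grid(c(chrA = 20e6), 5e6)
  # type T: 2 of 3 samples with one detectable segment each
  rec <- tibble::tibble(
    sample_id = c("t1", "t2", "t2", "n1"),
    chrom = "chrA",
    start = c(0, 0, 5e6, 0), end = c(5e6, 5e6, 10e6, 5e6),
    copies = c(3, 3, 3, 2))
  labels <- tibble::tibble(sample_id = c("t1", "t2", "t3", "n1"),
                           type = c("T", "T", "T", "N"))
  prof <- build_copy_profiles(rec, g, sample_ids = labels$sample_id)
  f1 <- cohort_detectable_fraction(prof, labels, min_events = 1)
  expect_equal(f1$fraction[f1$type == "T"], 2 / 3)
  expect_equal(f1$fraction[f1$type == "N"], 0)
  f2 <- cohort_detectable_fraction(prof, labels, min_events = 2)
  expect_true(all(f2$fraction <= f1$fraction))
  expect_equal(f2$fraction[f2$type == "T"], 1 / 3)
  # empty segment subset: vacuous, all fractions zero
  f0 <- cohort_detectable_fraction(prof, labels, segments = integer())
  expect_true(all(f0$fraction == 0))
})

test_that("probability-1 whole-segment signatures are always detectable", {
  grid <- genome_grid(c(chrA = 50e6), 5e6)
  sigs <- list(cancer_signature("A", tibble::tibble(segment = 3, prob = 1,
                                                    delta = 2)),
               cancer_signature("normal"))
  coh <- sim_tumor_cohort(sigs, c(A = 10, normal = 5), grid, seed = 3)
  prof <- build_copy_profiles(coh$records, grid,
                              sample_ids = coh$labels$sample_id)
  fr <- cohort_detectable_fraction(prof, coh$labels, segments = 3)
  expect_equal(fr$fraction[fr$type == "A"], 1)
  expect_equal(fr$fraction[fr$type == "normal"], 0)
})

test_that("whole-100Mb events give identical detectable calls at 5 Mb", {
  sizes <- c(chrA = 200e6)
  g100 <- genome_grid(sizes, 100e6)
  g5 <- genome_grid(sizes, 5e6)
  rec <- tibble::tibble(sample_id = "s", chrom = "chrA", start = 0,
                        end = 100e6, copies = 4)
  d100 <- segment_average_copy(rec, g100)
  d5 <- segment_average_copy(rec, g5)
  covered5 <- g5$start < 100e6
  expect_true(all(flag_detectable(d5[covered5])))
  expect_true(flag_detectable(d100)[1])
  expect_false(any(flag_detectable(d5[!covered5])))
  expect_false(flag_detectable(d100)[2])
})
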