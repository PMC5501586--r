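test_that("healthy generator matches its stated first two moments", {
  p <- healthy_sim_params(mean_per_bin = 300, dispersion = 50,
                          gc_bias_coeffs = c(1, 0, 0), outlier_fraction = 0,
                          n_bins = 50000, n_samples = 4,
                          sample_scaling_sd = 0)
  tbl <- sim_healthy_bins(p, seed = 7)
  x <- as.vector(as.matrix(tbl[bin_samples(tbl)]))
  expect_lt(abs(mean(x) - 300) / 300, 0.01)
  expect_lt(abs(var(x) / mean(x) - (1 + 300 / 50)) / 7, 0.05)
})

test_that("generators are reproducible under a fixed seed", {
  p <- healthy_sim_params(n_bins = 2000, n_samples = 3)
  expect_identical(sim_healthy_bins(p, seed = 3), sim_healthy_bins(p, seed = 3))
  expect_false(identical(sim_healthy_bins(p, seed = 3)$S1,
                         sim_healthy_bins(p, seed = 4)$S1))
  g <- sim_germline_af(n_events = 30, seed = 5)
  expect_identical(g, sim_germline_af(n_events = 30, seed = 5))
})

test_that("unit outlier multiplier leaves planted bins at background level", {
  p <- healthy_sim_params(mean_per_bin = 300, dispersion = 50,
                          gc_bias_coeffs = c(1, 0, 0),
                          outlier_fraction = 0.1, outlier_multiplier = 1,
                          n_bins = 50000, n_samples = 4,
                          sample_scaling_sd = 0)
  tbl <- sim_healthy_bins(p, seed = 11)
  x <- rowMeans(as.matrix(tbl[bin_samples(tbl)]))
  expect_lt(abs(mean(x[tbl$truth_outlier]) - mean(x[!tbl$truth_outlier])) /
              mean(x), 0.02)
})

test_that("simulator parameters are validated", {
  expect_error(healthy_sim_params(mean_per_bin = -1), "mean_per_bin")
  expect_error(healthy_sim_params(dispersion = 0), "dispersion")
  expect_error(healthy_sim_params(outlier_fraction = 0.6), "outlier_fraction")
  expect_error(healthy_sim_params(gc_bias_coeffs = c(1, 0, -30)), "positive")
})

test_that("spike_cnv scales in-region means by 1 + f * delta / 2", {
  p <- healthy_sim_params(mean_per_bin = 300, dispersion = 50,
                          gc_bias_coeffs = c(1, 0, 0), outlier_fraction = 0,
                          n_bins = 40000, n_samples = 4,
                          sample_scaling_sd = 0)
  tbl <- sim_healthy_bins(p, seed = 2)
  reg <- list(chrom = "pc1", start = 0, end = 2000 * 1e4)  # 2000 bins
  inreg <- tbl$chrom == reg$chrom & tbl$start < reg$end & tbl$end > reg$start

  sp <- spike_cnv(tbl, reg$chrom, reg$start, reg$end, copy_delta = 1,
                  fraction = 0.1, seed = 9)
  m_in <- mean(as.matrix(sp[inreg, bin_samples(sp)]))
  expect_lt(abs(m_in - 300 * 1.05) / (300 * 1.05), 0.01)
  # outside untouched (bitwise)
  expect_identical(sp$S1[!inreg], tbl$S1[!inreg])

  # fraction 0: same generating recipe
  s0 <- spike_cnv(tbl, reg$chrom, reg$start, reg$end, copy_delta = 1,
                  fraction = 0, seed = 9)
  expect_lt(abs(mean(as.matrix(s0[inreg, bin_samples(s0)])) - 300) / 300, 0.01)

  # pure tumor homozygous loss: expected depth 0
  s2 <- spike_cnv(tbl, reg$chrom, reg$start, reg$end, copy_delta = -2,
                  fraction = 1, seed = 9)
  expect_true(all(as.matrix(s2[inreg, bin_samples(s2)]) == 0))

  expect_error(spike_cnv(tbl, "pc1", 0, 1e5, 1, fraction = 1.2), "fraction")
  expect_error(spike_cnv(tbl, "pc1", 1e5, 1e5, 1, fraction = 0.1), "length")
  expect_error(spike_cnv(tbl, "pc1", 0, 1e5, -3, fraction = 0.1), "copy_delta")
})

test_that("tumor cohort realizes probability-1 events and bookkeeping", {
  grid <- genome_grid(c(chrA = 60e6), 5e6)
  sigs <- list(
    cancer_signature("A", tibble::tibble(segment = 7, prob = 1, delta = 2)),
    cancer_signature("B", tibble::tibble(segment = 2, prob = 0, delta = 1)),
    cancer_signature("normal"))
  coh <- sim_tumor_cohort(sigs, c(A = 30, B = 30, normal = 40), grid, seed = 1)
  expect_equal(as.vector(table(coh$labels$type)[c("A", "B", "normal")]),
               c(30, 30, 40))
  # every A sample covers segment 7 at 4 copies
  a_recs <- coh$records[grepl("^A_", coh$records$sample_id), ]
  expect_equal(nrow(a_recs), 30)
  expect_true(all(a_recs$start == grid$start[7] & a_recs$copies == 4))
  # probability-0 events and no passengers: B and normal are flat
  expect_false(any(grepl("^(B|normal)_", coh$records$sample_id)))
})

test_that("cohort simulation validates signatures and grid", {
  grid <- genome_grid(c(chrA = 10e6), 5e6)
  sig <- cancer_signature("A", tibble::tibble(segment = 99, prob = 1, delta = 1))
  expect_error(sim_tumor_cohort(list(sig), c(A = 2), grid), "segment")
  expect_error(cancer_signature("A", tibble::tibble(segment = 1, prob = 2, delta = 1)),
               "probabilities")
  expect_error(cancer_signature("A", tibble::tibble(segment = 1, prob = 1, delta = -4)),
               "copies")
})

test_that("germline resource generator covers its contract", {
  g <- sim_germline_af(n_events = 40, af_range = c(0.05, 0.10), seed = 2)
  expect_true(all(g$af > 0.01))  # all filterable at the 1% threshold
  expect_equal(nrow(sim_germline_af(n_events = 0)), 0)
  expect_true(all(g$end > g$start))
})

test_that("binomial thinning of NB counts matches NB(p*m, r) moments", {
  p <- healthy_sim_params(mean_per_bin = 300, dispersion = 50,
                          gc_bias_coeffs = c(1, 0, 0), outlier_fraction = 0,
                          n_bins = 50000, n_samples = 2,
                          sample_scaling_sd = 0)
  tbl <- sim_healthy_bins(p, seed = 5)
  th <- subsample_depth(tbl, 0.5, seed = 6)
  x <- as.vector(as.matrix(th[bin_samples(th)]))
  expect_lt(abs(mean(x) - 150) / 150, 0.01)
  expect_lt(abs(var(x) / mean(x) - (1 + 150 / 50)) / 4, 0.05)
})
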