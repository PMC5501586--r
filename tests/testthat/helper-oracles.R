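# Independent oracles and small fixture builders used across tests.

# Brute-force per-basepair average copy deviation over a single-chromosome
# grid. Records are applied in order with later records overwriting earlier
# ones (the precedence rule), then deviations are averaged per segment.
brute_avg_copy <- function(records, chrom_len, seg_len) {
  bp <- rep(0, chrom_len)  # deviation from diploid per basepair
  if (nrow(records) > 0) {
    for (i in seq_len(nrow(records))) {
      idx <- (records$start[i] + 1):records$end[i]
      bp[idx] <- records$copies[i] - 2
    }
  }
  starts <- seq(0, chrom_len - 1, by = seg_len)
  vapply(starts, function(s) {
    mean(bp[(s + 1):min(s + seg_len, chrom_len)])
  }, numeric(1))
}

# Random toy segmentation on one chromosome of `chrom_len` bp.
random_toy_records <- function(chrom_len, max_records = 10,
                               allow_overlap = TRUE) {
  n <- sample.int(max_records, 1)
  start <- sample.int(chrom_len, n, replace = TRUE) - 1
  len <- sample.int(max(1, chrom_len %/% 3), n, replace = TRUE)
  end <- pmin(start + len, chrom_len)
  keep <- end > start
  rec <- tibble::tibble(
    sample_id = "s1", chrom = "toy",
    start = start[keep], end = end[keep],
    copies = sample(c(0, 1, 3, 4, 7), sum(keep), replace = TRUE))
  if (!allow_overlap && nrow(rec) > 1) {
    rec <- rec[order(rec$start), ]
    ok <- c(TRUE, rec$start[-1] >= cummax(rec$end[-nrow(rec)]))
    rec <- rec[ok, ]
  }
  rec
}

# A perfectly separable synthetic cohort: disjoint probability-1 signature
# events, no passengers; returns profiles, labels and the planted segments.
build_separable_cohort <- function(n_types = 5, n_per_type = 50,
                                   events_per_type = 2, delta = 2,
                                   grid_size = 5e6, seed = 42) {
  grid <- genome_grid(segment_size = grid_size)
  types <- paste0("type", LETTERS[seq_len(n_types)])
  sigs <- separable_signatures(types, grid, events_per_type = events_per_type,
                               delta = delta)
  planted <- sort(unique(unlist(
    lapply(sigs, function(s) s$events$segment))))
  sigs$normal <- cancer_signature("normal")
  n_per <- setNames(rep(n_per_type, length(sigs)), names(sigs))
  coh <- sim_tumor_cohort(sigs, n_per, grid, seed = seed)
  profiles <- build_copy_profiles(coh$records, grid,
                                  sample_ids = coh$labels$sample_id)
  list(profiles = profiles, labels = coh$labels, planted = planted,
       grid = grid)
}

# Closed-form normal-approximation minimal detectable size: solves
# (f * dc / 2) / sqrt(1/M0 + 1/R) = qnorm(1 - p) for the region length L,
# with M0 = d L / read_length and R = r L / bin_size.
closed_form_lod <- function(depth, fraction, copy_delta, model,
                            p_threshold = 0.01) {
  z <- qnorm(1 - p_threshold)
  (z * sqrt(model$read_length / depth + model$bin_size / model$r) /
     (fraction * abs(copy_delta) / 2))^2
}
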