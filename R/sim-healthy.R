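#' Parameters for the healthy cfDNA bin-count simulator
#'
#' Describes a cohort of healthy-donor cell-free DNA samples sequenced to a
#' reference depth and counted in fixed-width genomic bins. Counts are
#' negative binomial around a per-bin mean that is modulated by a smooth
#' multiplicative GC-bias curve, a per-sample library-size factor, and a
#' small set of planted outlier bins (mimicking mismapping-prone regions).
#'
#' The GC-bias curve is quadratic in centered GC,
#' `bias(g) = b0 + b1 (g - 0.41) + b2 (g - 0.41)^2`, and must be strictly
#' positive on \[0, 1\]. GC fractions are Beta-distributed with mean about
#' 0.41, mimicking genomic GC composition. Per-sample scale factors are
#' log-normal with `sdlog = sample_scaling_sd`, so downstream preprocessing
#' has real library-size variation to normalise away.
#'
#' @param mean_per_bin Expected reads per bin at reference depth (> 0).
#' @param dispersion Negative-binomial shape `r` (> 0); bin-count variance is
#'   `m + m^2 / r`.
#' @param gc_bias_coeffs Numeric length 3: coefficients `b0`, `b1`, `b2` of
#'   the quadratic bias curve in centered GC.
#' @param outlier_fraction Proportion of bins with inflated counts, in
#'   \[0, 0.5).
#' @param outlier_multiplier Mean inflation factor for outlier bins (>= 1;
#'   1 makes "outliers" indistinguishable from background).
#' @param n_bins Number of bins in the simulated genome.
#' @param n_samples Number of donors.
#' @param bin_size Bin width in bp.
#' @param read_length Read length in bp (used to express depth).
#' @param sample_scaling_sd `sdlog` of the log-normal per-sample scale
#'   factors; 0 disables library-size variation.
#' @param gc_shape Length-2 shape parameters of the Beta distribution GC
#'   fractions are drawn from.
#' @return A list of class `healthy_sim_params`.
#' @export
healthy_sim_params <- function(mean_per_bin = 300,
                               dispersion = 50,
                               gc_bias_coeffs = c(1, 0.9, -2),
                               outlier_fraction = 0.01,
                               outlier_multiplier = 10,
                               n_bins = 200000,
                               n_samples = 9,
                               bin_size = 1e4,
                               read_length = 100,
                               sample_scaling_sd = 0.05,
                               gc_shape = c(10, 14.4)) {
  stopifnot(length(gc_bias_coeffs) == 3, length(gc_shape) == 2)
  if (mean_per_bin <= 0) stop("mean_per_bin must be > 0", call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  if (outlier_fraction < 0 || outlier_fraction >= 0.5) {
    stop("outlier_fraction must lie in [0, 0.5)", call. = FALSE)
  }
  if (outlier_multiplier <= 0) stop("outlier_multiplier must be > 0", call. = FALSE)
  if (n_bins < 1 || n_samples < 1) stop("n_bins and n_samples must be >= 1", call. = FALSE)
  if (sample_scaling_sd < 0) stop("sample_scaling_sd must be >= 0", call. = FALSE)
  bias <- gc_bias_curve(seq(0, 1, by = 0.01), gc_bias_coeffs)
  if (any(bias <= 0)) stop("GC bias curve must be strictly positive on [0, 1]", call. = FALSE)
  structure(
    list(
      mean_per_bin = mean_per_bin, dispersion = dispersion,
      gc_bias_coeffs = gc_bias_coeffs, outlier_fraction = outlier_fraction,
      outlier_multiplier = outlier_multiplier, n_bins = n_bins,
      n_samples = n_samples, bin_size = bin_size, read_length = read_length,
      sample_scaling_sd = sample_scaling_sd, gc_shape = gc_shape
    ),
    class = "healthy_sim_params"
  )
}

gc_bias_curve <- function(gc, coeffs) {
  g <- gc - 0.41
  coeffs[1] + coeffs[2] * g + coeffs[3] * g^2
}

# Per-bin, per-sample expected counts implied by a simulated table's recipe.
# bias_norm is the mean of the raw bias curve over the table's GC values:
# dividing by it makes mean_per_bin the marginal mean count of clean bins,
# whatever the bias amplitude.
sim_mu_matrix <- function(params, gc, truth_outlier, sample_scaling,
                          bias_norm = 1) {
  mu <- params$mean_per_bin * gc_bias_curve(gc, params$gc_bias_coeffs) / bias_norm
  mu[truth_outlier] <- mu[truth_outlier] * params$outlier_multiplier
  outer(mu, sample_scaling)
}

#' Simulate healthy cfDNA bin counts
#'
#' Draws a per-bin, per-sample read-count table under the model described in
#' [healthy_sim_params()]: `counts[i, j] ~ NB(mean = m * bias(gc_i) * s_j,
#' shape = r)`, with planted outlier bins whose mean is multiplied by
#' `outlier_multiplier`. Bins are laid out consecutively along
#' pseudo-chromosomes whose relative sizes follow [default_chrom_sizes()].
#'
#' @param params A [healthy_sim_params()] object.
#' @param seed Optional integer; when given, generation is reproducible.
#' @return A bin-count tibble with columns `chrom`, `start`, `end`, `gc`,
#'   `mask` (all `TRUE`), `truth_outlier` (ground-truth planted outliers) and
#'   one integer count column per sample (`S1`, `S2`, ...). The simulation
#'   recipe (parameters and per-sample scale factors) is attached as
#'   attribute `"sim"` so that [spike_cnv()] can re-draw regions.
#' @examples
#' tbl <- sim_healthy_bins(healthy_sim_params(n_bins = 500, n_samples = 3), seed = 1)
#' dplyr::glimpse(tbl)
#' @export
sim_healthy_bins <- function(params = healthy_sim_params(), seed = NULL) {
  stopifnot(inherits(params, "healthy_sim_params"))
  run <- function() {
    n <- params$n_bins
    gc <- rbeta(n, params$gc_shape[1], params$gc_shape[2])
    truth_outlier <- rep(FALSE, n)
    n_out <- round(params$outlier_fraction * n)
    if (n_out > 0) truth_outlier[sample.int(n, n_out)] <- TRUE
    s <- if (params$sample_scaling_sd > 0) {
      rlnorm(params$n_samples, meanlog = 0, sdlog = params$sample_scaling_sd)
    } else {
      rep(1, params$n_samples)
    }
    bias_norm <- mean(gc_bias_curve(gc, params$gc_bias_coeffs))
    mu <- sim_mu_matrix(params, gc, truth_outlier, s, bias_norm)
    counts <- matrix(
      rnbinom(n * params$n_samples, size = params$dispersion, mu = as.vector(mu)),
      nrow = n
    )
    colnames(counts) <- paste0("S", seq_len(params$n_samples))
    # consecutive bins across pseudo-chromosomes, proportional to the
    # default genome's chromosome sizes
    props <- default_chrom_sizes() / sum(default_chrom_sizes())
    cuts <- unique(c(0, round(cumsum(props) * n)))
    bins_per <- diff(cuts)
    chrom <- rep(names(default_chrom_sizes())[seq_along(bins_per)], bins_per)
    start <- unlist(lapply(bins_per, function(k) seq_len(k) - 1)) * params$bin_size
    tbl <- tibble::tibble(
      chrom = chrom, start = start, end = start + params$bin_size,
      gc = gc, mask = TRUE, truth_outlier = truth_outlier
    )
    tbl <- dplyr::bind_cols(tbl, tibble::as_tibble(counts))
    attr(tbl, "sim") <- list(params = params, sample_scaling = s,
                             bias_norm = bias_norm)
    tbl
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Sample (count) columns of a bin-count table
#'
#' @param table A bin-count tibble.
#' @return Character vector of count column names.
#' @export
bin_samples <- function(table) {
  setdiff(names(table),
          c("chrom", "start", "end", "gc", "mask", "truth_outlier", "mcd_distance"))
}

#' Spike a ctDNA copy-number variant into simulated bin counts
#'
#' Models plasma cfDNA as a linear mixture of tumor and normal fragments: a
#' region carrying `2 + copy_delta` tumor copies at ctDNA fraction `f` has
#' its expected read depth scaled by `1 + f * copy_delta / 2`. Counts of
#' bins overlapping the region are re-drawn from the negative binomial with
#' the scaled mean; all other bins are untouched.
#'
#' @param table A bin-count tibble from [sim_healthy_bins()] (the simulation
#'   recipe attribute is required to know the generating means).
#' @param chrom,start,end Region to spike (0-based half-open, on the table's
#'   pseudo-genome).
#' @param copy_delta Signed integer copy change (tumor copies minus 2);
#'   `2 + copy_delta` must be >= 0.
#' @param fraction ctDNA fraction in \[0, 1\].
#' @param seed Optional integer seed.
#' @return The table with in-region counts re-drawn; the spiked region is
#'   recorded in attribute `"spikes"`.
#' @examples
#' tbl <- sim_healthy_bins(healthy_sim_params(n_bins = 400, n_samples = 2,
#'                                            outlier_fraction = 0),
#'                         seed = 1)
#' sp <- spike_cnv(tbl, "pc1", 0, 2e5, copy_delta = 4, fraction = 0.2, seed = 2)
#' @export
spike_cnv <- function(table, chrom, start, end, copy_delta, fraction, seed = NULL) {
  sim <- attr(table, "sim")
  if (is.null(sim)) {
    stop("spike_cnv needs a table produced by sim_healthy_bins (simulation recipe attached)",
         call. = FALSE)
  }
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]", call. = FALSE)
  if (end <= start) stop("region must have positive length", call. = FALSE)
  if (2 + copy_delta < 0) stop("2 + copy_delta must be >= 0", call. = FALSE)
  idx <- which(table$chrom == chrom & table$start < end & table$end > start)
  if (length(idx) == 0) stop("region does not overlap the table's genome", call. = FALSE)
  run <- function() {
    params <- sim$params
    mu <- sim_mu_matrix(params, table$gc[idx], table$truth_outlier[idx],
                        sim$sample_scaling, sim$bias_norm)
    scale <- 1 + fraction * copy_delta / 2
    smp <- bin_samples(table)
    redraw <- matrix(
      rnbinom(length(idx) * length(smp), size = params$dispersion,
              mu = as.vector(mu * scale)),
      nrow = length(idx)
    )
    for (j in seq_along(smp)) table[[smp[j]]][idx] <- redraw[, j]
    attr(table, "spikes") <- dplyr::bind_rows(
      attr(table, "spikes"),
      tibble::tibble(chrom = chrom, start = start, end = end,
                     copy_delta = copy_delta, fraction = fraction)
    )
    table
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
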