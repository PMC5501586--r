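#' Mask outlier bins with a robust Minimum Covariance Determinant estimate
#'
#' Genomic bins prone to mismapping carry systematically aberrant counts in
#' every sample. Treating each bin as one observation in sample-dimensional
#' space, a robust MCD location/scatter is estimated over bins and each
#' bin's Mahalanobis distance from the raw (consistency-corrected, not
#' reweighted) estimate is computed; bins farther than `distance_threshold`
#' are masked out of all downstream modelling.
#'
#' @param table Bin-count tibble (see [sim_healthy_bins()] /
#'   [read_bincounts()]); needs >= 2 samples and at least 10x more bins than
#'   samples.
#' @param distance_threshold Mahalanobis distance above which a bin is
#'   masked (default 15).
#' @param support_fraction MCD support fraction h/n (default 0.75).
#' @param seed Seed for the MCD random starts; fixed by default so masking
#'   is deterministic and idempotent.
#' @return The table with `mcd_distance` filled in and `mask` updated
#'   (`mask = FALSE` for bins with distance > threshold).
#' @examples
#' tbl <- sim_healthy_bins(healthy_sim_params(n_bins = 2000, n_samples = 3),
#'                         seed = 1)
#' tbl <- mask_outlier_bins(tbl)
#' table(tbl$mask, tbl$truth_outlier)
#' @export
mask_outlier_bins <- function(table, distance_threshold = 15,
                              support_fraction = 0.75, seed = 171) {
  smp <- bin_samples(table)
  if (length(smp) < 2) stop("need >= 2 samples (bins live in sample space)", call. = FALSE)
  if (nrow(table) < 10 * length(smp)) {
    stop("need at least 10x more bins than samples", call. = FALSE)
  }
  X <- as.matrix(table[smp])
  if (any(apply(X, 2, sd) == 0)) {
    stop("degenerate input: constant counts in at least one sample", call. = FALSE)
  }
  est <- fast_mcd(X, support_fraction = support_fraction, seed = seed)
  table$mcd_distance <- est$dist
  table$mask <- table$mask & (est$dist <= distance_threshold)
  table
}

#' Correct bin counts for GC bias with a LOESS-style smooth
#'
#' Per sample, a locally weighted regression of count on GC fraction is
#' fitted over usable (unmasked) bins; each usable bin's count is rescaled
#' multiplicatively by `target mean / fitted(gc)` and re-rounded to an
#' integer so downstream fits remain count models. Masked bins pass through
#' unchanged. With `target = "grand"` (default) every sample is normalised
#' to the cohort's grand mean count, which also removes library-size
#' differences; `target = "sample"` preserves each sample's own mean.
#'
#' @param table Bin-count tibble with at least 1000 usable bins and
#'   non-constant GC.
#' @param span Smoother span in (0, 1\] (fraction of points in each local
#'   fit; default 0.3).
#' @param target `"grand"` or `"sample"` — the mean count each sample is
#'   rescaled towards.
#' @return The table with usable-bin counts GC-corrected.
#' @export
gc_correct <- function(table, span = 0.3, target = c("grand", "sample")) {
  target <- match.arg(target)
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]", call. = FALSE)
  usable <- table$mask
  if (sum(usable) < 1000) stop("need >= 1000 usable bins", call. = FALSE)
  gcu <- table$gc[usable]
  if (sd(gcu) == 0) stop("GC values are constant", call. = FALSE)
  smp <- bin_samples(table)
  grand <- mean(as.matrix(table[usable, smp]))
  for (s in smp) {
    cnt <- table[[s]]
    lw <- lowess(gcu, cnt[usable], f = span)
    fit <- approx(lw$x, lw$y, xout = gcu, rule = 2, ties = mean)$y
    if (any(fit <= 0)) {
      stop("degenerate input: non-positive fitted GC trend", call. = FALSE)
    }
    tgt <- if (target == "grand") grand else mean(cnt[usable])
    cnt[usable] <- pmax(0L, as.integer(round(cnt[usable] * tgt / fit)))
    table[[s]] <- cnt
  }
  table
}

#' Subsample sequencing depth by binomial thinning
#'
#' Emulates sequencing to a lower depth: each count is replaced by a
#' Binomial(count, `target_fraction`) draw. Thinning a negative binomial
#' NB(m, r) count yields NB(`target_fraction` * m, r), so refitting the
#' count model at thinned depths traces the mean while leaving the
#' dispersion parameter unchanged.
#'
#' @param table Bin-count tibble.
#' @param target_fraction Retention probability in (0, 1\].
#' @param seed Optional integer seed.
#' @return The table with thinned counts; attribute `"depth_fraction"`
#'   multiplied by `target_fraction`.
#' @export
subsample_depth <- function(table, target_fraction, seed = NULL) {
  if (target_fraction <= 0 || target_fraction > 1) {
    stop("target_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (target_fraction == 1) return(table)
  run <- function() {
    for (s in bin_samples(table)) {
      table[[s]] <- rbinom(nrow(table), table[[s]], target_fraction)
    }
    prev <- attr(table, "depth_fraction")
    attr(table, "depth_fraction") <- (if (is.null(prev)) 1 else prev) * target_fraction
    table
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
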