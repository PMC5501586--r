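#' Negative-binomial probability mass function
#'
#' The parameterisation used throughout the package:
#' `P(X = k) = (r/(r+m))^r * Gamma(r+k) / (k! Gamma(r)) * (m/(r+m))^k`,
#' with mean `m` and variance `m + m^2 / r`. Evaluated in log space for
#' numerical stability; `r = 1` reduces to the geometric distribution and
#' `r -> Inf` to the Poisson.
#'
#' @param k Non-negative integer count(s).
#' @param m Mean (> 0).
#' @param r Dispersion / shape (> 0).
#' @return Probability mass at `k` (vectorised).
#' @examples
#' nb_pmf(0, m = 1, r = 1)  # geometric with p = 1/2 -> 0.5
#' @export
nb_pmf <- function(k, m, r) {
  if (any(m <= 0) || any(r <= 0)) stop("m and r must be > 0", call. = FALSE)
  if (any(k < 0) || any(k != floor(k))) {
    stop("k must be a non-negative integer", call. = FALSE)
  }
  exp(r * log(r / (r + m)) + lgamma(r + k) - lgamma(k + 1) - lgamma(r) +
        k * log(m / (r + m)))
}

#' Right tail of the negative binomial
#'
#' `P(X >= k)` under NB(`m`, `r`) — the detection p-value primitive: how
#' surprising a count at least as large as `k` is under the diploid
#' background model.
#'
#' @inheritParams nb_pmf
#' @return Upper-tail probability in \[0, 1\] (vectorised).
#' @export
nb_right_tail <- function(k, m, r) {
  if (any(m <= 0) || any(r <= 0)) stop("m and r must be > 0", call. = FALSE)
  if (any(k < 0) || any(k != floor(k))) {
    stop("k must be a non-negative integer", call. = FALSE)
  }
  pnbinom(k - 1, size = r, mu = m, lower.tail = FALSE)
}

#' Expected read counts for a CNV region under the mixture model
#'
#' A CNV of length `L` spanning whole bins is treated as one super-bin: a
#' sum of `n = L / bin_size` i.i.d. NB(m, r) bin counts is NB(n m, n r), so
#' the region inherits mean `M0 = depth * L / read_length` and dispersion
#' `R = r * n`. At ctDNA fraction `f` and copy change `delta_c`, the
#' affected expectation is `M1 = M0 * (1 + f * delta_c / 2)` (losses give
#' the symmetric reduction).
#'
#' @param depth Haploid genome coverage (> 0).
#' @param fraction ctDNA fraction in \[0, 1\].
#' @param copy_delta Signed copy change (tumor copies minus 2).
#' @param size CNV length in bp; floored to whole bins with a warning if not
#'   a bin multiple.
#' @param model An `nb_fit` / [nb_model()] object supplying `r`, `bin_size`,
#'   `read_length`.
#' @return One-row tibble: `M0`, `M1`, `R`, `n_bins`, `size_bp` (effective,
#'   bin-floored size).
#' @export
expected_region_counts <- function(depth, fraction, copy_delta, size, model) {
  stopifnot(inherits(model, "nb_fit"), depth > 0, size >= model$bin_size)
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]", call. = FALSE)
  if (2 + copy_delta < 0) stop("2 + copy_delta must be >= 0", call. = FALSE)
  n_bins <- floor(size / model$bin_size)
  if (any(size %% model$bin_size != 0)) {
    warning("size not a multiple of bin_size; floored to whole bins")
  }
  size_eff <- n_bins * model$bin_size
  m0 <- depth * size_eff / model$read_length
  tibble::tibble(
    M0 = m0,
    M1 = m0 * (1 + fraction * copy_delta / 2),
    R = model$r * n_bins,
    n_bins = n_bins,
    size_bp = size_eff
  )
}

#' Detection p-value for a ctDNA CNV query
#'
#' The p-value is the tail mass of the diploid background NB(`M0`, `R`)
#' region model evaluated at the expected affected count `M1`: the right
#' tail at `ceiling(M1)` for gains, the left tail at `floor(M1)` for losses.
#' A region is called detectable when the p-value falls below the screening
#' threshold (0.01 by convention).
#'
#' @inheritParams expected_region_counts
#' @return Numeric p-value (vectorised over `size`).
#' @export
detection_pvalue <- function(depth, fraction, copy_delta, size, model) {
  ex <- expected_region_counts(depth, fraction, copy_delta, size, model)
  if (copy_delta < 0) {
    pnbinom(floor(ex$M1), size = ex$R, mu = ex$M0)
  } else {
    pnbinom(ceiling(ex$M1) - 1, size = ex$R, mu = ex$M0, lower.tail = FALSE)
  }
}

#' Minimal detectable CNV size at a depth / fraction / copy change
#'
#' Scans an ascending size grid (default 1-250 Mb in 1 Mb steps — 1 Mb is
#' the focal-amplification scale, 250 Mb the largest chromosome) and returns
#' the smallest size whose detection p-value falls below `p_threshold`.
#'
#' @inheritParams expected_region_counts
#' @param size_grid Ascending vector of candidate sizes (bp).
#' @param p_threshold Detection threshold (default 0.01).
#' @return One-row tibble: `depth`, `fraction`, `copy_delta`,
#'   `min_detectable_size` (bp; `NA` if no grid size is detectable),
#'   `p_at_min_size`.
#' @export
min_detectable_size <- function(depth, fraction, copy_delta, model,
                                size_grid = seq(1e6, 250e6, by = 1e6),
                                p_threshold = 0.01) {
  if (length(size_grid) == 0) stop("size_grid is empty", call. = FALSE)
  if (is.unsorted(size_grid)) stop("size_grid must be ascending", call. = FALSE)
  p <- detection_pvalue(depth, fraction, copy_delta, size_grid, model)
  hit <- which(p < p_threshold)
  tibble::tibble(
    depth = depth, fraction = fraction, copy_delta = copy_delta,
    min_detectable_size = if (length(hit)) size_grid[hit[1]] else NA_real_,
    p_at_min_size = if (length(hit)) p[hit[1]] else NA_real_
  )
}

#' Limit-of-detection table over depth x fraction x copy-change axes
#'
#' Evaluates [min_detectable_size()] on the Cartesian product of the axes;
#' undetectable cells are kept as `NA` rows, so the table is plot-ready.
#'
#' @param depths,fractions,copy_deltas Non-empty numeric axes.
#' @inheritParams min_detectable_size
#' @return A tibble of class `lod_table` with one row per query.
#' @examples
#' lod <- lod_grid(c(1, 3, 10), c(0.01, 0.1), c(1, 4), nb_model(300, 50))
#' @export
lod_grid <- function(depths, fractions, copy_deltas, model,
                     size_grid = seq(1e6, 250e6, by = 1e6),
                     p_threshold = 0.01) {
  stopifnot(length(depths) > 0, length(fractions) > 0, length(copy_deltas) > 0)
  grid <- tidyr::expand_grid(depth = depths, fraction = fractions,
                             copy_delta = copy_deltas)
  out <- purrr::pmap(grid, function(depth, fraction, copy_delta) {
    min_detectable_size(depth, fraction, copy_delta, model,
                        size_grid = size_grid, p_threshold = p_threshold)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("lod_table", class(out))
  out
}

#' Plot limit-of-detection curves
#'
#' Minimal detectable CNV size (Mb) against sequencing depth, one line per
#' ctDNA fraction, faceted by copy change.
#'
#' @param object A `lod_table` from [lod_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lod_table <- function(object, ...) {
  ggplot2::ggplot(
    dplyr::filter(object, !is.na(.data$min_detectable_size)),
    ggplot2::aes(x = .data$depth, y = .data$min_detectable_size / 1e6,
                 colour = factor(.data$fraction))
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~copy_delta,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "haploid depth (x)", y = "limit of detection (Mb)",
                  colour = "ctDNA fraction")
}
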