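#' Fit negative-binomial and Poisson models to usable bin counts
#'
#' Pools the usable (unmasked) bins of every sample and fits both candidate
#' count distributions: the negative binomial NB(m, r) — variance
#' `m + m^2 / r` — by maximum likelihood with a method-of-moments start, and
#' the Poisson by its mean. The NB mean `m` per bin, together with
#' `bin_size` and `read_length`, fixes the haploid genome coverage
#' `depth = m * read_length / bin_size` the fit corresponds to.
#'
#' If the pooled counts are underdispersed (variance < mean, where the NB
#' family degenerates), the dispersion is capped at a large finite value and
#' the fit flagged.
#'
#' @param table Bin-count tibble with >= 1000 usable bins, or a plain
#'   numeric vector of counts.
#' @param bin_size,read_length Bin width and read length in bp (defaults
#'   10 kb and 100 bp).
#' @return An object of class `nb_fit`: list with `m`, `r`, `bin_size`,
#'   `read_length`, `depth`, `pois_lambda`, log-likelihoods `loglik_nb` and
#'   `loglik_pois`, `n_obs` and flag `underdispersed`.
#' @examples
#' x <- rnbinom(5000, size = 50, mu = 300)
#' fit <- fit_count_model(x)
#' glance(fit)
#' @export
fit_count_model <- function(table, bin_size = 1e4, read_length = 100) {
  x <- if (is.data.frame(table)) {
    as.vector(as.matrix(table[table$mask, bin_samples(table)]))
  } else {
    as.numeric(table)
  }
  if (length(x) < 1000) stop("need >= 1000 usable counts", call. = FALSE)
  if (sd(x) == 0) stop("degenerate input: all counts identical", call. = FALSE)
  m0 <- mean(x)
  v0 <- var(x)
  underdispersed <- v0 <= m0
  if (underdispersed) {
    warning("counts underdispersed relative to Poisson; dispersion capped")
    m <- m0
    r <- 1e8
  } else {
    r0 <- m0^2 / (v0 - m0)
    fit <- tryCatch(
      MASS::fitdistr(x, "negative binomial",
                     start = list(size = r0, mu = m0),
                     method = "L-BFGS-B", lower = c(1e-8, 1e-8)),
      error = function(e) NULL
    )
    if (is.null(fit)) {  # fall back to the moment estimate
      m <- m0
      r <- r0
    } else {
      r <- unname(fit$estimate["size"])
      m <- unname(fit$estimate["mu"])
    }
  }
  structure(
    list(
      m = m, r = r, bin_size = bin_size, read_length = read_length,
      depth = m * read_length / bin_size,
      pois_lambda = m0,
      loglik_nb = sum(dnbinom(x, size = r, mu = m, log = TRUE)),
      loglik_pois = sum(dpois(x, lambda = m0, log = TRUE)),
      n_obs = length(x),
      underdispersed = underdispersed
    ),
    class = "nb_fit"
  )
}

#' Construct a count model without fitting
#'
#' Useful for power calculations at stated parameters.
#'
#' @param m Mean reads per bin (> 0).
#' @param r Negative-binomial dispersion (> 0).
#' @param bin_size,read_length Bin width and read length in bp.
#' @return An `nb_fit` object.
#' @export
nb_model <- function(m, r, bin_size = 1e4, read_length = 100) {
  stopifnot(m > 0, r > 0, bin_size > 0, read_length > 0)
  structure(
    list(m = m, r = r, bin_size = bin_size, read_length = read_length,
         depth = m * read_length / bin_size, pois_lambda = m,
         loglik_nb = NA_real_, loglik_pois = NA_real_, n_obs = 0L,
         underdispersed = FALSE),
    class = "nb_fit"
  )
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf(
    "Negative-binomial bin-count model: m = %.2f, r = %.2f (var = %.2f)\n",
    x$m, x$r, x$m + x$m^2 / x$r))
  cat(sprintf("  bin %d bp, read %d bp -> haploid depth %.3fx\n",
              as.integer(x$bin_size), as.integer(x$read_length), x$depth))
  if (is.finite(x$loglik_nb)) {
    cat(sprintf("  logLik NB %.1f vs Poisson %.1f on %d bins\n",
                x$loglik_nb, x$loglik_pois, x$n_obs))
  }
  invisible(x)
}

#' @rdname fit_count_model
#' @param x An `nb_fit` object.
#' @param ... Unused.
#' @export
tidy.nb_fit <- function(x, ...) {
  tibble::tibble(
    term = c("m", "r", "pois_lambda"),
    estimate = c(x$m, x$r, x$pois_lambda)
  )
}

#' @rdname fit_count_model
#' @export
glance.nb_fit <- function(x, ...) {
  tibble::tibble(
    m = x$m, r = x$r, depth = x$depth,
    loglik_nb = x$loglik_nb, loglik_pois = x$loglik_pois,
    n_obs = x$n_obs, underdispersed = x$underdispersed
  )
}

#' Chi-squared goodness of fit for a fitted count model
#'
#' Partitions the count support into `n_cells` equal-probability cells under
#' the candidate model, and computes the Pearson chi-squared statistic with
#' `n_cells - (number of fitted parameters) - 1` degrees of freedom (2
#' parameters for the negative binomial, 1 for the Poisson).
#'
#' @param table Bin-count tibble or numeric count vector.
#' @param model An `nb_fit` object.
#' @param family `"nb"` or `"poisson"` — which fitted distribution to test.
#' @param n_cells Number of equal-probability cells (>= 5); duplicate cell
#'   boundaries (discrete ties) are merged.
#' @return One-row tibble: `family`, `statistic`, `df`, `p_value`,
#'   `n_cells`.
#' @export
gof_chisq <- function(table, model, family = c("nb", "poisson"), n_cells = 20) {
  family <- match.arg(family)
  stopifnot(inherits(model, "nb_fit"), n_cells >= 5)
  x <- if (is.data.frame(table)) {
    as.vector(as.matrix(table[table$mask, bin_samples(table)]))
  } else {
    as.numeric(table)
  }
  qf <- switch(family,
    nb = function(p) qnbinom(p, size = model$r, mu = model$m),
    poisson = function(p) stats::qpois(p, lambda = model$pois_lambda))
  pf <- switch(family,
    nb = function(q) pnbinom(q, size = model$r, mu = model$m),
    poisson = function(q) ppois(q, lambda = model$pois_lambda))
  edges <- unique(c(-1, qf(seq_len(n_cells - 1) / n_cells), Inf))
  probs <- diff(pf(edges))
  probs[length(probs)] <- 1 - pf(edges[length(edges) - 1])
  expected <- probs * length(x)
  if (length(expected) < 5 || any(expected < 5)) {
    stop("too few observations to populate the goodness-of-fit cells", call. = FALSE)
  }
  obs <- as.vector(table(cut(x, breaks = edges, right = TRUE)))
  stat <- sum((obs - expected)^2 / expected)
  k_params <- if (family == "nb") 2L else 1L
  df <- length(expected) - k_params - 1L
  tibble::tibble(
    family = family, statistic = stat, df = df,
    p_value = pchisq(stat, df = df, lower.tail = FALSE),
    n_cells = length(expected)
  )
}
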