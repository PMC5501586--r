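# Fast Minimum Covariance Determinant estimator (C-step algorithm).
#
# The estimator searches for the h-subset (h > n/2) of observations whose
# classical covariance matrix has minimal determinant; location is the mean
# of that subset and scatter its covariance times a consistency factor.
# Implemented here with the usual large-n strategy: many cheap starts
# (random (p+1)-subsets, two C-steps) on a random subsample, then the best
# candidates refined with C-steps to convergence on the full data. Each
# C-step is a vectorised Mahalanobis ranking, so the estimator stays fast at
# hundreds of thousands of observations.

log_det <- function(S) {
  d <- determinant(S, logarithm = TRUE)
  if (d$sign <= 0) Inf else as.numeric(d$modulus)
}

c_step <- function(X, center, scatter, h) {
  d2 <- mahalanobis(X, center, scatter)
  keep <- order(d2)[seq_len(h)]
  Xs <- X[keep, , drop = FALSE]
  list(center = colMeans(Xs), scatter = cov(Xs), subset = keep)
}

refine_to_convergence <- function(X, center, scatter, h, max_iter = 30) {
  old <- Inf
  for (i in seq_len(max_iter)) {
    st <- c_step(X, center, scatter, h)
    ld <- log_det(st$scatter)
    if (!is.finite(ld) || ld >= old - 1e-10) break
    old <- ld
    center <- st$center
    scatter <- st$scatter
  }
  list(center = center, scatter = scatter, log_det = old)
}

#' Fast Minimum Covariance Determinant location and scatter
#'
#' @param X Numeric matrix (observations x variables).
#' @param support_fraction Fraction h/n of observations the estimate is based
#'   on, in (0.5, 1\].
#' @param n_starts Random elemental starts evaluated on the working
#'   subsample.
#' @param subsample_size Observations used for the cheap search phase; the
#'   best candidates are refined on all of `X`.
#' @param seed Integer seed for the random starts (fixed by default so the
#'   estimate is deterministic for a given input).
#' @return List with `center`, `cov` (consistency-corrected raw MCD
#'   scatter), `dist` (Mahalanobis distance of every observation from the
#'   raw estimates), `h`, and `support` (indices of the optimal h-subset).
#' @export
fast_mcd <- function(X, support_fraction = 0.75, n_starts = 100,
                     subsample_size = 1500, seed = 171) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2 * p) stop("need at least 2 * ncol observations", call. = FALSE)
  if (support_fraction <= 0.5 || support_fraction > 1) {
    stop("support_fraction must lie in (0.5, 1]", call. = FALSE)
  }
  h <- max(floor(support_fraction * n), floor((n + p + 1) / 2))
  withr::with_seed(seed, {
    work_idx <- if (n > subsample_size) sample.int(n, subsample_size) else seq_len(n)
    W <- X[work_idx, , drop = FALSE]
    hw <- max(floor(support_fraction * nrow(W)), floor((nrow(W) + p + 1) / 2))
    cands <- vector("list", n_starts)
    for (s in seq_len(n_starts)) {
      sub <- sample.int(nrow(W), p + 1)
      S0 <- cov(W[sub, , drop = FALSE])
      tries <- 0
      while (!is.finite(log_det(S0)) && tries < 10) {
        sub <- c(sub, sample.int(nrow(W), 1))
        S0 <- cov(W[sub, , drop = FALSE])
        tries <- tries + 1
      }
      if (!is.finite(log_det(S0))) next
      st <- list(center = colMeans(W[sub, , drop = FALSE]), scatter = S0)
      for (it in 1:2) st <- c_step(W, st$center, st$scatter, hw)
      cands[[s]] <- list(center = st$center, scatter = st$scatter,
                         log_det = log_det(st$scatter))
    }
    cands <- Filter(Negate(is.null), cands)
    if (length(cands) == 0) {
      stop("degenerate input: could not find a non-singular covariance subset",
           call. = FALSE)
    }
    ord <- order(vapply(cands, `[[`, numeric(1), "log_det"))
    best <- NULL
    for (i in head(ord, 5)) {
      ref <- refine_to_convergence(X, cands[[i]]$center, cands[[i]]$scatter, h)
      if (is.null(best) || ref$log_det < best$log_det) best <- ref
    }
    if (!is.finite(log_det(best$scatter))) {
      stop("degenerate input: singular MCD scatter matrix", call. = FALSE)
    }
    final <- c_step(X, best$center, best$scatter, h)
    # consistency factor for the raw estimate at normality
    alpha <- h / n
    cc <- alpha / pchisq(qchisq(alpha, df = p), df = p + 2)
    cov_raw <- final$scatter * cc
    if (!is.finite(log_det(cov_raw))) {
      stop("degenerate input: singular MCD scatter matrix", call. = FALSE)
    }
    list(center = final$center, cov = cov_raw,
         dist = sqrt(mahalanobis(X, final$center, cov_raw)),
         h = h, support = final$subset)
  })
}
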