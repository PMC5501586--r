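# Category vectors -> integer copy-state codes (-2..2).
as_category_codes <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  codes <- CATEGORY_CODES[as.character(x)]
  if (anyNA(codes)) stop("unknown copy-state category", call. = FALSE)
  as.integer(codes)
}

#' Modified Hamming distance between two copy profiles
#'
#' Per genomic segment the contribution is 0 for identical copy states, 0.5
#' for adjacent states in the order `DEL2 < DEL1 < NEUTRAL < AMP1 <
#' AMP2PLUS` (e.g. neutral vs one extra copy), and 1 for any larger
#' divergence; the distance is the sum over segments.
#'
#' @param profile_a,profile_b Equal-length category vectors (factors or
#'   characters over [category_levels()], or integer codes -2..2).
#' @return Non-negative numeric distance.
#' @examples
#' mod_hamming(c("NEUTRAL", "AMP1", "DEL1"),
#'             c("NEUTRAL", "AMP2PLUS", "AMP1"))  # 0 + 0.5 + 1
#' @export
mod_hamming <- function(profile_a, profile_b) {
  a <- as_category_codes(profile_a)
  b <- as_category_codes(profile_b)
  if (length(a) != length(b)) stop("profiles must have equal length", call. = FALSE)
  d <- abs(a - b)
  sum(ifelse(d == 0, 0, ifelse(d == 1, 0.5, 1)))
}

#' Pairwise modified-Hamming distance matrix
#'
#' Vectorised over all sample pairs via indicator cross-products, so cohorts
#' of hundreds of samples are handled in milliseconds.
#'
#' @param a Matrix of copy-state codes (samples x segments).
#' @param b Optional second matrix on the same segments (defaults to `a`).
#' @return Numeric matrix `nrow(a)` x `nrow(b)` of distances.
#' @export
hamming_dist_matrix <- function(a, b = a) {
  a <- matrix(as_category_codes(a), nrow = nrow(a), dimnames = dimnames(a))
  b <- matrix(as_category_codes(b), nrow = nrow(b), dimnames = dimnames(b))
  if (ncol(a) != ncol(b)) stop("matrices must share segments", call. = FALSE)
  D <- matrix(0, nrow(a), nrow(b), dimnames = list(rownames(a), rownames(b)))
  for (l1 in -2:2) {
    Ia <- a == l1
    storage.mode(Ia) <- "numeric"
    for (l2 in -2:2) {
      d <- abs(l1 - l2)
      if (d == 0) next
      Ib <- b == l2
      storage.mode(Ib) <- "numeric"
      D <- D + (if (d == 1) 0.5 else 1) * (Ia %*% t(Ib))
    }
  }
  D
}

# Majority vote among the k nearest neighbours; ties broken by smallest
# summed distance to the tied class, then lexicographically.
vote_knn <- function(dist_row, labels, k) {
  ord <- order(dist_row, seq_along(dist_row))  # stable under distance ties
  top <- ord[seq_len(min(k, length(ord)))]
  votes <- table(labels[top])
  winners <- names(votes)[votes == max(votes)]
  if (length(winners) > 1) {
    sums <- vapply(winners, function(cl) sum(dist_row[top][labels[top] == cl]),
                   numeric(1))
    winners <- winners[sums == min(sums)]
    winners <- sort(winners)
  }
  winners[1]
}

#' k-nearest-neighbour classification of copy profiles
#'
#' Each test sample is assigned the majority class among its `k` nearest
#' training samples under the modified Hamming distance; `k` defaults to the
#' floor of the square root of the training-set size.
#'
#' @param train Matrix of training copy-state codes (samples x segments) or
#'   a `copy_profiles` tibble.
#' @param train_labels Tibble `sample_id`, `type` (or a character vector
#'   aligned with the training rows).
#' @param test Matrix / `copy_profiles` of samples to classify.
#' @param k Neighbours to poll (default `floor(sqrt(N))`).
#' @return Tibble `sample_id`, `pred`.
#' @export
knn_classify <- function(train, train_labels, test, k = NULL) {
  trm <- if (inherits(train, "copy_profiles")) profile_matrix(train) else train
  tem <- if (inherits(test, "copy_profiles")) profile_matrix(test) else test
  if (nrow(trm) < 1) stop("empty training set", call. = FALSE)
  y <- align_labels(train_labels, rownames(trm))
  k <- k %||% max(1L, floor(sqrt(nrow(trm))))
  D <- hamming_dist_matrix(tem, trm)
  pred <- vapply(seq_len(nrow(D)), function(i) vote_knn(D[i, ], y, k), character(1))
  tibble::tibble(sample_id = rownames(tem) %||% as.character(seq_len(nrow(tem))),
                 pred = pred)
}

#' Leave-one-out KNN evaluation of a labelled cohort
#'
#' Every sample is classified against all the others (`k` = floor of the
#' square root of the total sample count), which mirrors nearest-neighbour
#' screening of a new sample against a reference cohort.
#'
#' @param profiles `copy_profiles` tibble or code matrix.
#' @param labels Tibble `sample_id`, `type`.
#' @param k Neighbours (default `floor(sqrt(N))` with N the cohort size).
#' @return A `ctdna_report` (see [classifier_report()]) with pooled
#'   leave-one-out predictions.
#' @export
knn_loo <- function(profiles, labels, k = NULL) {
  m <- if (inherits(profiles, "copy_profiles")) profile_matrix(profiles) else profiles
  y <- align_labels(labels, rownames(m))
  n <- nrow(m)
  k <- k %||% max(1L, floor(sqrt(n)))
  D <- hamming_dist_matrix(m)
  diag(D) <- Inf
  pred <- vapply(seq_len(n), function(i) vote_knn(D[i, ], y, k), character(1))
  classifier_report(truth = y, pred = pred,
                    sample_id = rownames(m) %||% as.character(seq_len(n)),
                    method = "knn_loo", k = k)
}

#' Hierarchical clustering of copy profiles
#'
#' Agglomerative clustering (average linkage by default) on modified-Hamming
#' distances, optionally restricted to a discriminative segment subset, with
#' the reordered category matrix ready for heat-map display.
#'
#' @param profiles `copy_profiles` tibble or code matrix (>= 2 samples).
#' @param segments Optional segment-id subset used for the distance (must be
#'   non-empty when given).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return List with `hclust` (the tree), `order` (leaf sample ids) and
#'   `matrix` (codes reordered by leaf order).
#' @export
hcluster_profiles <- function(profiles, segments = NULL, linkage = "average") {
  m <- if (inherits(profiles, "copy_profiles")) profile_matrix(profiles) else profiles
  if (nrow(m) < 2) stop("need >= 2 profiles", call. = FALSE)
  if (!is.null(segments)) {
    keep <- colnames(m) %in% as.character(segments)
    if (!any(keep)) stop("segment subset is empty", call. = FALSE)
    msub <- m[, keep, drop = FALSE]
  } else {
    msub <- m
  }
  D <- hamming_dist_matrix(msub)
  hc <- hclust(as.dist(D), method = linkage)
  list(hclust = hc, order = rownames(m)[hc$order],
       matrix = m[hc$order, , drop = FALSE])
}

align_labels <- function(labels, ids) {
  if (is.data.frame(labels)) {
    if (is.null(ids)) stop("profiles need sample ids to match label table", call. = FALSE)
    y <- labels$type[match(ids, labels$sample_id)]
    if (anyNA(y)) stop("labels missing for some samples", call. = FALSE)
    y
  } else {
    as.character(labels)
  }
}
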