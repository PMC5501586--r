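#' Assemble a classifier report
#'
#' Standard container for pooled out-of-sample predictions: confusion table,
#' per-class TPR/PPV, overall accuracy (with cross-validation dispersion
#' when fold accuracies are supplied), class-probability table and segment
#' importances.
#'
#' @param truth,pred Character vectors of true and predicted classes.
#' @param sample_id Sample identifiers.
#' @param prob Optional tibble of class probabilities (one column per
#'   class), rows aligned with `truth`.
#' @param importances Optional tibble `segment_id`, `importance` in genomic
#'   order.
#' @param fold_accuracy Optional numeric vector of per-fold accuracies.
#' @param method Label for the method that produced the predictions.
#' @param ... Extra scalar fields stored on the report (e.g. `k`, `mtry`).
#' @return Object of class `ctdna_report`.
#' @export
classifier_report <- function(truth, pred, sample_id = NULL, prob = NULL,
                              importances = NULL, fold_accuracy = NULL,
                              method = "classifier", ...) {
  classes <- sort(unique(c(truth, pred)))
  confusion <- table(truth = factor(truth, classes), pred = factor(pred, classes))
  structure(
    list(
      method = method,
      confusion = confusion,
      metrics = perf_metrics(confusion),
      accuracy = sum(diag(confusion)) / sum(confusion),
      accuracy_sd = if (is.null(fold_accuracy)) NA_real_ else sd(fold_accuracy),
      fold_accuracy = fold_accuracy,
      predictions = tibble::tibble(
        sample_id = sample_id %||% as.character(seq_along(truth)),
        truth = truth, pred = pred),
      prob = prob,
      importances = importances,
      extra = list(...)
    ),
    class = "ctdna_report"
  )
}

#' @export
print.ctdna_report <- function(x, ...) {
  cat(sprintf("<ctdna_report: %s> %d samples, %d classes, accuracy %.3f",
              x$method, nrow(x$predictions), nrow(x$confusion), x$accuracy))
  if (!is.na(x$accuracy_sd)) cat(sprintf(" (fold sd %.4f)", x$accuracy_sd))
  cat("\n")
  invisible(x)
}

#' @rdname classifier_report
#' @param x A `ctdna_report`.
#' @export
tidy.ctdna_report <- function(x, ...) x$metrics$per_class

#' @rdname classifier_report
#' @export
glance.ctdna_report <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    accuracy = x$accuracy,
    accuracy_sd = x$accuracy_sd,
    n = nrow(x$predictions),
    n_classes = nrow(x$confusion)
  )
}

#' Per-class classification metrics from a confusion table
#'
#' @param confusion Table / matrix, true class in rows, predicted class in
#'   columns (same class order).
#' @return List with `per_class` (tibble `class`, `n`, `tpr`, `ppv`; PPV is
#'   `NA` for classes never predicted) and `accuracy`.
#' @export
perf_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (sum(confusion) == 0) stop("empty confusion table", call. = FALSE)
  n_true <- rowSums(confusion)
  n_pred <- colSums(confusion)
  correct <- diag(confusion)
  list(
    per_class = tibble::tibble(
      class = rownames(confusion),
      n = as.integer(unname(n_true)),
      tpr = unname(ifelse(n_true > 0, correct / n_true, NA_real_)),
      ppv = unname(ifelse(n_pred > 0, correct / n_pred, NA_real_))
    ),
    accuracy = sum(correct) / sum(confusion)
  )
}

#' Cross-validated random-forest classification of copy profiles
#'
#' Copy states are encoded as ordered integers (-2..2). The number of
#' variables tried at each split is tuned heuristically over
#' `{floor(sqrt(p)/2), floor(sqrt(p)), 2 floor(sqrt(p))}` by stratified
#' k-fold cross-validation; the report pools the held-out predictions and
#' class-vote probabilities of the winning setting, and importances
#' (mean Gini decrease) come from a final forest fit on all samples.
#'
#' @param profiles `copy_profiles` tibble or code matrix.
#' @param labels Tibble `sample_id`, `type` (every class needs at least
#'   `cv_folds` samples for stratification).
#' @param n_trees Trees per forest (default 100).
#' @param cv_folds Cross-validation folds (default 10).
#' @param mtry_grid Optional integer vector overriding the tuning grid.
#' @param seed Integer seed controlling folds and forests.
#' @return A `ctdna_report` with `prob`, `importances` and fold accuracies;
#'   the fitted full-data forest is stored in `extra$forest`.
#' @export
rf_model <- function(profiles, labels, n_trees = 100, cv_folds = 10,
                     mtry_grid = NULL, seed = 1) {
  m <- if (inherits(profiles, "copy_profiles")) profile_matrix(profiles) else profiles
  y <- factor(align_labels(labels, rownames(m)))
  if (nlevels(y) < 2) stop("need >= 2 classes", call. = FALSE)
  if (any(table(y) < cv_folds)) {
    stop("every class needs at least cv_folds samples for stratification",
         call. = FALSE)
  }
  p <- ncol(m)
  mtry_grid <- mtry_grid %||%
    unique(pmax(1, c(floor(sqrt(p) / 2), floor(sqrt(p)), 2 * floor(sqrt(p)))))
  withr::with_seed(seed, {
    fold <- integer(length(y))
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
    }
    cv_one <- function(mtry) {
      pred <- character(length(y))
      prob <- matrix(NA_real_, length(y), nlevels(y),
                     dimnames = list(NULL, levels(y)))
      acc <- numeric(cv_folds)
      for (f in seq_len(cv_folds)) {
        tr <- fold != f
        fit <- randomForest::randomForest(
          x = m[tr, , drop = FALSE], y = y[tr],
          ntree = n_trees, mtry = min(mtry, p))
        prob[!tr, ] <- predict(fit, m[!tr, , drop = FALSE], type = "prob")
        pred[!tr] <- as.character(predict(fit, m[!tr, , drop = FALSE]))
        acc[f] <- mean(pred[!tr] == as.character(y[!tr]))
      }
      list(pred = pred, prob = prob, acc = acc)
    }
    runs <- lapply(mtry_grid, cv_one)
    best <- which.max(vapply(runs, function(r) mean(r$acc), numeric(1)))
    final <- randomForest::randomForest(x = m, y = y, ntree = n_trees,
                                        mtry = min(mtry_grid[best], p),
                                        importance = FALSE)
    imp <- tibble::tibble(
      segment_id = as.integer(colnames(m)),
      importance = as.numeric(final$importance[, "MeanDecreaseGini"]))
    classifier_report(
      truth = as.character(y), pred = runs[[best]]$pred,
      sample_id = rownames(m),
      prob = tibble::as_tibble(runs[[best]]$prob),
      importances = imp,
      fold_accuracy = runs[[best]]$acc,
      method = "random_forest",
      mtry = mtry_grid[best], n_trees = n_trees, cv_folds = cv_folds,
      forest = final
    )
  })
}

#' Most discriminative genomic segments of a classifier report
#'
#' @param report A `ctdna_report` carrying importances.
#' @param top_q Number of segments to keep (default 50); ties and equal
#'   importances resolve by genomic order. Requests beyond the segment count
#'   return all segments with a warning.
#' @return Integer vector of segment ids.
#' @export
important_segments <- function(report, top_q = 50) {
  imp <- report$importances
  if (is.null(imp)) stop("report carries no importances", call. = FALSE)
  if (top_q > nrow(imp)) {
    warning("top_q exceeds segment count; returning all segments")
    top_q <- nrow(imp)
  }
  ord <- order(-imp$importance, seq_len(nrow(imp)))
  sort(imp$segment_id[ord[seq_len(top_q)]])
}

#' One-vs-rest ROC curves and optimal operating points
#'
#' Builds a per-class ROC curve from pooled class probabilities and reports
#' the operating point nearest (in Euclidean distance) to perfect
#' classification — 100% specificity and 100% sensitivity, i.e. the (0, 1)
#' corner — with the TPR and PPV attained there.
#'
#' @param report A `ctdna_report` with a probability table, or a tibble of
#'   class probabilities.
#' @param truth True class labels (taken from the report when omitted).
#' @return List with `roc_points` (tibble `class`, `threshold`, `fpr`,
#'   `tpr`) and `optimal` (tibble `class`, `threshold`, `fpr`, `tpr`, `ppv`,
#'   `auc`).
#' @export
roc_and_optimal <- function(report, truth = NULL) {
  if (inherits(report, "ctdna_report")) {
    prob <- report$prob
    truth <- truth %||% report$predictions$truth
  } else {
    prob <- tibble::as_tibble(report)
  }
  if (is.null(prob)) stop("no class probabilities available", call. = FALSE)
  rs <- rowSums(as.matrix(prob))
  if (any(abs(rs - 1) > 1e-6)) {
    stop("probability rows must sum to 1", call. = FALSE)
  }
  if (length(unique(truth)) < 2) {
    stop("degenerate single-class input", call. = FALSE)
  }
  pts <- list()
  opt <- list()
  for (cl in colnames(prob)) {
    resp <- truth == cl
    if (length(unique(resp)) < 2) next
    ro <- pROC::roc(response = resp, predictor = prob[[cl]],
                    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    fpr <- 1 - ro$specificities
    tpr <- ro$sensitivities
    ord <- order(fpr, tpr)
    pts[[cl]] <- tibble::tibble(class = cl, threshold = ro$thresholds[ord],
                                fpr = fpr[ord], tpr = tpr[ord])
    d <- sqrt(fpr^2 + (1 - tpr)^2)
    i <- which.min(d)
    thr <- ro$thresholds[i]
    call_pos <- prob[[cl]] >= thr
    ppv <- if (any(call_pos)) sum(call_pos & resp) / sum(call_pos) else NA_real_
    opt[[cl]] <- tibble::tibble(class = cl, threshold = thr, fpr = fpr[i],
                                tpr = tpr[i], ppv = ppv,
                                auc = as.numeric(pROC::auc(ro)))
  }
  list(roc_points = dplyr::bind_rows(pts), optimal = dplyr::bind_rows(opt))
}

#' Misclassification similarity between cancer types
#'
#' For an unordered type pair (A, B) with `A_n`, `B_n` samples, `alpha` the
#' fraction of A predicted as B, `beta` the fraction of B predicted as A and
#' `N` the total sample count, the similarity is
#' `S(A, B) = (alpha + beta) * (A_n + B_n) / N` — symmetric, zero exactly
#' when no cross-misclassification occurs. Types are ordered by average-
#' linkage clustering on the dissimilarity `max(S) - S`, and the exported
#' heat-map matrix has correct classifications (the diagonal) set to 0.
#'
#' @param confusion Confusion table/matrix (truth x predicted) or a
#'   `ctdna_report`.
#' @return List with `pairs` (tibble `type_a`, `type_b`, `alpha`, `beta`,
#'   `a_n`, `b_n`, `s`), `matrix` (symmetric S matrix, zero diagonal) and
#'   `type_order` (clustered display order).
#' @export
misclass_similarity <- function(confusion) {
  if (inherits(confusion, "ctdna_report")) confusion <- confusion$confusion
  cm <- as.matrix(confusion)
  if (nrow(cm) != ncol(cm) || !identical(rownames(cm), colnames(cm))) {
    stop("confusion must be square with matching class order", call. = FALSE)
  }
  N <- sum(cm)
  if (N == 0) stop("empty confusion table", call. = FALSE)
  types <- rownames(cm)
  n_type <- rowSums(cm)
  S <- matrix(0, length(types), length(types), dimnames = list(types, types))
  pairs <- list()
  for (i in seq_along(types)) {
    for (j in seq_along(types)) {
      if (j <= i) next
      alpha <- if (n_type[i] > 0) unname(cm[i, j] / n_type[i]) else 0
      beta <- if (n_type[j] > 0) unname(cm[j, i] / n_type[j]) else 0
      s <- unname((alpha + beta) * (n_type[i] + n_type[j]) / N)
      S[i, j] <- S[j, i] <- s
      pairs[[length(pairs) + 1]] <- tibble::tibble(
        type_a = types[i], type_b = types[j], alpha = alpha, beta = beta,
        a_n = as.integer(n_type[i]), b_n = as.integer(n_type[j]), s = s)
    }
  }
  type_order <- if (length(types) > 2) {
    hc <- hclust(as.dist(max(S) - S), method = "average")
    types[hc$order]
  } else {
    types
  }
  list(pairs = dplyr::bind_rows(pairs), matrix = S, type_order = type_order)
}

#' Plot a classifier report
#'
#' Confusion heat map of pooled out-of-sample predictions.
#'
#' @param object A `ctdna_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ctdna_report <- function(object, ...) {
  df <- tibble::as_tibble(as.table(object$confusion))
  names(df) <- c("truth", "pred", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$pred,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "true type", y = "predicted type",
                  title = sprintf("%s — accuracy %.3f", object$method,
                                  object$accuracy)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
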