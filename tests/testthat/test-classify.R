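test_that("modified Hamming distance follows the adjacency rule", {
  expect_equal(mod_hamming(c("NEUTRAL", "AMP1", "DEL1"),
                           c("NEUTRAL", "AMP2PLUS", "AMP1")), 1.5)
  expect_equal(mod_hamming(rep("AMP1", 4), rep("AMP1", 4)), 0)
  set.seed(71)
  lv <- category_levels()
  for (i in 1:20) {
    a <- sample(lv, 12, replace = TRUE)
    b <- sample(lv, 12, replace = TRUE)
    expect_equal(mod_hamming(a, b), mod_hamming(b, a))
    expect_gte(mod_hamming(a, b), 0)
    expect_lte(mod_hamming(a, b), 12)
  }
  expect_error(mod_hamming(lv[1:3], lv[1:2]), "equal length")
  expect_error(mod_hamming("NOPE", "DEL1"), "unknown")
})

test_that("per-segment distance satisfies the metric axioms exhaustively", {
  lv <- category_levels()
  for (a in lv) for (b in lv) for (c in lv) {
    dab <- mod_hamming(a, b)
    expect_equal(dab == 0, a == b)
    expect_equal(dab, mod_hamming(b, a))
    expect_lte(dab, mod_hamming(a, c) + mod_hamming(c, b))
  }
})

test_that("the distance matrix equals elementwise mod_hamming", {
  set.seed(72)
  m <- matrix(sample(-2:2, 6 * 9, replace = TRUE), 6, 9,
              dimnames = list(paste0("s", 1:6), NULL))
  D <- hamming_dist_matrix(m)
  for (i in 1:6) for (j in 1:6) {
    expect_equal(D[i, j], mod_hamming(m[i, ], m[j, ]))
  }
})

test_that("KNN votes its nearest neighbours and defaults k to floor(sqrt(N))", {
  # test sample identical to one training sample, all others maximally far
  train <- rbind(a = rep(2L, 5), b = rep(-2L, 5), c = rep(-2L, 5))
  labels <- tibble::tibble(sample_id = c("a", "b", "c"),
                           type = c("T", "U", "U"))
  test <- matrix(rep(2L, 5), 1, dimnames = list("x", NULL))
  expect_equal(knn_classify(train, labels, test, k = 1)$pred, "T")
  # default k = floor(sqrt(N)): 2 types + normal at 50 each -> N = 150
  coh <- build_separable_cohort(n_types = 2, n_per_type = 50,
                                grid_size = 100e6, seed = 4)
  rep100 <- knn_loo(coh$profiles, coh$labels)
  expect_equal(rep100$extra$k, floor(sqrt(150)))
  expect_error(knn_classify(train[0, ], labels, test), "empty")
})

test_that("pooled leave-one-out predictions cover each sample exactly once", {
  coh <- build_separable_cohort(n_types = 3, n_per_type = 15,
                                grid_size = 100e6, seed = 5)
  rep <- knn_loo(coh$profiles, coh$labels)
  expect_setequal(rep$predictions$sample_id, coh$labels$sample_id)
  expect_equal(nrow(rep$predictions), nrow(coh$labels))
  expect_gte(rep$accuracy, 0.95)
})

test_that("hierarchical clustering separates blocks and is order-invariant", {
  m <- rbind(matrix(2L, 4, 8), matrix(-2L, 4, 8))
  rownames(m) <- paste0("s", 1:8)
  hc <- hcluster_profiles(m)
  ord <- hc$order
  blockA <- which(ord %in% paste0("s", 1:4))
  expect_true(all(diff(blockA) == 1))  # contiguous block
  expect_equal(hc$hclust$height[1], 0)  # identical profiles merge first
  perm <- sample(8)
  hc2 <- hcluster_profiles(m[perm, ])
  expect_setequal(hc2$order, hc$order)
  expect_error(hcluster_profiles(m, segments = 999), "empty")
  expect_error(hcluster_profiles(m[1, , drop = FALSE]), ">= 2")
})

test_that("per-class metrics follow the confusion-table arithmetic", {
  # pos: TP = 8, FN = 2; neg: FP = 1, TN = 9
  cm <- matrix(c(8, 2, 1, 9), 2, 2, byrow = TRUE,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  pm <- perf_metrics(cm)
  expect_equal(pm$per_class$tpr[1], 0.8)
  expect_equal(pm$per_class$ppv[1], 8 / 9)
  expect_equal(pm$accuracy, 17 / 20)
  # class never predicted -> PPV is NA
  cm2 <- matrix(c(0, 5, 0, 5), 2, 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("A", "B")))
  expect_true(is.na(perf_metrics(cm2)$per_class$ppv[1]))
  # perfect classifier
  cm3 <- diag(c(4, 6))
  dimnames(cm3) <- list(c("A", "B"), c("A", "B"))
  pm3 <- perf_metrics(cm3)
  expect_true(all(pm3$per_class$tpr == 1, pm3$per_class$ppv == 1))
  expect_equal(pm3$accuracy, 1)
})

test_that("misclassification similarity matches hand computation", {
  cm <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cm["A", "A"] <- 8; cm["A", "B"] <- 2        # alpha = 0.2
  cm["B", "B"] <- 9; cm["B", "A"] <- 1        # beta = 0.1
  cm["C", "C"] <- 80
  ms <- misclass_similarity(cm)
  sAB <- ms$pairs$s[ms$pairs$type_a == "A" & ms$pairs$type_b == "B"]
  expect_equal(sAB, (0.2 + 0.1) * (10 + 10) / 100)
  expect_equal(ms$matrix["A", "B"], ms$matrix["B", "A"])
  expect_true(all(diag(ms$matrix) == 0))
  # S = 0 iff no cross errors
  expect_equal(ms$matrix["A", "C"], 0)
  expect_equal(ms$matrix["B", "C"], 0)
  expect_gt(ms$matrix["A", "B"], 0)
})

test_that("ROC optimal point is perfect for perfect probabilities", {
  truth <- rep(c("A", "B"), each = 20)
  prob <- tibble::tibble(A = rep(c(0.99, 0.01), each = 20),
                         B = rep(c(0.01, 0.99), each = 20))
  ro <- roc_and_optimal(prob, truth)
  optA <- ro$optimal[ro$optimal$class == "A", ]
  expect_equal(optA$fpr, 0)
  expect_equal(optA$tpr, 1)
  expect_equal(optA$ppv, 1)
  expect_equal(optA$auc, 1)
  # curves span (0,0) to (1,1)
  ptsA <- ro$roc_points[ro$roc_points$class == "A", ]
  expect_equal(c(ptsA$fpr[1], ptsA$tpr[1]), c(0, 0))
  expect_equal(c(ptsA$fpr[nrow(ptsA)], ptsA$tpr[nrow(ptsA)]), c(1, 1))
  expect_true(all(diff(ptsA$tpr) >= 0))
  bad <- tibble::tibble(A = c(0.9, 0.8), B = c(0.3, 0.2))
  expect_error(roc_and_optimal(bad, c("A", "B")), "sum to 1")
  expect_error(roc_and_optimal(prob, rep("A", 40)), "single-class")
})

test_that("label-independent probabilities give chance-level AUC", {
  set.seed(73)
  truth <- sample(c("A", "B"), 400, replace = TRUE)
  pa <- runif(400)
  ro <- roc_and_optimal(tibble::tibble(A = pa, B = 1 - pa), truth)
  expect_lt(abs(ro$optimal$auc[ro$optimal$class == "A"] - 0.5), 0.1)
})

test_that("random forest separates a separable cohort and tunes mtry", {
  coh <- build_separable_cohort(n_types = 3, n_per_type = 16,
                                grid_size = 100e6, seed = 6)
  rep <- rf_model(coh$profiles, coh$labels, cv_folds = 4, seed = 7)
  expect_gte(rep$accuracy, 0.95)
  expect_equal(sort(rep$predictions$sample_id), sort(coh$labels$sample_id))
  expect_false(anyNA(rep$prob))
  expect_equal(length(rep$fold_accuracy), 4)
  expect_error(rf_model(coh$profiles, coh$labels, cv_folds = 20), "cv_folds")
})

test_that("important segments are importance-ranked with genomic tie-breaks", {
  rep <- list(importances = tibble::tibble(segment_id = 1:6,
                                           importance = c(1, 5, 5, 0, 2, 0)))
  class(rep) <- "ctdna_report"
  expect_equal(important_segments(rep, 3), c(2, 3, 5))
  expect_equal(important_segments(rep, 6), 1:6)
  expect_warning(all6 <- important_segments(rep, 10), "top_q")
  expect_equal(all6, 1:6)
  # equal importances: first q in genomic order
  rep$importances$importance <- rep(1, 6)
  expect_equal(important_segments(rep, 2), c(1, 2))
})
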