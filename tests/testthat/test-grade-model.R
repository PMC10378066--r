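# build a small harmonized_dataset by hand for model tests
toy_hd <- function(x, outcome, source = "study") {
  ids <- sprintf("t%02d", seq_len(nrow(x)))
  rownames(x) <- ids
  structure(list(matrix = x,
                 source = setNames(rep(source, nrow(x)), ids),
                 outcome = setNames(outcome, ids),
                 imputed = matrix(FALSE, nrow(x), ncol(x),
                                  dimnames = dimnames(x)),
                 fits = list()),
            class = "harmonized_dataset")
}

signal_hd <- function(n = 44, p = 6, sep = 2, seed = 1) {
  set.seed(seed)
  y <- rep(c("LG", "HG"), length.out = n)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, c(paste0("g", 1:(p - 2), "_T"),
                                      "h1_TA", "h2_TA")))
  x[y == "HG", 1] <- x[y == "HG", 1] + sep
  toy_hd(x, y)
}

test_that("rank-based AUC matches the U-statistic oracle", {
  set.seed(71)
  for (i in 1:25) {
    n <- sample(8:40, 1)
    labels <- sample(c("HG", "LG"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("HG", "LG")
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # with ties
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
  }
  expect_equal(roc_auc(c(1, 2, 3, 4), c("LG", "LG", "HG", "HG")), 1)
  expect_equal(roc_auc(rep(0.3, 6), rep(c("LG", "HG"), 3)), 0.5)
  expect_lt(roc_auc(c(4, 3, 2, 1), c("LG", "LG", "HG", "HG")), 0.5)
  expect_error(roc_auc(1:3, c("LG", "LG", "LG")), "both classes")
})

test_that("Fisher confusion p matches the worked example and symmetries", {
  p <- fisher_confusion(tp = 4, fp = 2, tn = 8, fn = 0)
  expect_equal(p, 0.014985, tolerance = 1e-4)
  expect_equal(fisher_confusion(2, 5, 5, 2), 1)
  expect_equal(fisher_confusion(8, 2, 4, 0), fisher_confusion(4, 0, 8, 2))
  expect_error(fisher_confusion(0, 0, 0, 0), "total")
})

test_that("Fisher confusion matches hypergeometric enumeration", {
  set.seed(73)
  for (i in 1:40) {
    counts <- as.integer(rmultinom(1, sample(4:40, 1), rep(0.25, 4)))
    if (sum(counts) < 1) next
    expect_equal(fisher_confusion(counts[1], counts[2], counts[3], counts[4]),
                 oracle_fisher_p(counts[1], counts[2], counts[3], counts[4]),
                 tolerance = 1e-9)
  }
})

test_that("confusion metrics reproduce the published worked example", {
  m <- confusion_metrics(tp = 4, fp = 2, tn = 8, fn = 0)
  expect_equal(round(100 * m$accuracy, 1), 85.7)
  expect_equal(round(100 * m$precision, 1), 66.7)
  expect_equal(m$recall, 1)
  expect_equal(100 * m$f1, 80)
  expect_equal(100 * m$specificity, 80)
})

test_that("confusion-metric identities hold over random tables", {
  set.seed(77)
  for (i in 1:50) {
    cts <- as.integer(rmultinom(1, sample(1:60, 1), rep(0.25, 4)))
    m <- confusion_metrics(cts[1], cts[2], cts[3], cts[4])
    tp <- cts[1]; fp <- cts[2]; tn <- cts[3]; fn <- cts[4]
    if (tp + fn > 0) expect_equal(m$recall, tp / (tp + fn))
    expect_identical(m$recall, m$sensitivity)
    if (tn + fp > 0) expect_equal(m$specificity, tn / (tn + fp))
    if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp))
    if (!is.na(m$f1)) {
      expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
    }
    expect_equal(m$accuracy, (tp + tn) / sum(cts))
  }
})

test_that("training selects by CV AUC and is deterministic under a seed", {
  hd <- signal_hd(seed = 79)
  m1 <- train_grade_classifier(hd, feature_set = "all", seed = 5,
                               learner_menu = c("ridge", "knn"))
  m2 <- train_grade_classifier(hd, feature_set = "all", seed = 5,
                               learner_menu = c("ridge", "knn"))
  expect_identical(m1$report, m2$report)
  expect_identical(m1$threshold, m2$threshold)
  expect_equal(m1$learner,
               m1$report$learner[which.max(m1$report$cv_auc)])
  expect_gte(max(m1$report$cv_auc), 0.85)  # strong injected signal
})

test_that("permuted labels give chance-level CV AUC", {
  hd <- signal_hd(seed = 83)
  set.seed(83)
  hd$outcome[] <- sample(hd$outcome)
  m <- train_grade_classifier(hd, feature_set = "all", seed = 7,
                              learner_menu = "ridge")
  expect_gt(m$report$cv_auc, 0.5 - 0.15)
  expect_lt(m$report$cv_auc, 0.5 + 0.15)
})

test_that("single-class training is rejected", {
  hd <- signal_hd()
  hd$outcome[] <- "LG"
  expect_error(train_grade_classifier(hd, "all", seed = 1), "both classes")
})

test_that("evaluation freezes the threshold and reports exact counts", {
  hd <- signal_hd(seed = 87)
  m <- train_grade_classifier(hd, feature_set = "all", seed = 3,
                              learner_menu = "ridge")
  test <- signal_hd(n = 20, seed = 88)
  e1 <- evaluate_on_test(m, test)
  e2 <- evaluate_on_test(m, test)
  expect_identical(e1[c("tp", "fp", "tn", "fn")],
                   e2[c("tp", "fp", "tn", "fn")])
  expect_equal(e1$tp + e1$fp + e1$tn + e1$fn, 20)
  expect_identical(e1$threshold, m$threshold)
  # perfectly separated scores give accuracy 1 and AUC 1 for any threshold
  # inside the gap
  sep <- toy_hd(matrix(c(rep(0, 5), rep(1, 5)), ncol = 1,
                       dimnames = list(NULL, "f_T")),
                rep(c("LG", "HG"), each = 5))
  mk <- train_grade_classifier(sep, feature_set = "f_T", seed = 1,
                               learner_menu = "knn", k = 5)
  ev <- evaluate_on_test(mk, sep)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$auc, 1)
})

test_that("unseen feature names are rejected at prediction", {
  hd <- signal_hd(seed = 91)
  m <- train_grade_classifier(hd, feature_set = "all", seed = 2,
                              learner_menu = "ridge")
  test <- hd
  colnames(test$matrix)[1] <- "renamed"
  colnames(test$imputed)[1] <- "renamed"
  expect_error(evaluate_on_test(m, test), "unseen")
})
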