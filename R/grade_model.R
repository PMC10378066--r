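# Low- vs high-grade classification: seeded stratified 5-fold CV model
# selection optimising ROC AUC, a training-derived decision threshold,
# and held-out evaluation with confusion-matrix inference.
#
# The positive class is high grade throughout.

#' Rank-based ROC AUC
#'
#' Tie-corrected area under the ROC curve, computed as the normalised
#' Mann-Whitney U statistic: with mean ranks r of the scores,
#' AUC = (sum of positive-class ranks - n1(n1+1)/2) / (n1 * n0).
#'
#' @param scores numeric classification scores (higher = more positive).
#' @param labels class labels.
#' @param positive the positive-class label.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels, positive = "HG") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fisher's exact test of a confusion matrix
#'
#' Two-sided exact p for the 2x2 table [[tp, fn], [fp, tn]] under fixed
#' margins, two-sidedness by the minimum-likelihood convention (sum of
#' hypergeometric probabilities no larger than the observed table's).
#'
#' @param tp,fp,tn,fn nonnegative confusion counts, total >= 1.
#' @return Two-sided p-value.
#' @export
fisher_confusion <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || sum(counts) < 1) {
    stop("counts must be nonnegative with a positive total")
  }
  stats::fisher.test(matrix(c(tp, fn, fp, tn), nrow = 2, byrow = TRUE))$p.value
}

#' Metrics derived from confusion counts
#'
#' @param tp,fp,tn,fn confusion counts (positive class = high grade).
#' @return List: accuracy, precision, recall, sensitivity, specificity, f1
#'   (proportions in [0, 1]; NA where the denominator is zero).
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  list(accuracy = div(tp + tn, tp + fp + tn + fn),
       precision = precision, recall = recall, sensitivity = recall,
       specificity = div(tn, tn + fp), f1 = f1)
}

# --- learners ----------------------------------------------------------
# each learner is fit(x, y01, seed) -> model ; score(model, x) -> P(HG)

.learners <- list(
  ridge = list(
    fit = function(x, y, seed) {
      set.seed(seed)
      glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                     lambda = c(1, 0.3, 0.1, 0.03))
    },
    score = function(m, x) {
      as.numeric(stats::predict(m, newx = x, s = 0.1, type = "response"))
    }),
  rf = list(
    fit = function(x, y, seed) {
      ranger::ranger(x = as.data.frame(x), y = factor(y, levels = c(0, 1)),
                     probability = TRUE, num.trees = 500, seed = seed,
                     num.threads = 1)
    },
    score = function(m, x) {
      stats::predict(m, data = as.data.frame(x),
                     num.threads = 1)$predictions[, "1"]
    }),
  gbt = list(
    fit = function(x, y, seed) {
      set.seed(seed)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 2,
                      eta = 0.1, nthread = 1, seed = seed),
        data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
        nrounds = 100, verbose = 0)
    },
    score = function(m, x) {
      as.numeric(stats::predict(m, xgboost::xgb.DMatrix(x, nthread = 1)))
    }),
  knn = list(
    fit = function(x, y, seed) list(x = x, y = y, k = 5),
    score = function(m, x) {
      k <- min(m$k, nrow(m$x))
      pr <- class::knn(train = m$x, test = x,
                       cl = factor(m$y, levels = c(0, 1)), k = k, prob = TRUE)
      p_win <- attr(pr, "prob")
      ifelse(pr == "1", p_win, 1 - p_win)
    })
)

# seeded stratified fold assignment: within each class, shuffle and deal
# round-robin into k folds
.stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# decision threshold maximising F1 over scores; candidates are midpoints
# between adjacent distinct scores plus the extremes
.max_f1_threshold <- function(scores, y01) {
  s <- sort(unique(scores))
  cand <- if (length(s) > 1L) {
    c(min(s) - 1e-6, (utils::head(s, -1) + utils::tail(s, -1)) / 2,
      max(s) + 1e-6)
  } else s
  f1 <- vapply(cand, function(th) {
    pred <- scores >= th
    tp <- sum(pred & y01 == 1); fp <- sum(pred & y01 == 0)
    fn <- sum(!pred & y01 == 1)
    if (tp == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  cand[which.max(f1)]
}

#' Train a grade classifier with cross-validated model selection
#'
#' Every learner in the menu is evaluated by seeded stratified 5-fold
#' cross-validation on the training set, scored by mean per-fold ROC AUC.
#' The best learner is refitted on the full training data; the decision
#' threshold is the cutoff maximising F1 over the selected learner's
#' pooled out-of-fold training predictions, frozen before any test
#' exposure.
#'
#' @param train a `harmonized_dataset` (training rows).
#' @param feature_set "all", "tumour" or "adjacent" (resolved via
#'   [build_feature_sets()]), or a character vector of feature names.
#' @param seed integer seed controlling folds and learner RNG.
#' @param learner_menu subset of c("ridge", "rf", "gbt", "knn").
#' @param k number of CV folds.
#' @return List of class `grade_model`: model, learner, threshold,
#'   features, report (learner x mean CV AUC), seed, positive.
#' @export
train_grade_classifier <- function(train, feature_set = "all", seed = 1L,
                                   learner_menu = c("ridge", "rf", "gbt",
                                                    "knn"),
                                   k = 5L) {
  stopifnot(inherits(train, "harmonized_dataset"))
  learner_menu <- match.arg(learner_menu, names(.learners),
                            several.ok = TRUE)
  features <- if (length(feature_set) == 1L &&
                  feature_set %in% c("all", "tumour", "adjacent")) {
    build_feature_sets(train)[[feature_set]]
  } else feature_set
  x <- train$matrix[, features, drop = FALSE]
  y01 <- as.integer(train$outcome == "HG")
  if (length(unique(y01)) < 2L) stop("training set must contain both classes")
  if (length(y01) != nrow(x)) stop("feature/outcome size mismatch")
  folds <- .stratified_folds(y01, k, derive_seed(seed, 5L))
  oof <- matrix(NA_real_, nrow(x), length(learner_menu),
                dimnames = list(NULL, learner_menu))
  cv_auc <- stats::setNames(numeric(length(learner_menu)), learner_menu)
  for (ln in learner_menu) {
    fold_auc <- numeric(k)
    for (f in seq_len(k)) {
      tr <- folds != f
      m <- .learners[[ln]]$fit(x[tr, , drop = FALSE], y01[tr],
                               derive_seed(seed, 100L + f))
      sc <- .learners[[ln]]$score(m, x[!tr, , drop = FALSE])
      oof[!tr, ln] <- sc
      fold_auc[f] <- if (length(unique(y01[!tr])) < 2L) NA_real_ else
        roc_auc(sc, y01[!tr], positive = 1L)
    }
    cv_auc[ln] <- mean(fold_auc, na.rm = TRUE)
  }
  best <- names(cv_auc)[which.max(cv_auc)]
  final <- .learners[[best]]$fit(x, y01, derive_seed(seed, 6L))
  threshold <- .max_f1_threshold(oof[, best], y01)
  structure(list(model = final, learner = best, threshold = threshold,
                 features = features,
                 report = data.frame(learner = names(cv_auc),
                                     cv_auc = unname(cv_auc),
                                     selected = names(cv_auc) == best,
                                     stringsAsFactors = FALSE),
                 folds = k, seed = as.integer(seed), positive = "HG"),
            class = "grade_model")
}

#' Score new samples with a trained grade model
#'
#' @param object a `grade_model`.
#' @param hd a `harmonized_dataset` with the training features present.
#' @param ... unused.
#' @return Numeric scores (probability of high grade).
#' @export
predict.grade_model <- function(object, hd, ...) {
  unseen <- setdiff(object$features, colnames(hd$matrix))
  if (length(unseen)) {
    stop("unseen feature name(s): ",
         paste(utils::head(unseen, 3), collapse = ", "))
  }
  x <- hd$matrix[, object$features, drop = FALSE]
  .learners[[object$learner]]$score(object$model, x)
}

#' Evaluate a trained grade model on held-out samples
#'
#' Applies the frozen training threshold to the model's test scores,
#' builds the confusion matrix (positive class = high grade), and derives
#' accuracy, precision, recall/sensitivity, specificity, F1, the
#' threshold-free rank-based AUC, and the two-sided Fisher exact p of the
#' confusion table. No refitting occurs.
#'
#' @param model a `grade_model`.
#' @param test a `harmonized_dataset` of held-out samples.
#' @return List of class `model_evaluation`: tp, fp, tn, fn, threshold,
#'   the six metrics, auc, fisher_p, scores.
#' @export
evaluate_on_test <- function(model, test) {
  stopifnot(inherits(model, "grade_model"),
            inherits(test, "harmonized_dataset"))
  if (nrow(test$matrix) == 0L) stop("test set is empty")
  scores <- predict(model, test)
  truth <- test$outcome == model$positive
  pred <- scores >= model$threshold
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
  met <- confusion_metrics(tp, fp, tn, fn)
  auc <- if (length(unique(truth)) < 2L) NA_real_ else
    roc_auc(scores, test$outcome, positive = model$positive)
  structure(c(list(tp = tp, fp = fp, tn = tn, fn = fn,
                   threshold = model$threshold),
              met,
              list(auc = auc, fisher_p = fisher_confusion(tp, fp, tn, fn),
                   scores = scores)),
            class = "model_evaluation")
}
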