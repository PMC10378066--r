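# Cross-platform harmonisation by per-column gamma-CDF transformation,
# dataset merging, and the stratified train/test split.
#
# The idea: each feature column (gene x tissue, or tumour/adjacent ratio)
# is fitted with a gamma distribution within its own source dataset, and
# every value is replaced by the fitted CDF evaluated at that value - the
# expected fraction of the population below it. This yields a common
# [0, 1] scale that is invariant to each platform's multiplicative
# measurement scale, which is what makes merging cohorts measured on
# different scales defensible.

#' Right-shift values to strict positivity
#'
#' Positive-support families (gamma, log-normal) need positive data. If
#' the minimum is already positive nothing changes; otherwise every value
#' is shifted by `epsilon - min(values)` where epsilon is 1e-6 times the
#' data range (or 1e-6 if the range is zero). Ordering is preserved.
#'
#' @param values finite numeric vector.
#' @return List: values (shifted), shift (amount added).
#' @export
right_shift <- function(values) {
  if (length(values) == 0L) stop("empty input")
  if (any(!is.finite(values))) stop("values must be finite")
  mn <- min(values)
  if (mn > 0) return(list(values = values, shift = 0))
  rng <- diff(range(values))
  eps <- 1e-6 * if (rng > 0) rng else 1
  shift <- eps - mn
  list(values = values + shift, shift = shift)
}

.qq_gof <- function(values, theo_q) {
  ct <- suppressWarnings(stats::cor.test(sort(values), theo_q))
  list(r = unname(ct$estimate), p = ct$p.value,
       ci_lo = ct$conf.int[1], ci_hi = ct$conf.int[2])
}

#' Fit a gamma distribution to one feature column
#'
#' Maximum-likelihood gamma fit (method-of-moments fallback on
#' non-convergence, flagged) on right-shifted values, with a Q-Q
#' goodness-of-fit: the Pearson correlation between the sorted values and
#' the fitted gamma quantiles at plotting positions, with its p-value and
#' 95% confidence bounds.
#'
#' @param values numeric vector, n >= 8.
#' @return List of class `distribution_fit`: family, shape_alpha,
#'   scale_beta, shift, gof_r, gof_p, ci_lo, ci_hi, method.
#' @export
fit_gamma_column <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 8L) stop("at least 8 observations required")
  sh <- right_shift(values)
  x <- sh$values
  fit <- tryCatch({
    f <- suppressWarnings(fitdistrplus::fitdist(x, "gamma", method = "mle",
                                                keepdata = FALSE))
    list(shape = unname(f$estimate["shape"]),
         rate = unname(f$estimate["rate"]), method = "mle")
  }, error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$shape) || !is.finite(fit$rate)) {
    m <- mean(x); v <- stats::var(x)
    if (v <= 0) stop("constant column: gamma fit undefined")
    fit <- list(shape = m^2 / v, rate = m / v, method = "moments")
  }
  gof <- .qq_gof(x, stats::qgamma(stats::ppoints(length(x)),
                                  shape = fit$shape, rate = fit$rate))
  structure(list(family = "gamma", shape_alpha = fit$shape,
                 scale_beta = 1 / fit$rate, shift = sh$shift,
                 gof_r = gof$r, gof_p = gof$p,
                 ci_lo = gof$ci_lo, ci_hi = gof$ci_hi,
                 method = fit$method),
            class = "distribution_fit")
}

# fit one candidate family to a (shifted where needed) column and return
# its Q-Q goodness-of-fit correlation, or NULL when the family is not
# applicable to the data
.fit_family_gof <- function(values, family) {
  n <- length(values)
  pp <- stats::ppoints(n)
  tryCatch({
    switch(family,
      normal = {
        f <- suppressWarnings(fitdistrplus::fitdist(values, "norm",
                                                    keepdata = FALSE))
        .qq_gof(values, stats::qnorm(pp, f$estimate["mean"],
                                     f$estimate["sd"]))$r
      },
      lognormal = {
        x <- right_shift(values)$values
        f <- suppressWarnings(fitdistrplus::fitdist(x, "lnorm",
                                                    keepdata = FALSE))
        .qq_gof(x, stats::qlnorm(pp, f$estimate["meanlog"],
                                 f$estimate["sdlog"]))$r
      },
      poisson = {
        if (any(values < 0) || any(values != round(values))) return(NULL)
        lam <- mean(values)
        .qq_gof(values, stats::qpois(pp, lam))$r
      },
      beta = {
        if (any(values <= 0) || any(values >= 1)) return(NULL)
        f <- suppressWarnings(fitdistrplus::fitdist(values, "beta",
                                                    keepdata = FALSE))
        .qq_gof(values, stats::qbeta(pp, f$estimate["shape1"],
                                     f$estimate["shape2"]))$r
      },
      gamma = {
        f <- fit_gamma_column(values)
        f$gof_r
      })
  }, error = function(e) NULL)
}

#' Select the distribution family shared by all columns
#'
#' Fits each of the candidate families (normal, log-normal, Poisson,
#' beta, gamma) to every column, scores each fit by its Q-Q correlation,
#' and returns the family that wins the per-column vote; that single
#' family is then applied uniformly to all columns downstream. Columns
#' where no family can be fitted are flagged and excluded from the vote.
#'
#' @param mat numeric matrix, samples x features (>= 8 rows).
#' @param families candidate family names.
#' @return List: family (winner), votes (named counts), diagnostics
#'   (data.frame column x family of gof_r), failed (flagged columns).
#' @export
select_distribution_family <- function(mat,
                                       families = c("normal", "lognormal",
                                                    "poisson", "beta",
                                                    "gamma")) {
  stopifnot(!is.null(colnames(mat)))
  if (nrow(mat) < 8L) stop("at least 8 observations per column required")
  diag <- matrix(NA_real_, ncol(mat), length(families),
                 dimnames = list(colnames(mat), families))
  for (j in seq_len(ncol(mat))) {
    v <- mat[, j][!is.na(mat[, j])]
    if (length(unique(v)) < 2L) next
    for (f in families) {
      r <- .fit_family_gof(v, f)
      if (!is.null(r)) diag[j, f] <- r
    }
  }
  failed <- rownames(diag)[rowSums(!is.na(diag)) == 0L]
  votable <- diag[rowSums(!is.na(diag)) > 0L, , drop = FALSE]
  if (nrow(votable) == 0L) stop("no column could be fitted by any family")
  best <- apply(votable, 1L, function(r) families[which.max(r)])
  votes <- table(factor(best, levels = families))
  list(family = names(votes)[which.max(votes)],
       votes = c(votes),
       diagnostics = as.data.frame(diag),
       failed = failed)
}

#' CDF-transform values through a fitted distribution
#'
#' Maps each value to the fitted gamma CDF evaluated at (value + shift),
#' yielding the expected population fraction below it - a number in
#' [0, 1]. Missing values are imputed as 0.5 (the median of the
#' transformed scale).
#'
#' @param values numeric vector (may contain NA).
#' @param fit a `distribution_fit` from [fit_gamma_column()].
#' @return Numeric vector in [0, 1] with attribute `imputed` (logical).
#' @export
cdf_transform <- function(values, fit) {
  stopifnot(inherits(fit, "distribution_fit"), fit$family == "gamma")
  imputed <- is.na(values)
  out <- stats::pgamma(values + fit$shift, shape = fit$shape_alpha,
                       scale = fit$scale_beta)
  out[imputed] <- 0.5
  attr(out, "imputed") <- imputed
  out
}

# long (sample_id, grade, gene, tissue, value) -> raw wide feature matrix
# with per-gene tumour, adjacent and raw-ratio columns
.raw_feature_matrix <- function(expression) {
  ids <- unique(expression$sample_id)
  genes <- sort(unique(expression$gene))
  get <- function(tissue) {
    sub <- expression[expression$tissue == tissue, ]
    m <- matrix(NA_real_, length(ids), length(genes),
                dimnames = list(ids, genes))
    m[cbind(match(sub$sample_id, ids), match(sub$gene, genes))] <- sub$value
    m
  }
  t_mat <- get("T"); ta_mat <- get("TA")
  if (all(is.na(ta_mat))) {
    stop("adjacent-tissue block absent: ratio and TA features unavailable")
  }
  ratio <- t_mat / ta_mat
  cols <- c(paste0(genes, "_T"), paste0(genes, "_TA"), paste0(genes, "_ratio"))
  out <- cbind(t_mat, ta_mat, ratio)
  colnames(out) <- cols
  out
}

#' Harmonise one cohort into CDF-transformed features
#'
#' Builds the raw feature matrix (per-gene tumour, adjacent, and raw
#' tumour/adjacent ratio columns), fits a gamma distribution to each
#' column within this source, and CDF-transforms every column to [0, 1].
#' Missing cells become 0.5 and are flagged. Ratios are computed on the
#' raw scale before transformation and transformed as their own columns.
#'
#' @param expression long data.frame: sample_id, grade, gene, tissue, value.
#' @param source label for this dataset ("study" or "tcga").
#' @return List of class `harmonized_dataset`: matrix (samples x features,
#'   values in [0, 1]), source, outcome (LG/HG per sample), imputed
#'   (logical matrix), fits (per-column `distribution_fit`s).
#' @export
harmonize_cohort <- function(expression, source = "study") {
  raw <- .raw_feature_matrix(expression)
  ids <- rownames(raw)
  grade <- expression$grade[match(ids, expression$sample_id)]
  mat <- raw
  imputed <- matrix(FALSE, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  fits <- vector("list", ncol(raw))
  names(fits) <- colnames(raw)
  for (j in seq_len(ncol(raw))) {
    fits[[j]] <- fit_gamma_column(raw[, j])
    tr <- cdf_transform(raw[, j], fits[[j]])
    mat[, j] <- tr
    imputed[, j] <- attr(tr, "imputed")
  }
  structure(list(matrix = mat,
                 source = stats::setNames(rep(source, length(ids)), ids),
                 outcome = stats::setNames(grade, ids),
                 imputed = imputed, fits = fits),
            class = "harmonized_dataset")
}

#' Fitted-parameter table of a harmonised dataset
#'
#' @param hd a `harmonized_dataset`.
#' @return data.frame mirroring the per-column fit diagnostics: column,
#'   family, alpha, beta, shift, gof_r, gof_p, ci_lo, ci_hi, method.
#' @export
fit_parameter_table <- function(hd) {
  stopifnot(inherits(hd, "harmonized_dataset"))
  do.call(rbind, lapply(names(hd$fits), function(cn) {
    f <- hd$fits[[cn]]
    data.frame(column = cn, family = f$family, alpha = f$shape_alpha,
               beta = f$scale_beta, shift = f$shift, gof_r = f$gof_r,
               gof_p = f$gof_p, ci_lo = f$ci_lo, ci_hi = f$ci_hi,
               method = f$method, stringsAsFactors = FALSE)
  }))
}

#' Feature subsets for the three candidate models
#'
#' Returns the feature-name sets for the three models: `all` (tumour +
#' adjacent + ratio columns), `tumour` (tumour columns only), and
#' `adjacent` (adjacent columns only).
#'
#' @param hd a `harmonized_dataset`.
#' @return Named list of character vectors.
#' @export
build_feature_sets <- function(hd) {
  stopifnot(inherits(hd, "harmonized_dataset"))
  cols <- colnames(hd$matrix)
  tum <- grep("_T$", cols, value = TRUE)
  adj <- grep("_TA$", cols, value = TRUE)
  if (!length(tum)) stop("tumour feature block absent")
  if (!length(adj)) stop("adjacent feature block absent")
  list(all = cols, tumour = tum, adjacent = adj)
}

#' Merge two harmonised cohorts and split into train/test
#'
#' The training set takes every consortium (tcga) sample plus
#' `train_study_n` study samples drawn by seeded stratified sampling so
#' that the training outcome distribution is exactly balanced when
#' feasible (nearest-balanced with a warning otherwise); the remaining
#' study samples form the test set.
#'
#' @param study,tcga `harmonized_dataset`s with identical feature names.
#' @param seed integer RNG seed for the stratified draw.
#' @param train_study_n number of study samples moved into training.
#' @return List: merged (`harmonized_dataset`), split (list with
#'   train_ids, test_ids, seed, and outcome/source count tables).
#' @export
merge_and_split <- function(study, tcga, seed = 1L, train_study_n = 22L) {
  stopifnot(inherits(study, "harmonized_dataset"),
            inherits(tcga, "harmonized_dataset"))
  if (!identical(colnames(study$matrix), colnames(tcga$matrix))) {
    stop("feature names differ between sources")
  }
  n_study <- nrow(study$matrix)
  if (n_study < train_study_n) {
    stop("study cohort smaller than the requested training draw")
  }
  study_ids <- paste0("study:", rownames(study$matrix))
  tcga_ids <- paste0("tcga:", rownames(tcga$matrix))
  merged <- structure(list(
    matrix = rbind(study$matrix, tcga$matrix),
    source = stats::setNames(c(study$source, tcga$source),
                             c(study_ids, tcga_ids)),
    outcome = stats::setNames(c(study$outcome, tcga$outcome),
                              c(study_ids, tcga_ids)),
    imputed = rbind(study$imputed, tcga$imputed),
    fits = list(study = study$fits, tcga = tcga$fits)),
    class = "harmonized_dataset")
  rownames(merged$matrix) <- c(study_ids, tcga_ids)
  rownames(merged$imputed) <- c(study_ids, tcga_ids)

  # per-class study draw that balances the training outcome
  classes <- c("LG", "HG")
  tcga_counts <- vapply(classes, function(cl) sum(tcga$outcome == cl),
                        integer(1))
  study_counts <- vapply(classes, function(cl) sum(study$outcome == cl),
                         integer(1))
  target_per_class <- (sum(tcga_counts) + train_study_n) / 2
  want <- target_per_class - tcga_counts
  take <- pmin(pmax(round(want), 0L), study_counts)
  # keep the total draw fixed; redistribute if clipping changed it
  deficit <- train_study_n - sum(take)
  if (deficit != 0L) {
    room <- study_counts - take
    for (cl in order(-room)) {
      adj <- max(min(deficit, room[cl]), -take[cl])
      take[cl] <- take[cl] + adj
      deficit <- deficit - adj
      if (deficit == 0L) break
    }
  }
  train_outcome_target <- tcga_counts + take
  if (length(unique(train_outcome_target)) > 1L) {
    warning("exact outcome balance infeasible; using nearest-balanced split")
  }
  set.seed(derive_seed(seed, 4L))
  picked <- unlist(lapply(seq_along(classes), function(k) {
    pool <- study_ids[study$outcome == classes[k]]
    sample(pool, take[k])
  }))
  train_ids <- c(tcga_ids, sort(picked))
  test_ids <- setdiff(study_ids, picked)
  split <- list(
    train_ids = train_ids, test_ids = test_ids, seed = as.integer(seed),
    train_n = length(train_ids), test_n = length(test_ids),
    train_outcome = table(merged$outcome[train_ids]),
    test_outcome = table(merged$outcome[test_ids]),
    train_source = table(merged$source[train_ids]))
  list(merged = merged, split = split)
}

#' Subset a harmonised dataset by sample ids and/or features
#'
#' @param hd a `harmonized_dataset`.
#' @param ids sample ids to keep (default all).
#' @param features feature names to keep (default all).
#' @return A `harmonized_dataset` restricted to the selection.
#' @export
subset_harmonized <- function(hd, ids = NULL, features = NULL) {
  stopifnot(inherits(hd, "harmonized_dataset"))
  if (is.null(ids)) ids <- rownames(hd$matrix)
  if (is.null(features)) features <- colnames(hd$matrix)
  unseen <- setdiff(features, colnames(hd$matrix))
  if (length(unseen)) {
    stop("unknown feature(s): ", paste(utils::head(unseen, 3), collapse = ", "))
  }
  structure(list(matrix = hd$matrix[ids, features, drop = FALSE],
                 source = hd$source[ids],
                 outcome = hd$outcome[ids],
                 imputed = hd$imputed[ids, features, drop = FALSE],
                 fits = hd$fits),
            class = "harmonized_dataset")
}

#' Compare train and test sets feature by feature
#'
#' Runs the two-sided Mann-Whitney rank-sum test per feature between the
#' training and test rows and reports which features differ at the given
#' level. A split is considered clean when no feature differs.
#'
#' @param merged a merged `harmonized_dataset`.
#' @param split the split list from [merge_and_split()].
#' @param alpha significance level.
#' @return List: table (feature, p, significant), n_significant, clean.
#' @export
compare_split <- function(merged, split, alpha = 0.05) {
  tr <- merged$matrix[split$train_ids, , drop = FALSE]
  te <- merged$matrix[split$test_ids, , drop = FALSE]
  if (nrow(tr) == 0L || nrow(te) == 0L) stop("both sets must be nonempty")
  p <- vapply(colnames(tr), function(cn) {
    unpaired_mannwhitney(tr[, cn], te[, cn])
  }, numeric(1))
  tab <- data.frame(feature = colnames(tr), p = unname(p),
                    significant = unname(p < alpha),
                    stringsAsFactors = FALSE)
  list(table = tab, n_significant = sum(tab$significant),
       clean = !any(tab$significant))
}
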