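test_that("right shift leaves positive data alone and preserves order", {
  rs <- right_shift(c(1, 2, 3))
  expect_equal(rs$shift, 0)
  expect_equal(rs$values, c(1, 2, 3))
  rs2 <- right_shift(c(-2, 0, 5))
  expect_gt(min(rs2$values), 0)
  expect_equal(order(rs2$values), order(c(-2, 0, 5)))
  rs3 <- right_shift(0)
  expect_gt(rs3$values, 0)
  expect_error(right_shift(numeric(0)), "empty")
})

test_that("gamma fitting recovers known parameters within 5%", {
  set.seed(51)
  x <- rgamma(10000, shape = 2, scale = 3)
  f <- fit_gamma_column(x)
  expect_lt(abs(f$shape_alpha - 2) / 2, 0.05)
  expect_lt(abs(f$scale_beta - 3) / 3, 0.05)
  expect_gt(f$gof_r, 0.99)
  expect_true(f$ci_lo <= f$gof_r && f$gof_r <= f$ci_hi)

  y <- rexp(10000)  # gamma with shape 1
  fy <- fit_gamma_column(y)
  expect_lt(abs(fy$shape_alpha - 1), 0.05)

  expect_error(fit_gamma_column(c(1, 2, 3)), "8")
})

test_that("family selection votes for the generating family", {
  set.seed(53)
  gmat <- sapply(1:6, function(j) rgamma(1000, 2, scale = 3))
  colnames(gmat) <- paste0("g", 1:6)
  sel_g <- select_distribution_family(gmat)
  expect_equal(sel_g$family, "gamma")

  nmat <- sapply(1:6, function(j) rnorm(1000))
  colnames(nmat) <- paste0("n", 1:6)
  sel_n <- select_distribution_family(nmat)
  expect_equal(sel_n$family, "normal")

  cmat <- cbind(gmat, const = 1)
  sel_c <- select_distribution_family(cmat)
  expect_equal(sel_c$failed, "const")
  expect_equal(sel_c$family, "gamma")
})

test_that("CDF transform maps to [0,1], is monotone, and imputes 0.5", {
  set.seed(57)
  x <- rgamma(200, 2, scale = 1)
  f <- fit_gamma_column(x)
  tr <- cdf_transform(x, f)
  expect_true(all(tr >= 0 & tr <= 1))
  expect_equal(order(tr), order(x))
  # exponential closed form: alpha=1, beta=1 at ln 2 -> 0.5
  fe <- structure(list(family = "gamma", shape_alpha = 1, scale_beta = 1,
                       shift = 0), class = "distribution_fit")
  expect_equal(cdf_transform(log(2), fe), 0.5, ignore_attr = TRUE)
  expect_equal(cdf_transform(1e-12, fe), 0, tolerance = 1e-10,
               ignore_attr = TRUE)
  tr_na <- cdf_transform(c(1, NA, 2), f)
  expect_equal(tr_na[2], 0.5)
  expect_equal(attr(tr_na, "imputed"), c(FALSE, TRUE, FALSE))
})

test_that("transformed draws from the fitted model are uniform", {
  set.seed(59)
  x <- rgamma(10000, shape = 2.5, scale = 2)
  f <- fit_gamma_column(x)
  u <- cdf_transform(x, f)
  ks <- suppressWarnings(ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("harmonisation is invariant to a global measurement scale", {
  set.seed(61)
  spec <- synthetic_cohort_spec(seed = 61)
  e <- generate_paired_expression(spec)
  h1 <- harmonize_cohort(e)
  e2 <- e; e2$value <- e2$value * 1000
  h2 <- harmonize_cohort(e2)
  expect_lt(mean(abs(h1$matrix - h2$matrix)), 0.01)
})

test_that("feature blocks are assembled per gene with raw-scale ratios", {
  spec <- synthetic_cohort_spec(seed = 63)
  e <- generate_paired_expression(spec)
  h <- harmonize_cohort(e)
  fs <- build_feature_sets(h)
  expect_length(fs$tumour, 15L)
  expect_length(fs$adjacent, 15L)
  expect_length(fs$all, 45L)
  expect_error(harmonize_cohort(e[e$tissue == "T", ]), "adjacent")
})

test_that("missing cells are imputed to exactly 0.5 and flagged", {
  spec <- synthetic_cohort_spec(seed = 65, missing_rate = 0.08)
  e <- generate_paired_expression(spec)
  h <- harmonize_cohort(e)
  expect_true(any(h$imputed))
  expect_true(all(h$matrix[h$imputed] == 0.5))
  expect_false(any(is.na(h$matrix)))
})

test_that("merge and split reproduce the published protocol counts", {
  spec <- synthetic_cohort_spec(seed = 67)
  study <- harmonize_cohort(generate_paired_expression(spec), "study")
  tcga <- harmonize_cohort(generate_tcga_like(spec), "tcga")
  ms <- merge_and_split(study, tcga, seed = 67)
  expect_equal(ms$split$train_n, 44L)
  expect_equal(ms$split$test_n, 14L)
  expect_equal(as.integer(ms$split$train_outcome[c("LG", "HG")]), c(22L, 22L))
  expect_equal(as.integer(ms$split$test_outcome[c("LG", "HG")]), c(10L, 4L))
  expect_equal(as.integer(ms$split$train_source["tcga"]), 22L)
  # determinism
  ms2 <- merge_and_split(study, tcga, seed = 67)
  expect_identical(ms$split, ms2$split)
  # different seed draws a different study subset (almost surely)
  ms3 <- merge_and_split(study, tcga, seed = 68)
  expect_false(identical(sort(ms$split$train_ids), sort(ms3$split$train_ids)))
})

test_that("split comparison flags disjoint features and passes identity", {
  spec <- synthetic_cohort_spec(seed = 69)
  study <- harmonize_cohort(generate_paired_expression(spec), "study")
  tcga <- harmonize_cohort(generate_tcga_like(spec), "tcga")
  ms <- merge_and_split(study, tcga, seed = 69)
  same <- ms$split
  same$test_ids <- same$train_ids
  res_same <- compare_split(ms$merged, same)
  expect_true(all(res_same$table$p == 1))
  # a feature with disjoint train/test ranges is flagged
  rigged <- ms$merged
  rigged$matrix[ms$split$train_ids, 1] <-
    seq(0, 0.4, length.out = ms$split$train_n)
  rigged$matrix[ms$split$test_ids, 1] <-
    seq(0.6, 1, length.out = ms$split$test_n)
  res <- compare_split(rigged, ms$split)
  expect_true(res$table$significant[1])
})
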