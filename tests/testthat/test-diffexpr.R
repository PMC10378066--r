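test_that("fold regulation applies the signed per-pair transform", {
  expect_equal(fold_regulation(c(3, 5), c(3, 5))$mean_fr, 1)
  expect_equal(fold_regulation(c(4, 8), c(1, 2))$mean_fr, 4)
  expect_equal(fold_regulation(c(1, 2), c(4, 8))$mean_fr, -4)
  r <- fold_regulation(c(2, 8), c(1, 2))  # FR 2 and 4
  expect_equal(r$mean_fr, 3)
  expect_true(r$ci95_lo <= r$mean_fr && r$mean_fr <= r$ci95_hi)
  expect_error(fold_regulation(c(1, -1), c(1, 1)), "positive")
  single <- fold_regulation(4, 2)
  expect_true(is.na(single$ci95_lo))
})

test_that("fold regulation is antisymmetric under tissue swap", {
  set.seed(4)
  t_v <- rexp(12); ta_v <- rexp(12)
  a <- fold_regulation(t_v, ta_v)
  b <- fold_regulation(ta_v, t_v)
  expect_equal(a$fr, -b$fr)
})

test_that("paired signed-rank matches spec examples", {
  expect_equal(paired_wilcoxon(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(paired_wilcoxon(1:6 + 0.5, (1:6) * 0.1), 0.03125)
  expect_equal(paired_wilcoxon(1:8 + 0.5, (1:8) * 0.1), 0.0078125)
  expect_true(is.na(paired_wilcoxon(c(1, 2), c(0, 0))))
})

test_that("paired signed-rank matches the 2^n enumeration oracle", {
  set.seed(17)
  for (i in 1:15) {
    n <- sample(4:10, 1)
    t_v <- rnorm(n); ta_v <- rnorm(n)
    expect_equal(paired_wilcoxon(t_v, ta_v),
                 oracle_signed_rank_p(t_v - ta_v), tolerance = 1e-12)
  }
})

test_that("Sidak adjustment is correct, monotone and below Bonferroni", {
  expect_equal(sidak_adjust(0, 7), 0)
  expect_equal(sidak_adjust(0.01, 15), 1 - 0.99^15)
  expect_equal(sidak_adjust(0.3, 1), 0.3)
  expect_equal(sidak_adjust(0.9, 50), 1)
  expect_error(sidak_adjust(0.1, 0), "m")
  ps <- seq(0, 1, by = 0.05)
  for (m in c(2, 15, 40)) {
    adj <- sidak_adjust(ps, m)
    expect_true(all(diff(adj) >= 0))
    expect_true(all(adj >= ps))
    expect_true(all(adj <= pmin(1, m * ps) + 1e-12))
  }
  adj_by_m <- sapply(1:10, function(m) sidak_adjust(0.02, m))
  expect_true(all(diff(adj_by_m) >= 0))
})

test_that("Mann-Whitney matches exact small-sample values", {
  expect_equal(unpaired_mannwhitney(c(5, 5, 5), c(5, 5)), 1)
  expect_equal(unpaired_mannwhitney(1:4, 5:8), 2 / choose(8, 4))
  a <- rnorm(6); b <- rnorm(5)
  expect_equal(unpaired_mannwhitney(a, b), unpaired_mannwhitney(b, a))
  expect_error(unpaired_mannwhitney(numeric(0), 1:3), "nonempty")
})

test_that("candidate screen applies strict dual thresholds", {
  mrna <- data.frame(feature = c("A", "B", "C"),
                     log2_fc = c(log2(3.5), log2(3), -log2(4)),
                     p_adj = c(0.005, 0.005, 0.02))
  prot <- data.frame(feature = c("A", "B", "C"),
                     log2_fc = c(log2(2.5), log2(2.5), -log2(3)),
                     p_adj = c(0.005, 0.005, 0.005))
  res <- screen_candidates(mrna, prot)
  expect_equal(res$selected, "A")        # B fails strict >3-fold, C fails p
  expect_equal(res$venn[["both"]], 1L)
})

test_that("packaged screening fixtures reproduce the published selection", {
  res <- screen_candidates(load_screening_table("mrna"),
                           load_screening_table("protein"))
  expect_equal(res$selected,
               c("CXCL12", "ENPP2", "FBLN5", "FGF2", "LYVE1", "PDGFRB",
                 "SERPINF1", "TIMP2", "TIMP3"))
  expect_length(res$mrna_pass, 21L)
  expect_length(res$protein_pass, 22L)
})

test_that("unmapped protein labels are excluded with a warning", {
  mrna <- data.frame(feature = "A", log2_fc = 2, p_adj = 0.001)
  prot <- data.frame(feature = c("pA", "pX"), log2_fc = c(1.5, 1.5),
                     p_adj = c(0.001, 0.001))
  expect_warning(
    res <- screen_candidates(mrna, prot,
                             mapping = data.frame(protein = "pA", gene = "A")),
    "pX")
  expect_equal(res$selected, "A")
})

test_that("LVI stratification sizes follow the cohort with unknown excluded", {
  co <- load_cohort()
  spec <- synthetic_cohort_spec(seed = 6)
  e <- generate_paired_expression(spec)
  # graft the cohort's sample ids onto the synthetic patients
  map <- setNames(co$sample_id, unique(e$sample_id))
  e$sample_id <- map[e$sample_id]
  res <- stratified_diffexpr(e, co, "lvi")
  expect_equal(res$absent$n_pairs, 28L)
  expect_equal(res$present$n_pairs, 7L)
  expect_true(res$present$testable)
})

test_that("grade-attenuated effects yield fewer significant genes in HG", {
  co <- load_cohort()
  spec <- synthetic_cohort_spec(seed = 19)
  e <- generate_paired_expression(spec)
  # synthetic grades are ordered LG then HG; align cohort ids by grade
  ids <- unique(e$sample_id)
  grade <- e$grade[match(ids, e$sample_id)]
  map <- character(length(ids))
  map[grade == "LG"] <- co$sample_id[co$grade_class == "LG"]
  map[grade == "HG"] <- co$sample_id[co$grade_class == "HG"]
  e$sample_id <- setNames(map, ids)[e$sample_id]
  res <- stratified_diffexpr(e, co, "grade_class")
  n_sig <- function(tab) sum(tab$p_adj < 0.05, na.rm = TRUE)
  expect_gt(n_sig(res$LG$table), n_sig(res$HG$table))
})

test_that("an empty stratum is flagged, not dropped", {
  co <- load_cohort()
  co_lg <- co[co$grade_class == "LG", ]
  spec <- synthetic_cohort_spec(n_study = 26, study_lg = 26, study_hg = 0,
                                seed = 12)
  e <- generate_paired_expression(spec)
  map <- setNames(co_lg$sample_id, unique(e$sample_id))
  e$sample_id <- map[e$sample_id]
  res <- stratified_diffexpr(e, co_lg, "grade_class")
  expect_named(res, "LG")
  expect_true(res$LG$testable)
})

test_that("fold-regulation table adjusts within the tested family", {
  spec <- synthetic_cohort_spec(seed = 14)
  e <- generate_paired_expression(spec)
  tab <- fold_regulation_table(e)
  expect_equal(nrow(tab), 15L)
  expect_true(all(tab$p_adj >= tab$p_raw, na.rm = TRUE))
  expect_true(all(tab$ci95_lo <= tab$mean_fr & tab$mean_fr <= tab$ci95_hi,
                  na.rm = TRUE))
  # family size matters: m = 1 leaves p unadjusted
  tab1 <- fold_regulation_table(e, genes = "IL8", family_size = 1)
  expect_equal(tab1$p_adj, tab1$p_raw)
})
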