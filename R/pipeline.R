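# End-to-end orchestration: simulate/load -> quantify -> differential
# expression -> co-expression -> harmonise -> split -> model -> report.

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run so a run is reproducible
#' from the config alone: the synthetic cohort spec, gene panel and
#' reference genes, statistical thresholds, and the seeds of the split and
#' model stages.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param profiles gene effect profiles.
#' @param cohort_path path to a clinical cohort TSV.
#' @param ref_genes reference genes for qPCR normalisation.
#' @param r_min,alpha_corr strong-correlation screen thresholds.
#' @param train_study_n study samples drawn into training.
#' @param learner_menu learners offered to model selection.
#' @param split_seed,model_seed stage seeds.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = synthetic_cohort_spec(),
                            profiles = default_gene_profiles(),
                            cohort_path = cohort_fixture_path(),
                            ref_genes = c("HPRT1", "POLR2A"),
                            r_min = 0.85, alpha_corr = 0.05,
                            train_study_n = 22L,
                            learner_menu = c("ridge", "rf", "gbt", "knn"),
                            split_seed = NULL, model_seed = NULL) {
  structure(list(spec = spec, profiles = profiles,
                 cohort_path = cohort_path, ref_genes = ref_genes,
                 r_min = r_min, alpha_corr = alpha_corr,
                 train_study_n = as.integer(train_study_n),
                 learner_menu = learner_menu,
                 split_seed = as.integer(split_seed %||% spec$seed),
                 model_seed = as.integer(model_seed %||% spec$seed)),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes every stage on synthetic cohorts generated from the config's
#' spec: cohort summary (from the clinical fixture), synthetic paired
#' expression and Cq generation, qPCR quantification, the per-gene
#' fold-regulation table, strong co-expression screening, per-source
#' gamma-CDF harmonisation, the stratified merge/split with its rank-sum
#' diagnostic, and training/evaluation of the three feature-set models.
#' When `outdir` is given, each stage's table is written beneath it
#' (TSV; train/test matrices as CSV).
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory.
#' @return List with the outputs of every stage.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- load_cohort(config$cohort_path)
  cohort_summary <- summarize_cohort(cohort)

  expr_true <- generate_paired_expression(config$spec, config$profiles)
  cq <- generate_cq_data(expr_true, ref_genes = config$ref_genes,
                         seed = config$spec$seed)
  quantified <- quantify_cq(cq, ref_genes = config$ref_genes)
  quantified$grade <- expr_true$grade[match(quantified$sample_id,
                                            expr_true$sample_id)]

  de_table <- fold_regulation_table(quantified)
  correlations <- spearman_matrix(quantified)
  strong <- strong_correlations(correlations, r_min = config$r_min,
                                alpha = config$alpha_corr)

  tcga <- generate_tcga_like(config$spec, config$profiles)
  h_study <- harmonize_cohort(quantified, source = "study")
  h_tcga <- harmonize_cohort(tcga, source = "tcga")
  ms <- merge_and_split(h_study, h_tcga, seed = config$split_seed,
                        train_study_n = config$train_study_n)
  split_check <- compare_split(ms$merged, ms$split)

  train <- subset_harmonized(ms$merged, ms$split$train_ids)
  test <- subset_harmonized(ms$merged, ms$split$test_ids)
  models <- lapply(c(all = "all", tumour = "tumour", adjacent = "adjacent"),
                   function(fs) {
                     m <- train_grade_classifier(train, feature_set = fs,
                                                 seed = config$model_seed,
                                                 learner_menu = config$learner_menu)
                     list(model = m, evaluation = evaluate_on_test(m, test))
                   })
  metrics <- do.call(rbind, lapply(names(models), function(nm) {
    ev <- models[[nm]]$evaluation
    data.frame(feature_set = nm, tp = ev$tp, fp = ev$fp, tn = ev$tn,
               fn = ev$fn, accuracy = ev$accuracy, precision = ev$precision,
               recall = ev$recall, f1 = ev$f1, specificity = ev$specificity,
               auc = ev$auc, fisher_p = ev$fisher_p,
               stringsAsFactors = FALSE)
  }))

  result <- list(cohort = cohort, cohort_summary = cohort_summary,
                 expression = quantified, de_table = de_table,
                 correlations = correlations, strong_correlations = strong,
                 harmonized = ms$merged, split = ms$split,
                 split_check = split_check, models = models,
                 metrics = metrics, config = config)
  if (!is.null(outdir)) .write_pipeline_outputs(result, outdir)
  result
}

.write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  w(result$de_table, "fold_regulation.tsv")
  w(result$strong_correlations, "strong_correlations.tsv")
  w(result$split_check$table, "split_ranksum.tsv")
  w(result$metrics, "model_metrics.tsv")
  w(fit_parameter_table_merged(result$harmonized), "fit_parameters.tsv")
  tr <- result$harmonized$matrix[result$split$train_ids, , drop = FALSE]
  te <- result$harmonized$matrix[result$split$test_ids, , drop = FALSE]
  add_outcome <- function(m, ids) {
    data.frame(sample_id = ids, outcome = result$harmonized$outcome[ids],
               m, check.names = FALSE)
  }
  utils::write.csv(add_outcome(tr, result$split$train_ids),
                   file.path(outdir, "train.csv"), row.names = FALSE)
  utils::write.csv(add_outcome(te, result$split$test_ids),
                   file.path(outdir, "test.csv"), row.names = FALSE)
  invisible(outdir)
}

# fitted-parameter table for a merged dataset (per-source fit lists)
fit_parameter_table_merged <- function(hd) {
  per_source <- length(hd$fits) &&
    !inherits(hd$fits[[1]], "distribution_fit")
  if (per_source) {
    do.call(rbind, lapply(names(hd$fits), function(src) {
      tab <- fit_parameter_table(
        structure(list(fits = hd$fits[[src]]), class = "harmonized_dataset"))
      cbind(source = src, tab)
    }))
  } else {
    fit_parameter_table(hd)
  }
}
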