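# Synthetic paired-cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes:
# gamma-distributed adjacent-tissue baselines, log-normal patient-level
# tumour/adjacent ratio noise around a gene-specific target fold
# regulation, binary grade labels, and a second cohort on a shifted
# measurement scale standing in for an RNA-seq consortium dataset.

#' Default gene effect profiles for the 15-gene angiogenic factor panel
#'
#' One row per panel gene with its target signed fold regulation
#' (tumour vs adjacent), the standard deviation of the patient-level
#' log-ratio noise, and the gamma baseline for adjacent-tissue expression.
#' The target fold regulations are the panel's published mean effects; the
#' noise and baseline parameters are generator defaults (see the methods
#' vignette for the rationale).
#'
#' @param ratio_dispersion sd of the log-ratio noise, shared across genes.
#' @param baseline_shape,baseline_scale gamma parameters of the
#'   adjacent-tissue expression baseline. The default scale puts
#'   expression around 2e-9 so that an efficiency-2 assay yields Cq values
#'   near 29.
#' @return data.frame with columns gene, target_fr, ratio_dispersion,
#'   baseline_shape, baseline_scale.
#' @export
default_gene_profiles <- function(ratio_dispersion = 0.8,
                                  baseline_shape = 2,
                                  baseline_scale = 1e-9) {
  genes <- c("IL8", "CXCL12", "FGF2", "LEP", "LYVE1", "NRP1", "TIMP2",
             "TIMP3", "CSF3", "ENPP2", "FBLN5", "FST", "PDGFRB", "TEK",
             "SERPINF1")
  target <- c(4.75, -18.21, -7.39, 4.68, -10.98, -3.67, -6.79,
              -14.77, -10.43, -10.10, -8.27, -6.77, -4.50, -5.20,
              -8.68)
  data.frame(gene = genes, target_fr = target,
             ratio_dispersion = ratio_dispersion,
             baseline_shape = baseline_shape,
             baseline_scale = baseline_scale,
             stringsAsFactors = FALSE)
}

#' Specification of a synthetic two-cohort study
#'
#' Defaults mirror the study conditions: a 36-patient qPCR cohort with
#' 26 low-grade and 10 high-grade patients, and a 22-record consortium-like
#' cohort with 6 low-grade and 16 high-grade records measured on a scale
#' 1000-fold larger. `grade_attenuation` shrinks the tumour-tissue
#' log-ratio effect toward zero for high-grade patients (0 = no grade
#' signal, 1 = complete attenuation), giving the grade classifier a
#' documented, learnable signal confined to tumour tissue.
#'
#' @param n_study,study_lg,study_hg study cohort size and grade mix.
#' @param n_tcga,tcga_lg,tcga_hg consortium-like cohort size and grade mix.
#' @param scale_factor_tcga multiplicative measurement-scale offset of the
#'   consortium-like cohort.
#' @param grade_attenuation fraction of the tumour log-ratio effect removed
#'   in high-grade patients.
#' @param missing_rate optional MCAR missingness rate applied to generated
#'   expression values (exercises the imputation path downstream).
#' @param seed integer RNG seed.
#' @return A list of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_study = 36, study_lg = 26, study_hg = 10,
                                  n_tcga = 22, tcga_lg = 6, tcga_hg = 16,
                                  scale_factor_tcga = 1000,
                                  grade_attenuation = 0.7,
                                  missing_rate = 0,
                                  seed = 1L) {
  stopifnot(study_lg + study_hg == n_study, tcga_lg + tcga_hg == n_tcga,
            scale_factor_tcga > 0, grade_attenuation >= 0,
            grade_attenuation <= 1, missing_rate >= 0, missing_rate < 1)
  structure(list(n_study = n_study, study_lg = study_lg, study_hg = study_hg,
                 n_tcga = n_tcga, tcga_lg = tcga_lg, tcga_hg = tcga_hg,
                 scale_factor_tcga = scale_factor_tcga,
                 grade_attenuation = grade_attenuation,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

# mean of the log-ratio distribution such that the expected per-pair fold
# regulation equals the target: for an up-regulated gene E[ratio] = f needs
# mu = log(f) - sd^2/2; for a down-regulated gene E[1/ratio] = |f| needs
# mu = -(log|f| - sd^2/2). A null gene (|f| = 1) gets mu = 0.
.log_ratio_mean <- function(target_fr, dispersion) {
  if (abs(target_fr) == 1) return(0)
  s <- if (target_fr >= 1) 1 else -1
  s * (log(abs(target_fr)) - dispersion^2 / 2)
}

.generate_cohort <- function(n, n_lg, profiles, grade_attenuation,
                             missing_rate, scale = 1, prefix = "S") {
  grade <- c(rep("LG", n_lg), rep("HG", n - n_lg))
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  out <- vector("list", nrow(profiles))
  for (j in seq_len(nrow(profiles))) {
    pr <- profiles[j, ]
    ta <- stats::rgamma(n, shape = pr$baseline_shape,
                        scale = pr$baseline_scale) * scale
    mu <- .log_ratio_mean(pr$target_fr, pr$ratio_dispersion)
    mus <- ifelse(grade == "HG", mu * (1 - grade_attenuation), mu)
    r <- exp(stats::rnorm(n, mean = mus, sd = pr$ratio_dispersion))
    out[[j]] <- data.frame(
      sample_id = rep(ids, 2L),
      grade = rep(grade, 2L),
      gene = pr$gene,
      tissue = rep(c("TA", "T"), each = n),
      value = c(ta, ta * r),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  if (missing_rate > 0) {
    df$value[stats::runif(nrow(df)) < missing_rate] <- NA_real_
  }
  df
}

#' Generate paired tumour/adjacent expression for the study-like cohort
#'
#' For each patient and gene the adjacent-tissue value is drawn from the
#' gene's gamma baseline and the tumour value is the adjacent value times a
#' log-normal ratio whose mean is calibrated so that the expected per-pair
#' fold regulation equals the profile's target. High-grade patients have
#' the tumour effect attenuated by the cohort spec's `grade_attenuation`.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param profiles gene effect profiles, as [default_gene_profiles()].
#' @param genes optional subset of genes to generate.
#' @return Long data.frame: sample_id, grade, gene, tissue (T/TA), value.
#' @export
generate_paired_expression <- function(spec = synthetic_cohort_spec(),
                                       profiles = default_gene_profiles(),
                                       genes = NULL) {
  if (!is.null(genes)) {
    missing <- setdiff(genes, profiles$gene)
    if (length(missing)) {
      stop("no effect profile for gene(s): ", paste(missing, collapse = ", "))
    }
    profiles <- profiles[profiles$gene %in% genes, , drop = FALSE]
  }
  set.seed(derive_seed(spec$seed, 1L))
  .generate_cohort(spec$n_study, spec$study_lg, profiles,
                   spec$grade_attenuation, spec$missing_rate,
                   scale = 1, prefix = "S")
}

#' Generate a consortium-like cohort on a shifted measurement scale
#'
#' Same generative model as [generate_paired_expression()] but with every
#' value multiplied by `scale_factor_tcga` (default 1000), so the two
#' cohorts are not directly mergeable without harmonisation, and with the
#' consortium grade mix (default 6 low-grade / 16 high-grade out of 22).
#'
#' @inheritParams generate_paired_expression
#' @return Long data.frame: sample_id, grade, gene, tissue, value.
#' @export
generate_tcga_like <- function(spec = synthetic_cohort_spec(),
                               profiles = default_gene_profiles(),
                               genes = NULL) {
  if (!is.null(genes)) {
    missing <- setdiff(genes, profiles$gene)
    if (length(missing)) {
      stop("no effect profile for gene(s): ", paste(missing, collapse = ", "))
    }
    profiles <- profiles[profiles$gene %in% genes, , drop = FALSE]
  }
  set.seed(derive_seed(spec$seed, 2L))
  .generate_cohort(spec$n_tcga, spec$tcga_lg, profiles,
                   spec$grade_attenuation, spec$missing_rate,
                   scale = spec$scale_factor_tcga, prefix = "G")
}

#' Generate Cq triplicates from an expression table
#'
#' Inverts the efficiency relation expression = E^-Cq, i.e.
#' Cq = -log(expression) / log(E), and adds independent normal replicate
#' noise to each of three technical replicates. Reference genes are
#' generated per sample with a near-zero between-tissue effect
#' (`ref_tissue_sd` on the log scale) so they are usable for
#' reference-gene normalisation downstream.
#'
#' @param expression long data.frame from [generate_paired_expression()].
#' @param efficiencies named numeric vector of per-gene amplification
#'   efficiencies E (1 < E <= 2); genes without an entry default to 2.
#' @param ref_genes character vector of reference gene names to synthesise.
#' @param replicate_sd sd of replicate noise in Cq units.
#' @param ref_tissue_sd sd of the reference genes' log-scale tissue effect.
#' @param seed integer RNG seed.
#' @return Long data.frame: sample_id, gene, tissue, cq_1..cq_3.
#' @export
generate_cq_data <- function(expression, efficiencies = NULL,
                             ref_genes = c("HPRT1", "POLR2A"),
                             replicate_sd = 0.1, ref_tissue_sd = 0.02,
                             seed = 1L) {
  if (any(is.na(expression$value)) || any(expression$value <= 0)) {
    stop("expression values must be strictly positive to derive Cq")
  }
  set.seed(derive_seed(seed, 3L))
  base <- expression[, c("sample_id", "gene", "tissue", "value")]
  if (length(ref_genes)) {
    ids <- unique(expression$sample_id)
    refs <- lapply(ref_genes, function(g) {
      lvl <- stats::rgamma(length(ids), shape = 2, scale = 1e-9)
      data.frame(
        sample_id = rep(ids, 2L), gene = g,
        tissue = rep(c("TA", "T"), each = length(ids)),
        value = c(lvl, lvl * exp(stats::rnorm(length(ids), 0, ref_tissue_sd))),
        stringsAsFactors = FALSE)
    })
    base <- rbind(base, do.call(rbind, refs))
  }
  eff <- rep(2, nrow(base))
  if (!is.null(efficiencies)) {
    hit <- base$gene %in% names(efficiencies)
    eff[hit] <- efficiencies[base$gene[hit]]
  }
  if (any(eff <= 1 | eff > 2)) stop("efficiencies must satisfy 1 < E <= 2")
  cq <- -log(base$value) / log(eff)
  reps <- matrix(cq, nrow = length(cq), ncol = 3) +
    matrix(stats::rnorm(3 * length(cq), 0, replicate_sd), ncol = 3)
  data.frame(base[, c("sample_id", "gene", "tissue")],
             cq_1 = reps[, 1], cq_2 = reps[, 2], cq_3 = reps[, 3],
             stringsAsFactors = FALSE)
}
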