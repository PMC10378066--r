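# Fold-regulation differential expression: candidate screening, paired and
# unpaired nonparametric tests, Sidak multiplicity correction, and clinical
# stratification.

#' Signed fold regulation of paired tumour/adjacent values
#'
#' Each pair contributes a ratio rho_i = t_i / ta_i, transformed per pair
#' to a signed fold regulation FR_i = rho_i when rho_i >= 1 and -1/rho_i
#' otherwise. The summary effect is the mean of the per-pair FR values with
#' a t-interval 95% CI across pairs. Pairs with a missing member are
#' dropped.
#'
#' @param t_values,ta_values positive paired expression values.
#' @param conf confidence level of the interval.
#' @return List: mean_fr, ci95_lo, ci95_hi (NA with a single pair),
#'   n_pairs, fr (per-pair values).
#' @export
fold_regulation <- function(t_values, ta_values, conf = 0.95) {
  stopifnot(length(t_values) == length(ta_values))
  keep <- !is.na(t_values) & !is.na(ta_values)
  t_values <- t_values[keep]; ta_values <- ta_values[keep]
  if (length(t_values) == 0L) stop("no complete pairs")
  if (any(t_values <= 0) || any(ta_values <= 0)) {
    stop("expression values must be strictly positive")
  }
  fr <- ratio_to_fr(t_values / ta_values)
  n <- length(fr)
  m <- mean(fr)
  if (n >= 2L) {
    half <- stats::qt(1 - (1 - conf) / 2, df = n - 1L) * stats::sd(fr) / sqrt(n)
    ci <- c(m - half, m + half)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  list(mean_fr = m, ci95_lo = ci[1], ci95_hi = ci[2], n_pairs = n, fr = fr)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided matched-pairs signed-rank p-value. Zero differences are
#' uninformative and dropped; if every difference is zero the p-value is 1.
#' With fewer than 3 informative pairs the test is not testable and `NA`
#' is returned. The exact null distribution is used for up to 25
#' informative tie-free pairs, the normal approximation with tie
#' correction otherwise.
#'
#' @param t_values,ta_values paired numeric vectors (pairs with a missing
#'   member are dropped).
#' @return Two-sided p-value, or `NA_real_` when not testable.
#' @export
paired_wilcoxon <- function(t_values, ta_values) {
  stopifnot(length(t_values) == length(ta_values))
  keep <- !is.na(t_values) & !is.na(ta_values)
  d <- t_values[keep] - ta_values[keep]
  if (length(d) == 0L) return(NA_real_)
  if (all(d == 0)) return(1)
  d <- d[d != 0]
  if (length(d) < 3L) return(NA_real_)
  use_exact <- length(d) <= 25L && !any(duplicated(abs(d)))
  suppressWarnings(
    stats::wilcox.test(d, exact = use_exact, correct = FALSE)$p.value
  )
}

#' Bonferroni-Sidak multiplicity adjustment
#'
#' p_adj = 1 - (1 - p)^m for a family of m tests, capped at 1. Computed
#' via `expm1`/`log1p` so that very small p-values stay accurate.
#'
#' @param p_raw raw p-value(s) in [0, 1].
#' @param m family size (>= 1).
#' @return Adjusted p-value(s).
#' @export
sidak_adjust <- function(p_raw, m) {
  if (length(m) != 1L || is.na(m) || m < 1) stop("family size m must be >= 1")
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE)) stop("p values must be in [0, 1]")
  pmin(1, -expm1(m * log1p(-p_raw)))
}

#' Unpaired Mann-Whitney U test
#'
#' Two-sided rank-sum p-value; exact for small tie-free samples, normal
#' approximation with tie correction otherwise.
#'
#' @param group_a,group_b numeric vectors, each nonempty.
#' @return Two-sided p-value.
#' @export
unpaired_mannwhitney <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be nonempty")
  }
  if (all(c(group_a, group_b) == c(group_a, group_b)[1])) return(1)
  exact <- length(group_a) + length(group_b) <= 50L &&
    !any(duplicated(c(group_a, group_b)))
  suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = FALSE)$p.value
  )
}

#' Load a packaged screening table
#'
#' The packaged screening tables are synthetic stand-ins for the
#' consortium differential-expression results that seeded the candidate
#' screen: per-feature log2 fold changes (tumour vs adjacent) with
#' adjusted p-values, constructed so that the screen reproduces the
#' published selection (21 transcripts, 22 proteins, 9 in the
#' intersection).
#'
#' @param layer "mrna" or "protein".
#' @return data.frame: feature, log2_fc, p_adj, layer.
#' @export
load_screening_table <- function(layer = c("mrna", "protein")) {
  layer <- match.arg(layer)
  path <- system.file("extdata",
                      sprintf("screening_%s_synthetic.tsv", layer),
                      package = "ecangio", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Screen candidate genes/proteins from fold-change tables
#'
#' A gene passes the transcript screen when its absolute log2 fold change
#' exceeds log2(3) (strictly more than 3-fold, either direction) with
#' adjusted p < 0.01; a protein passes at strictly more than 2-fold with
#' adjusted p < 0.01. Selected features are the intersection of the two
#' pass lists after mapping protein labels to gene labels.
#'
#' @param mrna data.frame: feature, log2_fc, p_adj.
#' @param protein data.frame: feature, log2_fc, p_adj.
#' @param mapping optional data.frame (protein, gene) translating protein
#'   labels; unmapped protein labels are dropped from the intersection with
#'   a warning. Defaults to the identity mapping.
#' @param fc_mrna,fc_protein fold-change cutoffs (strict).
#' @param alpha adjusted-p cutoff (strict).
#' @return List: selected (sorted gene labels), mrna_pass, protein_pass,
#'   venn (counts: mrna_only, protein_only, both).
#' @export
screen_candidates <- function(mrna, protein, mapping = NULL,
                              fc_mrna = 3, fc_protein = 2, alpha = 0.01) {
  pass <- function(df, fc) {
    df$feature[abs(df$log2_fc) > log2(fc) & df$p_adj < alpha &
                 is.finite(df$log2_fc)]
  }
  mrna_pass <- pass(mrna, fc_mrna)
  protein_pass_raw <- pass(protein, fc_protein)
  if (!is.null(mapping)) {
    idx <- match(protein_pass_raw, mapping$protein)
    if (any(is.na(idx))) {
      warning("unmapped protein label(s) excluded: ",
              paste(protein_pass_raw[is.na(idx)], collapse = ", "))
    }
    protein_pass <- mapping$gene[idx[!is.na(idx)]]
  } else {
    protein_pass <- protein_pass_raw
  }
  selected <- sort(intersect(mrna_pass, protein_pass))
  list(selected = selected,
       mrna_pass = sort(mrna_pass),
       protein_pass = sort(protein_pass),
       venn = c(mrna_only = length(setdiff(mrna_pass, protein_pass)),
                protein_only = length(setdiff(protein_pass, mrna_pass)),
                both = length(selected)))
}

#' Per-gene fold-regulation table with paired tests
#'
#' Mirrors the main differential-expression table: per gene, the mean
#' signed fold regulation with its 95% CI across patients, the paired
#' signed-rank p-value, and the Sidak-adjusted p over the family of genes
#' tested together.
#'
#' @param expression long data.frame: sample_id, gene, tissue (T/TA), value.
#' @param genes genes to test; default all genes present.
#' @param family_size Sidak family size m; defaults to the number of genes
#'   tested.
#' @return data.frame: gene, n_pairs, mean_fr, ci95_lo, ci95_hi, p_raw,
#'   p_adj, testable.
#' @export
fold_regulation_table <- function(expression, genes = NULL,
                                  family_size = NULL) {
  if (is.null(genes)) genes <- sort(unique(expression$gene))
  if (is.null(family_size)) family_size <- length(genes)
  rows <- lapply(genes, function(g) {
    sub <- expression[expression$gene == g, ]
    ids <- unique(sub$sample_id)
    t_sub <- sub[sub$tissue == "T", ]
    ta_sub <- sub[sub$tissue == "TA", ]
    t_w <- t_sub$value[match(ids, t_sub$sample_id)]
    ta_w <- ta_sub$value[match(ids, ta_sub$sample_id)]
    keep <- !is.na(t_w) & !is.na(ta_w)
    if (!any(keep)) {
      return(data.frame(gene = g, n_pairs = 0L, mean_fr = NA_real_,
                        ci95_lo = NA_real_, ci95_hi = NA_real_,
                        p_raw = NA_real_, p_adj = NA_real_, testable = FALSE))
    }
    fr <- fold_regulation(t_w[keep], ta_w[keep])
    p <- paired_wilcoxon(t_w[keep], ta_w[keep])
    data.frame(gene = g, n_pairs = fr$n_pairs, mean_fr = fr$mean_fr,
               ci95_lo = fr$ci95_lo, ci95_hi = fr$ci95_hi,
               p_raw = p, p_adj = if (is.na(p)) NA_real_ else
                 sidak_adjust(p, family_size),
               testable = !is.na(p), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Stratified fold-regulation analysis
#'
#' Splits the cohort by a clinical stratifier and runs the per-gene
#' fold-regulation analysis within each stratum, with the Sidak family
#' adjusted within stratum. FIGO is dichotomised as IA vs IB-IV; records
#' with unknown LVI are excluded from the LVI stratification only. Strata
#' with fewer than 3 pairs are reported but flagged not testable.
#'
#' @param expression long expression data.frame (sample_id, gene, tissue,
#'   value); sample ids must be a subset of the cohort's.
#' @param cohort data.frame from [load_cohort()], or any data.frame with
#'   sample_id plus the stratifier columns.
#' @param stratifier one of grade_class, figo_group, dmi, lvi, menopause.
#' @return Named list of per-stratum results, each a list with `n_pairs`,
#'   `testable`, and `table` (the fold-regulation table, NULL when the
#'   stratum is empty).
#' @export
stratified_diffexpr <- function(expression, cohort,
                                stratifier = c("grade_class", "figo_group",
                                               "dmi", "lvi", "menopause")) {
  stratifier <- match.arg(stratifier)
  extra <- setdiff(unique(expression$sample_id), cohort$sample_id)
  if (length(extra)) {
    stop("expression contains sample ids absent from the cohort: ",
         paste(utils::head(extra, 3), collapse = ", "))
  }
  groups <- switch(stratifier,
    grade_class = split(cohort$sample_id, cohort$grade_class),
    menopause = split(cohort$sample_id, cohort$menopause),
    figo_group = split(cohort$sample_id,
                       ifelse(cohort$figo == "IA", "IA", "IB-IV")),
    dmi = split(cohort$sample_id,
                ifelse(cohort$myometrial_invasion == "gt50",
                       "present", "absent")),
    lvi = {
      known <- cohort[cohort$lvi != "unknown", ]
      split(known$sample_id,
            ifelse(known$lvi == "yes", "present", "absent"))
    })
  lapply(groups, function(ids) {
    sub <- expression[expression$sample_id %in% ids, ]
    n_pairs <- length(intersect(sub$sample_id[sub$tissue == "T"],
                                sub$sample_id[sub$tissue == "TA"]))
    if (nrow(sub) == 0L) {
      return(list(n_pairs = 0L, testable = FALSE, table = NULL))
    }
    list(n_pairs = n_pairs, testable = n_pairs >= 3L,
         table = fold_regulation_table(sub))
  })
}
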