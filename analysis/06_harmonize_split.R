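#!/usr/bin/env Rscript
# Stage 6: gamma-CDF harmonisation of the study cohort and the
# consortium-like cohort (fitted per column within each source), merge,
# stratified balanced train/test split, and the per-feature rank-sum
# split diagnostic. Requires stage 3 output.

suppressPackageStartupMessages(library(ecangio))
seed <- as.integer(Sys.getenv("ECANGIO_SEED", "1"))
expr <- read.delim("results/normalized_expression.tsv")
spec <- synthetic_cohort_spec(seed = seed)

# family vote on the study cohort's tumour columns: which standard
# distribution fits most columns best
ids <- unique(expr$sample_id)
genes <- sort(unique(expr$gene))
t_sub <- expr[expr$tissue == "T", ]
t_mat <- matrix(NA_real_, length(ids), length(genes),
                dimnames = list(ids, genes))
t_mat[cbind(match(t_sub$sample_id, ids), match(t_sub$gene, genes))] <-
  t_sub$value
fam <- select_distribution_family(t_mat)
cat("distribution family vote on tumour columns:",
    paste(names(fam$votes), fam$votes, collapse = ", "),
    "(winner:", fam$family, ")\n")
cat("harmonisation applies the gamma family uniformly, per the method\n")

h_study <- harmonize_cohort(expr, "study")
tcga <- generate_tcga_like(spec)
h_tcga <- harmonize_cohort(tcga, "tcga")

ms <- merge_and_split(h_study, h_tcga, seed = seed)
cat(sprintf("train %d (%.1f%%), test %d (%.1f%%)\n",
            ms$split$train_n, 100 * ms$split$train_n / 58,
            ms$split$test_n, 100 * ms$split$test_n / 58))
cat("train outcome: ", paste(names(ms$split$train_outcome),
                             ms$split$train_outcome, collapse = ", "), "\n")
cat("test outcome:  ", paste(names(ms$split$test_outcome),
                             ms$split$test_outcome, collapse = ", "), "\n")

check <- compare_split(ms$merged, ms$split)
cat(sprintf("rank-sum split check: %d of %d features differ at p < 0.05\n",
            check$n_significant, nrow(check$table)))

dir.create("results", showWarnings = FALSE)
write.table(check$table, "results/split_ranksum.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
saveRDS(list(merged = ms$merged, split = ms$split), "results/harmonized.rds")
tr <- ms$merged$matrix[ms$split$train_ids, ]
te <- ms$merged$matrix[ms$split$test_ids, ]
write.csv(data.frame(sample_id = rownames(tr),
                     outcome = ms$merged$outcome[rownames(tr)], tr,
                     check.names = FALSE),
          "results/train.csv", row.names = FALSE)
write.csv(data.frame(sample_id = rownames(te),
                     outcome = ms$merged$outcome[rownames(te)], te,
                     check.names = FALSE),
          "results/test.csv", row.names = FALSE)
cat("wrote results/split_ranksum.tsv, results/train.csv, results/test.csv\n")
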