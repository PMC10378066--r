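#!/usr/bin/env Rscript
# Stage 5: Spearman co-expression within tumour tissue, within adjacent
# tissue, and across tissues, with the strong-correlation screen
# (r > 0.85, p < 0.05). Requires stage 3 output.

suppressPackageStartupMessages(library(ecangio))
expr <- read.delim("results/normalized_expression.tsv")

m <- spearman_matrix(expr)
strong <- strong_correlations(m)
cat(sprintf("computed %d correlation entries across three contexts\n",
            nrow(m)))
if (nrow(strong)) {
  cat("strong positive correlations (r > 0.85, p < 0.05):\n")
  print(strong, digits = 3, row.names = FALSE)
} else {
  cat("no correlation passed the strong screen\n")
}

write.table(m, "results/correlations.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(strong, "results/strong_correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/correlations.tsv, results/strong_correlations.tsv\n")
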