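#!/usr/bin/env Rscript
# Stage 2: candidate screen over the packaged (synthetic) consortium
# fold-change tables: transcripts passing >3-fold at adjusted p < 0.01,
# proteins passing >2-fold at adjusted p < 0.01, and their intersection.

suppressPackageStartupMessages(library(ecangio))
dir.create("results", showWarnings = FALSE)

res <- screen_candidates(load_screening_table("mrna"),
                         load_screening_table("protein"))
cat(sprintf("transcript screen: %d pass; protein screen: %d pass\n",
            length(res$mrna_pass), length(res$protein_pass)))
cat("intersection (", length(res$selected), "): ",
    paste(res$selected, collapse = ", "), "\n", sep = "")

write.table(data.frame(gene = res$selected),
            "results/selected_candidates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/selected_candidates.tsv\n")
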