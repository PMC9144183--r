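#!/usr/bin/env Rscript
# Step 3 — tumor-vs-normal direction calls.
#
# Per gene and modality: two-sided Wilcoxon rank-sum test between groups,
# Benjamini-Hochberg adjustment across genes, and an effect gate —
# |delta beta| >= 0.1 for methylation, |log2 fold change| >= 1 for
# expression — before a direction is assigned at q < 0.05.

suppressMessages(library(epitarget))

beta <- read_matrix_table("results/sim/beta.tsv")
tpm <- read_matrix_table("results/sim/tpm.tsv")
group <- read_sample_sheet("results/sim/samples.tsv")

meth <- call_methylation(beta, group, delta_threshold = 0.1,
                         q_threshold = 0.05)
expr <- call_expression(tpm, group, lfc_threshold = 1, q_threshold = 0.05)
readr::write_tsv(meth, "results/methylation_calls.tsv")
readr::write_tsv(expr, "results/expression_calls.tsv")

cat("methylation directions:\n")
print(table(meth$direction))
cat("expression directions:\n")
print(table(expr$direction))
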