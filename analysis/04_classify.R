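#!/usr/bin/env Rscript
# Step 4 — the filtration flow: DEG list -> promoter-CGI subset ->
# concordance classification.
#
# Genes whose promoter carries a qualifying island are kept; among those,
# upregulated + hypomethylated genes are called oncogene-like and
# downregulated + hypermethylated genes tumor-suppressor-like. Every input
# DEG stays in the report (non-island and discordant genes as unclassified)
# so the stage counts are auditable.

suppressMessages(library(epitarget))

deg <- read_deg_table("results/sim/deg.tsv")
cgi <- readr::read_tsv("results/promoter_cgi.tsv", show_col_types = FALSE)
presence <- stats::setNames(cgi$has_cgi, cgi$gene_id)
expr <- readr::read_tsv("results/expression_calls.tsv", show_col_types = FALSE)
meth <- readr::read_tsv("results/methylation_calls.tsv", show_col_types = FALSE)

report <- build_target_report(deg$gene_id, presence, expr, meth)
readr::write_tsv(report, "results/target_report.tsv")
lines <- write_summary(report, path = "results/summary.txt")
cat(lines, sep = "\n")

truth <- readr::read_tsv("results/sim/truth.tsv", show_col_types = FALSE)
hit <- report$target_class[match(truth$gene_id, report$gene_id)] ==
  truth$intended_class
cat("\nclasses matching planted truth:", sum(hit), "/", length(hit), "\n")
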