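#!/usr/bin/env Rscript

# Step 4: exact pairwise equal-expression tests, treated vs control within
# each time point (replicates pooled per condition), at FDR <= 0.001 and
# |log2 ratio| >= 2.

suppressPackageStartupMessages(library(tagdge))

run_dir <- "results/analysis"
counts_df <- read.delim(file.path(run_dir, "counts.tsv"),
                        stringsAsFactors = FALSE, check.names = FALSE)
counts <- as.matrix(counts_df[, -1])
rownames(counts) <- counts_df$gene_id
design <- read.delim(file.path(run_dir, "design.tsv"),
                     stringsAsFactors = FALSE)

de <- de_pairwise(counts, design, fdr_threshold = 0.001, lfc_threshold = 2)
for (nm in names(de))
  write.table(de[[nm]], file.path(run_dir, sprintf("de_%s.tsv", nm)),
              sep = "\t", quote = FALSE, row.names = FALSE)
deg_summary <- call_deg(de)
write.table(deg_summary, file.path(run_dir, "deg_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(deg_summary)

truth <- read.delim(file.path(run_dir, "truth.tsv"), stringsAsFactors = FALSE)
planted <- truth$gene_id[truth$is_planted_de]
for (nm in names(de)) {
  called <- de[[nm]]$gene_id[de[[nm]]$call != "not_significant"]
  cat(sprintf("%s: %d calls, %d of %d planted recovered, %d false\n",
              nm, length(called), length(intersect(called, planted)),
              length(planted), length(setdiff(called, planted))))
}
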