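#!/usr/bin/env Rscript

# Step 1: simulate the study design on synthetic data with planted truth.
# Ten libraries (five time points x control/treated), two biological
# replicates pooled per condition downstream; 150 genes, 12 with planted
# |log2 fold change| = 3; 30,000 tags per library at 0.1% substitution
# error. Writes FASTA/FASTQ/TSV inputs for the later steps.

suppressPackageStartupMessages(library(tagdge))

run_dir <- "results/analysis"
dir.create(file.path(run_dir, "reads"), recursive = TRUE, showWarnings = FALSE)
seed <- 2024L

tx <- generate_transcriptome(150L, c(300L, 1500L), catg_guarantee = TRUE,
                             seed = seed)
truth <- truth_table(tx, n_de = 12L, log2fc = 3, base = "lognormal",
                     seed = seed + 1L)
design <- default_design()

libs <- simulate_experiment(tx, truth, design, library_size = 30000L,
                            error_rate = 0.001, seed = seed + 10L)

write_transcriptome_fasta(tx, file.path(run_dir, "transcriptome.fa"))
write_gene_map(tx, file.path(run_dir, "gene_map.tsv"))
write_truth_table(truth, file.path(run_dir, "truth.tsv"))
write.table(design, file.path(run_dir, "design.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
for (nm in names(libs))
  write_library_fastq(libs[[nm]], file.path(run_dir, "reads", paste0(nm, ".fastq")))

cat(sprintf("simulated %d genes (%d planted DE), %d libraries of %d reads\n",
            nrow(tx), sum(truth$is_planted_de), length(libs), 30000L))
cat(sprintf("planted genes: %s\n",
            paste(truth$gene_id[truth$is_planted_de], collapse = ", ")))
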