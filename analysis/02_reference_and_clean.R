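#!/usr/bin/env Rscript

# Step 2: build the CATG+17 reference tag library from the simulated
# transcriptome and filter each library's raw reads into clean tags
# (no N, no adapter-only, no low-complexity, copy number >= 2).

suppressPackageStartupMessages(library(tagdge))

run_dir <- "results/analysis"
tx <- read_transcriptome_fasta(file.path(run_dir, "transcriptome.fa"),
                               file.path(run_dir, "gene_map.tsv"))

ref <- build_reference_library(tx)
write_reference_library(ref, file.path(run_dir, "reference_tags.tsv"))
cat(sprintf("reference library: %d tags over %d genes (%d multi-gene, %d genes undetectable)\n",
            nrow(ref$tags), length(ref$gene_lengths),
            sum(ref$tags$ambiguity_class == "multi_gene"),
            length(ref$undetectable_genes)))

fastqs <- list.files(file.path(run_dir, "reads"), full.names = TRUE)
dir.create(file.path(run_dir, "clean"), showWarnings = FALSE)
log_rows <- list()
for (fq in fastqs) {
  id <- sub("\\.fastq$", "", basename(fq))
  clean <- extract_and_filter_tags(read_library_fastq(fq, library_id = id))
  write_clean_tags(clean, file.path(run_dir, "clean", paste0(id, ".tsv")))
  log_rows[[id]] <- data.frame(
    library_id = id, raw = clean$raw_total,
    clean = sum(clean$counts$count),
    clean_pct = clean_read_fraction(clean$raw_total, sum(clean$counts$count)),
    t(clean$filter_log))
}
filter_log <- do.call(rbind, log_rows)
write.table(filter_log, file.path(run_dir, "filter_log.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("clean-tag percentage across libraries: %.2f-%.2f%%\n",
            min(filter_log$clean_pct), max(filter_log$clean_pct)))
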