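# File I/O for the standard interchange formats. FASTA/FASTQ go through
# Biostrings; tables are plain TSV.

#' Write a transcriptome to FASTA
#'
#' @param transcriptome A `transcriptome`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_transcriptome_fasta <- function(transcriptome, path) {
  ss <- Biostrings::DNAStringSet(transcriptome$sequence)
  names(ss) <- transcriptome$transcript_id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a transcriptome from FASTA plus a gene map
#'
#' @param fasta Path to a FASTA of transcript sequences.
#' @param gene_map Path to a TSV with columns `transcript_id`, `gene_id`, or
#'   NULL to treat every transcript as its own gene.
#' @return A `transcriptome` data.frame.
#' @export
read_transcriptome_fasta <- function(fasta, gene_map = NULL) {
  ss <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(ss))
  gene <- if (is.null(gene_map)) ids else {
    map <- utils::read.delim(gene_map, stringsAsFactors = FALSE)
    map$gene_id[match(ids, map$transcript_id)]
  }
  structure(
    data.frame(transcript_id = ids, gene_id = gene,
               sequence = as.character(ss), length = Biostrings::width(ss),
               stringsAsFactors = FALSE),
    class = c("transcriptome", "data.frame"))
}

#' Write the transcript-to-gene map
#' @param transcriptome A `transcriptome`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_map <- function(transcriptome, path) {
  utils::write.table(transcriptome[, c("transcript_id", "gene_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated library to FASTQ
#'
#' Reads are written with constant Sanger (+33) quality 'I' (Q40); the
#' pipeline's quality handling happens at the tag level, not per base.
#'
#' @param library A `simulated_library`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_library_fastq <- function(library, path) {
  seqs <- rep(library$reads$sequence, library$reads$count)
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- sprintf("%s_read%07d", library$library_id, seq_along(seqs))
  qual <- Biostrings::BStringSet(rep(strrep("I", READ_LENGTH), length(seqs)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read FASTQ reads into the run-length representation used internally
#'
#' @param path FASTQ path.
#' @param library_id,condition,replicate Metadata to attach.
#' @return A `simulated_library`-shaped list (no truth counts).
#' @export
read_library_fastq <- function(path, library_id = basename(path),
                               condition = NA_character_, replicate = NA_integer_) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  tab <- table(as.character(ss))
  structure(list(
    library_id = library_id, condition = condition, replicate = replicate,
    reads = data.frame(sequence = names(tab), count = as.integer(tab),
                       stringsAsFactors = FALSE),
    truth_counts = NULL, dropped_genes = character(0),
    seed = NA_integer_, library_size = length(ss), error_rate = NA_real_),
    class = "simulated_library")
}

#' Write a truth table to TSV
#' @param truth A `truth_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a reference tag library to TSV
#' @param ref A `reference_tag_library`.
#' @param path Output TSV path (columns tag, gene_id, transcript_id, position,
#'   ambiguity_class).
#' @return `path`, invisibly.
#' @export
write_reference_library <- function(ref, path) {
  tab <- merge(ref$hits, ref$tags[, c("tag", "ambiguity_class")], by = "tag")
  tab <- tab[order(tab$tag, tab$gene_id, tab$position), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write clean tags to TSV
#' @param clean A `clean_tag_set`.
#' @param path Output TSV path (columns tag, count).
#' @return `path`, invisibly.
#' @export
write_clean_tags <- function(clean, path) {
  utils::write.table(clean$counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Generic matrix writer: gene x library table with a gene_id first column.
write_gene_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
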