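# Shared fixture builders; everything is generated in code.

# A transcriptome from explicit sequences (one transcript per gene).
make_tx <- function(sequences, gene_ids = NULL) {
  gene_ids <- gene_ids %||% sprintf("g%02d", seq_along(sequences))
  structure(
    data.frame(transcript_id = paste0(gene_ids, "_t1"), gene_id = gene_ids,
               sequence = sequences, length = nchar(sequences),
               stringsAsFactors = FALSE),
    class = c("transcriptome", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A simulated_library-shaped object from explicit reads (each repeated
# `counts` times).
make_library <- function(sequences, counts = 1L, library_id = "test") {
  counts <- rep_len(counts, length(sequences))
  structure(list(
    library_id = library_id, condition = "control", replicate = 1L,
    reads = data.frame(sequence = sequences, count = as.integer(counts),
                       stringsAsFactors = FALSE),
    truth_counts = NULL, dropped_genes = character(0), seed = NA_integer_,
    library_size = sum(counts), error_rate = 0),
    class = "simulated_library")
}

# Pad a 21-nt tag to a full 49-nt read with the package adapter suffix.
pad_read <- function(tag) paste0(tag, substr(tag_adapter(), 1, 28))

# Random 21-nt CATG-anchored tag.
random_tag <- function() {
  paste0("CATG", paste(sample(c("A", "C", "G", "T"), 17, replace = TRUE),
                       collapse = ""))
}

# Direct log-space summation oracle for the equal-expression test:
# p(i|x) = r^i (x+i)! / (x! i! (1+r)^(x+i+1)), tails summed term by term.
ac_pvalue_oracle <- function(x, y, N1, N2, upper_max = y + 4000) {
  r <- N2 / N1
  lp <- function(i) i * log(r) + lgamma(x + i + 1) - lgamma(x + 1) -
    lgamma(i + 1) - (x + i + 1) * log1p(r)
  lower <- sum(exp(lp(0:y)))
  upper <- sum(exp(lp(y:upper_max)))
  min(1, 2 * min(lower, upper))
}

# Exhaustive log-binomial summation oracle for hypergeometric enrichment.
hyper_oracle <- function(N, n, M, m) {
  if (m == 0) return(1)
  i <- m:min(n, M)
  sum(exp(lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)))
}
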