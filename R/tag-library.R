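# Reference tag-library construction and clean-tag filtering.
#
# The reference library indexes EVERY CATG site with >= 17 nt downstream
# (CATG + 17 = 21-nt tags), while the simulator draws reads only from the
# 3'-most site of each transcript; the asymmetry mirrors library preparation,
# where oligo(dT) bead capture retains the 3'-most NlaIII fragment but the
# in-silico reference must cover all possible tags.

#' Build the CATG+17 reference tag library
#'
#' Scans every transcript for CATG occurrences with at least 17 nt downstream
#' and records the 21-mer starting at each such site. A tag is
#' `unique_gene` when all of its occurrences fall in transcripts of a single
#' gene, `multi_gene` otherwise; only `unique_gene` tags can contribute to
#' per-gene counts downstream. Genes none of whose transcripts carry an
#' eligible site are reported as undetectable.
#'
#' @param transcriptome A `transcriptome`.
#' @return A `reference_tag_library`: list with `tags` (data.frame `tag`,
#'   `ambiguity_class`, `n_genes`, `n_hits`, `gene_id` — the gene for
#'   unique_gene tags, NA otherwise), `hits` (data.frame `tag`, `gene_id`,
#'   `transcript_id`, `position` 0-based offset of the C of CATG),
#'   `undetectable_genes`, and `gene_lengths` (longest transcript per gene).
#' @examples
#' tx <- generate_transcriptome(10, c(100, 300), seed = 2)
#' ref <- build_reference_library(tx)
#' @export
build_reference_library <- function(transcriptome) {
  if (nrow(transcriptome) == 0) stop_domain("empty transcriptome")
  hits_list <- lapply(seq_len(nrow(transcriptome)), function(i) {
    s <- transcriptome$sequence[i]
    p <- gregexpr("CATG", s, fixed = TRUE)[[1]]
    if (p[1] == -1L) return(NULL)
    p <- p[p + TAG_LENGTH - 1L <= nchar(s)]
    if (length(p) == 0L) return(NULL)
    data.frame(tag = substr(rep(s, length(p)), p, p + TAG_LENGTH - 1L),
               gene_id = transcriptome$gene_id[i],
               transcript_id = transcriptome$transcript_id[i],
               position = p - 1L,          # 0-based
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits_list)
  if (is.null(hits))
    hits <- data.frame(tag = character(0), gene_id = character(0),
                       transcript_id = character(0), position = integer(0),
                       stringsAsFactors = FALSE)

  n_genes <- tapply(hits$gene_id, hits$tag, function(g) length(unique(g)))
  n_hits <- tapply(hits$tag, hits$tag, length)
  tag_ids <- names(n_genes)
  uniq_gene <- tapply(hits$gene_id, hits$tag, function(g) {
    u <- unique(g); if (length(u) == 1L) u else NA_character_
  })
  tags <- data.frame(
    tag = tag_ids,
    ambiguity_class = ifelse(n_genes == 1L, "unique_gene", "multi_gene"),
    n_genes = as.integer(n_genes), n_hits = as.integer(n_hits),
    gene_id = as.character(uniq_gene)[match(tag_ids, names(uniq_gene))],
    stringsAsFactors = FALSE, row.names = NULL)

  detectable <- unique(hits$gene_id)
  glen <- tapply(transcriptome$length, transcriptome$gene_id, max)
  structure(list(
    tags = tags, hits = hits,
    undetectable_genes = setdiff(unique(transcriptome$gene_id), detectable),
    gene_lengths = stats::setNames(as.integer(glen), names(glen))),
    class = "reference_tag_library")
}

#' @export
print.reference_tag_library <- function(x, ...) {
  cat(sprintf("reference_tag_library: %d tags (%d multi-gene), %d genes, %d undetectable\n",
              nrow(x$tags), sum(x$tags$ambiguity_class == "multi_gene"),
              length(x$gene_lengths), length(x$undetectable_genes)))
  invisible(x)
}

# A tag is low-complexity when one nucleotide occupies >= 80% of the 17
# variable positions (i.e. >= 14 of 17) or the whole tag is one base run.
is_low_complexity <- function(tags, frac = 0.8) {
  var_part <- substr(tags, 5L, TAG_LENGTH)
  n_var <- TAG_LENGTH - 4L
  thr <- ceiling(frac * n_var)
  counts <- vapply(c("A", "C", "G", "T"), function(b) {
    nchar(var_part) - nchar(gsub(b, "", var_part, fixed = TRUE))
  }, integer(length(tags)))
  if (length(tags) == 1L) counts <- matrix(counts, nrow = 1L)
  apply(counts, 1L, max) >= thr
}

#' Extract and filter tags from raw reads
#'
#' Takes the 21-nt tag at the start of every read, then removes in order:
#' tags containing N; adapter-only reads (tag region equals the adapter
#' prefix); low-complexity tags (one base at >= 80% of the 17 variable
#' positions); and tags observed exactly once in the whole library (likely
#' sequencing errors). Removal counts per category are logged so that
#' retained + filtered always reconstructs the raw read count.
#'
#' @param library A `simulated_library` (or the list returned by
#'   [read_library_fastq()]).
#' @param adapter Adapter sequence used for adapter-only detection; its first
#'   21 nt are compared to the tag region.
#' @return A `clean_tag_set`: list with `library_id`, `counts` (data.frame
#'   `tag`, `count`, every count >= 2), `filter_log` (named integer:
#'   contains_n, adapter_only, low_complexity, singleton), `raw_total`.
#' @export
extract_and_filter_tags <- function(library, adapter = tag_adapter()) {
  reads <- library$reads
  if (nrow(reads) > 0 && any(nchar(reads$sequence) < TAG_LENGTH))
    stop_domain("malformed read shorter than ", TAG_LENGTH, " nt: ",
                reads$sequence[which(nchar(reads$sequence) < TAG_LENGTH)[1]])
  raw_total <- sum(reads$count)
  tag <- substr(reads$sequence, 1L, TAG_LENGTH)
  adapter_prefix <- substr(adapter, 1L, TAG_LENGTH)

  flog <- c(contains_n = 0L, adapter_only = 0L, low_complexity = 0L,
            singleton = 0L)

  bad_n <- grepl("N", tag, fixed = TRUE)
  flog["contains_n"] <- sum(reads$count[bad_n])
  keep <- !bad_n

  bad_adapter <- keep & tag == adapter_prefix
  flog["adapter_only"] <- sum(reads$count[bad_adapter])
  keep <- keep & !bad_adapter

  if (any(keep)) {
    bad_lc <- keep
    bad_lc[keep] <- is_low_complexity(tag[keep])
    flog["low_complexity"] <- sum(reads$count[bad_lc])
    keep <- keep & !bad_lc
  }

  if (any(keep)) {
    pooled <- tapply(reads$count[keep], tag[keep], sum)
    counts <- data.frame(tag = names(pooled), count = as.integer(pooled),
                         stringsAsFactors = FALSE, row.names = NULL)
  } else {
    counts <- data.frame(tag = character(0), count = integer(0),
                         stringsAsFactors = FALSE)
  }
  single <- counts$count == 1L
  flog["singleton"] <- sum(counts$count[single])
  counts <- counts[!single, , drop = FALSE]
  counts <- counts[order(counts$tag), , drop = FALSE]
  rownames(counts) <- NULL

  structure(list(library_id = library$library_id, counts = counts,
                 filter_log = flog, raw_total = raw_total),
            class = "clean_tag_set")
}

#' @export
print.clean_tag_set <- function(x, ...) {
  cat(sprintf("clean_tag_set '%s': %d distinct tags, %d tags retained of %d raw (%.2f%%)\n",
              x$library_id, nrow(x$counts), sum(x$counts$count), x$raw_total,
              clean_read_fraction(x$raw_total, sum(x$counts$count))))
  invisible(x)
}

#' Percentage of clean reads
#'
#' @param raw Raw read count (> 0).
#' @param clean Clean read count, `0 <= clean <= raw`.
#' @return `100 * clean / raw`, rounded half-up to 2 decimals.
#' @examples
#' clean_read_fraction(7041039, 7007499)  # 99.52
#' @export
clean_read_fraction <- function(raw, clean) {
  if (raw <= 0) stop_domain("undefined ratio: raw read count must be > 0")
  if (clean < 0 || clean > raw) stop_domain("need 0 <= clean <= raw")
  round_half_up(100 * clean / raw, 2L)
}
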