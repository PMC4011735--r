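# Tag-to-gene mapping and RPKM quantification.

# All 63 Hamming-distance-1 neighbours of each 21-mer, as a data.frame
# (orig index, neighbour string).
hamming1_neighbors <- function(tags) {
  n <- length(tags)
  bases <- c("A", "C", "G", "T")
  out_tag <- vector("list", TAG_LENGTH * 4L)
  out_idx <- vector("list", TAG_LENGTH * 4L)
  k <- 0L
  for (p in seq_len(TAG_LENGTH)) {
    cur <- substr(tags, p, p)
    left <- substr(tags, 1L, p - 1L)
    right <- substr(tags, p + 1L, TAG_LENGTH)
    for (b in bases) {
      k <- k + 1L
      sel <- which(cur != b)  # paste0() on zero-length input would yield "b"
      out_tag[[k]] <- if (length(sel)) paste0(left[sel], b, right[sel])
                      else character(0)
      out_idx[[k]] <- sel
    }
  }
  data.frame(idx = unlist(out_idx), neighbor = unlist(out_tag),
             stringsAsFactors = FALSE)
}

#' Map clean tags to the reference library (at most one mismatch)
#'
#' Exact matches take priority: a tag identical to a reference tag is
#' assigned to that tag's positions only, even if other reference tags lie at
#' Hamming distance 1. A tag with no exact match is compared against the
#' library at distance 1 and accepts every hit found. A tag is unambiguous
#' when the union of genes over its accepted hits is a single gene; only
#' unambiguous tag counts enter per-gene counts. The summary tallies
#' perfect/one-mismatch, unique-position/multi-position and unmapped tag
#' counts (all in units of tags, i.e. weighted by copy number).
#'
#' @param clean A `clean_tag_set`.
#' @param ref A `reference_tag_library`.
#' @return List with `gene_counts` (named integer, unambiguous tags per
#'   gene), `summary` (a `mapping_summary`), and `assignments` (per distinct
#'   tag: match_type, n_positions, gene_id or NA).
#' @export
map_tags <- function(clean, ref) {
  if (nrow(ref$tags) == 0) stop_domain("reference library is empty")
  tags <- clean$counts$tag
  cnt <- clean$counts$count
  m <- length(tags)

  ref_tags <- ref$tags$tag
  ref_genes <- split(ref$hits$gene_id, ref$hits$tag)  # per-tag gene vectors
  ref_nhits <- stats::setNames(ref$tags$n_hits, ref$tags$tag)

  exact <- match(tags, ref_tags)
  match_type <- ifelse(is.na(exact), "unmapped", "perfect")
  gene_id <- rep(NA_character_, m)
  n_pos <- integer(m)

  has_exact <- !is.na(exact)
  if (any(has_exact)) {
    gene_id[has_exact] <- ref$tags$gene_id[exact[has_exact]]
    n_pos[has_exact] <- ref$tags$n_hits[exact[has_exact]]
  }

  todo <- which(!has_exact)
  if (length(todo) > 0) {
    nb <- hamming1_neighbors(tags[todo])
    nb$hit <- match(nb$neighbor, ref_tags)
    nb <- nb[!is.na(nb$hit), , drop = FALSE]
    if (nrow(nb) > 0) {
      by_tag <- split(nb$hit, nb$idx)
      for (nm in names(by_tag)) {
        i <- todo[as.integer(nm)]
        hit_tags <- ref_tags[by_tag[[nm]]]
        genes <- unique(unlist(ref_genes[hit_tags], use.names = FALSE))
        match_type[i] <- "one_mismatch"
        n_pos[i] <- sum(ref_nhits[hit_tags])
        if (length(genes) == 1L) gene_id[i] <- genes
      }
    }
  }

  mapped <- match_type != "unmapped"
  unambiguous <- mapped & !is.na(gene_id)
  gene_counts <- integer(0)
  if (any(unambiguous)) {
    gc <- tapply(cnt[unambiguous], gene_id[unambiguous], sum)
    gene_counts <- stats::setNames(as.integer(gc), names(gc))
  }
  # genes present in the reference but without counts get an explicit zero
  all_genes <- names(ref$gene_lengths)
  full <- stats::setNames(integer(length(all_genes)), all_genes)
  full[names(gene_counts)] <- gene_counts

  summary <- structure(list(
    library_id = clean$library_id,
    total_reads = sum(cnt),
    total_mapped = sum(cnt[mapped]),
    perfect_match = sum(cnt[match_type == "perfect"]),
    one_mismatch = sum(cnt[match_type == "one_mismatch"]),
    unique_match = sum(cnt[mapped & n_pos == 1L]),
    multi_position_match = sum(cnt[mapped & n_pos > 1L]),
    unmapped = sum(cnt[!mapped])), class = "mapping_summary")

  list(gene_counts = full, summary = summary,
       assignments = data.frame(tag = tags, count = cnt,
                                match_type = match_type, n_positions = n_pos,
                                gene_id = gene_id, stringsAsFactors = FALSE))
}

#' @export
print.mapping_summary <- function(x, ...) {
  cat(sprintf("mapping_summary '%s': %d tags, %d mapped (%d perfect, %d 1-mismatch), %d unmapped\n",
              x$library_id, x$total_reads, x$total_mapped, x$perfect_match,
              x$one_mismatch, x$unmapped))
  invisible(x)
}

check_mapping_summary <- function(s) {
  ok <- s$unique_match + s$multi_position_match == s$total_mapped &&
    s$total_mapped + s$unmapped == s$total_reads &&
    s$perfect_match + s$one_mismatch == s$total_mapped
  if (!ok) stop_domain("inconsistent mapping summary for ", s$library_id)
  invisible(TRUE)
}

#' RPKM normalization
#'
#' Reads per kilobase of gene model per million mapped reads:
#' `10^9 * C / (N * L)`.
#'
#' @param C Unambiguous tag count(s) for the gene, >= 0.
#' @param N Total mapped tag count of the library, > 0.
#' @param L Gene length in nt (longest transcript), > 0.
#' @return RPKM value(s); 0 exactly when `C` is 0.
#' @examples
#' rpkm(250, 5e6, 2000)  # 25
#' @export
rpkm <- function(C, N, L) {
  if (any(N <= 0) || any(L <= 0)) stop_domain("N and L must be > 0")
  if (any(C < 0)) stop_domain("C must be >= 0")
  1e9 * C / (N * L)
}

#' Per-gene expression table (counts and RPKM)
#'
#' @param gene_counts Named integer vector of unambiguous tag counts.
#' @param ref A `reference_tag_library` (provides gene lengths).
#' @param N RPKM denominator; by default the total mapped tags
#'   (`sum(gene_counts)` counts only unambiguous ones, so pass the summary's
#'   `total_mapped` for the conventional denominator).
#' @return data.frame `gene_id`, `count`, `length`, `rpkm`.
#' @export
gene_expression <- function(gene_counts, ref, N = sum(gene_counts)) {
  genes <- names(gene_counts)
  L <- ref$gene_lengths[genes]
  data.frame(gene_id = genes, count = as.integer(gene_counts),
             length = as.integer(L),
             rpkm = rpkm(as.numeric(gene_counts), N, as.numeric(L)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Percentage breakdown of a mapping summary
#'
#' @param summary A `mapping_summary` (its count identities are checked).
#' @return One-row data.frame with the raw counts and each category as
#'   `100 * count / total_reads`, rounded half-up to 2 decimals.
#' @export
mapping_percentages <- function(summary) {
  check_mapping_summary(summary)
  tot <- summary$total_reads
  if (tot <= 0) stop_domain("total_reads must be > 0")
  pct <- function(x) round_half_up(100 * x / tot, 2L)
  data.frame(
    library_id = summary$library_id,
    total_reads = tot,
    total_mapped = summary$total_mapped,
    total_mapped_pct = pct(summary$total_mapped),
    perfect_match = summary$perfect_match,
    perfect_match_pct = pct(summary$perfect_match),
    one_mismatch = summary$one_mismatch,
    one_mismatch_pct = pct(summary$one_mismatch),
    unique_match = summary$unique_match,
    unique_match_pct = pct(summary$unique_match),
    multi_position_match = summary$multi_position_match,
    multi_position_match_pct = pct(summary$multi_position_match),
    unmapped = summary$unmapped,
    unmapped_pct = pct(summary$unmapped),
    stringsAsFactors = FALSE)
}

#' Assemble a gene-by-library count matrix
#'
#' @param map_results Named list of [map_tags()] results (names = library
#'   ids).
#' @return Integer matrix, genes in rows, libraries in columns.
#' @export
count_matrix <- function(map_results) {
  genes <- names(map_results[[1]]$gene_counts)
  mat <- vapply(map_results, function(r) r$gene_counts[genes],
                integer(length(genes)))
  rownames(mat) <- genes
  mat
}
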