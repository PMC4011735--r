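# Accessors for the published validation tables bundled with the package:
# library quality-assessment counts and the qRT-PCR validation of DGE calls
# from a ten-library silkworm hemocyte Destruxin A time course.

#' Published library quality-assessment counts
#'
#' Mapping counts for the ten hemocyte DGE libraries (five time points,
#' control CK vs Destruxin-A-treated DA), against the reference gene set and
#' the reference genome. Useful for exercising [mapping_percentages()] and
#' [quality_report()] on real-scale numbers.
#'
#' @param section `"genes"` (transcriptome mapping) or `"genome"`.
#' @return List of `mapping_summary` objects, one per library.
#' @export
published_mapping_counts <- function(section = c("genes", "genome")) {
  section <- match.arg(section)
  path <- system.file("extdata", "mapping_summary_published.tsv",
                      package = "tagdge", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab <- tab[tab$section == section, , drop = FALSE]
  out <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    structure(list(library_id = r$library_id,
                   total_reads = r$total_reads,
                   total_mapped = r$total_mapped,
                   perfect_match = r$perfect_match,
                   one_mismatch = r$one_mismatch,
                   unique_match = r$unique_match,
                   multi_position_match = r$multi_position_match,
                   unmapped = r$unmapped),
              class = "mapping_summary")
  })
  stats::setNames(out, tab$library_id)
}

#' Published qRT-PCR validation table
#'
#' Twenty qRT-PCR measurements (relative expression, fold-repression display
#' convention: negative means `-1/fold`) alongside the DGE log2 ratios they
#' validate; two rows are flagged non-significant in the source data. One
#' gene appears twice (two primer pairs at 24 h); `unique_ids = TRUE`
#' disambiguates the duplicate for joining.
#'
#' @param unique_ids Suffix duplicated gene ids with `.1`, `.2`, ...
#' @return data.frame `gene_id`, `timepoint`, `dge_log2_ratio`,
#'   `qpcr_display`, `qpcr_sd`, `significant`.
#' @export
qpcr_validation <- function(unique_ids = TRUE) {
  path <- system.file("extdata", "qpcr_validation.tsv",
                      package = "tagdge", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (unique_ids) tab$gene_id <- make.unique(tab$gene_id)
  tab
}
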