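# Sequencing QC: saturation analysis, gene-body coverage, quality report.

#' Sequencing saturation analysis
#'
#' Subsamples the mapped unambiguous tag stream at increasing fractions and
#' counts the genes detected (>= 1 unambiguous tag). Subsamples are nested by
#' construction — one random permutation of the tag occurrences is drawn and
#' each fraction takes a prefix — so detection counts are monotone
#' non-decreasing along the curve, not merely in expectation.
#'
#' @param map_result A [map_tags()] result (its `assignments` supply the
#'   per-tag gene and copy number; only unambiguous tags are used).
#' @param fractions Sorted subsample fractions in (0, 1].
#' @param seed Integer RNG seed for the permutation.
#' @return A `saturation_curve`: data.frame `fraction`, `reads_sampled`,
#'   `genes_detected`, with attributes `library_id`, `plateau` (TRUE when the
#'   last 10% of reads adds < 0.5% new genes) and `detectable_genes`.
#' @export
saturation_analysis <- function(map_result, fractions = seq(0.05, 1, by = 0.05),
                                seed = 1L) {
  if (any(fractions <= 0 | fractions > 1) || is.unsorted(fractions))
    stop_domain("`fractions` must be sorted values in (0, 1]")
  a <- map_result$assignments
  a <- a[!is.na(a$gene_id), , drop = FALSE]
  genes <- rep(a$gene_id, a$count)
  total <- length(genes)
  if (total == 0) stop_domain("no unambiguous mappings to subsample")

  curve <- with_seed(seed, {
    perm <- genes[sample.int(total)]
    # position of each gene's first occurrence in the permuted stream
    first <- match(unique(perm), perm)
    ks <- pmax(1L, as.integer(round(fractions * total)))
    detected <- vapply(ks, function(k) sum(first <= k), integer(1))
    data.frame(fraction = fractions, reads_sampled = ks,
               genes_detected = detected)
  })

  # plateau: the last 10% of reads contributes < 0.5% additional genes
  k90 <- max(1L, as.integer(round(0.9 * total)))
  plateau <- with_seed(seed, {
    perm <- genes[sample.int(total)]
    f <- match(unique(perm), perm)
    d90 <- sum(f <= k90); dall <- length(f)
    (dall - d90) / max(1L, dall) < 0.005
  })

  structure(curve, library_id = map_result$summary$library_id,
            plateau = plateau,
            detectable_genes = length(unique(genes)),
            class = c("saturation_curve", "data.frame"))
}

#' Gene-body distribution of tag positions and expression dynamic range
#'
#' Each unambiguous tag mapping contributes its relative tag-start position
#' (0-based position / gene length) to a 100-bin histogram, weighted by copy
#' number; a per-gene covered fraction (distinct tag positions x 21 nt /
#' length, capped at 1) summarizes coverage; the dynamic range is
#' `log10(max RPKM / min nonzero RPKM)` over detected genes.
#'
#' @param map_result A [map_tags()] result.
#' @param ref The `reference_tag_library` used for mapping.
#' @return A `coverage_profile`: list with `histogram` (integer[100]),
#'   `coverage_fraction` (named per-gene), `dynamic_range`, `library_id`.
#' @export
gene_body_distribution <- function(map_result, ref) {
  a <- map_result$assignments
  a <- a[!is.na(a$gene_id), , drop = FALSE]
  if (nrow(a) == 0) {
    warning("no unambiguous mappings; empty coverage profile")
    return(structure(list(histogram = integer(100),
                          coverage_fraction = numeric(0),
                          dynamic_range = 0,
                          library_id = map_result$summary$library_id),
                     class = "coverage_profile"))
  }
  # tag positions: for unambiguous tags use the reference hits of the
  # exact tag (perfect) — 1-mismatch tags inherit their matched positions
  # only through exact neighbours, so restrict to hits of the gene assigned
  hits <- ref$hits
  key <- paste(hits$tag, hits$gene_id)
  idx <- match(paste(a$tag, a$gene_id), key)
  pos <- hits$position[idx]
  len <- ref$gene_lengths[a$gene_id]
  ok <- !is.na(pos)
  rel <- pos[ok] / len[ok]
  bin <- pmin(100L, floor(rel * 100) + 1L)
  histogram <- vapply(1:100, function(b) sum(a$count[ok][bin == b]),
                      numeric(1))

  cov_df <- data.frame(gene = a$gene_id[ok], pos = pos[ok])
  covered <- tapply(cov_df$pos, cov_df$gene,
                    function(p) length(unique(p)) * TAG_LENGTH)
  cov_frac <- pmin(1, as.numeric(covered) /
                        as.numeric(ref$gene_lengths[names(covered)]))
  names(cov_frac) <- names(covered)

  counts <- tapply(a$count, a$gene_id, sum)
  N <- map_result$summary$total_mapped
  r <- rpkm(as.numeric(counts), N, as.numeric(ref$gene_lengths[names(counts)]))
  r <- r[r > 0]
  dr <- if (length(r) <= 1) 0 else log10(max(r) / min(r))

  structure(list(histogram = as.integer(histogram),
                 coverage_fraction = cov_frac,
                 dynamic_range = dr,
                 library_id = map_result$summary$library_id),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("coverage_profile '%s': %d positioned tags, dynamic range %.3f\n",
              x$library_id, sum(x$histogram), x$dynamic_range))
  invisible(x)
}

#' Library quality report
#'
#' One row per library with counts and 2-decimal percentages in the
#' conventional column order (total reads, total mapped, perfect match,
#' 1-mismatch, unique match, multi-position match, unmapped).
#'
#' @param summaries List of `mapping_summary` objects.
#' @return data.frame, one row per library (see [mapping_percentages()]).
#' @export
quality_report <- function(summaries) {
  rows <- lapply(summaries, function(s) {
    if (s$total_reads == 0) {
      check_mapping_summary(s)
      z <- mapping_percentages(structure(
        list(library_id = s$library_id, total_reads = 1L, total_mapped = 0L,
             perfect_match = 0L, one_mismatch = 0L, unique_match = 0L,
             multi_position_match = 0L, unmapped = 1L),
        class = "mapping_summary"))
      z$total_reads <- 0L; z$unmapped <- 0L; z$unmapped_pct <- 0
      z
    } else {
      mapping_percentages(s)
    }
  })
  do.call(rbind, rows)
}
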