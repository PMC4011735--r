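# Hypergeometric term enrichment of DEG lists (GO-style with Bonferroni,
# pathway-style with BH Q-values).

#' Hypergeometric enrichment p-value
#'
#' Upper-tail probability of drawing at least `m` term-annotated genes in a
#' DEG sample of `n` from a background of `N` annotated genes of which `M`
#' carry the term: `P(X >= m) = 1 - sum_{i<m} C(M,i) C(N-M,n-i) / C(N,n)`.
#' Exactly 1 when `m = 0`. Vectorized.
#'
#' @param N Background size (genes with any annotation).
#' @param n DEGs within the background.
#' @param M Genes annotated to the term.
#' @param m DEGs annotated to the term, `m <= min(n, M)`.
#' @return Upper-tail p-value(s).
#' @examples
#' hypergeom_enrich_pvalue(10, 5, 5, 5)  # 1/252
#' @export
hypergeom_enrich_pvalue <- function(N, n, M, m) {
  k <- max(length(N), length(n), length(M), length(m))
  N <- rep_len(N, k); n <- rep_len(n, k); M <- rep_len(M, k)
  m <- rep_len(m, k)
  if (any(M > N | n > N | m > pmin(n, M) | m < 0 | M < 0 | n < 0))
    stop_domain("need 0 <= m <= min(n, M), M <= N, n <= N")
  ifelse(m == 0, 1, stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE))
}

#' Bonferroni correction of a set of term p-values
#'
#' @param p_raws Raw p-values.
#' @param alpha Significance threshold in (0, 1).
#' @return data.frame `p_raw`, `p_bonferroni` (`min(1, k * p)` with `k` the
#'   number of terms tested), `significant`.
#' @export
bonferroni <- function(p_raws, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop_domain("`alpha` must be in (0, 1)")
  adj <- pmin(1, length(p_raws) * p_raws)
  data.frame(p_raw = p_raws, p_bonferroni = adj, significant = adj <= alpha)
}

#' Term enrichment of a DEG list against flat gene-term annotations
#'
#' Builds the 2x2 membership counts per term (`N` background genes with any
#' annotation, `n` DEGs among them, `M` genes carrying the term, `m` DEGs
#' carrying it), computes hypergeometric upper-tail p-values, and corrects
#' with both Bonferroni and Benjamini-Hochberg Q-values. Annotations are
#' taken as given, flat gene-to-term pairs (no ontology propagation).
#'
#' @param deg_genes Character vector of differentially expressed gene ids.
#' @param annotation data.frame with columns `gene_id`, `term_id` (extra
#'   columns such as `term_name` are carried through).
#' @return data.frame of class `enrichment_result`, one row per term with
#'   `term_id`, `N`, `n`, `M`, `m`, `p_raw`, `p_bonferroni`, `q_value`,
#'   sorted by `p_raw`.
#' @export
enrich_terms <- function(deg_genes, annotation) {
  if (!all(c("gene_id", "term_id") %in% names(annotation)))
    stop_domain("`annotation` needs columns gene_id, term_id")
  annotation <- unique(annotation[, intersect(c("gene_id", "term_id", "term_name"),
                                              names(annotation))])
  background <- unique(annotation$gene_id)
  N <- length(background)
  if (N == 0) stop_domain("annotation table is empty")
  deg_in <- intersect(unique(deg_genes), background)
  n <- length(deg_in)

  M <- tapply(annotation$gene_id, annotation$term_id,
              function(g) length(unique(g)))
  m <- tapply(annotation$gene_id, annotation$term_id,
              function(g) length(intersect(unique(g), deg_in)))
  terms <- names(M)
  p <- hypergeom_enrich_pvalue(N, n, as.integer(M), as.integer(m))
  res <- data.frame(term_id = terms, N = N, n = n,
                    M = as.integer(M), m = as.integer(m),
                    p_raw = p,
                    p_bonferroni = pmin(1, length(terms) * p),
                    q_value = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  if ("term_name" %in% names(annotation)) {
    nm <- unique(annotation[, c("term_id", "term_name")])
    res$term_name <- nm$term_name[match(res$term_id, nm$term_id)]
  }
  res <- res[order(res$p_raw, res$term_id), ]
  rownames(res) <- NULL
  structure(res, class = c("enrichment_result", "data.frame"))
}

#' Significantly enriched pathways at a Q-value threshold
#'
#' Same hypergeometric statistic as GO-style enrichment; significance is
#' declared on the Benjamini-Hochberg Q-value instead of the Bonferroni
#' bound.
#'
#' @param terms An `enrichment_result` (from [enrich_terms()]).
#' @param q_threshold Q-value threshold (default 0.05).
#' @return The significant subset, sorted by `q_value`.
#' @export
pathway_enrich <- function(terms, q_threshold = 0.05) {
  sig <- terms[terms$q_value <= q_threshold, , drop = FALSE]
  sig <- sig[order(sig$q_value, sig$p_raw, sig$term_id), ]
  rownames(sig) <- NULL
  sig
}
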