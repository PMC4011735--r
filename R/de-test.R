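# Exact pairwise test of equal expression between two tag libraries.
#
# The test conditions on the total x + y tags of a gene: if the gene is
# expressed equally, y | x follows the Audic-Claverie conditional
# distribution p(y|x) = (N2/N1)^y * (x+y)! / (x! y! (1+N2/N1)^(x+y+1)),
# which is the negative-binomial pmf with size x+1 and success probability
# N1/(N1+N2). Tails are therefore computed through the regularized
# incomplete beta function, which is stable for library sizes up to 10^7
# and beyond (no explicit factorials ever formed).

#' Exact equal-expression p-value for tag counts
#'
#' Two-sided probability that gene counts `x` (library 1, total `N1` tags)
#' and `y` (library 2, total `N2` tags) arise from equal expression. The
#' smaller of the lower tail `P(Y <= y | x)` and upper tail `P(Y >= y | x)`
#' is doubled and capped at 1. Vectorized over `x`, `y`, `N1`, `N2`.
#'
#' @param x,y Non-negative tag counts in libraries 1 and 2.
#' @param N1,N2 Total clean tag counts of libraries 1 and 2 (> 0).
#' @param alternative `"two.sided"` (default), or the one-sided tails:
#'   `"less"` gives `P(Y <= y | x)`, `"greater"` gives `P(Y >= y | x)`.
#' @return p-values in `[0, 1]`; 1 when `x = y = 0` at equal depths. Note
#'   the doubled-smaller-tail convention is not exactly symmetric under
#'   swapping samples at small counts; the one-sided tails obey the exact
#'   duality `P(Y >= y+1 | x; N1, N2) == P(X <= x | y; N2, N1)`.
#' @examples
#' equal_expression_pvalue(5, 50, 1e6, 1e6)
#' @export
equal_expression_pvalue <- function(x, y, N1, N2,
                                    alternative = c("two.sided", "less",
                                                    "greater")) {
  alternative <- match.arg(alternative)
  n <- max(length(x), length(y), length(N1), length(N2))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  N1 <- rep_len(as.numeric(N1), n); N2 <- rep_len(as.numeric(N2), n)
  if (any(x < 0 | y < 0)) stop_domain("counts must be >= 0")
  if (any(N1 <= 0 | N2 <= 0)) stop_domain("library totals must be > 0")
  if (any(x > N1 | y > N2)) stop_domain("counts cannot exceed library totals")

  p0 <- N1 / (N1 + N2)                    # P(success) of the NB form
  lower <- stats::pbeta(p0, x + 1, y + 1) # P(Y <= y | x)
  upper <- ifelse(y == 0, 1, stats::pbeta(1 - p0, y, x + 1)) # P(Y >= y | x)
  switch(alternative,
         less = lower,
         greater = upper,
         two.sided = pmin(1, 2 * pmin(lower, upper)))
}

#' Normalized log2 expression ratio (library 2 over library 1)
#'
#' `log2(((y + d2) / N2) / ((x + d1) / N1))`, where the pseudocount is added
#' only on a zero side, so finite large ratios are reported for on/off genes
#' while nonzero counts stay untouched. Positive values mean higher
#' expression in library 2 (by convention, the treated sample).
#'
#' @param x,y Tag counts.
#' @param N1,N2 Library totals.
#' @param pseudocount Added to `x` (resp. `y`) only when it is 0; > 0.
#' @return log2 ratio(s).
#' @export
log2_ratio <- function(x, y, N1, N2, pseudocount = 1) {
  if (pseudocount <= 0) stop_domain("`pseudocount` must be > 0")
  xx <- ifelse(x == 0, pseudocount, x)
  yy <- ifelse(y == 0, pseudocount, y)
  log2((yy / N2) / (xx / N1))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted values, order-preserving and clipped to `[0, 1]`.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted values, same order as the input.
#' @export
fdr_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop_domain("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Pairwise differential-expression test between two libraries
#'
#' Runs the exact equal-expression test per gene, adjusts with
#' Benjamini-Hochberg, computes log2 ratios, and calls genes up (higher in
#' sample 2) or down at the joint threshold `fdr <= fdr_threshold` and
#' `|log2_ratio| >= lfc_threshold`.
#'
#' @param x,y Named per-gene tag counts for samples 1 and 2 (same genes).
#' @param N1,N2 Total clean tag counts; default `sum(x)`, `sum(y)`.
#' @param fdr_threshold FDR call threshold (default 0.001).
#' @param lfc_threshold Absolute log2-ratio call threshold (default 2).
#' @param pseudocount Zero-side pseudocount for the ratio.
#' @return data.frame of class `de_result`: `gene_id`, `x`, `y`, `N1`, `N2`,
#'   `p`, `fdr`, `log2_ratio`, `call` in `{up, down, not_significant}`.
#' @export
de_test <- function(x, y, N1 = sum(x), N2 = sum(y),
                    fdr_threshold = 0.001, lfc_threshold = 2,
                    pseudocount = 1) {
  genes <- names(x) %||% as.character(seq_along(x))
  stopifnot(length(x) == length(y))
  p <- equal_expression_pvalue(x, y, N1, N2)
  fdr <- fdr_adjust(p)
  lr <- log2_ratio(x, y, N1, N2, pseudocount)
  call <- ifelse(fdr <= fdr_threshold & lr >= lfc_threshold, "up",
                 ifelse(fdr <= fdr_threshold & lr <= -lfc_threshold, "down",
                        "not_significant"))
  structure(
    data.frame(gene_id = genes, x = as.integer(x), y = as.integer(y),
               N1 = N1, N2 = N2, p = p, fdr = fdr, log2_ratio = lr,
               call = call, stringsAsFactors = FALSE, row.names = NULL),
    class = c("de_result", "data.frame"))
}

#' Summarize up/down calls
#'
#' @param results A `de_result` (or list of them, one per comparison).
#' @return For a single result: list with `n_up`, `n_down`, `up_genes`,
#'   `down_genes`. For a named list: data.frame with one row per comparison.
#' @export
call_deg <- function(results) {
  one <- function(r) {
    list(n_up = sum(r$call == "up"), n_down = sum(r$call == "down"),
         up_genes = r$gene_id[r$call == "up"],
         down_genes = r$gene_id[r$call == "down"])
  }
  if (is.data.frame(results)) return(one(results))
  rows <- lapply(results, one)
  data.frame(comparison = names(results),
             n_up = vapply(rows, `[[`, integer(1), "n_up"),
             n_down = vapply(rows, `[[`, integer(1), "n_down"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run all treated-vs-control comparisons of a design
#'
#' For each time point, pools replicate counts per condition (the default,
#' matching the two-library formulation of the test) or tests replicates
#' separately, and runs [de_test()] with control as sample 1 and treated as
#' sample 2.
#'
#' @param counts Gene-by-library count matrix (see [count_matrix()]).
#' @param design Design data.frame (`library_id`, `condition`, `timepoint`,
#'   `replicate`).
#' @param pool_replicates Pool replicate counts per condition (default TRUE).
#' @param ... Passed to [de_test()].
#' @return Named list of `de_result`, one per comparison
#'   (`<timepoint>` when pooled, `<timepoint>_r<k>` otherwise).
#' @export
de_pairwise <- function(counts, design, pool_replicates = TRUE, ...) {
  out <- list()
  for (tp in unique(design$timepoint)) {
    ck <- design$library_id[design$timepoint == tp &
                            design$condition == "control"]
    da <- design$library_id[design$timepoint == tp &
                            design$condition == "treated"]
    if (length(ck) == 0 || length(da) == 0)
      stop_domain("time point ", tp, " lacks a control or treated library")
    if (pool_replicates) {
      x <- rowSums(counts[, ck, drop = FALSE])
      y <- rowSums(counts[, da, drop = FALSE])
      out[[tp]] <- de_test(x, y, ...)
    } else {
      for (k in seq_along(ck)) {
        x <- counts[, ck[k]]
        y <- counts[, da[min(k, length(da))]]
        out[[sprintf("%s_r%d", tp, k)]] <- de_test(x, y, ...)
      }
    }
  }
  out
}
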