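# qPCR relative quantification (2^-ddCt) and DGE concordance.

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, dCt = Ct(target) - Ct(reference); ddCt is the mean treated
#' dCt minus the mean control dCt; fold change = `2^-ddCt`. The SD is taken
#' over the treated replicates' `2^-dCt` values normalized to the control
#' mean `2^-dCt`, and the p-value comes from a two-sample t-test on the dCt
#' values (equal-variance by default; Welch via `var_equal = FALSE`).
#'
#' @param records data.frame with columns `gene_id`, `condition`
#'   (`"treated"`/`"control"`), `replicate`, `ct_target`, `ct_reference`;
#'   one gene at a time.
#' @param var_equal Equal-variance t-test (default TRUE).
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return A one-row data.frame of class `relative_expression`: `gene_id`,
#'   `fold_change` (`2^-ddCt`, always > 0), `signed_display` (the fold change
#'   when >= 1, else `-1/fold_change`, the fold-repression display
#'   convention), `sd`, `p_value`, `significant`.
#' @examples
#' ct <- data.frame(gene_id = "g1",
#'                  condition = rep(c("control", "treated"), each = 3),
#'                  replicate = rep(1:3, 2),
#'                  ct_target = c(25, 25.1, 24.9, 23, 23.1, 22.9),
#'                  ct_reference = 18)
#' ddct(ct)  # ~4-fold induction
#' @export
ddct <- function(records, var_equal = TRUE, alpha = 0.05) {
  need <- c("gene_id", "condition", "replicate", "ct_target", "ct_reference")
  if (!all(need %in% names(records)))
    stop_domain("`records` needs columns ", paste(need, collapse = ", "))
  if (length(unique(records$gene_id)) != 1L)
    stop_domain("`records` must contain a single gene; see ddct_all()")
  if (!all(c("treated", "control") %in% records$condition))
    stop_domain("incomplete design: need both treated and control records")
  if (any(!is.finite(records$ct_target)) || any(!is.finite(records$ct_reference)) ||
      any(records$ct_target <= 0) || any(records$ct_reference <= 0))
    stop_domain("Ct values must be positive and finite")

  dct <- records$ct_target - records$ct_reference
  trt <- dct[records$condition == "treated"]
  ctl <- dct[records$condition == "control"]
  ddct_val <- mean(trt) - mean(ctl)
  fold <- 2^(-ddct_val)

  # replicate-level relative expression, normalized to the control mean
  rel_trt <- 2^(-trt) / mean(2^(-ctl))
  sd_fold <- if (length(trt) >= 2) stats::sd(rel_trt) else NA_real_

  p <- if (length(trt) >= 2 && length(ctl) >= 2) {
    # zero-variance data (e.g. idealized Ct values) has no defined t-statistic
    tryCatch(stats::t.test(trt, ctl, var.equal = var_equal)$p.value,
             error = function(e) NA_real_)
  } else NA_real_

  structure(
    data.frame(gene_id = records$gene_id[1],
               fold_change = fold,
               signed_display = if (fold >= 1) fold else -1 / fold,
               sd = sd_fold, p_value = p,
               significant = !is.na(p) && p < alpha,
               stringsAsFactors = FALSE),
    class = c("relative_expression", "data.frame"))
}

#' 2^-ddCt for every gene of a Ct table
#'
#' @param records Multi-gene Ct data.frame (see [ddct()]).
#' @param ... Passed to [ddct()].
#' @return data.frame with one row per gene.
#' @export
ddct_all <- function(records, ...) {
  out <- lapply(split(records, records$gene_id), ddct, ...)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate qPCR Ct measurements for a known fold change
#'
#' Generates treated/control Ct values whose expected 2^-ddCt equals
#' `fold_change`, with iid Gaussian cycle noise — the generator used to test
#' parameter recovery of the ddCt estimator.
#'
#' @param gene_id Gene label.
#' @param fold_change True fold change (> 0; < 1 means repression).
#' @param n_replicates Replicates per condition (default 3).
#' @param ct_noise_sd SD of per-measurement Ct noise in cycles (default 0.1).
#' @param base_ct Control-condition target Ct (default 25).
#' @param reference_ct Reference-gene Ct in all wells (default 18).
#' @param seed Integer RNG seed.
#' @return Ct data.frame suitable for [ddct()].
#' @export
simulate_qpcr <- function(gene_id, fold_change, n_replicates = 3L,
                          ct_noise_sd = 0.1, base_ct = 25, reference_ct = 18,
                          seed = 1L) {
  if (fold_change <= 0) stop_domain("`fold_change` must be > 0")
  with_seed(seed, {
    n <- n_replicates
    treated_ct <- base_ct - log2(fold_change)
    data.frame(
      gene_id = gene_id,
      condition = rep(c("control", "treated"), each = n),
      replicate = rep(seq_len(n), 2),
      ct_target = c(base_ct + stats::rnorm(n, 0, ct_noise_sd),
                    treated_ct + stats::rnorm(n, 0, ct_noise_sd)),
      ct_reference = reference_ct + stats::rnorm(2 * n, 0, ct_noise_sd),
      stringsAsFactors = FALSE)
  })
}

#' Concordance between DGE calls and qPCR relative expression
#'
#' Joins the two result sets on gene id and reports, per gene, whether the
#' DGE log2 ratio and the qPCR signed display value agree in sign, and
#' whether both methods flag the gene significant.
#'
#' @param dge data.frame with `gene_id` and `log2_ratio` (e.g. a
#'   `de_result`, or any table of published log2 ratios).
#' @param qpcr data.frame with `gene_id`, `signed_display`, `significant`.
#' @return List with `table` (per-gene `gene_id`, `dge_log2_ratio`,
#'   `qpcr_display`, `sign_concordant`, `qpcr_significant`) and summary
#'   fields `n_genes`, `n_sign_concordant`, `n_concordant_significant`,
#'   `n_nonsignificant`, `fraction_sign_concordant`.
#' @export
concordance <- function(dge, qpcr) {
  joined <- merge(dge[, c("gene_id", "log2_ratio")],
                  qpcr[, c("gene_id", "signed_display", "significant")],
                  by = "gene_id")
  if (nrow(joined) == 0) stop_domain("no shared genes between DGE and qPCR")
  tab <- data.frame(
    gene_id = joined$gene_id,
    dge_log2_ratio = joined$log2_ratio,
    qpcr_display = joined$signed_display,
    sign_concordant = sign(joined$log2_ratio) == sign(joined$signed_display),
    qpcr_significant = joined$significant,
    stringsAsFactors = FALSE)
  list(table = tab,
       n_genes = nrow(tab),
       n_sign_concordant = sum(tab$sign_concordant),
       n_concordant_significant = sum(tab$sign_concordant & tab$qpcr_significant),
       n_nonsignificant = sum(!tab$qpcr_significant),
       fraction_sign_concordant = mean(tab$sign_concordant))
}
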