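#' Paired differential expression testing
#'
#' Tests each gene for a nonzero mean within-pair log2 expression
#' difference (tumor minus matched normal) with the same empirical-Bayes
#' moderated paired t machinery as the methylation layer
#' ([moderated_paired_t()]), followed by Benjamini-Hochberg adjustment
#' across genes. Expression is assumed already normalized and log2-scaled.
#' Optional linear-scale fold-change gates (`< 0.7` or `> 1.5`) can be
#' switched on; by default only the FDR threshold applies.
#'
#' @param expression Genes x samples log2 expression matrix.
#' @param sheet Sample sheet defining pairing (`sample_id`, `pair_id`,
#'   `tissue`).
#' @param q_threshold FDR threshold for the DEG flag (default 0.05).
#' @param fc_gate If TRUE additionally require linear fold change
#'   `< fc_low` or `> fc_high`.
#' @param fc_low,fc_high Linear-scale fold-change gates (defaults 0.7 and
#'   1.5).
#' @return `data.frame` of class `dge_results`: `gene_symbol`, `log_fc`
#'   (mean paired log2 difference), `statistic`, `p`, `q`, `direction`
#'   (`up`/`down`), `deg` (logical).
#' @export
test_dge <- function(expression, sheet, q_threshold = 0.05,
                     fc_gate = FALSE, fc_low = 0.7, fc_high = 1.5) {
  if (anyDuplicated(rownames(expression))) {
    stop("duplicate gene symbols in expression matrix", call. = FALSE)
  }
  al <- align_pairs(expression, expression, sheet)
  if (ncol(al$hcc) < 3) stop("at least 3 pairs are required", call. = FALSE)
  fit <- moderated_paired_t(al$hcc, al$ntl)
  out <- data.frame(
    gene_symbol = rownames(expression),
    log_fc = fit$mean_diff,
    statistic = fit$statistic,
    p = fit$p,
    q = stats::p.adjust(fit$p, method = "BH"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$direction <- ifelse(out$log_fc > 0, "up", "down")
  out$deg <- out$q < q_threshold
  if (fc_gate) {
    fc <- 2^out$log_fc
    out$deg <- out$deg & (fc < fc_low | fc > fc_high)
  }
  class(out) <- c("dge_results", "data.frame")
  out
}
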