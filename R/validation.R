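#' Enrichment of signature genes for CRISPR essentiality
#'
#' Builds the 2x2 table {in signature, not in signature} x {essential,
#' non-essential}, where a gene is essential when its mean gene-effect score
#' across the provided cell lines is at or below `effect_thresh` (more
#' negative = stronger viability loss on knockout; -0.5 is the conventional
#' depletion bound). Tested with Pearson's chi-squared without continuity
#' correction.
#'
#' @param gene_effect Tibble with `gene` and either an `effect` column (mean
#'   score) or one numeric column per cell line (averaged).
#' @param signature_genes Genes of interest (e.g. high-VIP genes).
#' @param all_model_genes The gene universe the signature was drawn from;
#'   must be covered at >= 50% by `gene_effect` (uncovered genes are
#'   dropped).
#' @param effect_thresh Essentiality bound on the mean gene effect.
#' @return List of class `combiphen_enrichment`: `table` (2x2), `statistic`,
#'   `p_value`, `df`, `coverage`, `effect_thresh`.
#' @export
essentiality_enrichment <- function(gene_effect, signature_genes,
                                    all_model_genes, effect_thresh = -0.5) {
  gene_effect <- tibble::as_tibble(gene_effect)
  stopifnot("gene" %in% names(gene_effect))
  if ("effect" %in% names(gene_effect)) {
    eff <- setNames(gene_effect$effect, gene_effect$gene)
  } else {
    num <- vapply(gene_effect, is.numeric, logical(1))
    if (!any(num)) abort("gene_effect needs an `effect` column or per-line numeric columns.")
    eff <- setNames(rowMeans(as.matrix(gene_effect[num]), na.rm = TRUE),
                    gene_effect$gene)
  }
  covered <- intersect(all_model_genes, names(eff))
  coverage <- length(covered) / length(all_model_genes)
  if (coverage < 0.5) {
    abort(sprintf("gene-effect table covers only %.0f%% of model genes (need >= 50%%).",
                  100 * coverage))
  }
  in_sig <- covered %in% signature_genes
  essential <- eff[covered] <= effect_thresh
  tab <- table(factor(in_sig, c(TRUE, FALSE), c("signature", "other")),
               factor(essential, c(TRUE, FALSE), c("essential", "non_essential")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("a margin of the contingency table is empty; the test is undefined.")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  structure(list(table = tab, statistic = unname(ct$statistic),
                 p_value = ct$p.value, df = unname(ct$parameter),
                 coverage = coverage, effect_thresh = effect_thresh),
            class = "combiphen_enrichment")
}

#' @export
print.combiphen_enrichment <- function(x, ...) {
  cat(sprintf("Essentiality enrichment (gene effect <= %.2g): X^2 = %.2f, p = %.3g\n",
              x$effect_thresh, x$statistic, x$p_value))
  print(x$table)
  invisible(x)
}

#' Correlation between predicted and measured phenotypes
#'
#' Squared Pearson correlation with its t-test p-value, for validating model
#' predictions against independently measured rates.
#'
#' @param data Tibble of paired values (n >= 3).
#' @param predicted_col,measured_col Column names.
#' @return One-row tibble: `r`, `r_squared`, `p_value`, `n`.
#' @export
external_prediction_correlation <- function(data, predicted_col = "predicted",
                                            measured_col = "measured") {
  x <- data[[predicted_col]]; y <- data[[measured_col]]
  if (length(x) < 3) abort("need at least 3 paired samples.")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in predicted or measured values.")
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
                 p_value = ct$p.value, n = length(x))
}
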