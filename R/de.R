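#' Log2 counts-per-million normalisation
#'
#' `log2(count / library_size * 1e6 + pseudocount)`; with the default
#' pseudocount of 1 a zero count maps to 0 and doubling every count in a
#' sample leaves its CPM unchanged.
#'
#' @param counts Non-negative gene x sample matrix.
#' @param pseudocount Added on the CPM scale before the log.
#' @param method `"cpm"` divides by the total count; `"median_ratios"`
#'   additionally corrects the per-sample totals with DESeq-style
#'   median-of-ratios size factors, which removes the composition bias a few
#'   strongly regulated genes impose on every other gene's fold change.
#' @return Matrix of log2-CPM values, same dimnames.
#' @export
log_normalize <- function(counts, pseudocount = 1,
                          method = c("cpm", "median_ratios")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("counts must be non-negative.")
  libs <- colSums(counts)
  if (any(libs == 0)) abort("a sample has zero total counts.")
  if (method == "median_ratios") {
    sf <- median_ratio_factors(counts)
    libs <- mean(libs) * sf
  }
  log2(sweep(counts, 2, libs, "/") * 1e6 + pseudocount)
}

#' Median-of-ratios size factors
#'
#' Per-sample median of the ratio to the per-gene geometric mean, over genes
#' observed in every sample, rescaled to geometric mean 1.
#'
#' @param counts Gene x sample count matrix.
#' @return Numeric size factors, one per sample.
#' @export
median_ratio_factors <- function(counts) {
  counts <- as.matrix(counts)
  lg <- log(counts)
  lg[!is.finite(lg)] <- NA
  geo <- exp(rowMeans(lg))
  ok <- which(is.finite(geo) & geo > 0)
  if (length(ok) < 10) {
    # too few always-observed genes to estimate ratios; fall back to totals
    sf <- colSums(counts)
  } else {
    sf <- apply(counts[ok, , drop = FALSE], 2, function(cj) median(cj / geo[ok]))
  }
  sf / exp(mean(log(sf)))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement, via
#' `stats::p.adjust(method = "BH")`. Non-finite p-values propagate with a
#' warning.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.nan(p))) {
    warn("NaN p-values propagated through BH adjustment.")
    p[is.nan(p)] <- NA_real_
  }
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Two-group differential expression on log2-CPM
#'
#' A deliberately simple DE engine standing in for a full count model: the
#' per-gene log2 fold change is the mean log2-CPM difference; p-values come,
#' by default, from an empirical-Bayes moderated t-statistic
#' (`limma::lmFit`/`eBayes` on the log2-CPM matrix), which shares variance
#' information across genes — essential for power at n = 3 per side.
#' `method = "t"` gives an unmoderated per-gene t-test instead
#' (pooled-variance by default, which is well calibrated at small equal n;
#' `var_equal = FALSE` gives Welch). The same schema is produced by
#' [import_de_table()] for users with precomputed DESeq2-style results.
#'
#' @param counts Gene x sample count matrix.
#' @param samples Sample sheet covering the columns of `counts`.
#' @param group_a,group_b Condition labels (A vs B; `lfc > 0` means higher in
#'   A) or vectors of sample ids.
#' @param group_col Sample-sheet column holding the labels.
#' @param method `"moderated"` (default) or `"t"`.
#' @param var_equal For `method = "t"`: pooled-variance t (default) or Welch.
#' @param pseudocount Passed to [log_normalize()].
#' @return Tibble (`gene`, `lfc`, `p`, `q`, `contrast`). Genes with zero
#'   variance on both sides and equal means get p = 1.
#' @export
differential_expression <- function(counts, samples, group_a, group_b,
                                    group_col = "condition",
                                    method = c("moderated", "t"),
                                    var_equal = TRUE, pseudocount = 1) {
  method <- match.arg(method)
  pick <- function(g) {
    ids <- if (all(g %in% colnames(counts))) g
           else samples$sample_id[samples[[group_col]] %in% g]
    ids <- intersect(ids, colnames(counts))
    if (length(ids) < 2) abort("need at least 2 samples on each side of the contrast.")
    ids
  }
  ia <- pick(group_a); ib <- pick(group_b)
  lcpm <- log_normalize(counts[, c(ia, ib), drop = FALSE],
                        pseudocount = pseudocount, method = "median_ratios")
  a <- lcpm[, ia, drop = FALSE]; b <- lcpm[, ib, drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  if (method == "moderated") {
    des <- cbind(intercept = 1, ab = c(rep(1, n1), rep(0, n2)))
    fit <- suppressWarnings(limma::eBayes(limma::lmFit(lcpm, des), trend = TRUE))
    p <- fit$p.value[, "ab"]
    p[m1 == m2] <- 1
  } else {
    v1 <- matrixStats::rowVars(a); v2 <- matrixStats::rowVars(b)
    if (var_equal) {
      sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
      df <- rep(n1 + n2 - 2, length(se))
    } else {
      se <- sqrt(v1 / n1 + v2 / n2)
      df <- (v1 / n1 + v2 / n2)^2 /
        ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    }
    tstat <- (m1 - m2) / se
    p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
    p[se == 0 & abs(m1 - m2) < 1e-300] <- 1   # flat gene, no evidence
    p[se == 0 & abs(m1 - m2) >= 1e-300] <- 0
  }
  tibble::tibble(gene = rownames(lcpm), lfc = unname(m1 - m2), p = unname(p),
                 q = bh_adjust(unname(p)),
                 contrast = paste(paste(group_a, collapse = "|"), "vs",
                                  paste(group_b, collapse = "|")))
}

#' Validate and pass through an externally computed DE table
#'
#' Accepts precomputed per-gene results (e.g. from DESeq2) in the package's
#' DE schema; values are returned verbatim after validation.
#'
#' @param de Data frame with columns `gene`, `lfc`, `p`, `q` (and optionally
#'   `contrast`).
#' @param contrast Contrast label to attach if absent.
#' @return The validated tibble.
#' @export
import_de_table <- function(de, contrast = NULL) {
  de <- tibble::as_tibble(de)
  need <- c("gene", "lfc", "p", "q")
  if (!all(need %in% names(de))) {
    abort(paste0("DE table must have columns: ", paste(need, collapse = ", ")))
  }
  ok <- !is.na(de$p) & !is.na(de$q)
  if (any(de$p[ok] < 0 | de$p[ok] > 1) || any(de$q[ok] < 0 | de$q[ok] > 1)) {
    abort("p and q must lie in [0, 1].")
  }
  if (anyDuplicated(de$gene)) abort("duplicate gene ids in DE table.")
  if (!"contrast" %in% names(de)) de$contrast <- contrast %||% NA_character_
  de
}

#' Count differentially expressed genes
#'
#' Strict thresholds: `|lfc| > lfc_thresh` and `q < q_thresh`.
#'
#' @param de DE tibble.
#' @param lfc_thresh,q_thresh Thresholds.
#' @return Integer count.
#' @export
count_degs <- function(de, lfc_thresh = 1.5, q_thresh = 0.05) {
  sum(abs(de$lfc) > lfc_thresh & de$q < q_thresh, na.rm = TRUE)
}

#' Correlation between DEG burden and phenotypic response magnitude
#'
#' Ordinary least squares of the per-condition phenotypic response magnitude
#' on the per-condition DEG count.
#'
#' @param data Tibble with one row per condition.
#' @param deg_col,magnitude_col Column names.
#' @return One-row tibble: `r_squared`, `p_value` (slope test), `slope`,
#'   `intercept`, `n`.
#' @export
deg_phenotype_correlation <- function(data, deg_col = "degs",
                                      magnitude_col = "magnitude") {
  x <- data[[deg_col]]; y <- data[[magnitude_col]]
  if (length(x) < 3) abort("need at least 3 conditions.")
  if (sd(x) == 0) abort("DEG counts have zero variance.")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  tibble::tibble(r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 slope = sm$coefficients[2, 1],
                 intercept = sm$coefficients[1, 1],
                 n = length(x))
}
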