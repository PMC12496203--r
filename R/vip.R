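#' Variable Importance in Projection scores
#'
#' `VIP_j = sqrt( p * sum_a SSY_a w_ja^2 / sum_a SSY_a )` with unit-norm
#' weight columns, so the mean squared VIP is exactly 1 (`sum VIP^2 = p`).
#' Each gene's sign is the sign of the Pearson correlation between its
#' (standardized) column and the first-component scores.
#'
#' @param fit A [fit_pls1()] model.
#' @return Tibble: `gene`, `vip`, `sign` (-1, 0 or 1).
#' @export
vip_scores <- function(fit) {
  stopifnot(inherits(fit, "pls1_fit"))
  if (sum(fit$ssy) <= 0) abort("model explains no response variance; VIP undefined.")
  p <- length(fit$genes)
  w2 <- fit$W^2                           # columns already unit norm
  vip <- sqrt(p * drop(w2 %*% fit$ssy) / sum(fit$ssy))
  t1 <- fit$scores[, 1]
  cors <- suppressWarnings(as.numeric(cor(fit$x_std, t1)))
  cors[is.na(cors)] <- 0
  tibble::tibble(gene = fit$genes, vip = unname(vip), sign = sign(cors))
}

#' Extract a phenotype gene signature from VIP scores
#'
#' The top `n_each` genes by VIP among those positively correlated with the
#' model's first component, and likewise for negatively correlated genes.
#' Genes with zero correlation belong to neither list; ties are broken by
#' gene id.
#'
#' @param vip A [vip_scores()] tibble.
#' @param n_each Genes per side.
#' @param phenotype Optional label stored with the signature.
#' @return List of class `combiphen_signature`: `positive`, `negative`
#'   (character vectors, VIP-descending), `phenotype`, `shortfall`.
#' @export
extract_signature <- function(vip, n_each = 100, phenotype = NULL) {
  pick <- function(s) {
    vip %>% filter(.data$sign == s) %>%
      arrange(dplyr::desc(.data$vip), .data$gene) %>%
      head(n_each) %>% pull(.data$gene)
  }
  pos <- pick(1); neg <- pick(-1)
  structure(list(positive = pos, negative = neg, phenotype = phenotype,
                 shortfall = c(positive = max(0, n_each - length(pos)),
                               negative = max(0, n_each - length(neg)))),
            class = "combiphen_signature")
}

#' @export
print.combiphen_signature <- function(x, ...) {
  cat(sprintf("Gene signature%s: %d positive / %d negative genes\n",
              if (is.null(x$phenotype)) "" else paste0(" (", x$phenotype, ")"),
              length(x$positive), length(x$negative)))
  invisible(x)
}

#' Select the most variable genes
#'
#' For abundance-scale input (all gene means positive) a local-regression
#' (loess) trend of log10 gene variance against log10 gene mean gives each
#' gene a trend-expected sd; values standardized by that sd are clipped at
#' `sqrt(n_samples)` and genes ranked by the variance of the clipped
#' standardized values — the variance-stabilising ranking popularised for
#' single-cell feature selection, which removes the technical mean-variance
#' relationship of expression data. For signed input such as log fold
#' changes, where the mean is itself biological signal and a mean trend would
#' absorb it, genes are ranked by their variance of values clipped at
#' `mean +/- sqrt(n) * sd` instead.
#'
#' @param expr Sample x gene numeric matrix.
#' @param n Number of genes to return (all, if fewer are available).
#' @param span Loess span for the abundance-scale trend.
#' @return Character vector of gene ids, ranked.
#' @export
select_variable_genes <- function(expr, n = 2500, span = 0.3) {
  x <- as.matrix(expr)
  if (is.null(colnames(x))) colnames(x) <- sprintf("x%04d", seq_len(ncol(x)))
  mu <- colMeans(x)
  v <- matrixStats::colVars(x)
  if (all(v == 0)) abort("constant matrix: no variable genes.")
  use <- v > 0
  clip <- sqrt(nrow(x))
  if (all(mu[use] > 0)) {
    xm <- log10(mu[use])
    fit <- loess(log10(v[use]) ~ xm, span = span, degree = 2,
                 control = stats::loess.control(surface = "direct"))
    sd_exp <- sqrt(10^predict(fit, xm))
    z <- sweep(sweep(x[, use, drop = FALSE], 2, mu[use]), 2, sd_exp, "/")
    z <- pmin(pmax(z, -clip), clip)
    score <- matrixStats::colVars(z)
  } else {
    sdv <- sqrt(v[use])
    xc <- x[, use, drop = FALSE]
    xc <- sweep(xc, 2, mu[use] + clip * sdv, FUN = pmin)
    xc <- sweep(xc, 2, mu[use] - clip * sdv, FUN = pmax)
    score <- matrixStats::colVars(xc)
  }
  ranked <- colnames(x)[use][order(-score, colnames(x)[use])]
  head(ranked, n)
}

#' Predict a phenotype for external expression profiles
#'
#' External log2 expression is restricted to the model's genes, z-scored
#' within the external dataset (gene-wise), with model genes absent from the
#' external data imputed as 0 (the post-scaling mean); predictions are the
#' standardized regression vector applied to these z-scores, returned on the
#' model's response scale.
#'
#' @param fit A [fit_pls1()] model.
#' @param external Sample x gene log2 expression matrix (column names = gene
#'   ids; rownames used as sample labels).
#' @param min_overlap Warn when the fraction of model genes present falls
#'   below this.
#' @return Tibble: `sample`, `predicted`. Attribute `overlap` records the
#'   fraction of model genes found.
#' @export
predict_phenotype <- function(fit, external, min_overlap = 0.5) {
  stopifnot(inherits(fit, "pls1_fit"))
  external <- as.matrix(external)
  if (is.null(colnames(external))) abort("external matrix needs gene column names.")
  common <- intersect(fit$genes, colnames(external))
  overlap <- length(common) / length(fit$genes)
  if (length(common) == 0) abort("no overlap between external genes and model genes.")
  if (overlap < min_overlap) {
    warn(sprintf("only %.0f%% of model genes present in the external data.",
                 100 * overlap))
  }
  z <- matrix(0, nrow(external), length(fit$genes),
              dimnames = list(rownames(external), fit$genes))
  sub <- external[, common, drop = FALSE]
  mu <- colMeans(sub)
  sdv <- matrixStats::colSds(sub)
  sdv[sdv == 0] <- 1
  z[, common] <- sweep(sweep(sub, 2, mu), 2, sdv, "/")
  pred <- drop(fit$y_center + fit$y_scale * (z %*% fit$beta_std))
  out <- tibble::tibble(sample = rownames(external) %||%
                          sprintf("s%03d", seq_len(nrow(external))),
                        predicted = pred)
  attr(out, "overlap") <- overlap
  out
}
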