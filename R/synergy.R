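#' Additive (null) prediction of combination expression
#'
#' Under the additive null the log2 fold change (vs T0) of a gene in a
#' combination equals the sum of its single-ligand fold changes. The fit is
#' restricted to genes upregulated (`lfc > lfc_filter`) in at least one
#' constituent single, and summarised by the R-squared of an OLS of observed
#' on predicted combination LFC.
#'
#' @param singles Named list of single-ligand DE tibbles (vs T0).
#' @param combo Combination DE tibble (vs T0), same gene universe.
#' @param lfc_filter Single-ligand LFC filter.
#' @return List of class `combiphen_additivity`: `data` (tibble `gene`,
#'   `predicted`, `observed`), `r_squared`, `p_value`, `n`, `lfc_filter`.
#' @export
additive_prediction <- function(singles, combo, lfc_filter = 0.5) {
  stopifnot(is.list(singles), length(singles) >= 2)
  genes <- combo$gene
  for (s in singles) {
    if (!identical(sort(s$gene), sort(genes))) {
      abort("single and combination DE tables must share the same gene universe.")
    }
  }
  lfc_s <- vapply(singles, function(s) s$lfc[match(genes, s$gene)],
                  numeric(length(genes)))
  keep <- rowSums(lfc_s > lfc_filter) >= 1
  if (!any(keep)) abort("no genes pass the single-ligand LFC filter.")
  predicted <- rowSums(lfc_s[keep, , drop = FALSE])
  observed <- combo$lfc[keep]
  fit <- lm(observed ~ predicted)
  sm <- summary(fit)
  structure(list(data = tibble::tibble(gene = genes[keep], predicted = predicted,
                                       observed = observed),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = sum(keep), lfc_filter = lfc_filter),
            class = "combiphen_additivity")
}

#' @export
print.combiphen_additivity <- function(x, ...) {
  cat(sprintf("Additive-null fit: n = %d genes (single LFC > %.2g), R^2 = %.3f, p = %.3g\n",
              x$n, x$lfc_filter, x$r_squared, x$p_value))
  invisible(x)
}

#' Call synergistic genes under the Highest Single Agent rule
#'
#' A gene is positively synergistic when its combination expression exceeds
#' *each* constituent single-ligand condition by more than `lfc_thresh` log2
#' units with adjusted p < alpha in every contrast; negatively synergistic
#' when below each single by more than `lfc_thresh`. All inequalities are
#' strict; the classes are mutually exclusive. With three contrasts the rule
#' extends to the triple combination.
#'
#' @param de_vs_singles Named list of combination-vs-single DE tibbles (names
#'   = single-ligand labels), computed on the same genes.
#' @param lfc_thresh Log2 threshold.
#' @param alpha Adjusted-p threshold.
#' @return Tibble: `gene`, `class` (`"positive"`/`"negative"`/`"none"`), plus
#'   `lfc_vs_<single>` and `q_vs_<single>` columns.
#' @export
call_synergistic_genes <- function(de_vs_singles, lfc_thresh = 1.5, alpha = 0.05) {
  stopifnot(is.list(de_vs_singles), length(de_vs_singles) >= 2,
            !is.null(names(de_vs_singles)))
  genes <- de_vs_singles[[1]]$gene
  for (s in de_vs_singles) {
    if (!identical(sort(s$gene), sort(genes))) {
      abort("combination-vs-single DE tables must share the same gene universe.")
    }
  }
  lfc <- vapply(de_vs_singles, function(s) s$lfc[match(genes, s$gene)],
                numeric(length(genes)))
  q <- vapply(de_vs_singles, function(s) s$q[match(genes, s$gene)],
              numeric(length(genes)))
  sig <- q < alpha
  pos <- rowSums(lfc > lfc_thresh & sig) == ncol(lfc)
  neg <- rowSums(lfc < -lfc_thresh & sig) == ncol(lfc)
  out <- tibble::tibble(gene = genes,
                        class = case_when(pos ~ "positive", neg ~ "negative",
                                          TRUE ~ "none"))
  for (nm in names(de_vs_singles)) {
    out[[paste0("lfc_vs_", nm)]] <- lfc[, nm]
    out[[paste0("q_vs_", nm)]] <- q[, nm]
  }
  out
}

#' Overlap of synergy-call gene sets across combinations
#'
#' Exact intersection cardinalities for every subset of the provided call
#' sets (pairwise, three-way, ...).
#'
#' @param calls Named list of [call_synergistic_genes()] tibbles or character
#'   gene vectors.
#' @param class Synergy class to extract when tibbles are given.
#' @return Tibble: `sets` (labels joined by " & "), `size` (number of sets in
#'   the intersection), `n` (cardinality of the intersection).
#' @export
synergy_overlap <- function(calls, class = "positive") {
  stopifnot(length(calls) >= 2, !is.null(names(calls)))
  sets <- lapply(calls, function(x) {
    if (is.data.frame(x)) x$gene[x$class == class] else as.character(x)
  })
  nm <- names(sets)
  out <- list()
  for (size in seq(2, length(sets))) {
    for (idx in as.data.frame(utils::combn(seq_along(sets), size))) {
      inter <- Reduce(intersect, sets[idx])
      out[[length(out) + 1]] <- tibble::tibble(
        sets = paste(nm[idx], collapse = " & "),
        size = size, n = length(inter))
    }
  }
  dplyr::bind_rows(out)
}
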