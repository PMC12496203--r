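#' Plot an MSD curve
#'
#' @param object A [compute_msd()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot combiphen_msd
#' @export
autoplot.combiphen_msd <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$msd)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "lag (h)", y = expression(MSD ~ (px^2))) +
    ggplot2::theme_minimal()
}

#' Plot a leave-one-out RRMSEP curve
#'
#' The chosen number of components (elbow rule) is marked; the dashed line
#' at 1 is the no-skill reference.
#'
#' @param object A [loo_rrmsep_select()] result.
#' @param ... Unused.
#' @method autoplot rrmsep_curve
#' @export
autoplot.rrmsep_curve <- function(object, ...) {
  chosen <- attr(object, "chosen")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ncomp, y = .data$rrmsep)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = object[object$ncomp == chosen, ],
                        colour = "firebrick", size = 3) +
    ggplot2::labs(x = "components", y = "RRMSEP") +
    ggplot2::theme_minimal()
}

#' Plot the gap-statistic curve of a module clustering
#'
#' @param object A [cluster_gene_modules()] result.
#' @param ... Unused.
#' @method autoplot combiphen_modules
#' @export
autoplot.combiphen_modules <- function(object, ...) {
  if (is.null(object$gap_curve)) abort("degenerate clustering has no gap curve.")
  ggplot2::ggplot(object$gap_curve, ggplot2::aes(x = .data$k, y = .data$gap)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$gap - .data$se,
                                        ymax = .data$gap + .data$se),
                           width = 0.15, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = 2, colour = "firebrick") +
    ggplot2::labs(x = "K", y = "Gap(K)") +
    ggplot2::theme_minimal()
}

#' Scatterplot of an additive-null fit
#'
#' Observed combination LFC against the sum of the single-ligand LFCs, with
#' the identity line.
#'
#' @param object An [additive_prediction()] result.
#' @param ... Unused.
#' @method autoplot combiphen_additivity
#' @export
autoplot.combiphen_additivity <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$predicted, y = .data$observed)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "firebrick") +
    ggplot2::labs(x = "additive prediction (sum of single-ligand LFC)",
                  y = "observed combination LFC",
                  subtitle = sprintf("R² = %.2f, n = %d", object$r_squared, object$n)) +
    ggplot2::theme_minimal()
}

#' HSA synergy scatterplot for one combination
#'
#' Combination-vs-single LFCs on the two axes, coloured by synergy class.
#'
#' @param calls A [call_synergistic_genes()] tibble with exactly two
#'   `lfc_vs_*` columns.
#' @return A ggplot.
#' @export
plot_synergy <- function(calls) {
  lfc_cols <- grep("^lfc_vs_", names(calls), value = TRUE)
  if (length(lfc_cols) != 2) abort("plot_synergy() needs a pairwise (two-single) call table.")
  ggplot2::ggplot(calls, ggplot2::aes(x = .data[[lfc_cols[1]]],
                                      y = .data[[lfc_cols[2]]],
                                      colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(positive = "forestgreen",
                                            negative = "darkorange",
                                            none = "grey70")) +
    ggplot2::labs(x = sub("lfc_vs_", "LFC vs ", lfc_cols[1]),
                  y = sub("lfc_vs_", "LFC vs ", lfc_cols[2])) +
    ggplot2::theme_minimal()
}
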