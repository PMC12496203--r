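#' Tidy a PLS1 fit
#'
#' One row per predictor with the standardized regression coefficient and
#' (optionally precomputed) VIP score.
#'
#' @param x A [fit_pls1()] object.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate` (standardized beta), `vip`, `sign`.
#' @export
tidy.pls1_fit <- function(x, ...) {
  v <- vip_scores(x)
  tibble::tibble(term = x$genes, estimate = unname(x$beta_std),
                 vip = v$vip, sign = v$sign)
}

#' Glance at a PLS1 fit
#'
#' @param x A [fit_pls1()] object.
#' @param ... Unused.
#' @return One-row tibble: `ncomp`, `r_squared` (in-sample), `n`, `p`.
#' @export
glance.pls1_fit <- function(x, ...) {
  tibble::tibble(ncomp = x$ncomp,
                 r_squared = 1 - sum((x$y - x$fitted)^2) / sum((x$y - mean(x$y))^2),
                 n = length(x$y), p = length(x$genes))
}

#' Tidy an additive-null fit
#'
#' @param x An [additive_prediction()] object.
#' @param ... Unused.
#' @return Per-gene tibble: `gene`, `predicted`, `observed`, `residual`.
#' @export
tidy.combiphen_additivity <- function(x, ...) {
  x$data %>% mutate(residual = .data$observed - .data$predicted)
}

#' Glance at an additive-null fit
#'
#' @param x An [additive_prediction()] object.
#' @param ... Unused.
#' @return One-row tibble: `r_squared`, `p_value`, `n`, `lfc_filter`.
#' @export
glance.combiphen_additivity <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, p_value = x$p_value, n = x$n,
                 lfc_filter = x$lfc_filter)
}

#' Tidy an essentiality-enrichment result
#'
#' @param x An [essentiality_enrichment()] object.
#' @param ... Unused.
#' @return Long tibble of the 2x2 table counts.
#' @export
tidy.combiphen_enrichment <- function(x, ...) {
  as.data.frame(x$table) %>%
    tibble::as_tibble() %>%
    rlang::set_names(c("membership", "essentiality", "n"))
}

#' Glance at an essentiality-enrichment result
#'
#' @param x An [essentiality_enrichment()] object.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `p_value`, `df`, `coverage`.
#' @export
glance.combiphen_enrichment <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value, df = x$df,
                 coverage = x$coverage)
}
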