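# base-R fast path: these summaries sit inside Monte-Carlo calibration loops
group_summaries <- function(data, value, group) {
  v <- data[[value]]
  g <- as.character(data[[group]])
  if (any(!is.finite(v))) abort("metric values must be finite.")
  parts <- split(v, g)
  tibble::new_tibble(list(
    group = names(parts),
    n = unname(lengths(parts)),
    mean = unname(vapply(parts, mean, numeric(1))),
    var = unname(vapply(parts, function(x)
      if (length(x) > 1) var(x) else NA_real_, numeric(1)))),
    nrow = length(parts))
}

#' Classical one-way ANOVA
#'
#' Computed directly from group sums of squares (cross-checked against
#' `stats::aov` in the test suite). When every group has zero within-group
#' variance and equal means the statistic is defined as 0 with p = 1.
#'
#' @param data Long tibble of replicate values.
#' @param value,group Column names (character) of the metric and grouping.
#' @return One-row tibble: `statistic` (F), `p_value`, `df_between`,
#'   `df_within`.
#' @export
one_way_anova <- function(data, value = "value", group = "condition") {
  s <- group_summaries(data, value, group)
  if (nrow(s) < 2) abort("need at least 2 groups.")
  if (any(s$n < 2)) abort("every group needs n >= 2.")
  N <- sum(s$n)
  gm <- sum(s$n * s$mean) / N
  ssb <- sum(s$n * (s$mean - gm)^2)
  ssw <- sum((s$n - 1) * s$var)
  dfb <- nrow(s) - 1
  dfw <- N - nrow(s)
  if (ssw <= 0 && ssb <= 1e-300) {
    f <- 0; p <- 1
  } else if (ssw <= 0) {
    f <- Inf; p <- 0
  } else {
    f <- (ssb / dfb) / (ssw / dfw)
    p <- pf(f, dfb, dfw, lower.tail = FALSE)
  }
  tibble::tibble(statistic = f, p_value = p, df_between = dfb, df_within = dfw)
}

#' Tukey honest-significant-difference pairwise comparisons
#'
#' Studentized-range adjusted p-values computed from group summaries with the
#' Tukey-Kramer standard error (cross-checked against `stats::TukeyHSD`).
#' Under the global null the family-wise error over all pairs is at most
#' alpha.
#'
#' @inheritParams one_way_anova
#' @return Tibble with one row per unordered pair: `group1`, `group2`,
#'   `estimate` (mean difference group2 - group1) and `p_adj`.
#' @export
tukey_hsd <- function(data, value = "value", group = "condition") {
  s <- group_summaries(data, value, group)
  if (nrow(s) < 2) abort("need at least 2 groups.")
  if (any(s$n < 2)) abort("Tukey HSD requires n >= 2 in every group.")
  k <- nrow(s)
  dfw <- sum(s$n) - k
  mse <- sum((s$n - 1) * s$var) / dfw
  pairs <- utils::combn(seq_len(k), 2)
  g1 <- s$group[pairs[1, ]]; g2 <- s$group[pairs[2, ]]
  diff <- s$mean[pairs[2, ]] - s$mean[pairs[1, ]]
  se <- sqrt(mse / 2 * (1 / s$n[pairs[1, ]] + 1 / s$n[pairs[2, ]]))
  q <- abs(diff) / se
  p <- ifelse(se == 0, ifelse(abs(diff) < 1e-300, 1, 0),
              ptukey(q, k, dfw, lower.tail = FALSE))
  tibble::new_tibble(list(group1 = g1, group2 = g2, estimate = unname(diff),
                          p_adj = unname(pmin(p, 1))), nrow = length(g1))
}

#' Dunnett many-to-one comparisons against a control group
#'
#' Adjusted p-values from the multivariate-t reference distribution
#' (via `multcomp::glht`, whose quantiles are computed by quasi-Monte-Carlo;
#' the seed fixes them).
#'
#' @inheritParams one_way_anova
#' @param control Control group label.
#' @param seed Seed for the multivariate-t quantile computation.
#' @return Tibble: `group`, `estimate` (group - control), `p_adj`.
#' @export
dunnett_vs_control <- function(data, value = "value", group = "condition",
                               control, seed = 1) {
  g <- as.character(data[[group]])
  if (!control %in% g) abort(sprintf("control group '%s' not present.", control))
  df <- data.frame(y = data[[value]],
                   g = stats::relevel(factor(g), ref = control))
  s <- group_summaries(data, value, group)
  scale2 <- 1 + mean(data[[value]])^2
  if (all(s$var < 1e-20 * scale2, na.rm = TRUE)) {
    # zero within-group variance: equality of means decides directly
    trt <- setdiff(s$group, control)
    est <- s$mean[match(trt, s$group)] - s$mean[s$group == control]
    return(tibble::tibble(group = trt, estimate = est,
                          p_adj = ifelse(abs(est) < sqrt(1e-20 * scale2), 1, 0)))
  }
  fit <- aov(y ~ g, data = df)
  set.seed(seed)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  sm <- summary(gl)
  lab <- sub(" - .*$", "", names(sm$test$coefficients))
  est <- as.numeric(sm$test$coefficients)
  p <- as.numeric(sm$test$pvalues)
  # zero residual variance: no evidence against equality unless means differ
  p[!is.finite(p)] <- ifelse(abs(est[!is.finite(p)]) < 1e-300, 1, 0)
  tibble::tibble(group = lab, estimate = est, p_adj = p)
}

#' Classify a combination phenotype as emergent under the HSA rule
#'
#' Under the Highest Single Agent expectation a combination should match the
#' best constituent single ligand. The combination is called emergent when
#' its metric differs significantly (Tukey-adjusted p < alpha) from *each*
#' constituent single-ligand condition. The HSA expectation (the most extreme
#' single-ligand mean on the side the combination deviates towards) is
#' reported but does not enter the call.
#'
#' @param data Long tibble of replicate metric values covering the
#'   combination and its singles (extra groups, if present, enlarge the Tukey
#'   family).
#' @param combination Combination condition label.
#' @param singles Labels of the constituent single-ligand conditions; default
#'   parsed from `combination`.
#' @param value,group Column names.
#' @param alpha Significance level (strict inequality).
#' @return One-row tibble: `combination`, `emergent`, `direction`
#'   (`"above"`/`"below"`/`"within"` the single-ligand envelope),
#'   `hsa_expected`, `p_max` (largest adjusted p vs a single) and a
#'   list-column `p_vs_single` (named vector).
#' @export
classify_emergent <- function(data, combination, singles = NULL,
                              value = "value", group = "condition",
                              alpha = 0.05) {
  singles <- singles %||% condition_ligands(combination)
  g <- as.character(data[[group]])
  missing <- setdiff(c(combination, singles), g)
  if (length(missing)) {
    abort(paste0("conditions missing from data: ", paste(missing, collapse = ", ")))
  }
  tk <- tukey_hsd(data, value = value, group = group)
  p_each <- vapply(singles, function(sg) {
    hit <- (tk$group1 == combination & tk$group2 == sg) |
      (tk$group2 == combination & tk$group1 == sg)
    tk$p_adj[hit][1]
  }, numeric(1))
  s <- group_summaries(data, value, group)
  m_combo <- s$mean[s$group == combination]
  m_singles <- s$mean[match(singles, s$group)]
  direction <- if (m_combo > max(m_singles)) "above"
               else if (m_combo < min(m_singles)) "below"
               else "within"
  hsa <- switch(direction, above = max(m_singles), below = min(m_singles),
                within = max(m_singles))
  tibble::new_tibble(list(combination = combination,
                          emergent = all(p_each < alpha),
                          direction = direction,
                          hsa_expected = unname(hsa),
                          p_max = max(p_each),
                          p_vs_single = list(p_each)), nrow = 1L)
}

#' Emergence calls for every combination and phenotype metric
#'
#' Convenience wrapper running [classify_emergent()] for each combination
#' condition and each metric column of a per-replicate phenotype table. Each
#' call uses only the combination and its constituent singles as the Tukey
#' family (replicates are the experimental units).
#'
#' @param phenotypes Tibble from [summarize_phenotypes()].
#' @param metric_cols Metric columns to scan.
#' @param combinations Combination labels; default all in the table.
#' @param alpha Significance level.
#' @return Tibble with one row per combination x metric.
#' @export
emergence_scan <- function(phenotypes,
                           metric_cols = c("count_fc", "motility",
                                           "nn_ratio", "cyto_area"),
                           combinations = NULL, alpha = 0.05) {
  combinations <- combinations %||%
    intersect(combination_conditions(), unique(phenotypes$condition))
  out <- list()
  for (combo in combinations) {
    singles <- condition_ligands(combo)
    sub <- phenotypes %>% filter(.data$condition %in% c(combo, singles))
    for (m in metric_cols) {
      call <- classify_emergent(sub, combo, singles, value = m,
                                group = "condition", alpha = alpha)
      out[[paste(combo, m)]] <- call %>% mutate(metric = m, .after = "combination")
    }
  }
  dplyr::bind_rows(out)
}
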