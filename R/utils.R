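#' Derive a deterministic child seed from a master seed
#'
#' Every stochastic stage draws from its own stream so that adding or removing
#' one stage never perturbs another. Child seeds are a fixed integer hash of
#' the master seed and a stream label, kept strictly below 2^31.
#'
#' @param seed Master seed (integer).
#' @param key Stream label (character scalar).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(key))
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(((abs(seed) %% 1000003) * 2011 + h) %% 2147483647)
}

check_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_min && x <= min) abort(sprintf("`%s` must be > %s.", name, min))
  if (!strict_min && x < min) abort(sprintf("`%s` must be >= %s.", name, min))
  invisible(x)
}

# canonical treatment panel: vehicle, three single ligands, pairs, triple
#' Treatment conditions of the standard ligand panel
#'
#' @param include_t0 Also include the pre-treatment `"T0"` label.
#' @return Character vector of condition labels.
#' @export
panel_conditions <- function(include_t0 = FALSE) {
  conds <- c("PBS", "EGF", "OSM", "TGFB",
             "EGF+OSM", "EGF+TGFB", "OSM+TGFB", "EGF+OSM+TGFB")
  if (include_t0) c("T0", conds) else conds
}

#' Constituent single ligands of a condition label
#'
#' @param condition Condition label, e.g. `"EGF+OSM"`.
#' @return Character vector of ligand names (empty for PBS/T0).
#' @export
condition_ligands <- function(condition) {
  stopifnot(is.character(condition), length(condition) == 1)
  if (condition %in% c("PBS", "T0")) return(character(0))
  strsplit(condition, "+", fixed = TRUE)[[1]]
}

#' Pairwise and higher combination conditions of a panel
#' @param conditions Condition labels.
#' @return Labels containing more than one ligand.
#' @export
combination_conditions <- function(conditions = panel_conditions()) {
  conditions[vapply(conditions, function(cc) length(condition_ligands(cc)) > 1, logical(1))]
}
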