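#' Default sample sheet for the count simulator
#'
#' T0 (pre-treatment) plus the full treatment panel, each with `n_replicates`
#' replicates harvested at 24 h.
#'
#' @param n_replicates Replicates per condition.
#' @return Tibble with `sample_id`, `condition`, `replicate`, `timepoint`.
#' @export
default_count_design <- function(n_replicates = 3) {
  conds <- panel_conditions(include_t0 = TRUE)
  tidyr::expand_grid(condition = conds, replicate = seq_len(n_replicates)) %>%
    mutate(sample_id = sprintf("%s_r%d", .data$condition, .data$replicate),
           timepoint = ifelse(.data$condition == "T0", 0, 24)) %>%
    select("sample_id", "condition", "replicate", "timepoint")
}

#' Parameters for the negative-binomial count simulator
#'
#' Expression follows an additive log2 model: the mean of gene g in condition
#' c is `library_size * 2^(baseline_g + sum of the single-ligand effects of
#' the ligands in c + synergy term)`, with counts drawn negative-binomially
#' (`variance = mu + dispersion * mu^2`). The synergy term is zero except for
#' genes listed in `synergy_sets` for that combination, which receive an extra
#' log2 shift beyond the additive expectation.
#'
#' @param n_genes Number of genes.
#' @param baseline_log2_mean Per-gene baseline log2 mean; `NULL` draws
#'   `N(5, 2)` at simulation time (deterministic given the seed).
#' @param dispersion Per-gene NB dispersion (scalar recycled); must be > 0,
#'   or 0 for the Poisson limit.
#' @param single_ligand_effects `n_genes x 3` matrix of log2 fold changes with
#'   columns `EGF`, `OSM`, `TGFB`; `NULL` draws sparse random effects.
#' @param responsive_fraction Named fractions of genes perturbed by each
#'   ligand when effects are drawn (EGF strongest, TGFB weakest, mirroring the
#'   transcriptional footprint hierarchy this generator emulates).
#' @param effect_sd SD of drawn non-zero log2 effects.
#' @param synergy_sets Named list (by combination condition) of data frames
#'   with columns `gene` (index or id) and `extra_log2`.
#' @param library_size Per-sample scale factor (> 0, scalar recycled).
#' @param n_replicates Replicates per condition for the default design.
#' @return A list of class `count_sim_params`.
#' @export
count_sim_params <- function(n_genes = 10000,
                             baseline_log2_mean = NULL,
                             dispersion = 0.05,
                             single_ligand_effects = NULL,
                             responsive_fraction = c(EGF = 0.12, OSM = 0.08, TGFB = 0.03),
                             effect_sd = 1.5,
                             synergy_sets = list(),
                             library_size = 20,
                             n_replicates = 3) {
  check_scalar_number(n_genes, "n_genes", 1)
  if (any(dispersion < 0) || any(!is.finite(dispersion))) abort("`dispersion` must be >= 0.")
  if (any(library_size <= 0)) abort("`library_size` must be > 0.")
  structure(list(n_genes = as.integer(n_genes),
                 baseline_log2_mean = baseline_log2_mean,
                 dispersion = dispersion,
                 single_ligand_effects = single_ligand_effects,
                 responsive_fraction = responsive_fraction,
                 effect_sd = effect_sd,
                 synergy_sets = synergy_sets,
                 library_size = library_size,
                 n_replicates = n_replicates),
            class = "count_sim_params")
}

gene_ids <- function(n) sprintf("g%05d", seq_len(n))

# resolve synergy gene references (indices or ids) to ids
resolve_synergy_sets <- function(synergy_sets, genes) {
  lapply(synergy_sets, function(s) {
    s <- as.data.frame(s)
    stopifnot(all(c("gene", "extra_log2") %in% names(s)))
    g <- if (is.numeric(s$gene)) genes[s$gene] else as.character(s$gene)
    if (any(is.na(g)) || !all(g %in% genes)) {
      abort("synergy genes must be a subset of the gene universe.")
    }
    tibble::tibble(gene = g, extra_log2 = s$extra_log2)
  })
}

#' Simulate gene x sample negative-binomial counts under an additive model
#'
#' @param params A [count_sim_params()] object.
#' @param design Sample sheet (`sample_id`, `condition`, `replicate`); default
#'   [default_count_design()]. Any combination condition present must have all
#'   its constituent single-ligand conditions in the design.
#' @param seed Master seed.
#' @return List with `counts` (integer matrix, genes x samples), `samples`
#'   (the design tibble) and `truth` (baseline, effect matrix, synergy sets,
#'   dispersion).
#' @export
simulate_counts <- function(params = count_sim_params(), design = NULL, seed = 1) {
  stopifnot(inherits(params, "count_sim_params"))
  if (is.null(design)) design <- default_count_design(params$n_replicates)
  design <- tibble::as_tibble(design)
  stopifnot(all(c("sample_id", "condition", "replicate") %in% names(design)))
  for (cc in unique(design$condition)) {
    lig <- condition_ligands(cc)
    if (length(lig) > 1 && !all(lig %in% design$condition)) {
      abort(sprintf(
        "design contains combination '%s' without all constituent single-ligand conditions.", cc))
    }
  }
  ng <- params$n_genes
  genes <- gene_ids(ng)
  set.seed(derive_seed(seed, "counts-baseline"))
  base <- params$baseline_log2_mean %||% rnorm(ng, 5, 2)
  stopifnot(length(base) == ng)
  eff <- params$single_ligand_effects
  if (is.null(eff)) {
    set.seed(derive_seed(seed, "counts-effects"))
    eff <- matrix(0, ng, 3, dimnames = list(genes, c("EGF", "OSM", "TGFB")))
    for (lg in colnames(eff)) {
      idx <- sample(ng, round(params$responsive_fraction[[lg]] * ng))
      eff[idx, lg] <- rnorm(length(idx), 0, params$effect_sd)
    }
  } else {
    eff <- as.matrix(eff)
    stopifnot(nrow(eff) == ng, all(c("EGF", "OSM", "TGFB") %in% colnames(eff)))
    rownames(eff) <- genes
  }
  syn <- resolve_synergy_sets(params$synergy_sets, genes)
  disp <- rep_len(params$dispersion, ng)
  libsize <- rep_len(params$library_size, nrow(design))
  counts <- matrix(0L, ng, nrow(design), dimnames = list(genes, design$sample_id))
  for (j in seq_len(nrow(design))) {
    cc <- design$condition[j]
    lig <- condition_ligands(cc)
    log2mu <- base
    if (length(lig)) log2mu <- log2mu + rowSums(eff[, lig, drop = FALSE])
    if (cc %in% names(syn)) {
      s <- syn[[cc]]
      log2mu[match(s$gene, genes)] <- log2mu[match(s$gene, genes)] + s$extra_log2
    }
    mu <- libsize[j] * 2^log2mu
    set.seed(derive_seed(seed, paste("counts-sample", design$sample_id[j])))
    # dispersion 0 is the Poisson limit; a huge size parameter realises it
    counts[, j] <- rnbinom(ng, mu = mu, size = 1 / pmax(disp, 1e-12))
  }
  storage.mode(counts) <- "integer"
  truth <- list(baseline_log2_mean = setNames(base, genes),
                single_ligand_effects = eff,
                synergy_sets = syn,
                dispersion = setNames(disp, genes),
                library_size = setNames(libsize, design$sample_id),
                seed = seed)
  list(counts = counts, samples = design, truth = truth)
}
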