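#' Coupling parameters for the linked track/expression experiment
#'
#' The linked generator plants a rank-one "driver program": a set of driver
#' genes whose ligand effects are proportional to a latent per-condition
#' activity score (the sum of the ligand weights present in the condition,
#' times a per-gene loading). Each replicate's phenotype metric is a linear
#' function of the realised replicate-level log2 fold changes of the driver
#' genes plus Gaussian noise, so expression and phenotype share biological
#' (replicate-to-replicate) variation.
#'
#' @param n_drivers Number of driver genes.
#' @param loading_range Range of the uniform positive per-driver loadings.
#' @param ligand_weights Latent activity contributed by each ligand.
#' @param snr Signal-to-noise ratio (sd of the phenotypic signal over the
#'   noise sd); `Inf` gives noiseless phenotypes.
#' @param metric_base Baseline value of each phenotype metric (PBS-like).
#' @param metric_coef Per-metric sign/strength multiplier of the driver signal
#'   (negative for the neighbour ratio: the driver program tightens packing).
#' @param slope Relative phenotype change per unit driver signal.
#' @param beta_scale Global multiplier on the expression-phenotype coupling;
#'   0 decouples phenotype from expression entirely.
#' @param noise_sd Optional fixed per-metric noise sd (named vector),
#'   overriding the SNR-derived value.
#' @return List of class `linked_coupling`.
#' @export
linked_coupling <- function(n_drivers = 50,
                            loading_range = c(1, 2),
                            ligand_weights = c(EGF = 1.2, OSM = 0.8, TGFB = 0.4),
                            snr = 3,
                            metric_base = c(count_fc = 2, motility = 200,
                                            nn_ratio = 1, cyto_area = 450),
                            metric_coef = c(count_fc = 1, motility = 1,
                                            nn_ratio = -0.5, cyto_area = 0.6),
                            slope = 0.004,
                            beta_scale = 1,
                            noise_sd = NULL) {
  structure(list(n_drivers = n_drivers, loading_range = loading_range,
                 ligand_weights = ligand_weights, snr = snr,
                 metric_base = metric_base, metric_coef = metric_coef,
                 slope = slope, beta_scale = beta_scale, noise_sd = noise_sd),
            class = "linked_coupling")
}

# per-replicate LFC vs the mean T0 log2-CPM profile
replicate_lfc <- function(counts, samples, pseudocount = 1) {
  lcpm <- log_normalize(counts, pseudocount = pseudocount)
  t0 <- samples$sample_id[samples$condition == "T0"]
  if (!length(t0)) abort("design has no T0 samples to reference LFCs against.")
  ref <- rowMeans(lcpm[, t0, drop = FALSE])
  lfc <- lcpm[, setdiff(colnames(lcpm), t0), drop = FALSE] - ref
  lfc
}

#' Simulate a paired track / count / phenotype experiment
#'
#' Counts are generated by [simulate_counts()] with the driver rows of the
#' single-ligand effect matrix replaced by the rank-one driver program of
#' `coupling`; replicate-level log2 fold changes (vs the mean T0 profile) of
#' the driver genes are then mapped linearly to the four phenotype metrics
#' with Gaussian noise. Tracks are simulated with per-condition diffusion and
#' division parameters matched to the condition-mean motility and count
#' metrics, so the imaging arm of the pipeline is qualitatively consistent
#' with the phenotype table.
#'
#' @param track_params [track_sim_params()]; per-condition `D`,
#'   `division_rate` and `area_mean` are overridden from the generated
#'   phenotypes.
#' @param count_params [count_sim_params()].
#' @param coupling [linked_coupling()].
#' @param seed Master seed.
#' @param include_tracks Simulate the track table (set `FALSE` to skip the
#'   imaging arm when only expression/phenotype data are needed).
#' @return List with `counts`, `samples`, `lfc` (genes x treated samples),
#'   `phenotypes` (condition, replicate, four metrics), `tracks` (or `NULL`)
#'   and `truth` (drivers, loadings, per-metric beta, noise sds, plus the
#'   count and track ground truths).
#' @export
simulate_linked_experiment <- function(track_params = track_sim_params(),
                                       count_params = count_sim_params(),
                                       coupling = linked_coupling(),
                                       seed = 1,
                                       include_tracks = TRUE) {
  stopifnot(inherits(coupling, "linked_coupling"))
  ng <- count_params$n_genes
  genes <- gene_ids(ng)
  if (coupling$n_drivers > ng) abort("more drivers than genes.")

  set.seed(derive_seed(seed, "linked-drivers"))
  drivers <- sort(sample(ng, coupling$n_drivers))
  loading <- runif(coupling$n_drivers, coupling$loading_range[1], coupling$loading_range[2])

  # materialise the effect matrix, then overwrite driver rows with the
  # rank-one program loading_g * w_ligand
  set.seed(derive_seed(seed, "counts-effects"))
  eff <- matrix(0, ng, 3, dimnames = list(genes, c("EGF", "OSM", "TGFB")))
  for (lg in colnames(eff)) {
    idx <- sample(ng, round(count_params$responsive_fraction[[lg]] * ng))
    eff[idx, lg] <- rnorm(length(idx), 0, count_params$effect_sd)
  }
  w <- coupling$ligand_weights[colnames(eff)]
  eff[drivers, ] <- outer(loading, as.numeric(w))
  count_params$single_ligand_effects <- eff

  sim <- simulate_counts(count_params, seed = seed)
  lfc <- replicate_lfc(sim$counts, sim$samples)
  treated <- sim$samples %>% filter(.data$condition != "T0")
  treated <- treated[match(colnames(lfc), treated$sample_id), ]

  u <- as.numeric(loading %*% lfc[drivers, , drop = FALSE])  # driver signal per sample
  metrics <- names(coupling$metric_base)
  set.seed(derive_seed(seed, "linked-phenotype-noise"))
  phen <- tibble::tibble(condition = treated$condition, replicate = treated$replicate)
  beta <- list()
  noise_sds <- numeric(0)
  for (m in metrics) {
    gain <- coupling$beta_scale * coupling$metric_coef[[m]] *
      coupling$slope * coupling$metric_base[[m]]
    signal <- gain * u
    nsd <- if (!is.null(coupling$noise_sd)) {
      coupling$noise_sd[[m]]
    } else if (is.finite(coupling$snr) && coupling$snr > 0) {
      max(sd(signal) / coupling$snr, 0.01 * coupling$metric_base[[m]] / coupling$snr)
    } else 0
    phen[[m]] <- coupling$metric_base[[m]] + signal +
      if (nsd > 0) rnorm(length(u), 0, nsd) else 0
    beta[[m]] <- setNames(gain * loading, genes[drivers])
    noise_sds[m] <- nsd
  }

  tracks <- NULL
  track_truth <- NULL
  if (include_tracks) {
    cond_phen <- phen %>%
      group_by(.data$condition) %>%
      summarise(across(all_of(metrics), mean), .groups = "drop")
    t_span <- (track_params$n_frames - 1) * track_params$frame_interval
    conds <- track_params$conditions %>%
      select("condition", "area_cv", "spatial_pattern") %>%
      left_join(cond_phen, by = "condition") %>%
      mutate(D = pmax(.data$motility, 0) / 4,
             division_rate = pmax(log(pmax(.data$count_fc, 1e-6)), 0) / t_span,
             area_mean = .data$cyto_area) %>%
      select("condition", "D", "division_rate", "area_mean", "area_cv", "spatial_pattern")
    track_params$conditions <- conds
    tr <- simulate_tracks(track_params, seed = derive_seed(seed, "linked-tracks"))
    tracks <- tr$tracks
    track_truth <- tr$truth
  }

  truth <- list(drivers = genes[drivers],
                loading = setNames(loading, genes[drivers]),
                beta = beta,
                noise_sd = noise_sds,
                ligand_weights = w,
                beta_scale = coupling$beta_scale,
                counts = sim$truth,
                tracks = track_truth,
                seed = seed)
  list(counts = sim$counts, samples = sim$samples, lfc = lfc,
       phenotypes = phen, tracks = tracks, truth = truth)
}

#' Simulate external cell-line expression with known phenotype
#'
#' Generates independent "cell lines" whose driver-gene expression follows the
#' same rank-one program as a linked experiment (latent activity drawn
#' uniformly over the panel's activity range) plus per-line idiosyncratic
#' expression noise, together with the true phenotype implied by the linked
#' model. Used to test generalisation of fitted phenotype models.
#'
#' @param linked Result of [simulate_linked_experiment()].
#' @param n_lines Number of external lines.
#' @param metric Which phenotype metric to generate.
#' @param noise_sd Measurement noise sd added to the true phenotype.
#' @param line_effect_sd Per-gene, per-line idiosyncratic log2 expression sd.
#' @param seed Seed.
#' @return List with `expr` (lines x genes log2 matrix), `phenotypes`
#'   (tibble: line, measured) and `truth` (latent activities).
#' @export
simulate_external_lines <- function(linked, n_lines = 20, metric = "motility",
                                    noise_sd = 0.5, line_effect_sd = 0.5,
                                    seed = 1) {
  truth <- linked$truth
  genes <- names(truth$counts$baseline_log2_mean)
  drivers <- truth$drivers
  loading <- truth$loading
  set.seed(derive_seed(seed, "external-lines"))
  s <- runif(n_lines, 0, sum(truth$ligand_weights))
  expr <- matrix(rep(truth$counts$baseline_log2_mean, each = n_lines),
                 nrow = n_lines, dimnames = list(sprintf("line%02d", seq_len(n_lines)), genes))
  expr <- expr + matrix(rnorm(length(expr), 0, line_effect_sd), nrow = n_lines)
  driver_sig <- outer(s, loading)                     # lines x drivers
  expr[, drivers] <- expr[, drivers] + driver_sig
  u <- as.numeric(driver_sig %*% loading)             # same beta support as training
  beta_m <- truth$beta[[metric]]
  gain_u <- sum(beta_m * loading) / sum(loading^2)    # beta = gain * loading
  measured <- gain_u * u + rnorm(n_lines, 0, noise_sd)
  list(expr = expr,
       phenotypes = tibble::tibble(line = rownames(expr), measured = measured),
       truth = list(latent = s, metric = metric, noise_sd = noise_sd))
}
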