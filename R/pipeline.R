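#' Default pipeline configuration
#'
#' Desk-scale defaults for the one-command demonstration run: the full
#' 8-condition x 3-replicate panel with a reduced gene count and field size
#' so the whole pipeline completes in well under a minute. Every stochastic
#' stage derives its stream from the single `seed`.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    outdir = "combiphen_out",
    stages = list(simulate = TRUE, phenotypes = TRUE, emergence = TRUE,
                  de = TRUE, synergy = TRUE, plsr = TRUE, validate = TRUE),
    simulate = list(n_genes = 2000, n_cells_init = 60, n_fields = 1,
                    n_frames = 49, n_replicates = 3, dispersion = 0.1,
                    synergy_genes = 40, synergy_extra = 2, snr = 3),
    phenotypes = list(t_eval = 24, neighbor_order = 1, max_jump = 200),
    emergence = list(alpha = 0.05),
    de = list(lfc_thresh = 1.5, q_thresh = 0.05, top_n = 200,
              top_p_thresh = 0.05, top_lfc_thresh = 1.5),
    modules = list(k_max = 8, gap_b = 50),
    synergy = list(lfc_thresh = 1.5, alpha = 0.05, lfc_filter = 0.5),
    plsr = list(n_variable_genes = 1000, a_max = 5, n_signature = 100),
    validate = list(effect_thresh = -0.5, n_external = 20,
                    external_noise_sd = 0.5)
  )
}

config_types <- function(x) {
  if (is.list(x)) lapply(x, config_types) else class(x)[1]
}

#' Validate and normalise a pipeline configuration
#'
#' Accepts a YAML file path, a (partial) list, or `NULL`; unknown keys, type
#' mismatches and negative rates/thresholds that must be non-negative are
#' collected and reported together. Missing keys are filled from
#' [default_config()].
#'
#' @param config Path to a YAML file, a list, or `NULL` for pure defaults.
#' @return The normalised configuration list (class `combiphen_config`) with
#'   attribute `hash`, the md5 of its canonical YAML form.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file '%s' not found.", config))
    config <- yaml::read_yaml(config) %||% list()
  }
  config <- config %||% list()
  if (!is.list(config)) abort("config must be a YAML mapping / list.")
  ref <- default_config()
  problems <- character(0)
  check_level <- function(cfg, ref, path) {
    unknown <- setdiff(names(cfg), names(ref))
    if (length(unknown)) {
      problems <<- c(problems, sprintf("unknown key(s): %s",
                                       paste0(path, unknown, collapse = ", ")))
    }
    for (nm in intersect(names(cfg), names(ref))) {
      key <- paste0(path, nm)
      if (is.list(ref[[nm]])) {
        if (!is.list(cfg[[nm]])) {
          problems <<- c(problems, sprintf("`%s` must be a mapping.", key))
        } else check_level(cfg[[nm]], ref[[nm]], paste0(key, "."))
      } else if (is.numeric(ref[[nm]])) {
        if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || !is.finite(cfg[[nm]])) {
          problems <<- c(problems, sprintf("`%s` must be a single finite number.", key))
        } else if (cfg[[nm]] < 0 && !nm %in% c("effect_thresh")) {
          problems <<- c(problems, sprintf("`%s` must be non-negative.", key))
        }
      } else if (is.logical(ref[[nm]])) {
        if (!is.logical(cfg[[nm]]) || length(cfg[[nm]]) != 1 || is.na(cfg[[nm]])) {
          problems <<- c(problems, sprintf("`%s` must be TRUE or FALSE.", key))
        }
      } else if (is.character(ref[[nm]])) {
        if (!is.character(cfg[[nm]]) || length(cfg[[nm]]) != 1) {
          problems <<- c(problems, sprintf("`%s` must be a single string.", key))
        }
      }
    }
  }
  check_level(config, ref, "")
  if (length(problems)) {
    abort(paste0("invalid configuration:\n  - ",
                 paste(problems, collapse = "\n  - ")))
  }
  out <- modifyList(ref, config)
  out$seed <- as.integer(out$seed)
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  # the hash identifies the analytical configuration; where outputs land
  # does not change what is computed
  writeLines(yaml::as.yaml(out[setdiff(names(out), "outdir")]), tf)
  attr(out, "hash") <- unname(tools::md5sum(tf))
  class(out) <- c("combiphen_config", class(out))
  out
}

require_stage_files <- function(files, stage, upstream) {
  if (!all(file.exists(files))) {
    abort(sprintf(
      "stage '%s' requires outputs of stage '%s' (missing: %s); enable '%s' or provide its outputs.",
      stage, upstream, paste(basename(files[!file.exists(files)]), collapse = ", "),
      upstream))
  }
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on a self-generated linked
#' experiment: simulate -> track phenotypes -> emergence calls -> differential
#' expression, DEG counts, modules -> synergy calls and additive fits -> PLS1
#' models, VIP signatures -> external-prediction and essentiality validation
#' (against a synthetic gene-effect table in which the generator's driver
#' genes are planted as essential). All outputs are plain-text tables under
#' `outdir`, listed with md5 checksums and the config hash in `MANIFEST.tsv`;
#' identical configurations reproduce identical tables.
#'
#' @param config Passed to [validate_config()].
#' @param seed,outdir Optional overrides of the config values.
#' @param resume Reuse existing stage outputs on disk instead of recomputing
#'   them.
#' @return (Invisibly) a list of the in-memory stage results, class
#'   `combiphen_report`.
#' @export
run_pipeline <- function(config = NULL, seed = NULL, outdir = NULL,
                         resume = FALSE) {
  cfg <- if (inherits(config, "combiphen_config")) config else validate_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (!is.null(seed) || !is.null(outdir)) {
    tmp <- unclass(cfg); attr(tmp, "hash") <- NULL
    cfg <- validate_config(tmp)
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(cfg$outdir, ...)
  res <- list(config = cfg)
  st <- cfg$stages
  metrics <- c("count_fc", "motility", "nn_ratio", "cyto_area")
  combos <- c("EGF+OSM", "EGF+TGFB", "OSM+TGFB")

  # ---- simulate -------------------------------------------------------------
  sim_files <- path(c("tracks.csv", "counts.tsv", "samples.tsv",
                      "phenotypes_model.tsv", "ground_truth.json"))
  if (st$simulate && !(resume && all(file.exists(sim_files)))) {
    sp <- cfg$simulate
    syn_sets <- list()
    if (sp$synergy_genes > 0) {
      # deterministic, disjoint synthetic synergy sets per pairwise combination
      set.seed(derive_seed(cfg$seed, "pipeline-synergy-sets"))
      pool <- sample(sp$n_genes, 3 * sp$synergy_genes)
      syn_sets <- setNames(lapply(seq_along(combos), function(i) {
        idx <- pool[seq((i - 1) * sp$synergy_genes + 1, i * sp$synergy_genes)]
        tibble::tibble(gene = idx, extra_log2 = sp$synergy_extra)
      }), combos)
    }
    linked <- simulate_linked_experiment(
      track_params = track_sim_params(n_cells_init = sp$n_cells_init,
                                      n_frames = sp$n_frames,
                                      n_replicates = sp$n_replicates,
                                      n_fields = sp$n_fields),
      count_params = count_sim_params(n_genes = sp$n_genes,
                                      dispersion = sp$dispersion,
                                      synergy_sets = syn_sets,
                                      n_replicates = sp$n_replicates),
      coupling = linked_coupling(snr = sp$snr),
      seed = cfg$seed)
    write_tracks(linked$tracks, path("tracks.csv"))
    write_counts(linked$counts, linked$samples, path("counts.tsv"), path("samples.tsv"))
    write_tsv_plain(linked$phenotypes, path("phenotypes_model.tsv"))
    truth_small <- linked$truth[c("drivers", "loading", "beta", "noise_sd",
                                  "ligand_weights", "beta_scale", "seed")]
    truth_small$synergy_sets <- lapply(linked$truth$counts$synergy_sets,
                                       function(s) s$gene)
    truth_small$true_D <- linked$truth$tracks$true_D
    jsonlite::write_json(truth_small, path("ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res$linked <- linked
  } else if (any(unlist(st[c("phenotypes", "emergence", "de", "synergy",
                             "plsr", "validate")]))) {
    require_stage_files(sim_files[2:4], "phenotypes/de", "simulate")
    cs <- read_counts(path("counts.tsv"), path("samples.tsv"))
    res$linked <- list(counts = cs$counts, samples = cs$samples,
                       lfc = replicate_lfc(cs$counts, cs$samples),
                       phenotypes = tibble::as_tibble(
                         read.delim(path("phenotypes_model.tsv"))),
                       tracks = if (file.exists(sim_files[1])) {
                         read_tracks(sim_files[1], field_size = 1024)
                       })
  }
  linked <- res$linked

  # ---- track phenotypes -----------------------------------------------------
  if (st$phenotypes) {
    if (is.null(linked$tracks)) {
      require_stage_files(path("tracks.csv"), "phenotypes", "simulate")
    }
    pp <- cfg$phenotypes
    res$phenotypes_tracks <- summarize_phenotypes(
      linked$tracks, t_eval = pp$t_eval, k = pp$neighbor_order,
      max_jump = pp$max_jump)
    write_tsv_plain(res$phenotypes_tracks, path("phenotypes_tracks.tsv"))
    res$magnitude <- response_magnitude(linked$phenotypes)
    write_tsv_plain(res$magnitude %>% select(-dplyr::any_of("p_vs_single")),
                    path("phenotype_magnitude.tsv"))
  }

  # ---- emergence ------------------------------------------------------------
  if (st$emergence) {
    em <- emergence_scan(linked$phenotypes, metric_cols = metrics,
                         alpha = cfg$emergence$alpha)
    res$emergence <- em
    write_tsv_plain(em %>%
                      mutate(p_vs_single = vapply(.data$p_vs_single, function(p)
                        paste(sprintf("%s=%.4g", names(p), p), collapse = ";"),
                        character(1))),
                    path("emergence.tsv"))
  }

  # ---- differential expression / modules ------------------------------------
  if (st$de) {
    conds <- setdiff(panel_conditions(), character(0))
    de_t0 <- setNames(lapply(conds, function(cc) {
      differential_expression(linked$counts, linked$samples, cc, "T0")
    }), conds)
    res$de_t0 <- de_t0
    dir.create(path("de"), showWarnings = FALSE)
    for (cc in conds) write_de_table(de_t0[[cc]], path("de", paste0(
      "de_", gsub("[^A-Za-z0-9]", "_", cc), "_vs_T0.tsv")))
    deg <- tibble::tibble(
      condition = setdiff(conds, "PBS"),
      degs = vapply(setdiff(conds, "PBS"), function(cc) {
        count_degs(differential_expression(linked$counts, linked$samples, cc, "PBS"),
                   lfc_thresh = cfg$de$lfc_thresh, q_thresh = cfg$de$q_thresh)
      }, numeric(1)))
    res$deg_counts <- deg
    write_tsv_plain(deg, path("deg_counts.tsv"))
    if (!is.null(res$magnitude)) {
      mag <- res$magnitude %>% group_by(.data$condition) %>%
        summarise(magnitude = mean(.data$magnitude), .groups = "drop")
      dp <- deg %>% left_join(mag, by = "condition")
      res$deg_phenotype <- deg_phenotype_correlation(dp)
      jsonlite::write_json(as.list(res$deg_phenotype), path("deg_phenotype.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    top <- select_top_genes(de_t0, n_up = cfg$de$top_n, n_down = cfg$de$top_n,
                            p_thresh = cfg$de$top_p_thresh,
                            lfc_thresh = cfg$de$top_lfc_thresh)
    res$top_genes <- top
    genes_u <- sort(unique(top$gene))
    lfc_mat <- vapply(conds, function(cc) {
      de_t0[[cc]]$lfc[match(genes_u, de_t0[[cc]]$gene)]
    }, numeric(length(genes_u)))
    rownames(lfc_mat) <- genes_u
    mods <- cluster_gene_modules(lfc_mat, k_max = cfg$modules$k_max,
                                 B = cfg$modules$gap_b, seed = cfg$seed)
    res$modules <- mods
    write_tsv_plain(mods$assignments, path("modules.tsv"))
    write_tsv_plain(mods$module_scores, path("module_scores.tsv"))
    if (!is.null(mods$gap_curve)) write_tsv_plain(mods$gap_curve, path("gap_curve.tsv"))
    write_tsv_plain(lfc_correlation(lfc_mat), path("lfc_correlation.tsv"))
  }

  # ---- synergy --------------------------------------------------------------
  if (st$synergy) {
    if (is.null(res$de_t0)) {
      require_stage_files(path("de", "de_EGF_vs_T0.tsv"), "synergy", "de")
    }
    calls <- list(); addfits <- list()
    for (combo in combos) {
      singles <- condition_ligands(combo)
      de_vs <- setNames(lapply(singles, function(sg) {
        differential_expression(linked$counts, linked$samples, combo, sg)
      }), singles)
      calls[[combo]] <- call_synergistic_genes(
        de_vs, lfc_thresh = cfg$synergy$lfc_thresh, alpha = cfg$synergy$alpha)
      write_tsv_plain(calls[[combo]], path(paste0(
        "synergy_", gsub("[^A-Za-z0-9]", "_", combo), ".tsv")))
      addfits[[combo]] <- additive_prediction(
        res$de_t0[singles], res$de_t0[[combo]], lfc_filter = cfg$synergy$lfc_filter)
    }
    res$synergy_calls <- calls
    res$additivity <- addfits
    jsonlite::write_json(
      lapply(addfits, function(f) f[c("r_squared", "p_value", "n")]),
      path("additivity.json"), auto_unbox = TRUE, digits = NA)
    res$synergy_overlap <- synergy_overlap(calls, class = "positive")
    jsonlite::write_json(purrr::transpose(res$synergy_overlap),
                         path("synergy_overlap.json"), auto_unbox = TRUE, digits = NA)
  }

  # ---- PLSR / VIP -----------------------------------------------------------
  if (st$plsr) {
    X <- t(linked$lfc)
    vg <- select_variable_genes(X, n = cfg$plsr$n_variable_genes)
    Xv <- X[, vg, drop = FALSE]
    phen <- linked$phenotypes
    key <- sprintf("%s_r%d", phen$condition, phen$replicate)
    Xv <- Xv[match(key, rownames(Xv)), , drop = FALSE]
    fits <- list(); curves <- list(); vips <- list(); sigs <- list()
    for (m in metrics) {
      y <- phen[[m]]
      curve <- loo_rrmsep_select(Xv, y, a_max = cfg$plsr$a_max)
      fit <- fit_pls1(Xv, y, ncomp = attr(curve, "chosen"))
      vip <- vip_scores(fit)
      sig <- extract_signature(vip, n_each = cfg$plsr$n_signature, phenotype = m)
      fits[[m]] <- fit; curves[[m]] <- curve; vips[[m]] <- vip; sigs[[m]] <- sig
      write_tsv_plain(vip, path(paste0("vip_", m, ".tsv")))
      write_pls_model(fit, path(paste0("pls_model_", m, ".json")))
    }
    res$pls_fits <- fits; res$rrmsep <- curves; res$vip <- vips
    res$signatures <- sigs
    write_tsv_plain(
      dplyr::bind_rows(lapply(metrics, function(m) tibble::tibble(
        metric = m, ncomp = curves[[m]]$ncomp, rrmsep = curves[[m]]$rrmsep,
        chosen = attr(curves[[m]], "chosen")))),
      path("rrmsep.tsv"))
    write_tsv_plain(
      dplyr::bind_rows(lapply(metrics, function(m) tibble::tibble(
        metric = m,
        gene = c(sigs[[m]]$positive, sigs[[m]]$negative),
        side = rep(c("positive", "negative"),
                   c(length(sigs[[m]]$positive), length(sigs[[m]]$negative)))))),
      path("signatures.tsv"))
  }

  # ---- validation -----------------------------------------------------------
  if (st$validate) {
    if (is.null(res$pls_fits)) {
      require_stage_files(path("rrmsep.tsv"), "validate", "plsr")
    }
    if (is.null(linked$truth)) {
      warn("ground truth unavailable (resumed run); skipping validation stage.")
    } else {
      vv <- cfg$validate
      ext <- simulate_external_lines(linked, n_lines = vv$n_external,
                                     metric = "motility",
                                     noise_sd = vv$external_noise_sd,
                                     seed = derive_seed(cfg$seed, "pipeline-external"))
      pred <- predict_phenotype(res$pls_fits$motility, ext$expr)
      paired <- pred %>% left_join(ext$phenotypes, by = c(sample = "line"))
      res$external_validation <- external_prediction_correlation(paired)
      # synthetic gene-effect table: driver genes planted as essential
      set.seed(derive_seed(cfg$seed, "pipeline-gene-effect"))
      genes_all <- res$pls_fits$count_fc$genes
      eff <- tibble::tibble(
        gene = genes_all,
        effect = rnorm(length(genes_all), 0, 0.2) -
          ifelse(genes_all %in% linked$truth$drivers, 1, 0))
      res$essentiality <- essentiality_enrichment(
        eff, res$signatures$count_fc$positive, genes_all,
        effect_thresh = vv$effect_thresh)
      jsonlite::write_json(
        list(external_prediction = as.list(res$external_validation),
             essentiality = list(statistic = res$essentiality$statistic,
                                 p_value = res$essentiality$p_value,
                                 table = as.integer(res$essentiality$table))),
        path("validation.json"), auto_unbox = TRUE, digits = NA)
    }
  }

  # ---- provenance -----------------------------------------------------------
  jsonlite::write_json(list(package = "combiphen",
                            version = as.character(utils::packageVersion("combiphen")),
                            seed = cfg$seed,
                            config_hash = attr(cfg, "hash")),
                       path("run_metadata.json"), auto_unbox = TRUE)
  files <- setdiff(list.files(cfg$outdir, recursive = TRUE), "MANIFEST.tsv")
  manifest <- tibble::tibble(file = files,
                             md5 = unname(tools::md5sum(path(files))),
                             config_hash = attr(cfg, "hash"))
  write_tsv_plain(manifest, path("MANIFEST.tsv"))
  res$manifest <- manifest
  class(res) <- "combiphen_report"
  invisible(res)
}

#' @export
print.combiphen_report <- function(x, ...) {
  cat("combiphen pipeline report\n")
  cat(sprintf("  outputs: %d files in '%s' (config %s)\n",
              nrow(x$manifest), x$config$outdir, substr(x$config |> attr("hash"), 1, 8)))
  if (!is.null(x$deg_phenotype)) {
    cat(sprintf("  DEG count vs phenotype magnitude: R^2 = %.2f (p = %.3g)\n",
                x$deg_phenotype$r_squared, x$deg_phenotype$p_value))
  }
  if (!is.null(x$external_validation)) {
    cat(sprintf("  external prediction (count_fc): R^2 = %.2f (p = %.3g)\n",
                x$external_validation$r_squared, x$external_validation$p_value))
  }
  invisible(x)
}
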