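test_that("track simulator is a pure function of (params, seed)", {
  p <- brownian_params(n_cells = 20, n_frames = 6, division_rate = 0.05)
  a <- simulate_tracks(p, seed = 42)
  b <- simulate_tracks(p, seed = 42)
  expect_identical(a$tracks, b$tracks)
  c <- simulate_tracks(p, seed = 43)
  expect_false(identical(a$tracks$x, c$tracks$x))
})

test_that("zero diffusion and zero division give stationary tracks", {
  p <- brownian_params(D = 0, n_cells = 15, n_frames = 8)
  tr <- simulate_tracks(p, seed = 1)$tracks
  drift <- tr %>% dplyr::group_by(cell_id) %>%
    dplyr::summarise(move = max(x) - min(x) + max(y) - min(y))
  expect_true(all(drift$move == 0))
  msd <- compute_msd(tr)
  expect_true(all(msd$msd == 0))
})

test_that("per-frame displacement variance matches 2 D dt", {
  D <- 100; dt <- 0.5
  p <- brownian_params(D = D, n_cells = 300, n_frames = 40)
  tr <- simulate_tracks(p, seed = 7)$tracks
  steps <- tr %>% dplyr::arrange(cell_id, frame) %>%
    dplyr::group_by(cell_id) %>%
    dplyr::summarise(dx = list(diff(x)), dy = list(diff(y))) %>%
    tidyr::unnest(c(dx, dy))
  n <- 2 * nrow(steps)
  expect_gt(n, 1e4)
  v <- var(c(steps$dx, steps$dy))
  se <- 2 * D * dt * sqrt(2 / (n - 1))   # var of a variance estimate
  expect_lt(abs(v - 2 * D * dt), 3 * se)
})

test_that("division bookkeeping: growth rate and daughter placement", {
  r <- 0.1
  p <- brownian_params(D = 0, n_cells = 200, n_frames = 21,
                       division_rate = r)
  tr <- simulate_tracks(p, seed = 3)$tracks
  n0 <- dplyr::n_distinct(tr$cell_id[tr$frame == 0])
  n1 <- dplyr::n_distinct(tr$cell_id[tr$frame == 20])
  t_span <- 10
  # per-frame branching with p = r dt: growth (1 + r dt)^frames
  expected <- n0 * (1 + r * 0.5)^20
  expect_lt(abs(n1 - expected) / expected, 0.15)
  expect_true(all(tr$x >= 0 & tr$x <= 1024 & tr$y >= 0 & tr$y <= 1024))
})

test_that("negative rates are rejected", {
  expect_error(track_sim_params(conditions = tibble::tibble(
    condition = "a", D = -1, division_rate = 0, area_mean = 1, area_cv = 0.1,
    spatial_pattern = "poisson")), "D")
  expect_error(count_sim_params(dispersion = -0.5), "dispersion")
})

test_that("count simulator is additive in log2 in the small-dispersion limit", {
  ng <- 400
  eff <- matrix(0, ng, 3, dimnames = list(NULL, c("EGF", "OSM", "TGFB")))
  set.seed(1)
  eff[, "EGF"] <- rnorm(ng, 0, 0.8)
  eff[, "OSM"] <- rnorm(ng, 0, 0.8)
  sim <- simulate_counts(count_sim_params(
    n_genes = ng, baseline_log2_mean = rep(14, ng), dispersion = 1e-8,
    single_ligand_effects = eff, library_size = 1), seed = 5)
  m <- function(cc) rowMeans(sim$counts[, sim$samples$condition == cc, drop = FALSE])
  lfc_combo <- log2(m("EGF+OSM")) - log2(m("T0"))
  lfc_sum <- (log2(m("EGF")) - log2(m("T0"))) + (log2(m("OSM")) - log2(m("T0")))
  expect_lt(max(abs(lfc_combo - lfc_sum)), 0.05)
})

test_that("planted synergy raises the combination beyond each single", {
  ng <- 200
  eff <- matrix(0.5, ng, 3, dimnames = list(NULL, c("EGF", "OSM", "TGFB")))
  syn <- tibble::tibble(gene = 1:20, extra_log2 = 2)
  sim <- simulate_counts(count_sim_params(
    n_genes = ng, baseline_log2_mean = rep(13, ng), dispersion = 1e-8,
    single_ligand_effects = eff, library_size = 1,
    synergy_sets = list("EGF+OSM" = syn)), seed = 2)
  m <- function(cc) rowMeans(sim$counts[, sim$samples$condition == cc, drop = FALSE])
  excess <- log2(m("EGF+OSM")) - pmax(log2(m("EGF")), log2(m("OSM")))
  expect_true(all(excess[1:20] >= 2 - 0.05))
  expect_true(all(abs(excess[21:200] - 0.5) < 0.05))  # additive: max + other effect
  # ground-truth bookkeeping
  expect_length(sim$truth$synergy_sets[["EGF+OSM"]]$gene, 20)
})

test_that("NB moments match the model within Monte-Carlo error per gene bin", {
  ng <- 2000; disp <- 0.05
  sim <- simulate_counts(count_sim_params(
    n_genes = ng, baseline_log2_mean = rep(8, ng), dispersion = disp,
    single_ligand_effects = matrix(0, ng, 3, dimnames = list(NULL, c("EGF", "OSM", "TGFB"))),
    library_size = 1), seed = 8)
  x <- as.numeric(sim$counts[, sim$samples$condition == "T0"])
  mu <- 2^8
  expect_lt(abs(mean(x) - mu), 3 * sd(x) / sqrt(length(x)))
  v_model <- mu + disp * mu^2
  expect_lt(abs(var(x) / v_model - 1), 0.1)
})

test_that("a combination without its constituent singles is rejected", {
  bad <- tibble::tibble(sample_id = c("a1", "a2", "b1", "b2"),
                        condition = c("EGF+OSM", "EGF+OSM", "T0", "T0"),
                        replicate = c(1, 2, 1, 2), timepoint = 24)
  expect_error(simulate_counts(count_sim_params(n_genes = 50), design = bad),
               "constituent")
})

test_that("synergy genes outside the gene universe are rejected", {
  expect_error(simulate_counts(count_sim_params(
    n_genes = 50,
    synergy_sets = list("EGF+OSM" = tibble::tibble(gene = 100, extra_log2 = 1)))),
    "subset")
})

test_that("linked experiment: noiseless phenotype is exactly linear in driver LFCs", {
  linked <- simulate_linked_experiment(
    count_params = count_sim_params(n_genes = 400),
    coupling = linked_coupling(n_drivers = 20, snr = Inf),
    seed = 4, include_tracks = FALSE)
  truth <- linked$truth
  u <- as.numeric(truth$loading %*% linked$lfc[truth$drivers, ])
  y <- linked$phenotypes$motility
  fit <- lm(y ~ u)
  expect_gt(summary(fit)$r.squared, 1 - 1e-10)
  # PLS1 with 1 component on the driver block predicts it essentially exactly
  X <- t(linked$lfc[truth$drivers, ])
  pfit <- fit_pls1(X, y, ncomp = 2)
  expect_gt(1 - sum((pfit$fitted - y)^2) / sum((y - mean(y))^2), 0.999)
})

test_that("linked experiment records drivers and betas in the ground truth", {
  linked <- simulate_linked_experiment(
    count_params = count_sim_params(n_genes = 300),
    coupling = linked_coupling(n_drivers = 30), seed = 6,
    include_tracks = FALSE)
  expect_length(linked$truth$drivers, 30)
  expect_named(linked$truth$beta, c("count_fc", "motility", "nn_ratio", "cyto_area"))
  expect_true(all(names(linked$truth$beta$motility) == linked$truth$drivers))
  # serialisable alongside outputs
  js <- jsonlite::toJSON(linked$truth[c("drivers", "loading", "noise_sd")],
                         auto_unbox = TRUE)
  expect_s3_class(js, "json")
})

test_that("decoupled phenotype (beta_scale 0) is pure noise: LOO RRMSEP near 1", {
  linked <- simulate_linked_experiment(
    count_params = count_sim_params(n_genes = 300),
    coupling = linked_coupling(beta_scale = 0), seed = 11,
    include_tracks = FALSE)
  X <- t(linked$lfc)
  curve <- loo_rrmsep_select(X, linked$phenotypes$count_fc, a_max = 4)
  expect_gt(min(curve$rrmsep), 0.8)
})
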