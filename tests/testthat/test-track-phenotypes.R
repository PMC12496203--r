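test_that("jump filter removes whole tracks on steps > 200 px, strictly", {
  tr <- make_tracks(list(
    list(id = "jumper", x = c(0, 5, 8, 258), y = c(0, 0, 0, 0)),
    list(id = "walker", x = c(0, 100, 300, 400), y = rep(0, 4)),   # 200 px steps
    list(id = "edge",   x = c(0, 200), y = c(0, 0))))
  out <- filter_tracks(tr)
  expect_setequal(unique(out$cell_id), c("walker", "edge"))
  # the offending track is removed entirely, not truncated
  expect_false("jumper" %in% out$cell_id)
  # empty input passes through
  expect_identical(nrow(filter_tracks(tr[0, ])), 0L)
})

test_that("jump filter only applies within the time window", {
  # same 250 px displacement but over a 2-frame gap (1 h > 0.5 h window)
  tr <- make_tracks(list(list(id = "gappy", x = c(0, 1, 251), y = c(0, 0, 0))))
  tr$frame <- c(0L, 1L, 3L); tr$t <- tr$frame * 0.5
  expect_true("gappy" %in% filter_tracks(tr)$cell_id)
})

test_that("MSD of ballistic and stationary motion is exact", {
  v <- 10  # px per frame
  tr <- make_tracks(list(list(id = "line", x = v * (0:10), y = rep(0, 11))))
  msd <- compute_msd(tr)
  expect_equal(msd$msd, (v * (1:10))^2, tolerance = 1e-12)
  expect_equal(msd$n_pairs, 10:1)
  still <- make_tracks(list(list(id = "s", x = rep(3, 6), y = rep(4, 6))))
  expect_true(all(compute_msd(still)$msd == 0))
})

test_that("MSD is invariant to translation and rotation", {
  p <- brownian_params(D = 50, n_cells = 40, n_frames = 12)
  tr <- simulate_tracks(p, seed = 5)$tracks
  m0 <- compute_msd(tr)
  th <- 0.7
  rot <- tr %>% dplyr::mutate(
    xr = cos(th) * x - sin(th) * y + 100,
    yr = sin(th) * x + cos(th) * y - 50) %>%
    dplyr::mutate(x = xr, y = yr) %>% dplyr::select(-xr, -yr)
  attr(rot, "frame_interval") <- 0.5
  m1 <- compute_msd(rot)
  expect_equal(m0$msd, m1$msd, tolerance = 1e-9)
})

test_that("MSD of pooled Brownian tracks follows 4 D tau and the slope recovers D", {
  D <- 100
  p <- brownian_params(D = D, n_cells = 500, n_frames = 49)
  tr <- simulate_tracks(p, seed = 2)$tracks
  msd <- compute_msd(tr)
  sub <- msd[msd$lag <= 6, ]
  expect_lt(max(abs(sub$msd - 4 * D * sub$lag) / (4 * D * sub$lag)), 0.05)
  slope <- motility_slope(msd)
  expect_lt(abs(slope / 4 - D) / D, 0.10)
})

test_that("motility slope handles exact lines, constants and short curves", {
  curve <- tibble::tibble(lag = seq(0.5, 6, 0.5), msd = 400 * seq(0.5, 6, 0.5),
                          n_pairs = 100)
  class(curve) <- c("combiphen_msd", class(curve))
  expect_equal(motility_slope(curve), 400, tolerance = 1e-12)
  flat <- curve %>% dplyr::mutate(msd = 7)
  expect_equal(motility_slope(flat), 0, tolerance = 1e-12)
  expect_error(motility_slope(curve[1:2, ]), "3 lags")
})

test_that("nearest-neighbour ratio: two-cell case and CSR expectation", {
  two <- tibble::tibble(x = c(0, 3), y = c(0, 4))
  st <- nearest_neighbor_ratio(two, area = 100)
  expect_equal(st$r_obs, 5)
  expect_equal(st$r_expected, 1 / (2 * sqrt(2 / 100)))
  expect_error(nearest_neighbor_ratio(two[1, ], area = 100), "at least")
  # CSR calibration over 20 layouts
  ratios <- vapply(1:20, function(s) {
    set.seed(s)
    pos <- tibble::tibble(x = runif(500, 0, 1024), y = runif(500, 0, 1024))
    nearest_neighbor_ratio(pos, 1024^2)$ratio
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.05)
})

test_that("spatial patterns order as cluster < CSR < grid", {
  p <- track_sim_params(conditions = tibble::tibble(
    condition = c("clus", "csr", "grid"), D = 0, division_rate = 0,
    area_mean = 400, area_cv = 0.3,
    spatial_pattern = c("thomas", "poisson", "grid")),
    n_cells_init = 400, n_frames = 2, n_replicates = 3, n_fields = 1)
  f0 <- simulate_tracks(p, seed = 9)$tracks %>% dplyr::filter(frame == 0)
  rr <- vapply(split(f0, paste(f0$condition, f0$replicate)), function(d) {
    nearest_neighbor_ratio(d, 1024^2)$ratio
  }, numeric(1))
  m <- tapply(rr, sub(" .*", "", names(rr)), mean)
  expect_lt(m[["clus"]], m[["csr"]])
  expect_lt(m[["csr"]], m[["grid"]])
})

test_that("phenotype summaries reduce to hand-computable cases", {
  # no division: count_fc 1; equal areas pass through
  tr <- simulate_tracks(brownian_params(D = 20, n_cells = 50, n_frames = 49),
                        seed = 3)$tracks
  tr$area <- 123
  ph <- summarize_phenotypes(tr)
  expect_equal(ph$count_fc, 1)
  expect_equal(ph$cyto_area, 123)
  # constant division rate: count_fc tracks the branching mean
  r <- 0.03
  tr2 <- simulate_tracks(brownian_params(D = 20, n_cells = 300, n_frames = 49,
                                         division_rate = r), seed = 4)$tracks
  ph2 <- summarize_phenotypes(tr2)
  expect_lt(abs(ph2$count_fc - (1 + r * 0.5)^48) / (1 + r * 0.5)^48, 0.15)
})

test_that("response magnitude is a norm with the documented scaling", {
  base <- tibble::tibble(condition = c("PBS", "EGF"), replicate = 1,
                         count_fc = c(2, 2), motility = c(100, 100),
                         nn_ratio = c(1, 1), cyto_area = c(400, 400))
  expect_equal(response_magnitude(base)$magnitude, 0)
  # one metric doubled -> magnitude exactly 1
  one <- base; one$count_fc[2] <- 4
  expect_equal(response_magnitude(one)$magnitude, 1)
  # 3-4-5 case: rel = (0.3, -0.4, 0, 0)
  mixed <- base
  mixed$count_fc[2] <- 2 * 1.3
  mixed$motility[2] <- 100 * 0.6
  expect_equal(response_magnitude(mixed)$magnitude, 0.5, tolerance = 1e-12)
  # homogeneity: scaling the deviations scales the norm
  half <- base
  half$count_fc[2] <- 2 * 1.15; half$motility[2] <- 100 * 0.8
  expect_equal(response_magnitude(half)$magnitude,
               response_magnitude(mixed)$magnitude / 2, tolerance = 1e-12)
  # zero reference is rejected
  zero <- base; zero$nn_ratio[1] <- 0
  expect_error(response_magnitude(zero), "zero")
})
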