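#' Default per-condition motility/growth parameters for the track simulator
#'
#' One row per treatment condition of the standard panel. Diffusion
#' coefficients (px^2/h), division rates (events/cell/h), mean cytoplasmic
#' areas (px^2) and initial spatial patterns are ordered to mirror the
#' qualitative single-ligand phenotype hierarchy of the assay this package
#' models: EGF drives proliferation, motility and larger cells; OSM drives
#' modest growth and tight clustering; TGFB is close to vehicle on its own;
#' EGF-containing combinations show emergent motility, EGF+TGFB emergent
#' spreading and cell enlargement.
#'
#' @return A tibble with columns `condition`, `D`, `division_rate`,
#'   `area_mean`, `area_cv`, `spatial_pattern`.
#' @export
default_track_conditions <- function() {
  tibble::tribble(
    ~condition,      ~D,  ~division_rate, ~area_mean, ~area_cv, ~spatial_pattern,
    "PBS",           30,  0.010,          400,        0.30,     "poisson",
    "EGF",          100,  0.035,          500,        0.30,     "poisson",
    "OSM",           60,  0.020,          380,        0.30,     "thomas",
    "TGFB",          30,  0.008,          420,        0.30,     "poisson",
    "EGF+OSM",      140,  0.045,          480,        0.30,     "poisson",
    "EGF+TGFB",     120,  0.030,          650,        0.30,     "grid",
    "OSM+TGFB",      50,  0.025,          400,        0.30,     "thomas",
    "EGF+OSM+TGFB", 150,  0.040,          520,        0.30,     "poisson"
  )
}

#' Parameters for the Brownian cell-track simulator
#'
#' @param conditions Tibble of per-condition parameters
#'   (see [default_track_conditions()]). `D` and `division_rate` must be
#'   non-negative.
#' @param n_cells_init Initial cells per field.
#' @param field_size Side of the square field, pixels.
#' @param frame_interval Time between frames, hours.
#' @param n_frames Number of frames (>= 2); 49 frames at 0.5 h spans 24 h.
#' @param n_replicates Biological replicates per condition.
#' @param n_fields Imaging fields per replicate.
#' @param division_offset_sd Gaussian offset (px) of a daughter cell from its
#'   parent at division.
#' @param thomas Parameters of the Thomas cluster process used when
#'   `spatial_pattern == "thomas"`: offspring per parent (mean) and offspring
#'   dispersion sd (px).
#' @return A list of class `track_sim_params`.
#' @export
track_sim_params <- function(conditions = default_track_conditions(),
                             n_cells_init = 200,
                             field_size = 1024,
                             frame_interval = 0.5,
                             n_frames = 49,
                             n_replicates = 3,
                             n_fields = 2,
                             division_offset_sd = 2,
                             thomas = list(offspring_mean = 10, offspring_sd = 40)) {
  check_scalar_number(n_cells_init, "n_cells_init", 1)
  check_scalar_number(field_size, "field_size", 0, strict_min = TRUE)
  check_scalar_number(frame_interval, "frame_interval", 0, strict_min = TRUE)
  check_scalar_number(n_frames, "n_frames", 2)
  stopifnot(is.data.frame(conditions),
            all(c("condition", "D", "division_rate", "area_mean", "area_cv",
                  "spatial_pattern") %in% names(conditions)))
  if (any(!is.finite(conditions$D)) || any(conditions$D < 0)) {
    abort("diffusion coefficients `D` must be finite and >= 0.")
  }
  if (any(!is.finite(conditions$division_rate)) || any(conditions$division_rate < 0)) {
    abort("`division_rate` must be finite and >= 0.")
  }
  structure(list(conditions = tibble::as_tibble(conditions),
                 n_cells_init = n_cells_init, field_size = field_size,
                 frame_interval = frame_interval, n_frames = n_frames,
                 n_replicates = n_replicates, n_fields = n_fields,
                 division_offset_sd = division_offset_sd, thomas = thomas),
            class = "track_sim_params")
}

# initial centroid layout for one field
init_positions <- function(n, L, pattern, thomas) {
  if (pattern == "poisson") {
    cbind(runif(n, 0, L), runif(n, 0, L))
  } else if (pattern == "grid") {
    m <- ceiling(sqrt(n))
    sp <- L / m
    g <- expand.grid(x = (seq_len(m) - 0.5) * sp, y = (seq_len(m) - 0.5) * sp)
    g <- as.matrix(g)[seq_len(n), , drop = FALSE]
    g + matrix(rnorm(2 * n, 0, sp / 10), ncol = 2)
  } else if (pattern == "thomas") {
    n_parents <- max(1, round(n / thomas$offspring_mean))
    par <- cbind(runif(n_parents, 0, L), runif(n_parents, 0, L))
    idx <- sample(rep_len(seq_len(n_parents), n))
    par[idx, , drop = FALSE] + matrix(rnorm(2 * n, 0, thomas$offspring_sd), ncol = 2)
  } else {
    abort(sprintf("unknown spatial_pattern '%s'.", pattern))
  }
}

reflect_into <- function(x, L) {
  # reflecting boundary on [0, L]; iterate for (rare) multi-bounce steps
  while (any(x < 0 | x > L)) {
    x <- ifelse(x < 0, -x, x)
    x <- ifelse(x > L, 2 * L - x, x)
  }
  x
}

draw_areas <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate Brownian cell tracks with division for the full treatment panel
#'
#' Initial centroids are drawn from the condition's spatial point pattern
#' (Poisson/CSR, Thomas cluster, or jittered grid); each frame every cell takes
#' an isotropic Gaussian step with per-axis variance `2 * D * frame_interval`
#' and is reflected at the field boundary; divisions occur independently with
#' probability `division_rate * frame_interval` per cell per frame, placing the
#' daughter at the parent position plus a small Gaussian offset; cytoplasmic
#' areas are lognormal per cell and constant along a track.
#'
#' @param params A [track_sim_params()] object.
#' @param seed Integer master seed; identical `(params, seed)` give identical
#'   output.
#' @return A list with `tracks` (tibble: `cell_id`, `frame`, `t`, `x`, `y`,
#'   `area`, `field`, `condition`, `replicate`; attribute `field_size`) and
#'   `truth` (list recording `true_D`, `division_rate` and the parameters).
#' @export
simulate_tracks <- function(params = track_sim_params(), seed = 1) {
  stopifnot(inherits(params, "track_sim_params"))
  L <- params$field_size
  dt <- params$frame_interval
  out <- vector("list", nrow(params$conditions) * params$n_replicates * params$n_fields)
  slot <- 1L
  for (ci in seq_len(nrow(params$conditions))) {
    cond <- params$conditions[ci, ]
    step_sd <- sqrt(2 * cond$D * dt)
    p_div <- min(1, cond$division_rate * dt)
    for (rep_i in seq_len(params$n_replicates)) {
      for (fld in seq_len(params$n_fields)) {
        set.seed(derive_seed(seed, paste("tracks", cond$condition, rep_i, fld)))
        n0 <- params$n_cells_init
        pos <- init_positions(n0, L, cond$spatial_pattern, params$thomas)
        pos[, 1] <- reflect_into(pos[, 1], L)
        pos[, 2] <- reflect_into(pos[, 2], L)
        areas <- draw_areas(n0, cond$area_mean, cond$area_cv)
        ids <- seq_len(n0)
        next_id <- n0 + 1L
        frames <- vector("list", params$n_frames)
        frames[[1]] <- cbind(id = ids, frame = 0, x = pos[, 1], y = pos[, 2], area = areas)
        for (fr in seq_len(params$n_frames - 1L)) {
          n_now <- length(ids)
          pos <- pos + matrix(rnorm(2 * n_now, 0, step_sd), ncol = 2)
          pos[, 1] <- reflect_into(pos[, 1], L)
          pos[, 2] <- reflect_into(pos[, 2], L)
          if (p_div > 0) {
            div <- runif(n_now) < p_div
            if (any(div)) {
              nd <- sum(div)
              dpos <- pos[div, , drop = FALSE] +
                matrix(rnorm(2 * nd, 0, params$division_offset_sd), ncol = 2)
              dpos[, 1] <- reflect_into(dpos[, 1], L)
              dpos[, 2] <- reflect_into(dpos[, 2], L)
              pos <- rbind(pos, dpos)
              areas <- c(areas, draw_areas(nd, cond$area_mean, cond$area_cv))
              ids <- c(ids, seq.int(next_id, length.out = nd))
              next_id <- next_id + nd
            }
          }
          frames[[fr + 1L]] <- cbind(id = ids, frame = fr, x = pos[, 1], y = pos[, 2], area = areas)
        }
        m <- do.call(rbind, frames)
        out[[slot]] <- tibble::tibble(
          cell_id = sprintf("%s_r%d_f%d_%05d", cond$condition, rep_i, fld, m[, "id"]),
          frame = as.integer(m[, "frame"]),
          t = m[, "frame"] * dt,
          x = m[, "x"], y = m[, "y"], area = m[, "area"],
          field = fld, condition = cond$condition, replicate = rep_i)
        slot <- slot + 1L
      }
    }
  }
  tracks <- dplyr::bind_rows(out) %>%
    arrange(.data$condition, .data$replicate, .data$field, .data$cell_id, .data$frame)
  attr(tracks, "field_size") <- L
  attr(tracks, "frame_interval") <- dt
  truth <- list(
    true_D = setNames(params$conditions$D, params$conditions$condition),
    division_rate = setNames(params$conditions$division_rate, params$conditions$condition),
    area_mean = setNames(params$conditions$area_mean, params$conditions$condition),
    field_size = L, frame_interval = dt, n_frames = params$n_frames, seed = seed)
  list(tracks = tracks, truth = truth)
}
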