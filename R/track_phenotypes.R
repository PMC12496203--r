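#' Remove tracks containing implausible jumps
#'
#' A track is dropped entirely if any displacement between frames no more than
#' `window` hours apart exceeds `max_jump` pixels (strict inequality: a step
#' of exactly `max_jump` is kept). Such jumps are segmentation/tracking
#' artefacts, not motility.
#'
#' @param tracks Track tibble (`cell_id`, `frame`, `t`, `x`, `y`, ...).
#' @param max_jump Pixel threshold.
#' @param window Maximum time separation (hours) over which the jump rule is
#'   applied; defaults to one 30-min frame interval.
#' @return The filtered track tibble (attributes preserved).
#' @export
filter_tracks <- function(tracks, max_jump = 200, window = 0.5) {
  if (nrow(tracks) == 0) return(tracks)
  check_scalar_number(max_jump, "max_jump", 0)
  bad <- tracks %>%
    arrange(.data$cell_id, .data$frame) %>%
    group_by(.data$cell_id) %>%
    summarise(bad = any(
      sqrt(diff(.data$x)^2 + diff(.data$y)^2) > max_jump &
        diff(.data$t) <= window + 1e-9), .groups = "drop") %>%
    filter(.data$bad) %>%
    pull(.data$cell_id)
  out <- tracks %>% filter(!.data$cell_id %in% bad)
  attr(out, "field_size") <- attr(tracks, "field_size")
  attr(out, "frame_interval") <- attr(tracks, "frame_interval")
  out
}

infer_frame_interval <- function(tracks) {
  dt <- attr(tracks, "frame_interval")
  if (!is.null(dt)) return(dt)
  tt <- sort(unique(tracks$t))
  if (length(tt) < 2) abort("cannot infer frame interval from a single frame.")
  min(diff(tt))
}

#' Mean squared displacement curve of a track table
#'
#' For each lag, squared displacements are taken over all overlapping frame
#' pairs within each track (time-averaged) and pooled across tracks weighted
#' by pair count (i.e. a single mean over all pairs).
#'
#' @param tracks Filtered track tibble.
#' @param lags Lags in hours (multiples of the frame interval); default every
#'   available lag up to the longest track span.
#' @return Tibble of class `combiphen_msd` with `lag` (hours), `msd` (px^2)
#'   and `n_pairs`. Requested lags with no pairs are dropped with a warning.
#' @export
compute_msd <- function(tracks, lags = NULL) {
  stopifnot(nrow(tracks) > 0)
  dt <- infer_frame_interval(tracks)
  span <- max(tracks$frame) - min(tracks$frame)
  if (is.null(lags)) lags <- seq_len(span) * dt
  k_all <- lags / dt
  if (any(abs(k_all - round(k_all)) > 1e-6)) {
    abort("`lags` must be multiples of the frame interval.")
  }
  k_all <- as.integer(round(k_all))
  d <- tracks %>% select("cell_id", "frame", "x", "y")
  rows <- lapply(k_all, function(k) {
    d2 <- d %>% mutate(frame = .data$frame - k) %>%
      rename(x2 = "x", y2 = "y")
    j <- dplyr::inner_join(d, d2, by = c("cell_id", "frame"))
    if (nrow(j) == 0) return(NULL)
    tibble::tibble(lag = k * dt,
                   msd = mean((j$x2 - j$x)^2 + (j$y2 - j$y)^2),
                   n_pairs = nrow(j))
  })
  dropped <- k_all[vapply(rows, is.null, logical(1))]
  if (length(dropped)) {
    warn(sprintf("lags with no displacement pairs dropped: %s h",
                 paste(dropped * dt, collapse = ", ")))
  }
  out <- dplyr::bind_rows(rows) %>% arrange(.data$lag)
  class(out) <- c("combiphen_msd", class(out))
  attr(out, "frame_interval") <- dt
  out
}

#' Motility as the slope of the MSD curve
#'
#' Ordinary least-squares slope of MSD against lag over `[lag_min, lag_max]`
#' hours, intercept included (tracking noise produces a positive offset).
#' For ideal two-dimensional Brownian motion the slope equals `4 D`.
#'
#' @param curve A [compute_msd()] result.
#' @param lag_min,lag_max Lag window in hours.
#' @return Slope in px^2/hour (scalar).
#' @export
motility_slope <- function(curve, lag_min = 0.5, lag_max = 6) {
  sub <- curve %>% filter(.data$lag >= lag_min - 1e-9, .data$lag <= lag_max + 1e-9)
  if (nrow(sub) < 3) abort("need at least 3 lags in [lag_min, lag_max] to fit a slope.")
  unname(coef(lm(msd ~ lag, data = sub))[2])
}

#' Clark-Evans style k-th nearest-neighbour ratio
#'
#' Mean observed distance to the k-th nearest other centroid divided by its
#' expectation under complete spatial randomness at the same intensity,
#' `E_k = gamma(k + 1/2) / ((k-1)! * sqrt(pi * lambda))` (for k = 1 this is
#' `1 / (2 sqrt(lambda))`). Ratios below 1 indicate clustering, above 1
#' spreading. No edge correction is applied.
#'
#' @param positions Data frame with `x`, `y` (one frame, one field).
#' @param area Field area in px^2.
#' @param k Neighbour order (1 = nearest other cell).
#' @return One-row tibble: `n`, `area`, `lambda`, `k`, `r_obs`, `r_expected`,
#'   `ratio`.
#' @export
nearest_neighbor_ratio <- function(positions, area, k = 1) {
  check_scalar_number(area, "area", 0, strict_min = TRUE)
  n <- nrow(positions)
  if (n < k + 1) abort(sprintf("need at least k + 1 = %d cells.", k + 1))
  dm <- as.matrix(stats::dist(cbind(positions$x, positions$y)))
  diag(dm) <- Inf
  rk <- apply(dm, 1, function(r) sort(r, partial = k)[k])
  lambda <- n / area
  ek <- gamma(k + 0.5) / (factorial(k - 1) * sqrt(pi * lambda))
  tibble::tibble(n = n, area = area, lambda = lambda, k = k,
                 r_obs = mean(rk), r_expected = ek, ratio = mean(rk) / ek)
}

#' Per-replicate phenotype metrics from a track table
#'
#' Computes, for every condition x replicate: the T0-normalised cell count at
#' `t_eval` (per field, then averaged over fields), the MSD-slope motility
#' (jump-filtered tracks, fields pooled), the Clark-Evans nearest-neighbour
#' ratio at `t_eval` (per field, averaged) and the mean cytoplasmic area of
#' cells present at `t_eval`. `t_eval` is snapped to the nearest available
#' frame.
#'
#' @param tracks Track tibble from [simulate_tracks()] or [read_tracks()].
#' @param t_eval Evaluation time, hours.
#' @param field_area Field area px^2; default `field_size^2` from the track
#'   attributes, falling back to the bounding-box area with a warning.
#' @param k Neighbour order for the spatial ratio.
#' @param lag_min,lag_max MSD slope window (hours).
#' @param max_jump Jump-filter threshold (px) applied before MSD.
#' @return Tibble: `condition`, `replicate`, `count_fc`, `motility`,
#'   `nn_ratio`, `cyto_area`.
#' @export
summarize_phenotypes <- function(tracks, t_eval = 24, field_area = NULL, k = 1,
                                 lag_min = 0.5, lag_max = 6, max_jump = 200) {
  stopifnot(nrow(tracks) > 0)
  if (is.null(field_area)) {
    L <- attr(tracks, "field_size")
    if (is.null(L)) {
      warn("no `field_size` attribute; using the bounding-box area.")
      field_area <- diff(range(tracks$x)) * diff(range(tracks$y))
    } else {
      field_area <- L^2
    }
  }
  frames <- sort(unique(tracks$frame))
  tt <- sort(unique(tracks$t))
  f_eval <- frames[which.min(abs(tt - t_eval))]
  if (max(tt) < t_eval - 1e-9) {
    warn(sprintf("tracks end at %.1f h; evaluating at the last frame.", max(tt)))
  }
  filtered <- filter_tracks(tracks, max_jump = max_jump)
  groups <- tracks %>% distinct(.data$condition, .data$replicate)
  out <- purrr::pmap(groups, function(condition, replicate) {
    sub <- tracks[tracks$condition == condition & tracks$replicate == replicate, ]
    subf <- filtered[filtered$condition == condition & filtered$replicate == replicate, ]
    attr(subf, "frame_interval") <- infer_frame_interval(tracks)
    # count fold change per field
    cfc <- sub %>% group_by(.data$field) %>%
      summarise(n0 = sum(.data$frame == 0), n1 = sum(.data$frame == f_eval),
                .groups = "drop")
    if (any(cfc$n0 == 0)) abort("a field has no cells at frame 0; count_fc undefined.")
    at_eval <- sub %>% filter(.data$frame == f_eval)
    nn_ratios <- vapply(split(at_eval, at_eval$field), function(d) {
      nearest_neighbor_ratio(d, area = field_area, k = k)$ratio
    }, numeric(1))
    slope <- motility_slope(compute_msd(subf), lag_min = lag_min, lag_max = lag_max)
    tibble::tibble(condition = condition, replicate = replicate,
                   count_fc = mean(cfc$n1 / cfc$n0),
                   motility = slope,
                   nn_ratio = mean(nn_ratios),
                   cyto_area = mean(at_eval$area))
  })
  dplyr::bind_rows(out) %>% arrange(.data$condition, .data$replicate)
}

#' PBS-relative response vector and phenotypic response magnitude
#'
#' Each metric is expressed as a relative change from the matched PBS
#' (vehicle) replicate, `rel = (m - m_PBS) / m_PBS`, making the four metrics
#' unitless and commensurable; the phenotypic response magnitude is the
#' Euclidean norm of the resulting four-dimensional vector. The origin
#' (magnitude 0) means no change from vehicle.
#'
#' @param metrics Phenotype tibble from [summarize_phenotypes()] (or the
#'   linked simulator), containing the PBS rows.
#' @param metric_cols The four metric columns.
#' @param reference Reference condition label.
#' @return Input tibble (reference rows removed) with added `rel_*` columns
#'   and `magnitude`.
#' @export
response_magnitude <- function(metrics,
                               metric_cols = c("count_fc", "motility",
                                               "nn_ratio", "cyto_area"),
                               reference = "PBS") {
  stopifnot(all(metric_cols %in% names(metrics)))
  ref <- metrics %>% filter(.data$condition == reference)
  if (nrow(ref) == 0) abort(sprintf("reference condition '%s' not found.", reference))
  if (any(abs(as.matrix(ref[metric_cols])) < 1e-300)) {
    abort("a reference metric is zero; relative changes are undefined.")
  }
  ref <- ref %>% select("replicate", all_of(metric_cols)) %>%
    rename_with_suffix(metric_cols, "_ref")
  out <- metrics %>% filter(.data$condition != reference) %>%
    left_join(ref, by = "replicate")
  if (any(!complete.cases(out[paste0(metric_cols, "_ref")]))) {
    abort("missing matched reference replicate for some rows.")
  }
  for (m in metric_cols) {
    out[[paste0("rel_", m)]] <- (out[[m]] - out[[paste0(m, "_ref")]]) / out[[paste0(m, "_ref")]]
  }
  rel <- as.matrix(out[paste0("rel_", metric_cols)])
  out$magnitude <- sqrt(rowSums(rel^2))
  out %>% select(-all_of(paste0(metric_cols, "_ref")))
}

rename_with_suffix <- function(df, cols, suffix) {
  names(df)[match(cols, names(df))] <- paste0(cols, suffix)
  df
}
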