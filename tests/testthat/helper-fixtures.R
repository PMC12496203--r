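# Small fixtures shared across test files. Everything is generated in code;
# sizes are kept minimal so the whole suite stays fast.

# a single-condition Brownian track set
brownian_params <- function(D = 100, n_cells = 100, n_frames = 25,
                            division_rate = 0, pattern = "poisson") {
  track_sim_params(
    conditions = tibble::tibble(condition = "sim", D = D,
                                division_rate = division_rate,
                                area_mean = 400, area_cv = 0.3,
                                spatial_pattern = pattern),
    n_cells_init = n_cells, n_frames = n_frames,
    n_replicates = 1, n_fields = 1)
}

# hand-built track tibble from a list of (cell_id, frames, x, y)
make_tracks <- function(steps, frame_interval = 0.5) {
  out <- dplyr::bind_rows(lapply(steps, function(s) {
    tibble::tibble(cell_id = s$id, frame = seq_along(s$x) - 1L,
                   t = (seq_along(s$x) - 1L) * frame_interval,
                   x = s$x, y = s$y,
                   area = s$area %||% rep(400, length(s$x)),
                   field = 1L, condition = s$condition %||% "c1",
                   replicate = 1L)
  }))
  attr(out, "frame_interval") <- frame_interval
  attr(out, "field_size") <- 1024
  out
}

`%||%` <- rlang::`%||%`

# tiny two-condition count experiment with known effects
tiny_counts <- function(ng = 300, seed = 1, dispersion = 0.05, ...) {
  simulate_counts(count_sim_params(n_genes = ng, dispersion = dispersion, ...),
                  seed = seed)
}

# brute-force BH step-up (independent of stats::p.adjust)
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
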