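# Shared fixtures and independent oracles, built in code at test time.

# Small, fast movie configuration for pipeline-level tests.
small_config <- function(seed = 1, n_events = 10, duration_s = 30, ...) {
  sim_config(seed = seed, duration_s = duration_s, n_events = n_events,
             width_px = 64, height_px = 64, consecutive_fraction = 0, ...)
}

# Render a single-event spot trace (plus background and optional noise)
# directly from the state machine, bypassing movies — used to test the
# kinetics module in isolation.
make_trace <- function(mech = "persistent", seed = 1, reacidification = TRUE,
                       noise_frac = 0.05, background = 200, cargo = 600,
                       t_on = 2, duration_s = 60, frame_rate = 10,
                       dwell_s = NULL, t_reopen_s = NA,
                       kinetics = vesicle_kinetics()) {
  set.seed(seed)
  kinetics$reacidification <- reacidification
  if (is.null(dwell_s)) dwell_s <- runif(1, 5, 15)
  ev <- list(mech_class = mech, t_on_s = t_on, cargo_units = cargo,
             dwell_s = dwell_s, t_reopen_s = t_reopen_s)
  tr <- render_event_traces(ev, kinetics, frame_rate, duration_s)
  v <- tr$sep_spot + background +
    stats::rnorm(length(tr$sep_spot), 0, noise_frac * max(tr$sep_spot))
  structure(list(event_id = 1L, channel = "SEP", times_s = tr$time_s,
                 spot_intensity = v, surround_intensity = tr$sep_surround,
                 background_B = background, t_on_s = t_on,
                 frame_rate_hz = frame_rate),
            class = "event_trace")
}

# Greedy one-to-one matching of detections to ground truth within a spatial
# window (px) and a time window (s); returns recall/precision counts.
match_detections <- function(det, truth, window_px = 3, window_s = 0.5) {
  tp <- 0L
  used <- rep(FALSE, nrow(det))
  for (i in order(truth$t_on_s)) {
    ok <- which(!used &
                abs(det$x_px - truth$x_px[i]) <= window_px &
                abs(det$y_px - truth$y_px[i]) <= window_px &
                abs(det$t_on_s - truth$t_on_s[i]) <= window_s)
    if (length(ok)) { tp <- tp + 1L; used[ok[1]] <- TRUE }
  }
  list(tp = tp, n_true = nrow(truth), n_det = nrow(det),
       recall = tp / max(1L, nrow(truth)),
       precision = tp / max(1L, nrow(det)))
}

# Exhaustive-enumeration oracle for the null model: averages the success
# indicator over every placement tuple (M^N) and every persistent subset,
# with the placement index serving as the time order. Independent of the
# package's replicate code path.
enumerate_null_probability <- function(cells, N, n_persistent,
                                       window_side = 1) {
  M <- length(cells)
  stopifnot(M^N <= 2e5)
  subsets <- utils::combn(N, n_persistent)
  grid <- as.matrix(expand.grid(rep(list(seq_len(M)), N)))
  succ_total <- 0
  for (g in seq_len(nrow(grid))) {
    ev_cells <- cells[grid[g, ]]
    hits <- 0
    for (s in seq_len(ncol(subsets))) {
      found <- FALSE
      for (p in subsets[, s]) {
        if (p < N && any(ev_cells[(p + 1):N] == ev_cells[p])) {
          found <- TRUE; break
        }
      }
      hits <- hits + found
    }
    succ_total <- succ_total + hits / ncol(subsets)
  }
  succ_total / nrow(grid)
}
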