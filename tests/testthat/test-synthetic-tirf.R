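test_that("mask generation is deterministic and honours exact pixel counts", {
  m <- generate_mask("full", 10, 10)
  expect_equal(sum(m), 100)

  m1 <- generate_mask("neuron", 64, 64, seed = 7)
  m2 <- generate_mask("neuron", 64, 64, seed = 7)
  expect_identical(m1, m2)
  expect_false(identical(m1, generate_mask("neuron", 64, 64, seed = 8)))

  # exact popcount verified by brute-force pixel scan
  tgt <- generate_mask(list(type = "neuron", target_foreground = 15318),
                       160, 160, seed = 3)
  count <- 0L
  for (i in seq_len(nrow(tgt))) for (j in seq_len(ncol(tgt)))
    if (tgt[i, j] == 1L) count <- count + 1L
  expect_identical(count, 15318L)

  expect_error(generate_mask(list(type = "neuron", target_foreground = 0),
                             32, 32), "zero-area")
})

test_that("neuron mask foreground is a single connected component", {
  skip_if_not_installed("EBImage")
  for (s in 1:3) {
    m <- generate_mask(list(type = "neuron", target_foreground = 4000),
                       96, 96, seed = s)
    lab <- EBImage::bwlabel(m)
    expect_equal(max(lab), 1)
  }
})

test_that("event sampling matches the generative model", {
  mask <- generate_mask("full", 32, 32)
  cfg0 <- sim_config(n_events = 0, exact_n_events = TRUE, seed = 1)
  expect_equal(nrow(sample_events(cfg0, mask)), 0)

  # forced pairing: every event persistent and paired
  cfgp <- sim_config(n_events = 4, exact_n_events = TRUE,
                     persistent_fraction = 1, consecutive_fraction = 1,
                     seed = 2)
  ev <- sample_events(cfgp, mask)
  expect_equal(nrow(ev), 8)
  expect_equal(sum(ev$mech_class == "kiss_and_run_pair_first"), 4)
  expect_equal(sum(ev$mech_class == "kiss_and_run_pair_second"), 4)
  for (pid in unique(ev$pair_id)) {
    pair <- ev[!is.na(ev$pair_id) & ev$pair_id == pid, ]
    expect_equal(pair$x_px[1], pair$x_px[2])
    expect_equal(pair$y_px[1], pair$y_px[2])
    expect_gt(max(pair$t_on_s), min(pair$t_on_s))
    expect_equal(pair$mech_class[order(pair$t_on_s)],
                 c("kiss_and_run_pair_first", "kiss_and_run_pair_second"))
  }

  # persistent fraction within 3 binomial SE at n = 10,000
  cfg <- sim_config(n_events = 10000, exact_n_events = TRUE, seed = 3,
                    consecutive_fraction = 0)
  ev <- sample_events(cfg, mask)
  frac <- mean(ev$mech_class == "persistent")
  se <- sqrt(0.098 * 0.902 / 10000)
  expect_lt(abs(frac - 0.098), 3 * se)

  # all sampled positions on the mask foreground
  neuron <- generate_mask("neuron", 64, 64, seed = 4)
  cfgm <- sim_config(n_events = 200, exact_n_events = TRUE, seed = 5,
                     width_px = 64, height_px = 64)
  evm <- sample_events(cfgm, neuron)
  expect_true(all(neuron[cbind(evm$y_px + 1, evm$x_px + 1)] == 1L))
})

test_that("trace state machine produces the expected per-class shapes", {
  kin <- vesicle_kinetics()
  fr <- 10
  idx <- function(t) round(t * fr) + 1
  f_open <- 1 / (1 + 10^(kin$sep_pka - kin$ph_open))

  # transient: one-frame rise, single exponential decay, mCherry steps to 0
  ev <- list(mech_class = "transient", t_on_s = 5, cargo_units = 600,
             dwell_s = NA, t_reopen_s = NA)
  tr <- render_event_traces(ev, kin, fr, 30)
  peak <- 600 * f_open
  expect_lt(tr$sep_spot[idx(4.9)], 0.05 * peak)
  expect_equal(tr$sep_spot[idx(5)], peak, tolerance = 1e-6)
  # decay half-life 2 s: value at t_on + 2 is half the peak
  expect_equal(tr$sep_spot[idx(7)], peak / 2, tolerance = 1e-6)
  expect_equal(tr$mch_spot[idx(4.9)], 600)
  expect_equal(tr$mch_spot[idx(5)], 0)

  # kiss-and-run, control: peak, partial drop, slow reacidification decay,
  # second peak at reopening; mCherry partial drop then 0
  ev <- list(mech_class = "kiss_and_run_pair_first", t_on_s = 5,
             cargo_units = 600, dwell_s = 10, t_reopen_s = 20)
  tr <- render_event_traces(ev, kin, fr, 40)
  expect_equal(max(tr$sep_spot), tr$sep_spot[idx(5)], tolerance = 0.01)
  mid <- tr$sep_spot[idx(15)]        # during reacidification
  expect_lt(mid, 0.5 * peak)         # decayed below the retained level
  repeak <- tr$sep_spot[idx(20)]
  expect_gt(repeak, mid)             # second opening re-brightens the spot
  expect_equal(repeak, 0.5 * peak, tolerance = 0.05)
  expect_equal(tr$mch_spot[idx(10)], 300)
  expect_equal(tr$mch_spot[idx(25)], 0)

  # kiss-and-run under bafilomycin: no inter-opening decay (plateau)
  kinb <- kin; kinb$reacidification <- FALSE
  trb <- render_event_traces(ev, kinb, fr, 40)
  # window starts after the first-release pool has dispersed (>4 half-lives)
  inter <- trb$sep_spot[idx(13):idx(19)]
  expect_lt(stats::sd(inter), 0.02 * peak)
  expect_equal(mean(inter), 0.5 * peak, tolerance = 0.05)

  # plain persistent control: slow decay with 17 s half-life from the close
  evp <- list(mech_class = "persistent", t_on_s = 2, cargo_units = 600,
              dwell_s = 10, t_reopen_s = NA)
  trp <- render_event_traces(evp, kin, fr, 60)
  t_close <- 2 + kin$pore_open_s
  v1 <- trp$sep_spot[idx(t_close)]
  v2 <- trp$sep_spot[idx(t_close + 17)]
  floor_v <- 600 / (1 + 10^(kin$sep_pka - kin$ph_closed))
  expect_equal((v2 - floor_v) / (v1 - floor_v), 0.5, tolerance = 0.01)
})

test_that("simulator invariants: cargo conservation and pre-fusion SEP quenching", {
  kin <- vesicle_kinetics()
  cfg <- small_config(seed = 11)
  mask <- generate_mask("full", 32, 32)
  ev <- sample_events(sim_config(n_events = 30, exact_n_events = TRUE,
                                 persistent_fraction = 0.3,
                                 consecutive_fraction = 0.5, seed = 12),
                      mask, kin)
  for (i in seq_len(nrow(ev))) {
    tr <- render_event_traces(ev[i, ], kin, 10, 60)
    # cargo conservation: retained + cumulative released is constant
    expect_equal(max(tr$retained + tr$cum_released),
                 min(tr$retained + tr$cum_released), tolerance = 1e-9)
    # SEP quenched pre-fusion: below 3% of the open-pore brightness
    pre <- tr$time_s < ev$t_on_s[i] - 0.1
    if (any(pre))
      expect_lt(max(tr$sep_spot[pre]), 0.03 * ev$cargo_units[i])
  }
})

test_that("movies render with correct background, bleaching and determinism", {
  # no events: frame mean ~ background
  cfg <- sim_config(n_events = 0, duration_s = 10, width_px = 48,
                    height_px = 48, bleach_fraction = 0, seed = 21,
                    mask_spec = "full", channels = "SEP")
  mov <- simulate_movie(cfg)$movie
  expect_equal(mean(mov$pixels$SEP), 200, tolerance = 0.01)

  # 10% bleaching: last-frame mean is 90% of first-frame mean
  cfgb <- sim_config(n_events = 0, duration_s = 20, width_px = 48,
                     height_px = 48, bleach_fraction = 0.10, seed = 22,
                     mask_spec = "full", channels = "SEP")
  movb <- simulate_movie(cfgb)$movie
  nt <- dim(movb$pixels$SEP)[3]
  ratio <- mean(movb$pixels$SEP[, , nt]) / mean(movb$pixels$SEP[, , 1])
  expect_equal(ratio, 0.90, tolerance = 0.01)

  # bit-identical reproduction under the same seed, ground truth included
  cfg2 <- small_config(seed = 23)
  a <- simulate_movie(cfg2); b <- simulate_movie(cfg2)
  expect_identical(a$movie$pixels, b$movie$pixels)
  expect_identical(a$events, b$events)

  # events off the mask are rejected
  bad <- data.frame(event_id = 1L, pair_id = NA, x_px = 0L, y_px = 0L,
                    t_on_s = 1, mech_class = "transient", cargo_units = 500,
                    dwell_s = NA, t_reopen_s = NA)
  msk <- matrix(0L, 48, 48); msk[20:30, 20:30] <- 1L
  cfg3 <- sim_config(width_px = 48, height_px = 48, duration_s = 5, seed = 1)
  expect_error(render_movie(cfg3, vesicle_kinetics(), bad, mask = msk),
               "outside mask")
})

test_that("condition knobs scale event statistics as expected", {
  mult_kcl <- condition_multipliers("KCl")
  expect_gt(mult_kcl$n_events_mult, 1)
  expect_gt(mult_kcl$persistent_mult, 1)
  expect_equal(condition_multipliers("cycloheximide")$n_events_mult, 1)

  mask <- generate_mask("full", 32, 32)
  n_basal <- sapply(1:20, function(s)
    nrow(sample_events(sim_config(condition = "basal", seed = s), mask)))
  n_kcl <- sapply(1:20, function(s)
    nrow(sample_events(sim_config(condition = "KCl", seed = 100 + s), mask)))
  expect_gt(mean(n_kcl), mean(n_basal))
})

test_that("movie TIFF round-trip preserves pixels and metadata", {
  cfg <- sim_config(duration_s = 2, width_px = 24, height_px = 24,
                    n_events = 2, exact_n_events = TRUE, seed = 31,
                    mask_spec = "full")
  sim <- suppressWarnings(simulate_movie(cfg))
  path <- tempfile(fileext = ".tif")
  write_movie(sim$movie, path)
  back <- read_movie(path)
  expect_equal(back$frame_rate_hz, 10)
  expect_equal(back$channels, c("SEP", "mCherry"))
  # 16-bit storage quantises to unit steps at this scale
  expect_lt(max(abs(back$pixels$SEP - sim$movie$pixels$SEP)), 1.01)

  gt_path <- tempfile(fileext = ".csv")
  write_ground_truth(sim$events, gt_path)
  gt <- read_ground_truth(gt_path)
  expect_equal(gt$x_px, sim$events$x_px)
  expect_equal(gt$mech_class, sim$events$mech_class)
  unlink(c(path, paste0(path, ".json"), gt_path))
})
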