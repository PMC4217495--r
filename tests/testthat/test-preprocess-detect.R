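make_uniform_movie <- function(value, ny = 32, nx = 32, nt = 20, fr = 10,
                               mask = NULL) {
  structure(list(pixels = list(SEP = array(value, dim = c(ny, nx, nt))),
                 frame_rate_hz = fr, pixel_pitch_um = 0.16,
                 channels = "SEP", mask = mask),
            class = "tirf_movie")
}

test_that("background subtraction recovers offsets and the generator's B", {
  # movie equal to the blank field -> all zeros
  mov <- make_uniform_movie(100)
  blank <- matrix(100, 32, 32)
  out <- subtract_background(mov, blank)
  expect_true(all(out$pixels$SEP == 0))

  # constant offset removed exactly
  base <- simulate_movie(small_config(seed = 41, n_events = 3,
                                      exact_n_events = TRUE))$movie
  shifted <- base
  shifted$pixels$SEP <- base$pixels$SEP + 100
  rec <- subtract_background(shifted, matrix(100, 64, 64), clip = FALSE)
  expect_equal(rec$pixels$SEP, base$pixels$SEP, tolerance = 1e-12)

  # mode estimator: off-mask mean ~ 0 after subtraction (generator B = 200)
  sim <- simulate_movie(small_config(seed = 42))
  sub <- subtract_background(sim$movie, clip = FALSE)
  off <- sim$mask == 0L
  offmean <- mean(apply(sub$pixels$SEP, 3, function(f) mean(f[off])))
  expect_lt(abs(offmean), 2)

  expect_error(subtract_background(mov, matrix(1, 5, 5)), "shape")
})

test_that("photobleaching estimation recovers the generator's loss", {
  # no bleaching: estimate ~ 0 and movie essentially unchanged
  cfg0 <- small_config(seed = 43, bleach_fraction = 0, n_events = 0)
  sim0 <- simulate_movie(cfg0)
  bc0 <- correct_bleaching(sim0$movie)
  expect_lt(abs(bc0$bleach_fraction_est["SEP"]), 0.02)
  expect_equal(bc0$movie$pixels$SEP, sim0$movie$pixels$SEP, tolerance = 0.03)

  # 10% bleaching recovered within +-0.02
  cfg <- small_config(seed = 44, bleach_fraction = 0.10)
  sim <- simulate_movie(cfg)
  bc <- correct_bleaching(sim$movie)
  expect_lt(abs(unname(bc$bleach_fraction_est["SEP"]) - 0.10), 0.02)

  # correction flattens the off-event whole-field trend >= 10-fold
  off <- sim$mask == 0L
  slope_of <- function(stack) {
    m <- apply(stack, 3, function(f) mean(f[off]))
    unname(stats::coef(stats::lm(m ~ seq_along(m)))[2])
  }
  s_raw <- slope_of(sim$movie$pixels$SEP)
  s_cor <- slope_of(bc$movie$pixels$SEP)
  expect_lt(abs(s_cor), abs(s_raw) / 10)

  expect_error(correct_bleaching(make_uniform_movie(1, nt = 5)), "10 frames")
})

test_that("detection is calibrated: rare false positives on pure noise", {
  fps <- sapply(1:6, function(s) {
    cfg <- small_config(seed = 200 + s, n_events = 0, bleach_fraction = 0)
    sim <- simulate_movie(cfg)
    nrow(detect_events(subtract_background(sim$movie, clip = FALSE)))
  })
  expect_lt(mean(fps), 1.5)   # MC bound on the expected FP count per movie
})

test_that("a single high-SNR event is localised to 1 px and 1 frame", {
  cfg <- sim_config(seed = 51, duration_s = 20, n_events = 0,
                    width_px = 48, height_px = 48, mask_spec = "full",
                    channels = "SEP")
  ev <- data.frame(event_id = 1L, pair_id = NA, x_px = 20L, y_px = 25L,
                   t_on_s = 8.0, mech_class = "transient",
                   cargo_units = 1500, dwell_s = NA, t_reopen_s = NA)
  mov <- render_movie(cfg, vesicle_kinetics(), ev, seed = 51)
  det <- detect_events(subtract_background(mov, clip = FALSE))
  expect_equal(nrow(det), 1)
  expect_lte(abs(det$x_px - 20), 1)
  expect_lte(abs(det$y_px - 25), 1)
  expect_lte(abs(det$t_on_s - 8.0), 0.1)
})

test_that("detection count is monotone non-increasing in the threshold", {
  cfg <- small_config(seed = 52, n_events = 15, exact_n_events = TRUE)
  sub <- subtract_background(simulate_movie(cfg)$movie, clip = FALSE)
  counts <- sapply(c(3, 5, 8, 15), function(k)
    nrow(detect_events(sub, min_rise_sigma = k)))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection is translation-equivariant", {
  cfg <- sim_config(seed = 53, duration_s = 15, n_events = 0,
                    width_px = 48, height_px = 48, mask_spec = "full",
                    channels = "SEP", read_noise_sd = 5)
  ev <- data.frame(event_id = 1:2, pair_id = NA, x_px = c(15L, 30L),
                   y_px = c(18L, 28L), t_on_s = c(4, 9),
                   mech_class = "transient", cargo_units = 1200,
                   dwell_s = NA, t_reopen_s = NA)
  mov <- render_movie(cfg, vesicle_kinetics(), ev, seed = 53)
  det0 <- detect_events(subtract_background(mov, clip = FALSE))

  shifted <- mov
  dx <- 5L; dy <- 3L
  arr <- array(200, dim = dim(mov$pixels$SEP))  # background fill
  arr[(1 + dy):48, (1 + dx):48, ] <-
    mov$pixels$SEP[1:(48 - dy), 1:(48 - dx), ]
  shifted$pixels$SEP <- arr
  det1 <- detect_events(subtract_background(shifted, clip = FALSE))
  det1 <- det1[order(det1$t_on_s), ]
  expect_equal(nrow(det1), nrow(det0))
  expect_equal(det1$x_px, det0$x_px + dx)
  expect_equal(det1$y_px, det0$y_px + dy)
  expect_equal(det1$t_on_s, det0$t_on_s)
})

test_that("trace extraction: ROI geometry, uniform movies and sustained surround", {
  # ROI physical-to-pixel conversion at the acquisition pitch
  expect_equal(roi_side_px(4, 0.16), 13)
  expect_equal(roi_side_px(16, 0.16), 25)
  expect_equal(roi_side_px(1, 0.16), 7)

  mov <- make_uniform_movie(42, ny = 40, nx = 40)
  ev <- data.frame(event_id = 1L, x_px = 20, y_px = 20, t_on_s = 1)
  tr <- extract_trace(mov, ev)
  expect_true(all(tr$spot_intensity == 42))
  expect_true(all(tr$surround_intensity == 42))

  # an edge event with a mostly clipped ROI errors
  ev_edge <- data.frame(event_id = 2L, x_px = 0, y_px = 0, t_on_s = 1)
  expect_error(suppressWarnings(extract_trace(mov, ev_edge)), "clipped")

  # transient event leaves a sustained surround elevation (released pool)
  cfg <- sim_config(seed = 54, duration_s = 30, n_events = 0,
                    width_px = 64, height_px = 64, mask_spec = "full",
                    channels = "SEP", bleach_fraction = 0)
  evt <- data.frame(event_id = 1L, pair_id = NA, x_px = 32L, y_px = 32L,
                    t_on_s = 10, mech_class = "transient",
                    cargo_units = 1500, dwell_s = NA, t_reopen_s = NA)
  movt <- render_movie(cfg, vesicle_kinetics(), evt, seed = 54)
  trt <- extract_trace(movt, evt)
  pre <- trt$surround_intensity[trt$times_s < 9]
  post <- trt$surround_intensity[trt$times_s > 20]
  expect_gt(mean(post), mean(pre) + 3 * stats::sd(pre) / sqrt(length(pre)))
})

test_that("rise time measurement: step, ramp and resolution limit", {
  mk <- function(v, fr = 10) structure(
    list(event_id = 1L, channel = "SEP", times_s = (seq_along(v) - 1) / fr,
         spot_intensity = v, surround_intensity = NULL, background_B = v[1],
         t_on_s = 0, frame_rate_hz = fr),
    class = "event_trace")

  # single-frame step: resolution-limited to one frame interval
  step <- mk(c(rep(10, 20), rep(110, 20)))
  expect_equal(measure_rise_time(step), 0.1)

  # linear ramp over 10 frames (1 s): 10-90% = 0.8 s
  ramp <- mk(c(rep(0, 10), seq(0, 100, length.out = 11), rep(100, 10)))
  expect_equal(measure_rise_time(ramp), 0.8, tolerance = 1e-6)

  # peak at first frame is flagged
  bad <- mk(c(100, seq(90, 10, length.out = 15)))
  expect_warning(rt <- measure_rise_time(bad), "first frame")
  expect_true(is.na(rt))
})

test_that("kymographs render static fields, streaks and persistent bands", {
  mov <- make_uniform_movie(7, ny = 40, nx = 40, nt = 30)
  path <- cbind(c(5, 35), c(20, 20))
  ky <- kymograph(mov, path)
  expect_true(all(ky == 7))
  expect_equal(ncol(ky), 30)

  cfg <- sim_config(seed = 55, duration_s = 30, n_events = 0,
                    width_px = 48, height_px = 48, mask_spec = "full",
                    channels = "SEP", bleach_fraction = 0)
  evs <- data.frame(event_id = 1:2, pair_id = NA, x_px = c(14L, 34L),
                    y_px = 24L, t_on_s = c(10, 12),
                    mech_class = c("transient", "persistent"),
                    cargo_units = 1500, dwell_s = c(NA, 12),
                    t_reopen_s = NA)
  mov2 <- render_movie(cfg, vesicle_kinetics(), evs, seed = 55)
  ky2 <- kymograph(mov2, cbind(c(5, 45), c(24, 24)), width_px = 3)
  row_tr <- which.min(abs(seq(5, 45, length.out = nrow(ky2)) - 14))
  row_pe <- which.min(abs(seq(5, 45, length.out = nrow(ky2)) - 34))
  base <- median(ky2)
  thr <- base + 500   # half the rendered peak amplitude
  # transient streak: short; persistent band: > 4 s of supra-threshold frames
  dur_tr <- sum(ky2[row_tr, ] > thr) / 10
  dur_pe <- sum(ky2[row_pe, ] > thr) / 10
  expect_lt(dur_tr, 4)
  expect_gt(dur_pe, 4)

  expect_error(kymograph(mov, cbind(5, 20)), "vertices")
})
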