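# Separable Gaussian smoothing of a [y, x, t] stack, edge-renormalised.
smooth_stack <- function(stack, sigma) {
  if (sigma <= 0) return(stack)
  d <- dim(stack)
  gy <- band_gaussian(d[1], sigma)
  gx <- band_gaussian(d[2], sigma)
  m <- gy %*% matrix(stack, d[1], d[2] * d[3])
  a <- aperm(array(m, d), c(2, 1, 3))
  m <- gx %*% matrix(a, d[2], d[1] * d[3])
  aperm(array(m, c(d[2], d[1], d[3])), c(2, 1, 3))
}

band_gaussian <- function(n, sigma) {
  r <- ceiling(3 * sigma)
  g <- outer(seq_len(n), seq_len(n), function(i, j) {
    w <- exp(-(i - j)^2 / (2 * sigma^2))
    w * (abs(i - j) <= r)
  })
  g / rowSums(g)
}

#' Detect exocytic events in a movie
#'
#' Automated replacement for by-eye event counting: a temporal forward
#' difference over two frames highlights rapid discrete intensity increases,
#' each difference frame is smoothed with a Gaussian matched to the spot
#' size, and local maxima above `min_rise_sigma` times the robust
#' (MAD-based) noise SD of the filtered stack are kept. Candidate maxima
#' within the same-site window (a 1 um square) and closer in time than
#' `min_separation_s` are merged into one detection, keeping the strongest;
#' rises further apart in time — e.g. the two openings of a kiss-and-run
#' pair — are reported as separate events. The onset frame is refined to the
#' frame with the largest single-frame increment at the site.
#'
#' @param movie a background-subtracted `tirf_movie`.
#' @param channel channel to detect on (default `"SEP"`).
#' @param min_rise_sigma detection threshold in robust noise SDs (default 5).
#' @param min_spot_sigma_px spatial smoothing sigma in pixels.
#' @param min_separation_s temporal merge window for same-site candidates.
#' @return data.frame of class `detected_events`, sorted by onset: columns
#'   `event_id`, `x_px`, `y_px` (0-based), `t_on_s`, `strength` (filter
#'   response in noise SDs).
#' @export
detect_events <- function(movie, channel = "SEP", min_rise_sigma = 5,
                          min_spot_sigma_px = 1.3, min_separation_s = 1) {
  stack <- movie$pixels[[channel]]
  d <- dim(stack); ny <- d[1]; nx <- d[2]; nt <- d[3]
  if (nt < 3) return(empty_detections())
  sm <- smooth_stack(stack, min_spot_sigma_px)
  dif <- sm[, , 3:nt, drop = FALSE] - sm[, , 1:(nt - 2), drop = FALSE]
  # Standardise with a per-pixel noise SD: shot noise scales with intensity
  # and the edge-renormalised smoothing leaves border pixels noisier than
  # the bulk. The raw-difference variance is estimated robustly per pixel
  # (temporal MAD, insensitive to the sparse event frames) and propagated
  # through the smoothing weights exactly (variance of a weighted sum).
  raw_dif <- stack[, , 3:nt, drop = FALSE] - stack[, , 1:(nt - 2), drop = FALSE]
  gy2 <- band_gaussian(ny, min_spot_sigma_px)^2
  gx2 <- band_gaussian(nx, min_spot_sigma_px)^2
  ntd <- nt - 2L
  # noise maps per temporal epoch: slow variance drift (bleach correction
  # rescaling, intensity changes) would otherwise decalibrate the threshold
  n_epochs <- max(1L, round(ntd / 100))
  epoch <- if (n_epochs == 1L) rep(1L, ntd)
           else cut(seq_len(ntd), n_epochs, labels = FALSE)
  z <- dif
  for (e in seq_len(n_epochs)) {
    idx <- which(epoch == e)
    var_raw <- apply(raw_dif[, , idx, drop = FALSE], c(1, 2), mad_sd)^2
    var_sm <- gy2 %*% var_raw %*% t(gx2)
    floor_var <- stats::median(var_sm) * 0.04 + 1e-12
    noise_map <- sqrt(pmax(var_sm, floor_var))
    z[, , idx] <- sweep(dif[, , idx, drop = FALSE], c(1, 2), noise_map, `/`)
  }

  cand <- which(z > min_rise_sigma & local_max3(z), arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty_detections())
  val <- z[cand]
  ord <- order(val, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]; val <- val[ord]
  if (nrow(cand) > 20000) stop("implausibly many candidate rises; check background subtraction")

  w_px <- max(1, round(0.5 / movie$pixel_pitch_um))
  w_t <- min_separation_s * movie$frame_rate_hz
  # a single fusion also lifts the diffuse released-pool halo, which can
  # carry secondary maxima well outside the 1 um window at the same instant
  w_sim <- max(w_px, round(2.5 / movie$pixel_pitch_um))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1) { keep[1] <- TRUE; next }
    prev <- which(keep[seq_len(i - 1)])
    dy <- abs(cand[prev, 1] - cand[i, 1])
    dx <- abs(cand[prev, 2] - cand[i, 2])
    dt <- abs(cand[prev, 3] - cand[i, 3])
    close <- (dx <= w_px & dy <= w_px & dt <= w_t) |
             (dx <= w_sim & dy <= w_sim & dt <= 2)
    keep[i] <- !any(close)
  }
  cand <- cand[keep, , drop = FALSE]; val <- val[keep]

  # onset refinement: largest single-frame increment around the rise
  t_on <- vapply(seq_len(nrow(cand)), function(i) {
    y <- cand[i, 1]; x <- cand[i, 2]; td <- cand[i, 3]  # dif index: rise in (td, td+2)
    u <- td + c(1L, 2L)
    u <- u[u >= 2 & u <= nt]
    inc <- sm[y, x, u] - sm[y, x, u - 1L]
    u[which.max(inc)]
  }, numeric(1))

  det <- data.frame(event_id = seq_along(val),
                    x_px = cand[, 2] - 1L, y_px = cand[, 1] - 1L,
                    t_on_s = (t_on - 1) / movie$frame_rate_hz,
                    strength = val)
  det <- det[order(det$t_on_s), ]
  det$event_id <- seq_len(nrow(det))
  rownames(det) <- NULL
  class(det) <- c("detected_events", "data.frame")
  det
}

empty_detections <- function() {
  det <- data.frame(event_id = integer(), x_px = integer(), y_px = integer(),
                    t_on_s = numeric(), strength = numeric())
  class(det) <- c("detected_events", "data.frame")
  det
}

# TRUE where a voxel is the strict maximum of its 3x3 spatial neighbourhood.
local_max3 <- function(stack) {
  d <- dim(stack)
  res <- array(TRUE, dim = d)
  pad <- array(-Inf, dim = d + c(2, 2, 0))
  pad[2:(d[1] + 1), 2:(d[2] + 1), ] <- stack
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[(2 + dy):(d[1] + 1 + dy), (2 + dx):(d[2] + 1 + dx), , drop = FALSE]
    res <- res & (stack >= nb)
  }
  res
}

#' Extract spot and surround intensity traces for an event
#'
#' The spot trace is the per-frame maximum inside a small square ROI
#' (default 4 um^2, 13x13 px at 0.16 um/px) centred on the insertion site;
#' the surround trace is the per-frame mean over a larger ROI (default
#' 16 um^2, 25x25 px) excluding the spot ROI. The background level `B` is
#' the median spot intensity over up to 10 frames (1 s) before onset, at
#' least 3 frames. ROIs clipped at the frame border raise a warning, and an
#' error if more than half the ROI is lost.
#'
#' @param movie a `tirf_movie`.
#' @param event one-row data.frame with `x_px`, `y_px`, `t_on_s` (a detected
#'   or ground-truth event).
#' @param channel channel name.
#' @param roi_small_um2,roi_large_um2 physical ROI areas.
#' @param exclude_px optional 2-column matrix of 0-based (x, y) positions of
#'   other events; ROI pixels within 3 px of any of them are excluded so a
#'   neighbouring event's point-spread skirt cannot masquerade as this
#'   event's signal.
#' @return object of class `event_trace`: list with `event_id`, `channel`,
#'   `times_s`, `spot_intensity`, `surround_intensity`, `background_B`,
#'   `t_on_s`, `frame_rate_hz`.
#' @export
extract_trace <- function(movie, event, channel = "SEP",
                          roi_small_um2 = 4, roi_large_um2 = 16,
                          exclude_px = NULL) {
  stack <- movie$pixels[[channel]]
  ny <- dim(stack)[1]; nx <- dim(stack)[2]; nt <- dim(stack)[3]
  s_small <- roi_side_px(roi_small_um2, movie$pixel_pitch_um)
  s_large <- roi_side_px(roi_large_um2, movie$pixel_pitch_um)
  r1 <- (s_small - 1L) %/% 2L; r2 <- (s_large - 1L) %/% 2L
  row0 <- event$y_px + 1L; col0 <- event$x_px + 1L

  rows2 <- max(1L, row0 - r2):min(ny, row0 + r2)
  cols2 <- max(1L, col0 - r2):min(nx, col0 + r2)
  clip <- 1 - length(rows2) * length(cols2) / s_large^2
  if (clip > 0.5) stop("event ROI clipped by more than 50% at the frame edge")
  if (clip > 0) warning("event ROI clipped at the frame edge")
  rows1 <- max(1L, row0 - r1):min(ny, row0 + r1)
  cols1 <- max(1L, col0 - r1):min(nx, col0 + r1)

  keep_ok <- function(rows, cols) {
    ok <- matrix(TRUE, length(rows), length(cols))
    if (!is.null(exclude_px) && nrow(exclude_px) > 0) {
      for (k in seq_len(nrow(exclude_px))) {
        dx2 <- outer(rows - (exclude_px[k, 2] + 1L),
                     cols - (exclude_px[k, 1] + 1L),
                     function(dy, dx) dy^2 + dx^2)
        ok <- ok & (dx2 > 9)
      }
    }
    ok
  }
  sub2 <- stack[rows2, cols2, , drop = FALSE]
  sub1 <- stack[rows1, cols1, , drop = FALSE]
  ok1 <- keep_ok(rows1, cols1)
  if (!any(ok1)) ok1[] <- TRUE   # fully shadowed: fall back to the full ROI
  spot <- apply(sub1, 3, function(f) max(f[ok1]))
  in_small <- outer(rows2 %in% rows1, cols2 %in% cols1, `&`)
  ok2 <- keep_ok(rows2, cols2) & !in_small
  if (!any(ok2)) ok2 <- !in_small
  surround <- apply(sub2, 3, function(f) mean(f[ok2]))

  fr <- movie$frame_rate_hz
  on_frame <- as.integer(floor(event$t_on_s * fr)) + 1L
  pre <- max(1L, on_frame - 10L):max(1L, on_frame - 1L)
  if (length(pre) < 3 || on_frame <= 1L) pre <- seq_len(min(3L, nt))
  # the whole-trace lower quartile guards the pre-onset estimate against a
  # neighbouring event still decaying through the pre-onset window
  b <- min(stats::median(spot[pre]),
           stats::quantile(spot, 0.25, names = FALSE))

  structure(list(event_id = event$event_id %||% NA_integer_,
                 channel = channel,
                 times_s = (seq_len(nt) - 1) / fr,
                 spot_intensity = spot, surround_intensity = surround,
                 background_B = b, t_on_s = event$t_on_s,
                 frame_rate_hz = fr),
            class = "event_trace")
}

#' Measure the 10-90% rise time of an event trace
#'
#' Linearly interpolates the times at which the spot trace crosses 10% and
#' 90% of the peak amplitude above background, searching backwards from the
#' peak. Rises faster than one frame interval cannot be resolved at the
#' acquisition rate, so the frame interval is the smallest value returned.
#'
#' @param trace an `event_trace`.
#' @return rise time in seconds; `NA` with a warning if the peak is at the
#'   first frame.
#' @export
measure_rise_time <- function(trace) {
  v <- trace$spot_intensity
  tt <- trace$times_s
  b <- trace$background_B
  fr <- trace$frame_rate_hz
  # Anchor on the event's own rise: the peak is searched near the onset and
  # taken at its first attainment — noise on later frames of a plateau or
  # decay top would otherwise inflate the 90% level and stretch the
  # apparent rise.
  anchored <- !is.null(trace$t_on_s) && !is.na(trace$t_on_s)
  if (anchored) {
    # work on the median-smoothed trace: single-frame noise at the decay
    # top would otherwise outrank the onset frame and stretch the rise
    v <- stats::runmed(v, 3)
    i0 <- max(1L, which(tt >= trace$t_on_s - 1e-9)[1] - 1L)
    win <- i0:min(length(v), i0 + as.integer(3 * fr))
    pk <- max(v[win])
    ip <- win[which(v[win] >= pk - 0.05 * (pk - b))[1]]
  } else {
    ip <- which.max(v)
  }
  if (ip == 1) { warning("peak at first frame; rise time undefined"); return(NA_real_) }
  # The 10/90% levels are relative to the local pre-onset baseline (the
  # minimum of the median-smoothed trace over the preceding second): an
  # earlier event at the same site would otherwise either hold the trace
  # above the global-background levels for seconds (its decay) or drag the
  # baseline to its own pre-rise level (its rise). Rises slower than the
  # 1 s window are right-truncated.
  prewin <- max(1L, ip - as.integer(1 * fr)):(ip - 1L)
  b_loc <- max(b, min(stats::runmed(v, 3)[prewin]))
  b_loc <- min(b_loc, v[ip])          # degenerate flat traces
  lev10 <- b_loc + 0.1 * (v[ip] - b_loc)
  lev90 <- b_loc + 0.9 * (v[ip] - b_loc)
  cross_time <- function(level) {
    below <- prewin[v[prewin] <= level]
    if (length(below) == 0) return(tt[prewin[1]])
    i <- max(below)
    tt[i] + (level - v[i]) / (v[i + 1] - v[i]) * (tt[i + 1] - tt[i])
  }
  rt <- cross_time(lev90) - cross_time(lev10)
  max(rt, 1 / fr)
}

#' Build a kymograph along a polyline path
#'
#' Samples the movie along a polyline at one-pixel arc steps, averaging over
#' `width_px` samples perpendicular to the path, and stacks the samples over
#' time: rows are positions along the path, columns are frames.
#'
#' @param movie a `tirf_movie`.
#' @param path_px 2-column matrix of 0-based (x, y) polyline vertices.
#' @param width_px perpendicular averaging width in pixels (odd).
#' @param channel channel name.
#' @return matrix (positions x frames).
#' @export
kymograph <- function(movie, path_px, width_px = 1, channel = "SEP") {
  if (is.null(dim(path_px)) || nrow(path_px) < 2) stop("path needs >= 2 vertices")
  stack <- movie$pixels[[channel]]
  ny <- dim(stack)[1]; nx <- dim(stack)[2]; nt <- dim(stack)[3]

  pts <- list(); dirs <- list()
  for (s in seq_len(nrow(path_px) - 1)) {
    p0 <- path_px[s, ]; p1 <- path_px[s + 1, ]
    len <- sqrt(sum((p1 - p0)^2))
    n <- max(2, ceiling(len))
    frac <- seq(0, 1, length.out = n)
    if (s > 1) frac <- frac[-1]
    seg <- cbind(p0[1] + frac * (p1[1] - p0[1]), p0[2] + frac * (p1[2] - p0[2]))
    u <- (p1 - p0) / len
    pts[[s]] <- seg
    dirs[[s]] <- matrix(rep(c(-u[2], u[1]), each = nrow(seg)), ncol = 2)
  }
  pts <- do.call(rbind, pts); perp <- do.call(rbind, dirs)
  offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2)

  idx <- sapply(offs, function(o) {
    x <- pmin(pmax(round(pts[, 1] + o * perp[, 1]), 0), nx - 1)
    y <- pmin(pmax(round(pts[, 2] + o * perp[, 2]), 0), ny - 1)
    (x * ny) + y + 1  # linear index into a [y, x] frame
  })
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 1)

  ky <- matrix(0, nrow = nrow(pts), ncol = nt)
  for (t in seq_len(nt)) {
    f <- stack[, , t]
    ky[, t] <- rowMeans(matrix(f[idx], nrow = nrow(idx)))
  }
  ky
}
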