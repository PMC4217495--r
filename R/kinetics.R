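#' Normalize an event trace to its peak
#'
#' Rescales the spot trace to `(F - B) / (F_peak - B)` so the fusion-pore
#' opening peak maps to 1 and the pre-onset baseline to ~0, and re-origins
#' time at the peak frame. Normalisation commutes with affine intensity
#' rescaling of the raw trace.
#'
#' @param trace an `event_trace`.
#' @return an `event_trace` with normalised `spot_intensity`,
#'   `background_B = 0` and `times_s` relative to the peak.
#' @export
normalize_trace <- function(trace) {
  v <- trace$spot_intensity
  b <- trace$background_B
  pk <- max(v)
  if (pk <= b) stop("trace peak does not exceed background")
  ip <- which.max(v)
  trace$spot_intensity <- (v - b) / (pk - b)
  if (!is.null(trace$surround_intensity))
    trace$surround_intensity <- (trace$surround_intensity - b) / (pk - b)
  trace$times_s <- trace$times_s - trace$times_s[ip]
  trace$background_B <- 0
  trace
}

#' Fit a plateau followed by a one-phase exponential decay
#'
#' Least-squares fit of the kinetic model
#' `F(t) = F0` for `t < t0` and
#' `F(t) = (F0 - B) * exp(-k * (t - t0)) + B` for `t >= t0`
#' to a post-peak trace. For each candidate plateau end `t0` on a grid
#' (0.5 s steps over the first half of the window, then refined at frame
#' resolution) the decay rate `k` is profiled by 1-D optimisation, with the
#' remaining parameters `(F0, B)` solved linearly — the model is linear in
#' them once `t0` and `k` are fixed. The half-life is `ln(2)/k`.
#'
#' @param times_s,intensity post-peak time and intensity vectors (>= 8
#'   samples); alternatively `times_s` may be an `event_trace`, in which
#'   case its spot trace from the peak onward is fitted.
#' @param t0_grid_step_s spacing of the plateau-end multi-start grid.
#' @param k_range search range for the decay rate (per second).
#' @return object of class `decay_fit`: `t0_s`, `F0`, `B_fit`, `k_per_s`,
#'   `half_life_s`, `rss`, `n`, `converged`. A fit is flagged unconverged
#'   (no half-life) when the rate sits at the search boundary or the fitted
#'   amplitude does not decay.
#' @export
fit_plateau_one_phase_decay <- function(times_s, intensity = NULL,
                                        t0_grid_step_s = 0.5,
                                        k_range = c(1e-3, 20)) {
  if (inherits(times_s, "event_trace")) {
    tr <- times_s
    ip <- which.max(tr$spot_intensity)
    intensity <- tr$spot_intensity[ip:length(tr$spot_intensity)]
    times_s <- tr$times_s[ip:length(tr$times_s)] - tr$times_s[ip]
  }
  y <- as.numeric(intensity)
  t <- as.numeric(times_s) - times_s[1]
  n <- length(y)
  if (n < 8) stop("need at least 8 post-peak samples")

  eval_t0 <- function(t0) {
    obj <- function(lk) piecewise_ls(t, y, t0, exp(lk))$rss
    op <- stats::optimize(obj, interval = log(k_range), tol = 1e-6)
    list(t0 = t0, log_k = op$minimum, rss = op$objective)
  }
  span <- max(t)
  grid <- unique(pmin(seq(0, span / 2, by = t0_grid_step_s), span / 2))
  fits <- lapply(grid, eval_t0)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
  dt <- if (n > 1) stats::median(diff(t)) else 0.1
  fine <- unique(pmax(0, best$t0 + seq(-t0_grid_step_s, t0_grid_step_s, by = dt)))
  fine <- fine[fine <= span / 2 + t0_grid_step_s]
  fits <- lapply(fine, eval_t0)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]

  k <- exp(best$log_k)
  sol <- piecewise_ls(t, y, best$t0, k)
  at_edge <- best$log_k < log(k_range[1]) + 1e-3 ||
             best$log_k > log(k_range[2]) - 1e-3
  scale <- max(abs(y)) + 1e-12
  decays <- (sol$F0 - sol$B) > 1e-3 * scale
  conv <- !at_edge && decays
  structure(list(t0_s = best$t0,
                 F0 = sol$F0, B_fit = sol$B, k_per_s = k,
                 half_life_s = if (conv) log(2) / k else NA_real_,
                 rss = sol$rss, n = n, converged = conv),
            class = "decay_fit")
}

# Linear LS for (F0, B) given t0 and k; refits with B = 0 if B comes out
# negative, keeping the asymptote physical.
piecewise_ls <- function(t, y, t0, k) {
  e <- ifelse(t >= t0, exp(-k * (t - t0)), 1)
  x2 <- ifelse(t >= t0, 1 - exp(-k * (t - t0)), 0)
  X <- cbind(e, x2)
  cf <- tryCatch(stats::lm.fit(X, y)$coefficients, error = function(e) c(NA, NA))
  if (anyNA(cf) || cf[2] < 0) {
    f0 <- sum(e * y) / sum(e * e)
    r <- y - f0 * e
    return(list(F0 = f0, B = 0, rss = sum(r^2)))
  }
  r <- y - X %*% cf
  list(F0 = unname(cf[1]), B = unname(cf[2]), rss = sum(r^2))
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("plateau + one-phase decay fit\n")
  cat(sprintf("  t0 = %.2f s, F0 = %.1f, B = %.1f, k = %.4f /s\n",
              x$t0_s, x$F0, x$B_fit, x$k_per_s))
  cat(sprintf("  half-life = %.2f s, rss = %.3g, n = %d, converged: %s\n",
              x$half_life_s, x$rss, x$n, x$converged))
  invisible(x)
}

#' Classify an event as transient, persistent or biphasic-persistent
#'
#' The dwell time is the time from the intensity peak until the (3-frame
#' median smoothed) spot trace first falls below `dwell_factor` times the
#' background level `B`. Events with dwell <= `transient_boundary_s`
#' (default 4 s) are transient; longer dwells are persistent. A persistent
#' event is biphasic (the bafilomycin phenotype: an initial plateau followed
#' by fast release) when the plateau-then-decay model beats the immediate
#' single decay by more than `delta_bic` BIC units with a plateau longer
#' than 1 s and a fast decay (half-life below the transient boundary).
#' Traces that never return below the threshold are right-censored: labelled
#' persistent if more than `transient_boundary_s` of post-peak data was
#' observed, otherwise unclassified.
#'
#' @param trace an `event_trace` (spot trace including background, with
#'   `background_B > 0`).
#' @param transient_boundary_s dwell boundary between transient and
#'   persistent (s).
#' @param dwell_factor threshold multiple of background (default 2).
#' @param delta_bic BIC margin for the biphasic call.
#' @return object of class `event_classification`: `event_id`, `label`
#'   (`transient`, `persistent`, `biphasic_persistent`, `unclassified`),
#'   `dwell_s`, `censored`, `half_life_s`, `fit` (selected model),
#'   `fit_immediate`, `fit_plateau`.
#' @export
classify_event <- function(trace, transient_boundary_s = 4, dwell_factor = 2,
                           delta_bic = 6) {
  stopifnot(trace$background_B > 0)
  v <- trace$spot_intensity
  tt <- trace$times_s
  smoothed <- stats::runmed(v, 3)
  # The dwell clock starts at the initial maximum (pore opening). The peak
  # is searched within 1 s of the event's own onset: the fusion rise is
  # effectively instantaneous, and anchoring on the global trace maximum
  # would latch onto a later co-located event (or, on a flat plateau, let
  # noise place the peak anywhere along it).
  fr <- trace$frame_rate_hz %||% (1 / stats::median(diff(tt)))
  on_idx <- if (!is.null(trace$t_on_s) && !is.na(trace$t_on_s)) {
    max(1L, which(tt >= trace$t_on_s - 1e-9)[1])
  } else which.max(smoothed)
  win <- on_idx:min(length(v), on_idx + as.integer(round(fr)))
  pk <- max(smoothed[win])
  ip <- win[which(smoothed[win] >= pk - 0.05 * (pk - trace$background_B))[1]]
  if (is.na(ip)) ip <- win[which.max(smoothed[win])]
  thr <- dwell_factor * trace$background_B
  post <- seq(ip, length(v))
  below <- post[smoothed[post] < thr]

  censored <- length(below) == 0
  window_s <- tt[length(tt)] - tt[ip]
  dwell <- if (censored) window_s else tt[below[1]] - tt[ip]

  label <- if (censored) {
    if (window_s > transient_boundary_s) "persistent" else "unclassified"
  } else if (dwell <= transient_boundary_s) "transient" else "persistent"

  fit_imm <- fit_plateau <- NULL
  half_life <- NA_real_
  y <- v[post]; ty <- tt[post] - tt[ip]
  if (length(y) >= 8 && label != "unclassified") {
    fit_plateau <- fit_plateau_one_phase_decay(ty, y)
    imm <- with_fixed_t0(ty, y)
    fit_imm <- imm
    fit <- fit_plateau
    if (label == "persistent") {
      n <- length(y)
      bic_imm <- n * log(imm$rss / n) + 3 * log(n)
      bic_pl <- n * log(fit_plateau$rss / n) + 4 * log(n)
      fast <- fit_plateau$converged &&
        !is.na(fit_plateau$half_life_s) &&
        fit_plateau$half_life_s < transient_boundary_s
      if (bic_imm - bic_pl > delta_bic && fit_plateau$t0_s > 1 && fast) {
        label <- "biphasic_persistent"
      } else {
        fit <- imm
      }
    } else {
      fit <- imm
    }
    half_life <- fit$half_life_s
  } else fit <- NULL

  structure(list(event_id = trace$event_id, label = label, dwell_s = dwell,
                 censored = censored, half_life_s = half_life, fit = fit,
                 fit_immediate = fit_imm, fit_plateau = fit_plateau),
            class = "event_classification")
}

# Immediate single decay: the plateau model with t0 pinned at 0.
with_fixed_t0 <- function(t, y, k_range = c(1e-3, 20)) {
  obj <- function(lk) piecewise_ls(t, y, 0, exp(lk))$rss
  op <- stats::optimize(obj, interval = log(k_range), tol = 1e-6)
  k <- exp(op$minimum)
  sol <- piecewise_ls(t, y, 0, k)
  at_edge <- op$minimum < log(k_range[1]) + 1e-3 ||
             op$minimum > log(k_range[2]) - 1e-3
  conv <- !at_edge && (sol$F0 - sol$B) > 1e-3 * (max(abs(y)) + 1e-12)
  structure(list(t0_s = 0, F0 = sol$F0, B_fit = sol$B, k_per_s = k,
                 half_life_s = if (conv) log(2) / k else NA_real_,
                 rss = sol$rss, n = length(y), converged = conv),
            class = "decay_fit")
}

#' Tabulate event classifications
#'
#' @param classifications list of `event_classification` objects.
#' @return data.frame with one row per event: `event_id`, `label`,
#'   `dwell_s`, `censored`, `half_life_s`, `k_per_s`, `t0_s`, `converged`.
#' @export
classification_table <- function(classifications) {
  do.call(rbind, lapply(classifications, function(cl) {
    f <- cl$fit
    data.frame(event_id = cl$event_id %||% NA_integer_, label = cl$label,
               dwell_s = cl$dwell_s, censored = cl$censored,
               half_life_s = cl$half_life_s %||% NA_real_,
               k_per_s = if (is.null(f)) NA_real_ else f$k_per_s,
               t0_s = if (is.null(f)) NA_real_ else f$t0_s,
               converged = if (is.null(f)) FALSE else f$converged,
               stringsAsFactors = FALSE)
  }))
}

#' Summarise half-lives per event class
#'
#' Per-class mean and SD of fitted half-lives (converged fits only), the
#' numeric backing of a half-life dot plot.
#'
#' @param classified a data.frame from [classification_table()], or a list
#'   of `event_classification` objects.
#' @param file optional CSV output path.
#' @return data.frame with columns `label`, `n`, `mean_half_life_s`,
#'   `sd_half_life_s`, `median_half_life_s`; empty classes are omitted.
#' @export
summarize_halflives <- function(classified, file = NULL) {
  tab <- if (is.data.frame(classified)) classified
         else classification_table(classified)
  ok <- tab[!is.na(tab$half_life_s) & tab$converged, , drop = FALSE]
  out <- do.call(rbind, lapply(split(ok, ok$label), function(g) {
    data.frame(label = g$label[1], n = nrow(g),
               mean_half_life_s = mean(g$half_life_s),
               sd_half_life_s = if (nrow(g) > 1) stats::sd(g$half_life_s) else NA_real_,
               median_half_life_s = stats::median(g$half_life_s),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
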