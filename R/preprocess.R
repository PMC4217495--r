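#' Subtract camera / cellular background from a movie
#'
#' With a blank field (a frame, or stack, acquired without the sample) the
#' time-averaged blank is subtracted per pixel. Without one, a per-frame
#' scalar background is estimated as the mode of the off-mask pixel
#' intensities (all pixels when no mask is available) — exocytic spots are
#' sparse, so the intensity mode tracks the background level. Negative
#' values are clipped at 0.
#'
#' @param movie a `tirf_movie`.
#' @param blank_field matrix (one frame) or `height x width x k` array
#'   averaged over time; `NULL` selects the mode estimator.
#' @param channels channels to correct (default: all).
#' @param clip clip negative residuals at 0 (default). [detect_events()] is
#'   calibrated on Gaussian-like noise, so the detection stage of the
#'   pipeline works on an unclipped residual; clipping rectifies the noise
#'   floor and slightly heavies the tail of the detection statistic.
#' @return the corrected `tirf_movie`, with attribute
#'   `background_estimate` (per-channel scalar or matrix used).
#' @export
subtract_background <- function(movie, blank_field = NULL,
                                channels = movie$channels, clip = TRUE) {
  est <- list()
  for (ch in channels) {
    stack <- movie$pixels[[ch]]
    if (!is.null(blank_field)) {
      bf <- if (length(dim(blank_field)) == 3) {
        apply(blank_field, c(1, 2), mean)
      } else blank_field
      if (!all(dim(bf) == dim(stack)[1:2])) stop("blank field shape mismatch")
      stack <- sweep(stack, c(1, 2), bf, `-`)
      est[[ch]] <- bf
    } else {
      off <- if (!is.null(movie$mask)) movie$mask == 0L else TRUE
      nt <- dim(stack)[3]
      b <- vapply(seq_len(nt), function(t) {
        v <- stack[, , t][off]
        if (length(v) < 10) v <- as.vector(stack[, , t])
        intensity_mode(v)
      }, numeric(1))
      # the background level drifts smoothly (bleaching); smoothing the
      # per-frame mode estimates removes their sampling jitter, which would
      # otherwise imprint coherent frame-wide offsets on the residual
      if (nt >= 10) b <- stats::lowess(seq_len(nt), b, f = 1 / 3)$y
      stack <- sweep(stack, 3, b, `-`)
      est[[ch]] <- b
    }
    movie$pixels[[ch]] <- if (clip) pmax(stack, 0) else stack
  }
  attr(movie, "background_estimate") <- est
  movie
}

# Mode of a continuous sample via a kernel density estimate.
intensity_mode <- function(v) {
  if (length(unique(v)) == 1) return(v[1])
  d <- stats::density(v, n = 512)
  d$x[which.max(d$y)]
}

#' Estimate and correct photobleaching
#'
#' Fits a monoexponential (or straight line) to the whole-field mean
#' intensity over time, excluding pixels in `exclude_mask` (detected-event
#' ROIs), then divides each frame by the fitted trend normalised to its
#' first-frame value. Acquisitions in this regime typically lose 2-10% of
#' their intensity over a movie; an estimated loss above 50% triggers a
#' warning as it more likely reflects focus drift than bleaching.
#'
#' @param movie a `tirf_movie` (at least 10 frames).
#' @param exclude_mask logical/0-1 matrix of pixels to exclude from the
#'   trend estimate (e.g. event ROIs or the whole cell footprint). Defaults
#'   to the movie's own mask when available, so the trend is estimated on
#'   event-free off-cell pixels whose background bleaches like the rest of
#'   the field; pass `FALSE` to use every pixel.
#' @param method `"exp"` (default) or `"linear"`.
#' @param channels channels to correct.
#' @return list with `movie` (corrected), `bleach_fraction_est` (per-channel
#'   fractional loss over the movie), `trend` (per-channel fitted trend).
#' @export
correct_bleaching <- function(movie, exclude_mask = NULL,
                              method = c("exp", "linear"),
                              channels = movie$channels) {
  method <- match.arg(method)
  nt <- dim(movie$pixels[[1]])[3]
  if (nt < 10) stop("need at least 10 frames to estimate bleaching")
  if (is.null(exclude_mask) && !is.null(movie$mask) &&
      sum(movie$mask == 0L) >= 100)
    exclude_mask <- movie$mask
  keep <- if (is.null(exclude_mask) || isFALSE(exclude_mask)) TRUE
          else !(exclude_mask == 1)
  loss <- numeric(0); trends <- list()
  for (ch in channels) {
    stack <- movie$pixels[[ch]]
    m <- vapply(seq_len(nt), function(t) mean(stack[, , t][keep]), numeric(1))
    tt <- seq_len(nt) - 1
    if (method == "exp") {
      # log-linear fit; the mean is strictly positive in fluorescence data
      fit <- stats::lm(log(pmax(m, 1e-9)) ~ tt)
      trend <- exp(stats::fitted(fit))
    } else {
      fit <- stats::lm(m ~ tt)
      trend <- stats::fitted(fit)
    }
    rel <- trend / trend[1]
    fr_loss <- 1 - rel[nt]
    if (fr_loss > 0.5)
      warning("estimated intensity loss > 50%; likely focus drift, not bleaching")
    movie$pixels[[ch]] <- sweep(stack, 3, rel, `/`)
    loss[ch] <- fr_loss
    trends[[ch]] <- trend
  }
  list(movie = movie, bleach_fraction_est = loss, trend = trends)
}
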