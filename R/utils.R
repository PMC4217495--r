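#' @keywords internal
"_PACKAGE"

# Run code under a given seed, restoring the caller's RNG state afterwards,
# so package functions are reproducible without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stream-specific child seed from a master seed, kept < 2^31.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483647
}

#' Convert a physical ROI area to an odd box side in pixels
#'
#' ROIs are squares; the side is the odd pixel count closest to
#' `sqrt(area_um2) / pixel_pitch_um`, and at least 1. At the default pitch of
#' 0.16 um/px a 4 um^2 box is 13x13 px and a 16 um^2 box is 25x25 px.
#'
#' @param area_um2 physical area in square micrometres.
#' @param pixel_pitch_um pixel size in micrometres.
#' @return odd integer box side in pixels.
#' @export
roi_side_px <- function(area_um2, pixel_pitch_um) {
  stopifnot(area_um2 > 0, pixel_pitch_um > 0)
  side <- sqrt(area_um2) / pixel_pitch_um
  odd <- 2L * as.integer(round((side - 1) / 2)) + 1L
  max(odd, 1L)
}

# Peak-normalised 2-D Gaussian kernel (matrix), truncated at +-radius px.
gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  d <- seq(-radius, radius)
  g <- exp(-d^2 / (2 * sigma^2))
  k <- outer(g, g)
  k
}

# Robust noise SD via the median absolute deviation.
mad_sd <- function(x) stats::mad(x, constant = 1.4826)

# pH -> relative pHluorin brightness (Hill sigmoid, slope 1).
sep_brightness <- function(ph, pka) 1 / (1 + 10^(pka - ph))

`%||%` <- function(a, b) if (is.null(a)) b else a
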