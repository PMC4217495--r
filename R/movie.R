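#' Render a synthetic TIRF movie from a ground-truth event table
#'
#' Composes the ideal event traces into image frames: each event becomes a
#' Gaussian spot (`psf_sigma_px`) at its insertion site whose amplitude
#' follows [render_event_traces()]; the sustained released-pool offset is
#' rendered with a wider Gaussian into the surrounding membrane; a uniform
#' background `B` is added; a global multiplicative bleaching ramp removes
#' `bleach_fraction` of all intensity by the last frame; and Poisson shot
#' noise (gain `gain`) plus Gaussian read noise are applied. The optional
#' clathrin channel contains transient 2x2-pixel endocytic puncta placed
#' independently of the exocytic sites.
#'
#' @param config a [sim_config()].
#' @param kinetics a [vesicle_kinetics()]; if `config$condition` is
#'   `"bafilomycin"`, reacidification is switched off automatically.
#' @param events ground-truth table from [sample_events()].
#' @param mask binary mask the events live on; regenerated from `config` when
#'   omitted. Events off the mask foreground are an error.
#' @param seed noise seed (defaults to `config$seed`).
#' @return object of class `tirf_movie`: list with `pixels` (named list of
#'   `height x width x frames` arrays, one per channel), `frame_rate_hz`,
#'   `pixel_pitch_um`, `channels`, `mask`.
#' @export
render_movie <- function(config, kinetics = vesicle_kinetics(), events,
                         mask = NULL, seed = config$seed) {
  if (config$condition == "bafilomycin") kinetics$reacidification <- FALSE
  if (is.null(mask))
    mask <- generate_mask(config$mask_spec, config$width_px, config$height_px,
                          seed = child_seed(config$seed, 1))
  ny <- config$height_px; nx <- config$width_px
  nt <- as.integer(round(config$duration_s * config$frame_rate_hz))
  if (nrow(events) > 0) {
    on_mask <- mask[cbind(events$y_px + 1L, events$x_px + 1L)] == 1L
    if (!all(on_mask)) stop("events outside mask foreground")
  }

  spot_k <- gaussian_kernel(config$psf_sigma_px)
  wide_k <- gaussian_kernel(4 * config$psf_sigma_px,
                            radius = ceiling(9 * config$psf_sigma_px))
  chans <- config$channels
  pix <- lapply(chans, function(ch) array(0, dim = c(ny, nx, nt)))
  names(pix) <- chans

  surround <- array(0, dim = c(ny, nx, nt))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (ev$mech_class == "kiss_and_run_pair_second") next
    tr <- render_event_traces(ev, kinetics, config$frame_rate_hz,
                              config$duration_s)
    pix$SEP <- add_spot(pix$SEP, spot_k, ev$x_px, ev$y_px, tr$sep_spot)
    surround <- add_spot(surround, wide_k, ev$x_px, ev$y_px, tr$sep_surround)
    if ("mCherry" %in% chans)
      pix$mCherry <- add_spot(pix$mCherry, spot_k, ev$x_px, ev$y_px,
                              tr$mch_spot)
  }
  # released receptors diffuse within the plasma membrane: the sustained
  # surround signal exists only on the cell footprint
  pix$SEP <- pix$SEP + sweep(surround, c(1, 2), mask, `*`)

  with_seed(seed, {
    if ("clathrin" %in% chans)
      pix$clathrin <- add_clathrin_puncta(pix$clathrin, mask, config)
    bleach <- (1 - config$bleach_fraction)^(if (nt > 1) (seq_len(nt) - 1) / (nt - 1) else 0)
    for (ch in chans) {
      p <- sweep(pix[[ch]] + config$background, 3, bleach, `*`)
      n <- length(p)
      p <- stats::rpois(n, lambda = pmax(p, 0) * config$gain) / config$gain +
        stats::rnorm(n, 0, config$read_noise_sd)
      pix[[ch]] <- array(pmax(p, 0), dim = c(ny, nx, nt))
    }
    structure(list(pixels = pix, frame_rate_hz = config$frame_rate_hz,
                   pixel_pitch_um = config$pixel_pitch_um,
                   channels = chans, mask = mask),
              class = "tirf_movie")
  })
}

# Add a time-modulated kernel into a [y, x, t] stack, clipping at borders.
add_spot <- function(stack, kernel, x0, y0, amp) {
  nz <- which(amp > 1e-9)
  if (length(nz) == 0) return(stack)
  r <- (nrow(kernel) - 1L) %/% 2L
  ny <- dim(stack)[1]; nx <- dim(stack)[2]
  row0 <- y0 + 1L; col0 <- x0 + 1L
  rows <- max(1L, row0 - r):min(ny, row0 + r)
  cols <- max(1L, col0 - r):min(nx, col0 + r)
  ks <- kernel[rows - row0 + r + 1L, cols - col0 + r + 1L, drop = FALSE]
  stack[rows, cols, nz] <- stack[rows, cols, nz, drop = FALSE] +
    outer(ks, amp[nz])
  stack
}

add_clathrin_puncta <- function(stack, mask, config) {
  fg <- which(mask == 1L)
  nt <- dim(stack)[3]; ny <- dim(stack)[1]; nx <- dim(stack)[2]
  n <- stats::rpois(1, config$n_clathrin_puncta)
  if (n == 0) return(stack)
  idx <- sample(fg, n, replace = TRUE)
  x <- (idx - 1L) %/% ny; y <- (idx - 1L) %% ny
  t_on <- stats::runif(n, 0, config$duration_s)
  life <- stats::runif(n, 2, 10)
  amp <- rlnorm_meancv(n, 150, 0.3)
  times <- (seq_len(nt) - 1) / config$frame_rate_hz
  for (i in seq_len(n)) {
    rows <- (y[i] + 1L):min(ny, y[i] + 2L)
    cols <- (x[i] + 1L):min(nx, x[i] + 2L)
    frames <- which(times >= t_on[i] & times < t_on[i] + life[i])
    if (length(frames))
      stack[rows, cols, frames] <- stack[rows, cols, frames] + amp[i]
  }
  stack
}

#' Simulate a complete movie with its ground truth
#'
#' Convenience wrapper chaining [generate_mask()], [sample_events()] and
#' [render_movie()] under seeds derived from `config$seed`.
#'
#' @inheritParams render_movie
#' @return list with `movie` (a `tirf_movie`), `events` (ground truth),
#'   `mask`, `config`, `kinetics`.
#' @export
simulate_movie <- function(config, kinetics = vesicle_kinetics()) {
  if (config$condition == "bafilomycin") kinetics$reacidification <- FALSE
  mask <- generate_mask(config$mask_spec, config$width_px, config$height_px,
                        seed = child_seed(config$seed, 1))
  events <- sample_events(config, mask, kinetics,
                          seed = child_seed(config$seed, 2))
  movie <- render_movie(config, kinetics, events, mask,
                        seed = child_seed(config$seed, 3))
  list(movie = movie, events = events, mask = mask, config = config,
       kinetics = kinetics)
}

#' Write / read a movie as a multi-page TIFF with a JSON sidecar
#'
#' Pages are frame-major and channel-interleaved (page = (t-1)*n_channels +
#' c), axis order Y,X within a page. Intensities are stored as 16-bit with a
#' scale factor recorded in the sidecar (`<path>.json`), which also carries
#' the frame rate, pixel pitch and channel names.
#'
#' @param movie a `tirf_movie`.
#' @param path output TIFF path.
#' @return `write_movie` returns `path` invisibly; `read_movie` returns a
#'   `tirf_movie`.
#' @export
write_movie <- function(movie, path) {
  scale <- 65535
  pages <- list()
  nt <- dim(movie$pixels[[1]])[3]
  for (t in seq_len(nt))
    for (ch in movie$channels)
      pages[[length(pages) + 1L]] <- pmin(movie$pixels[[ch]][, , t] / scale, 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  meta <- list(frame_rate_hz = movie$frame_rate_hz,
               pixel_pitch_um = movie$pixel_pitch_um,
               channels = as.list(movie$channels), scale = scale,
               n_frames = nt, page_order = "frame_major_channel_interleaved",
               axis_order = "T,C,Y,X")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nc <- length(meta$channels); nt <- meta$n_frames
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  pix <- lapply(seq_len(nc), function(c) {
    arr <- array(0, dim = c(ny, nx, nt))
    for (t in seq_len(nt)) arr[, , t] <- pages[[(t - 1) * nc + c]] * meta$scale
    arr
  })
  names(pix) <- meta$channels
  structure(list(pixels = pix, frame_rate_hz = meta$frame_rate_hz,
                 pixel_pitch_um = meta$pixel_pitch_um,
                 channels = meta$channels, mask = NULL),
            class = "tirf_movie")
}

#' Write / read a ground-truth event table as CSV
#' @param events ground-truth table.
#' @param path CSV path.
#' @export
write_ground_truth <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(ev) <- c("ground_truth_events", "data.frame")
  ev
}
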