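#' Generate a binary neuron-footprint mask
#'
#' Builds the binary support on which simulated exocytic events are placed:
#' either the whole frame (`"full"`) or a synthetic neuron-like footprint — a
#' soma blob with 2-4 tapering processes radiating from it. The footprint is
#' the superlevel set of a continuous "thickness" field (soma disk plus
#' tapered tubes along smooth random-walk paths), which keeps it connected;
#' when an exact foreground pixel count is requested the threshold is placed
#' at the count-th largest field value so the popcount matches exactly.
#'
#' @param mask_spec `"full"`, `"neuron"`, or a list with `type`
#'   (`"full"`/`"neuron"`), optional `target_foreground` (exact foreground
#'   pixel count) and optional `n_processes` (2-4).
#' @param width_px,height_px frame size in pixels (positive).
#' @param seed random seed; identical seeds give identical masks.
#' @return integer matrix (`height_px` rows = y, `width_px` cols = x) of 0/1,
#'   with attribute `foreground_count`.
#' @export
generate_mask <- function(mask_spec = "neuron", width_px, height_px, seed = 1) {
  stopifnot(width_px >= 1, height_px >= 1)
  spec <- if (is.character(mask_spec)) list(type = mask_spec) else mask_spec
  stopifnot(is.list(spec), spec$type %in% c("full", "neuron"))
  target <- spec$target_foreground
  npix <- as.integer(width_px) * as.integer(height_px)
  if (!is.null(target)) {
    if (target <= 0) stop("zero-area mask requested")
    if (target > npix) stop("target_foreground exceeds frame size")
  }

  if (spec$type == "full") {
    m <- matrix(1L, nrow = height_px, ncol = width_px)
    if (!is.null(target) && target < npix) {
      # keep the first `target` pixels in column-major order
      m[seq_len(npix) > target] <- 0L
    }
    attr(m, "foreground_count") <- sum(m)
    return(m)
  }

  field <- with_seed(seed, neuron_field(width_px, height_px,
                                        spec$n_processes %||% NULL))
  # a soma with dendrites typically fills a large part of a TIRF field of
  # view; default footprint is 45% of the frame so that ~40 events per
  # movie land at a realistic surface density
  if (is.null(target)) target <- round(0.45 * npix)
  ord <- order(field, decreasing = TRUE)
  m <- matrix(0L, nrow = height_px, ncol = width_px)
  m[ord[seq_len(target)]] <- 1L
  fg <- sum(m)
  if (fg == 0) stop("zero-area mask produced")
  attr(m, "foreground_count") <- fg
  m
}

# Continuous thickness field: max over soma disk and tapered process tubes.
neuron_field <- function(width_px, height_px, n_processes = NULL) {
  nx <- as.integer(width_px); ny <- as.integer(height_px)
  cx <- nx / 2 + stats::runif(1, -nx / 10, nx / 10)
  cy <- ny / 2 + stats::runif(1, -ny / 10, ny / 10)
  r_soma <- max(2, min(nx, ny) / 7)

  px <- matrix(rep(seq_len(nx), each = ny), nrow = ny)   # x per pixel
  py <- matrix(rep(seq_len(ny), times = nx), nrow = ny)  # y per pixel
  field <- r_soma - sqrt((px - cx)^2 + (py - cy)^2)

  k <- n_processes %||% sample(2:4, 1)
  len <- 0.55 * max(nx, ny)
  for (p in seq_len(k)) {
    theta <- stats::runif(1, 0, 2 * pi)
    x <- cx + (r_soma - 1) * cos(theta)
    y <- cy + (r_soma - 1) * sin(theta)
    n_steps <- ceiling(len)
    r0 <- r_soma / 2.2
    for (s in seq_len(n_steps)) {
      theta <- theta + stats::rnorm(1, 0, 0.08)  # smooth wandering heading
      x <- x + cos(theta); y <- y + sin(theta)
      if (x < 1 || x > nx || y < 1 || y > ny) break
      r <- max(0.8, r0 * (1 - 0.8 * s / n_steps))  # taper towards the tip
      d <- r - sqrt((px - x)^2 + (py - y)^2)
      field <- pmax(field, d)
    }
  }
  field
}
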