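#' Threshold an image into a binary mask
#'
#' `It(i,j) = 1` exactly when `I(i,j) >= T`, the footprint used as the
#' support of the random-placement null model.
#'
#' @param image numeric matrix.
#' @param T intensity threshold.
#' @param provenance free-text source tag.
#' @return object of class `threshold_mask`: `It` (0/1 integer matrix), `T`,
#'   `foreground_count`, `provenance`.
#' @export
threshold_image <- function(image, T, provenance = "unspecified") {
  stopifnot(is.numeric(image), is.matrix(image))
  It <- matrix(as.integer(image >= T), nrow = nrow(image))
  structure(list(It = It, T = T, foreground_count = sum(It),
                 provenance = provenance),
            class = "threshold_mask")
}

as_mask_matrix <- function(mask) {
  if (inherits(mask, "threshold_mask")) mask$It else mask
}

#' Configuration of the random-placement null model
#'
#' The null model asks how often, by chance alone, a persistent exocytic
#' event would be followed by a later event within 1 um^2 of it, when `N`
#' events are dropped uniformly at random on the cell footprint. "Within
#' 1 um^2" is realised as sharing a `window_side_px x window_side_px` grid
#' cell of the mask (default 2x2 pixels, i.e. an effective null-grid pitch
#' of ~0.5 um/px); `window_side_px = 1` means the same pixel.
#'
#' @param N total events per replicate.
#' @param persistent_fraction fraction of events marked persistent
#'   (default 0.10).
#' @param window_side_px side of the colocalization grid cell in mask
#'   pixels (>= 1).
#' @param replicates Monte Carlo replicates.
#' @param exact_persistent_count if `TRUE` exactly
#'   `round(persistent_fraction * N)` events are persistent per replicate;
#'   otherwise independent Bernoulli draws.
#' @param seed random seed.
#' @return object of class `null_model_config`.
#' @export
null_model_config <- function(N, persistent_fraction = 0.10,
                              window_side_px = 2, replicates = 1000,
                              exact_persistent_count = TRUE, seed = 1) {
  stopifnot(N >= 0, persistent_fraction >= 0, persistent_fraction <= 1,
            window_side_px >= 1, replicates >= 1)
  structure(list(N = as.integer(N),
                 persistent_fraction = persistent_fraction,
                 window_side_px = as.integer(window_side_px),
                 replicates = as.integer(replicates),
                 exact_persistent_count = exact_persistent_count,
                 seed = seed),
            class = "null_model_config")
}

# Grid-cell id of each foreground pixel for the colocalization window.
mask_cell_ids <- function(mask, window_side_px) {
  m <- as_mask_matrix(mask)
  fg <- which(m == 1L)
  if (length(fg) == 0) stop("mask has no foreground pixels")
  ny <- nrow(m)
  row <- (fg - 1L) %% ny
  col <- (fg - 1L) %/% ny
  cr <- row %/% window_side_px
  cc <- col %/% window_side_px
  cr * (ncol(m) %/% window_side_px + 1L) + cc + 1L
}

#' Run one replicate of the random-placement null model
#'
#' Places `N` events i.i.d. uniform on the mask foreground, assigns a
#' uniformly random time order, marks persistent events, and reports whether
#' any persistent event has a strictly later event in the same
#' colocalization grid cell.
#'
#' @param mask `threshold_mask` or binary matrix with >= 1 foreground pixel.
#' @param config a [null_model_config()].
#' @return logical: was a colocalized consecutive pair produced?
#' @export
run_null_replicate <- function(mask, config) {
  cells <- mask_cell_ids(mask, config$window_side_px)
  null_replicate_cells(cells, config)
}

null_replicate_cells <- function(cells, config) {
  N <- config$N
  if (N < 2) return(FALSE)
  # positions are i.i.d., so the placement index doubles as the time order
  ev_cells <- cells[sample.int(length(cells), N, replace = TRUE)]
  k <- if (config$exact_persistent_count)
    as.integer(round(config$persistent_fraction * N))
  else sum(stats::runif(N) < config$persistent_fraction)
  if (k < 1) return(FALSE)
  persist <- sample.int(N, k)
  for (p in persist) {
    if (p < N && any(ev_cells[(p + 1L):N] == ev_cells[p])) return(TRUE)
  }
  FALSE
}

#' Monte Carlo estimate of the consecutive-event null probability
#'
#' Repeats [run_null_replicate()] and reports the fraction of replicates in
#' which at least one persistent event was followed by a later, colocalized
#' event, with its Monte Carlo standard error
#' `sqrt(p_hat * (1 - p_hat) / replicates)`. Optionally traces the
#' probability as a function of the total event count `N`.
#'
#' @param mask `threshold_mask` or binary matrix.
#' @param config a [null_model_config()].
#' @param n_values optional vector of event counts at which to evaluate the
#'   probability curve.
#' @return object of class `null_model_result`: `p_hat`, `mc_se`,
#'   `replicates`, `config`, and `curve` (data.frame `N`, `p_hat`, `mc_se`,
#'   or `NULL`).
#' @export
estimate_probability <- function(mask, config, n_values = NULL) {
  cells <- mask_cell_ids(mask, config$window_side_px)
  run_at <- function(cfg) {
    hits <- with_seed(cfg$seed, {
      s <- 0L
      for (r in seq_len(cfg$replicates))
        s <- s + null_replicate_cells(cells, cfg)
      s
    })
    p <- hits / cfg$replicates
    c(p_hat = p, mc_se = sqrt(p * (1 - p) / cfg$replicates))
  }
  main <- run_at(config)
  curve <- NULL
  if (!is.null(n_values)) {
    curve <- do.call(rbind, lapply(seq_along(n_values), function(i) {
      cfg <- config
      cfg$N <- as.integer(n_values[i])
      cfg$seed <- child_seed(config$seed, i)
      data.frame(N = cfg$N, t(run_at(cfg)))
    }))
  }
  structure(list(p_hat = unname(main["p_hat"]), mc_se = unname(main["mc_se"]),
                 replicates = config$replicates, config = config,
                 curve = curve),
            class = "null_model_result")
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf("null-model consecutive-event probability: %.4f (MC SE %.4f, %d replicates, N = %d)\n",
              x$p_hat, x$mc_se, x$replicates, x$config$N))
  invisible(x)
}

#' Observed fraction of persistent events followed by a consecutive event
#'
#' For each persistent event, searches for any later event within a square
#' window of area `window_um2` centred on it and within `max_gap_s`
#' (default: the rest of the movie). Event tables may be ground truth
#' (`mech_class` column; persistent classes are `persistent` and
#' `kiss_and_run_pair_first`) or classified detections (`label` column;
#' persistent classes are `persistent` and `biphasic_persistent`).
#'
#' @param events data.frame with `x_px`, `y_px`, `t_on_s` and either
#'   `mech_class` or `label`; `persistent` may be supplied directly as a
#'   logical vector.
#' @param pixel_pitch_um pixel size of the coordinates.
#' @param window_um2 colocalization window area (default 1 um^2).
#' @param max_gap_s maximum time gap (default `Inf`).
#' @param persistent optional logical vector overriding the class columns.
#' @return list: `fraction` (NA with a warning when there are no persistent
#'   events), `n_persistent`, `n_paired`, `pairs` (data.frame `first_id`,
#'   `second_id`, `gap_s`).
#' @export
observed_consecutive_fraction <- function(events, pixel_pitch_um,
                                          window_um2 = 1, max_gap_s = Inf,
                                          persistent = NULL) {
  if (is.null(persistent)) {
    persistent <- if ("mech_class" %in% names(events)) {
      events$mech_class %in% c("persistent", "kiss_and_run_pair_first")
    } else if ("label" %in% names(events)) {
      events$label %in% c("persistent", "biphasic_persistent")
    } else stop("events need a mech_class or label column, or `persistent`")
  }
  half <- 0.5 * sqrt(window_um2) / pixel_pitch_um
  ids <- events$event_id %||% seq_len(nrow(events))
  pers_idx <- which(persistent)
  if (length(pers_idx) == 0) {
    warning("no persistent events; consecutive fraction undefined")
    return(list(fraction = NA_real_, n_persistent = 0L, n_paired = 0L,
                pairs = data.frame(first_id = integer(), second_id = integer(),
                                   gap_s = numeric())))
  }
  pairs <- list()
  for (i in pers_idx) {
    gap <- events$t_on_s - events$t_on_s[i]
    hit <- which(gap > 0 & gap <= max_gap_s &
                 abs(events$x_px - events$x_px[i]) <= half &
                 abs(events$y_px - events$y_px[i]) <= half)
    if (length(hit)) {
      j <- hit[which.min(gap[hit])]
      pairs[[length(pairs) + 1L]] <- data.frame(first_id = ids[i],
                                                second_id = ids[j],
                                                gap_s = gap[j])
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
           else data.frame(first_id = integer(), second_id = integer(),
                           gap_s = numeric())
  list(fraction = nrow(pairs) / length(pers_idx),
       n_persistent = length(pers_idx), n_paired = nrow(pairs),
       pairs = pairs)
}

#' Pearson colocalization of two channels
#'
#' Correlates the maximum-intensity time projections of two channels over
#' the mask foreground — the per-cell colocalization statistic for, e.g.,
#' exocytic events versus clathrin puncta.
#'
#' @param channel_a,channel_b same-shape stacks (`y x x x t`) or already
#'   projected matrices.
#' @param mask binary matrix restricting the correlated pixels; `NULL` uses
#'   all pixels.
#' @return Pearson r; `NA` with a warning if either channel has zero
#'   variance over the evaluated pixels.
#' @export
pearson_colocalization <- function(channel_a, channel_b, mask = NULL) {
  proj <- function(x) if (length(dim(x)) == 3) apply(x, c(1, 2), max) else x
  pa <- proj(channel_a); pb <- proj(channel_b)
  stopifnot(all(dim(pa) == dim(pb)))
  keep <- if (is.null(mask)) rep(TRUE, length(pa)) else as_mask_matrix(mask) == 1L
  if (sum(keep) < 2) stop("need at least 2 foreground pixels")
  a <- pa[keep]; b <- pb[keep]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance channel; correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}
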