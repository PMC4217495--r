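#' Sample ground-truth exocytic events on a mask
#'
#' Draws the per-movie event table from the generative model: the event count
#' is Poisson with mean `n_events` (scaled by the condition multiplier), or
#' exact when `exact_n_events` is set; each event is persistent with
#' probability `persistent_fraction` (condition-scaled, capped at 1);
#' insertion sites are uniform on the mask foreground; fusion times are
#' uniform over the movie. Each persistent event is, with probability
#' `consecutive_fraction`, the first opening of a kiss-and-run pair: a second
#' event is created at the same site after a pore-reopen delay drawn from
#' `kinetics$pore_reopen_delay_range_s`, carrying the cargo retained after
#' the partial first release.
#'
#' @param config a [sim_config()].
#' @param mask binary mask matrix from [generate_mask()].
#' @param kinetics a [vesicle_kinetics()]; supplies dwell and reopen-delay
#'   distributions and the partial-release fraction.
#' @param seed random seed (defaults to `config$seed`).
#' @return data.frame of class `ground_truth_events` with columns `event_id`,
#'   `pair_id` (NA unless in a pair), `x_px`, `y_px` (0-based), `t_on_s`,
#'   `mech_class` (`transient`, `persistent`, `kiss_and_run_pair_first`,
#'   `kiss_and_run_pair_second`), `cargo_units`, `dwell_s` (persistent
#'   classes), `t_reopen_s` (pair firsts).
#' @export
sample_events <- function(config, mask, kinetics = vesicle_kinetics(),
                          seed = config$seed) {
  fg <- which(mask == 1L)
  if (length(fg) == 0) stop("mask has no foreground pixels")
  mult <- condition_multipliers(config$condition)
  lambda <- config$n_events * mult$n_events_mult
  p_persist <- min(1, config$persistent_fraction * mult$persistent_mult)

  with_seed(seed, {
    n <- if (config$exact_n_events) as.integer(round(lambda))
         else stats::rpois(1, lambda)
    if (n == 0) return(empty_events())
    if (p_persist * lambda < 1 && config$consecutive_fraction > 0)
      warning("expected persistent count < 1; consecutive pairs unlikely")

    ny <- nrow(mask)
    idx <- sample(fg, n, replace = TRUE)
    x <- (idx - 1L) %/% ny          # 0-based column
    y <- (idx - 1L) %% ny           # 0-based row
    persistent <- stats::runif(n) < p_persist
    cargo <- rlnorm_meancv(n, config$cargo_mean, config$cargo_cv)
    dwell <- stats::runif(n, kinetics$persistence_dwell_range_s[1],
                          kinetics$persistence_dwell_range_s[2])
    dwell[!persistent] <- NA_real_

    paired <- persistent & stats::runif(n) < config$consecutive_fraction
    delay <- stats::runif(n, kinetics$pore_reopen_delay_range_s[1],
                          kinetics$pore_reopen_delay_range_s[2])
    # pair firsts start early enough that the reopening fits in the movie
    t_max1 <- pmax(0.1, config$duration_s - delay - 2)
    t_on <- stats::runif(n, 0, config$duration_s)
    t_on[paired] <- stats::runif(sum(paired)) * t_max1[paired]
    t_reopen <- ifelse(paired, t_on + delay, NA_real_)

    mech <- ifelse(persistent,
                   ifelse(paired, "kiss_and_run_pair_first", "persistent"),
                   "transient")
    ev <- data.frame(event_id = seq_len(n),
                     pair_id = ifelse(paired, seq_len(n), NA_integer_),
                     x_px = x, y_px = y, t_on_s = t_on, mech_class = mech,
                     cargo_units = cargo, dwell_s = dwell,
                     t_reopen_s = t_reopen,
                     stringsAsFactors = FALSE)
    if (any(paired)) {
      first <- ev[paired, , drop = FALSE]
      second <- data.frame(event_id = n + seq_len(nrow(first)),
                           pair_id = first$pair_id,
                           x_px = first$x_px, y_px = first$y_px,
                           t_on_s = first$t_reopen_s,
                           mech_class = "kiss_and_run_pair_second",
                           cargo_units = (1 - kinetics$partial_release_fraction) *
                             first$cargo_units,
                           dwell_s = NA_real_, t_reopen_s = NA_real_,
                           stringsAsFactors = FALSE)
      ev <- rbind(ev, second)
    }
    ev <- ev[order(ev$t_on_s), ]
    rownames(ev) <- NULL
    class(ev) <- c("ground_truth_events", "data.frame")
    ev
  })
}

empty_events <- function() {
  ev <- data.frame(event_id = integer(), pair_id = integer(),
                   x_px = integer(), y_px = integer(), t_on_s = numeric(),
                   mech_class = character(), cargo_units = numeric(),
                   dwell_s = numeric(), t_reopen_s = numeric(),
                   stringsAsFactors = FALSE)
  class(ev) <- c("ground_truth_events", "data.frame")
  ev
}

# Log-normal draws parameterised by mean and coefficient of variation.
rlnorm_meancv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}
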