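#' Render the ideal (noise-free) fluorescence trace of one event
#'
#' Evaluates the fusion-pore state machine on the movie's time grid and
#' returns the per-channel spot amplitudes for a single event, before PSF
#' convolution, background, bleaching and noise. The lumen of a docked
#' vesicle is acidic, so pHluorin (SEP) is quenched (`sep_brightness` at
#' `ph_closed`, a few percent) while mCherry reports the full cargo. On pore
#' opening the lumen neutralises and SEP jumps to the open-pH brightness.
#' Released cargo forms a local pool that decays with
#' `transient_release_halflife_s` as receptors diffuse away, leaving a small
#' sustained offset (`surround_fraction` of the cumulative release) on the
#' surrounding membrane. Retained cargo in a re-closed pore reacidifies, so
#' its SEP signal relaxes exponentially (half-life
#' `persistent_decay_halflife_s`) towards the quenched level — unless
#' `reacidification` is off (bafilomycin), in which case it plateaus at the
#' open-pH brightness until the final full release, which then decays with
#' `bafilomycin_fast_halflife_s`. mCherry is pH-independent: the spot
#' amplitude equals the retained cargo and steps down only at release
#' instants.
#'
#' Event classes:
#' * `transient`: full release at `t_on_s`; single fast decay.
#' * `persistent`: no release; pore re-closes after `pore_open_s` and the
#'   spot decays by reacidification (control) or plateaus for `dwell_s` and
#'   is then released in full (bafilomycin).
#' * `kiss_and_run_pair_first`: partial release (fraction
#'   `partial_release_fraction`) at the first opening, reacidification (or
#'   plateau), then full release of the remainder at `t_reopen_s`.
#' * `kiss_and_run_pair_second`: contributes no additional signal — the
#'   second peak is part of the first event's trace at the shared site; it
#'   exists in the ground truth for pairing statistics.
#'
#' @param event one-row data.frame (or list) with `mech_class`, `t_on_s`,
#'   `cargo_units`, and `dwell_s` / `t_reopen_s` where applicable.
#' @param kinetics a [vesicle_kinetics()].
#' @param frame_rate_hz sampling rate.
#' @param duration_s trace length in seconds.
#' @return data.frame with columns `time_s`, `sep_spot`, `mch_spot`,
#'   `sep_surround`, `retained`, `cum_released`.
#' @export
render_event_traces <- function(event, kinetics, frame_rate_hz = 10,
                                duration_s = 60) {
  stopifnot(event$t_on_s >= 0, event$t_on_s <= duration_s)
  nt <- as.integer(round(duration_s * frame_rate_hz))
  t <- (seq_len(nt) - 1) / frame_rate_hz
  c0 <- event$cargo_units
  f_o <- sep_brightness(kinetics$ph_open, kinetics$sep_pka)
  f_c <- sep_brightness(kinetics$ph_closed, kinetics$sep_pka)
  lam_rel <- log(2) / kinetics$transient_release_halflife_s
  lam_slow <- log(2) / kinetics$persistent_decay_halflife_s
  lam_fast <- log(2) / kinetics$bafilomycin_fast_halflife_s
  t_on <- event$t_on_s

  retained <- rep(c0, nt)
  cum_rel <- numeric(nt)
  pool <- numeric(nt)                    # SEP-visible released pool at spot
  bright <- rep(f_c, nt)                 # brightness of retained cargo

  decay_from <- function(t0, amp, lam) ifelse(t >= t0, amp * exp(-lam * (t - t0)), 0)

  cls <- as.character(event$mech_class)
  if (cls == "transient") {
    retained[t >= t_on] <- 0
    cum_rel[t >= t_on] <- c0
    pool <- decay_from(t_on, c0 * f_o, lam_rel)
  } else if (cls %in% c("persistent", "kiss_and_run_pair_first")) {
    r <- if (cls == "kiss_and_run_pair_first") kinetics$partial_release_fraction else 0
    t_close <- t_on + kinetics$pore_open_s
    open_ph <- t >= t_on & t < t_close
    bright[open_ph] <- f_o
    if (kinetics$reacidification) {
      after <- t >= t_close
      bright[after] <- f_c + (f_o - f_c) * exp(-lam_slow * (t[after] - t_close))
    } else {
      bright[t >= t_close] <- f_o
    }
    if (r > 0) {
      retained[t >= t_on] <- (1 - r) * c0
      cum_rel[t >= t_on] <- r * c0
      pool <- pool + decay_from(t_on, r * c0 * f_o, lam_rel)
    }
    # final full release: pair firsts reopen; bafilomycin-mode plain
    # persistent events release after their clustered dwell
    t_final <- if (cls == "kiss_and_run_pair_first") event$t_reopen_s
               else if (!kinetics$reacidification) t_on + event$dwell_s
               else NA_real_
    if (!is.na(t_final) && t_final <= duration_s) {
      amp <- (1 - r) * c0 * f_o
      lam_out <- if (kinetics$reacidification) lam_rel else lam_fast
      pool <- pool + decay_from(t_final, amp, lam_out)
      cum_rel[t >= t_final] <- c0
      retained[t >= t_final] <- 0
    }
  } else if (cls == "kiss_and_run_pair_second") {
    retained <- numeric(nt)              # signal carried by the pair first
  } else stop("unknown mech_class: ", cls)

  visible <- t >= (t_on - kinetics$prefusion_visible_s)
  mch_spot <- retained * as.numeric(visible)
  if (cls == "kiss_and_run_pair_second") mch_spot <- numeric(nt)
  sep_spot <- retained * bright * as.numeric(visible) + pool
  sep_surround <- kinetics$surround_fraction * cum_rel * f_o

  data.frame(time_s = t, sep_spot = sep_spot, mch_spot = mch_spot,
             sep_surround = sep_surround, retained = retained,
             cum_released = cum_rel)
}
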