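#' Simulation configuration for synthetic TIRF movies
#'
#' Collects every knob of the movie generator: acquisition geometry, event
#' statistics, pharmacological condition, photobleaching and the camera noise
#' model. Defaults reproduce the acquisition regime of the study the package
#' models: 10 Hz imaging for 60 s on an EMCCD at 0.16 um/px, ~40 exocytic
#' events per cell of which ~9.8% are persistent, and 15% of persistent
#' events followed by a consecutive (kiss-and-run) event at the same site.
#'
#' @param frame_rate_hz frames per second (default 10).
#' @param duration_s movie length in seconds (default 60; sessions run 60-90 s).
#' @param width_px,height_px frame size in pixels.
#' @param pixel_pitch_um physical pixel size (default 0.16, a 100x objective
#'   on a 16 um-pixel EMCCD).
#' @param mask_spec `"neuron"` for a synthetic soma-plus-processes footprint,
#'   `"full"` for the whole frame, or a list with elements `type` and
#'   optionally `target_foreground` (exact foreground pixel count) and
#'   `n_processes`.
#' @param n_events expected total exocytic events per movie (default 40).
#' @param exact_n_events if `TRUE` draw exactly `n_events` (after condition
#'   scaling); otherwise Poisson.
#' @param persistent_fraction fraction of events that are persistent
#'   (default 0.098).
#' @param consecutive_fraction fraction of persistent events followed by a
#'   second, co-located event (default 0.15, the middle of the observed
#'   12-19% range).
#' @param condition one of `"basal"`, `"KCl"`, `"A23187"`, `"bafilomycin"`,
#'   `"cycloheximide"`, `"dyngo"`. KCl and A23187 raise event counts and the
#'   persistent fraction; bafilomycin disables vesicle reacidification;
#'   cycloheximide and dyngo leave frequencies unchanged.
#' @param bleach_fraction whole-movie fractional photobleaching loss
#'   (default 0.05; acquisitions typically lose 2-10%).
#' @param background background fluorescence level B (camera counts).
#' @param read_noise_sd Gaussian read-noise SD (counts).
#' @param gain Poisson gain (counts per photon-equivalent; shot noise uses
#'   `rpois(intensity * gain) / gain`).
#' @param psf_sigma_px Gaussian PSF sigma in pixels (default 1.3, a
#'   diffraction-limited spot at 0.16 um/px).
#' @param cargo_mean,cargo_cv mean and coefficient of variation of the
#'   per-vesicle relative fluorophore count (log-normal). The default gives
#'   spot peaks 4-5x the extracted-trace baseline, the regime in which the
#'   2x-background dwell rule separates transient from persistent events.
#' @param channels character vector among `"SEP"`, `"mCherry"`, `"clathrin"`.
#' @param n_clathrin_puncta expected clathrin puncta when that channel is on.
#' @param seed random seed (mandatory for reproducible fixtures).
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(frame_rate_hz = 10,
                       duration_s = 60,
                       width_px = 128,
                       height_px = 128,
                       pixel_pitch_um = 0.16,
                       mask_spec = "neuron",
                       n_events = 40,
                       exact_n_events = FALSE,
                       persistent_fraction = 0.098,
                       consecutive_fraction = 0.15,
                       condition = c("basal", "KCl", "A23187", "bafilomycin",
                                     "cycloheximide", "dyngo"),
                       bleach_fraction = 0.05,
                       background = 200,
                       read_noise_sd = 10,
                       gain = 1,
                       psf_sigma_px = 1.3,
                       cargo_mean = 900,
                       cargo_cv = 0.15,
                       channels = c("SEP", "mCherry"),
                       n_clathrin_puncta = 30,
                       seed = 1) {
  condition <- match.arg(condition)
  stopifnot(frame_rate_hz > 0, duration_s > 0,
            width_px >= 1, height_px >= 1, pixel_pitch_um > 0,
            n_events >= 0,
            persistent_fraction >= 0, persistent_fraction <= 1,
            consecutive_fraction >= 0, consecutive_fraction <= 1,
            bleach_fraction >= 0, bleach_fraction < 1,
            background >= 0, read_noise_sd >= 0, gain > 0,
            psf_sigma_px > 0, cargo_mean > 0, cargo_cv >= 0)
  channels <- match.arg(channels, c("SEP", "mCherry", "clathrin"),
                        several.ok = TRUE)
  cfg <- list(frame_rate_hz = frame_rate_hz, duration_s = duration_s,
              width_px = as.integer(width_px), height_px = as.integer(height_px),
              pixel_pitch_um = pixel_pitch_um, mask_spec = mask_spec,
              n_events = n_events, exact_n_events = exact_n_events,
              persistent_fraction = persistent_fraction,
              consecutive_fraction = consecutive_fraction,
              condition = condition, bleach_fraction = bleach_fraction,
              background = background, read_noise_sd = read_noise_sd,
              gain = gain, psf_sigma_px = psf_sigma_px,
              cargo_mean = cargo_mean, cargo_cv = cargo_cv,
              channels = channels, n_clathrin_puncta = n_clathrin_puncta,
              seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Condition multipliers for event statistics
#'
#' Pharmacological conditions rescale the expected event count and the
#' persistent fraction. Depolarisation (KCl) and calcium ionophore (A23187)
#' raise both; bafilomycin, cycloheximide and dyngo leave frequencies at
#' basal levels (bafilomycin instead switches the kinetic model by blocking
#' reacidification).
#'
#' @param condition condition name as in [sim_config()].
#' @return list with `n_events_mult` and `persistent_mult`.
#' @export
condition_multipliers <- function(condition) {
  switch(condition,
    basal = list(n_events_mult = 1, persistent_mult = 1),
    KCl = list(n_events_mult = 2, persistent_mult = 2),
    A23187 = list(n_events_mult = 1.5, persistent_mult = 2),
    bafilomycin = ,
    cycloheximide = ,
    dyngo = list(n_events_mult = 1, persistent_mult = 1),
    stop("unknown condition: ", condition)
  )
}

#' Vesicle fusion-pore kinetic parameters
#'
#' The photophysical state machine behind every simulated trace: a vesicle
#' starts closed and acidic (pHluorin quenched, mCherry visible), the fusion
#' pore opens and neutralises the lumen, cargo is released fully (transient
#' events), retained (persistent events, pore re-closes and the vesicle
#' reacidifies) or partially released and later released in full at a second
#' pore opening (kiss-and-run pairs).
#'
#' @param transient_release_halflife_s spot decay half-life of released cargo
#'   diffusing away (default 2 s).
#' @param persistent_decay_halflife_s fluorescence half-life of the slow
#'   reacidification decay of control persistent events (default 17 s).
#' @param bafilomycin_fast_halflife_s decay half-life of the post-plateau
#'   full release under bafilomycin (default 2 s).
#' @param persistence_dwell_range_s range from which the clustered dwell of a
#'   persistent event is drawn uniformly; must exceed 4 s.
#' @param pore_open_s how long the pore stays open at a persistent first
#'   opening before re-closing.
#' @param partial_release_fraction cargo fraction released at the first
#'   kiss-and-run pore opening (default 0.5).
#' @param reacidification if `FALSE` (bafilomycin) the lumen stays neutral
#'   while the pore is closed, producing a plateau instead of the slow decay.
#' @param pore_reopen_delay_range_s range for the delay between the two
#'   openings of a kiss-and-run pair.
#' @param prefusion_visible_s how long before fusion the docked vesicle is
#'   visible in the (pH-insensitive) mCherry channel.
#' @param surround_fraction sustained surround elevation left by released
#'   receptors on the nearby membrane, as a fraction of the released spot
#'   peak (default 0.02 — the "small but sustained" rise of the surround
#'   trace after full release).
#' @param sep_pka pHluorin pKa (default 7.1).
#' @param ph_open,ph_closed lumenal pH with the pore open / closed
#'   (defaults 7.4 and 5.5).
#'
#' @return an object of class `vesicle_kinetics`.
#' @export
vesicle_kinetics <- function(transient_release_halflife_s = 2,
                             persistent_decay_halflife_s = 17,
                             bafilomycin_fast_halflife_s = 2,
                             persistence_dwell_range_s = c(5, 15),
                             pore_open_s = 0.5,
                             partial_release_fraction = 0.5,
                             reacidification = TRUE,
                             pore_reopen_delay_range_s = c(4, 20),
                             prefusion_visible_s = 2,
                             surround_fraction = 0.02,
                             sep_pka = 7.1,
                             ph_open = 7.4,
                             ph_closed = 5.5) {
  stopifnot(transient_release_halflife_s > 0,
            persistent_decay_halflife_s > 0,
            bafilomycin_fast_halflife_s > 0,
            length(persistence_dwell_range_s) == 2,
            all(persistence_dwell_range_s > 4),
            pore_open_s >= 0,
            partial_release_fraction > 0, partial_release_fraction < 1,
            is.logical(reacidification),
            length(pore_reopen_delay_range_s) == 2,
            all(pore_reopen_delay_range_s > 0),
            surround_fraction >= 0,
            ph_open > ph_closed)
  kin <- list(transient_release_halflife_s = transient_release_halflife_s,
              persistent_decay_halflife_s = persistent_decay_halflife_s,
              bafilomycin_fast_halflife_s = bafilomycin_fast_halflife_s,
              persistence_dwell_range_s = persistence_dwell_range_s,
              pore_open_s = pore_open_s,
              partial_release_fraction = partial_release_fraction,
              reacidification = reacidification,
              pore_reopen_delay_range_s = pore_reopen_delay_range_s,
              prefusion_visible_s = prefusion_visible_s,
              surround_fraction = surround_fraction,
              sep_pka = sep_pka, ph_open = ph_open, ph_closed = ph_closed)
  class(kin) <- "vesicle_kinetics"
  kin
}

#' Read a simulation configuration from a YAML file
#'
#' Every field of [sim_config()] and [vesicle_kinetics()] is addressable under
#' the top-level keys `config:` and `kinetics:`.
#'
#' @param path YAML file.
#' @return list with elements `config` and `kinetics`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- do.call(sim_config, y$config %||% list())
  kin <- do.call(vesicle_kinetics, y$kinetics %||% list())
  if (cfg$condition == "bafilomycin") kin$reacidification <- FALSE
  list(config = cfg, kinetics = kin)
}
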