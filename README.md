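# tirfex

Simulation and analysis of single-vesicle exocytosis in TIRF microscopy
movies of pHluorin-tagged receptors.

In TIRF imaging of neurons expressing receptors tagged with superecliptic
pHluorin (SEP), each exocytic event is a diffraction-limited spot that
lights up within one frame (10 Hz) when the fusion pore opens and the
acidic vesicle lumen neutralises. Events come in two kinetic flavours:
**transient** (full release; spot decay half-life ≈ 2 s) and **persistent**
(receptors stay clustered > 4 s; slow decay, half-life ≈ 17 s, consistent
with pore closure and vesicle reacidification). Some persistent events are
followed by a **consecutive** event within 1 µm² — a kiss-and-run cycle in
which the pore reopens and releases the retained cargo. Distinguishing that
mechanism from coincidence requires (a) kinetic classification of every
event and (b) a spatial null model for how often consecutive events would
occur by chance.

The package provides, end to end:

* a **mechanistic simulator** (`sim_config()`, `vesicle_kinetics()`,
  `simulate_movie()`): dual-colour SEP/mCherry movies with transient,
  persistent and kiss-and-run events on a neuron-shaped mask, pH-dependent
  SEP photophysics, EMCCD-like Poisson + Gaussian noise, photobleaching,
  and condition knobs (KCl, A23187, bafilomycin, …), all seeded and
  bit-reproducible, with ground truth exported as CSV and movies as TIFF;
* **preprocessing and detection** (`subtract_background()`,
  `correct_bleaching()`, `detect_events()`, `extract_trace()`,
  `measure_rise_time()`, `kymograph()`): a calibrated rapid-rise detector
  (5 robust SDs on a variance-standardised temporal difference) replacing
  by-eye counting;
* **kinetics** (`fit_plateau_one_phase_decay()`, `classify_event()`,
  `summarize_halflives()`): least-squares fits of
  `F(t) = F0` for `t < t0`, `(F0 − B)·exp(−k(t − t0)) + B` for `t ≥ t0`,
  half-life `ln 2 / k`, and the transient / persistent /
  biphasic-persistent dwell classification against 2× background;
* the **random-placement null model** (`threshold_image()`,
  `estimate_probability()`): N events uniform on a thresholded cell
  footprint `It(i,j) = 1 ⇔ I(i,j) ≥ T`, 10% persistent, success if a
  persistent event is followed by a later event in the same 1 µm² window —
  plus `observed_consecutive_fraction()` and `pearson_colocalization()`
  for the measured counterparts;
* a **pipeline with group statistics** (`run_pipeline()`,
  `compare_groups()`): per-cell tables, pooled summaries, pooled-variance
  Student's t-test and D'Agostino–Pearson normality check, and a thin CLI
  (`inst/scripts/tirfex`) with `simulate` / `detect` / `classify` /
  `nullmodel` / `run` subcommands.

## Worked example

```r
library(tirfex)

cfg <- sim_config(seed = 42, n_events = 20, duration_s = 30, channels = "SEP")
sim <- simulate_movie(cfg)                       # movie + ground truth
bc  <- correct_bleaching(sim$movie)              # photobleaching trend out
det <- detect_events(subtract_background(bc$movie, clip = FALSE))
head(as.data.frame(det), 3)
#>   event_id x_px y_px t_on_s strength
#> 1        1  115   51    2.8 44.04788
#> 2        2   53   83    3.3 33.93840
#> 3        3   72   78    3.7 42.84863

tr <- extract_trace(bc$movie, det[1, ])          # 4 / 16 um^2 ROI traces
cl <- classify_event(tr)
cl$label; cl$dwell_s; cl$half_life_s
#> "transient"   1.9   1.69
```

The detector found 18 of the 20 simulated events in this movie; the first
one peaks 2.8 s in, falls below twice its background within 1.9 s (hence
"transient"), and its post-peak decay fits a 1.69 s half-life — the
simulator's generative half-life is 2 s.

The null model, on a synthetic neuron footprint with 15,318 foreground
pixels and 40 events of which 4 are persistent:

```r
mask <- generate_mask(list(type = "neuron", target_foreground = 15318),
                      256, 256, seed = 1)
estimate_probability(mask, null_model_config(N = 40, replicates = 20000,
                                             seed = 1))
#> null-model consecutive-event probability: 0.0193 (MC SE 0.0010,
#>   20000 replicates, N = 40)
```

So a random-placement model produces a consecutive event in only ~2% of
cells — an order of magnitude below the observed 12–19% pairing rate of
persistent events, which is the argument that consecutive events are
mechanistic rather than coincidental.

## Documentation

`vignettes/tirfex-methods.Rmd` describes the photophysical state machine,
the noise and geometry defaults and why they were chosen, the fitting and
classification rules with their edge cases, the null-model construction,
and what the synthetic data do and do not establish about real movies.
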