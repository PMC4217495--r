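---
title: "Models and methods behind tirfex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tirfex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tirfex)
```

# The biological setting

Under total internal reflection fluorescence (TIRF) illumination only the
~100 nm of the sample closest to the coverslip is excited, which isolates the
plasma membrane of a cultured neuron. Receptors tagged on their lumenal
domain with superecliptic pHluorin (SEP) are invisible inside the acidic
lumen of a transport vesicle (pH ≈ 5.5) and light up the moment the fusion
pore opens and the lumen equilibrates with the neutral extracellular medium.
A single exocytic event therefore appears as a diffraction-limited spot
whose intensity rises within one frame at 10 Hz and then decays.

Two kinetic phenotypes are modelled:

* **transient** events — the full cargo is released at fusion and diffuses
  away, so the spot decays with a fast half-life (default 2 s);
* **persistent** events — receptors remain clustered at the insertion site
  for more than 4 s. In untreated cells the spot then decays slowly
  (default half-life 17 s), consistent with the pore re-closing and the
  vesicle re-acidifying, which quenches SEP without moving any cargo.

A fraction of persistent events is followed by a *consecutive* event at the
same site (within 1 µm²): the pore re-opens and releases the retained
cargo. This kiss-and-run cycle is made directly visible by two
manipulations the simulator reproduces: bafilomycin (a v-ATPase inhibitor)
prevents re-acidification, converting the slow decay into a plateau
followed by a fast (~2 s) final release; and a dual mCherry/SEP tag shows
the pH-insensitive channel stepping down only at release instants while
SEP tracks lumenal pH.

# The simulator

`sim_config()` + `vesicle_kinetics()` fully parameterise a movie;
`simulate_movie()` derives the mask, the ground-truth event table and the
rendered pixels from a single seed, and every stage is reproducible
bit-for-bit from `(config, seed)`.

**Photophysics.** SEP brightness follows a Hill sigmoid of lumenal pH with
unit slope, `1 / (1 + 10^(pKa − pH))`, with pKa 7.1, pH 7.4 when the pore
is open and 5.5 when closed — literature-typical values for superecliptic
pHluorin. A docked vesicle is therefore rendered at ~2.5% of its open-pore
brightness before fusion (the pre-fusion invisibility invariant is tested
at 3%). mCherry is pH-independent: its spot amplitude equals the retained
cargo and steps down only at release instants, so retained + cumulatively
released cargo is conserved exactly — a tested invariant.

**State machine.** Each event class maps to a trajectory of (retained
cargo, lumenal pH, local released pool): transient events release
everything at onset; persistent events keep everything and either
re-acidify (fluorescence half-life 17 s) or, without re-acidification,
plateau for their dwell (drawn uniformly from 5–15 s, respecting the
"> 4 s" definition) before full release; kiss-and-run pairs release a
fraction (default 0.5) at the first opening and the remainder at the
re-opening, 4–20 s later. The released pool decays at the spot with the
2 s release half-life and leaves a sustained elevation on the surrounding
membrane equal to 2% of the released spot peak — the "small but sustained"
surround rise. The surround term is confined to the cell footprint, since
released receptors diffuse within the membrane.

**Rendering and noise.** Events become Gaussian spots (σ 1.3 px at
0.16 µm/px — diffraction-limited on a 100×/16 µm-pixel EMCCD) on a uniform
background (200 counts); a multiplicative exponential ramp removes the
configured bleaching fraction (default 5%, within the 2–10% regime) by the
last frame; Poisson shot noise (gain 1) plus Gaussian read noise
(SD 10 counts) are applied. The EMCCD excess-noise factor is deliberately
omitted; it would scale the shot-noise term by up to √2 and is exposed
through `gain`.

**Cargo amplitude.** No absolute calibration is available, so cargo is in
arbitrary units, log-normal with mean 900 and CV 0.15. This mean puts spot
peaks at 4–5× the extracted trace baseline, matching the example traces'
peak-to-background ratios; it matters because the classification rule
below thresholds at 2× background, and at peak/background ratios under ~2
that rule cannot represent slow decays at all. Within the chosen range,
transient events always cross the threshold well before the 4 s boundary.

**Geometry.** The synthetic neuron footprint is the superlevel set of a
continuous thickness field (a soma disk plus 2–4 tapering processes along
smooth random-walk paths), which makes it connected by construction and
lets an exact foreground pixel count be hit by thresholding at the k-th
largest field value. The default footprint covers 45% of a 128×128 field,
i.e. ~7,400 px. That is about 20× denser in events per membrane area than
the real cells (40 events on a ~150,000-px footprint at acquisition
pitch); rendering fields that large is not affordable at full frame rate,
so crowding is the one respect in which the synthetic data are *harder*
than the real data, and the analysis stages carry explicit
crowding countermeasures (below). Passing tests therefore demonstrate
robustness at higher-than-real density but do not exercise real-data
nuisances such as drift, uneven illumination or intracellular transport.

# Preprocessing and detection

Bleaching is estimated by a log-linear fit to the whole-field mean over
time — excluding the cell footprint when a mask is available, because
accumulating released-receptor fluorescence otherwise cancels part of the
trend — and corrected by dividing each frame by the normalised trend.
Background subtraction either uses a supplied blank field or a per-frame
mode of off-mask intensities; the per-frame estimates are smoothed over
time (lowess) because their sampling jitter would otherwise imprint
coherent frame-wide offsets on the residual that decalibrate detection.
Subtraction clips at zero by default; the pipeline's detection stage works
on an unclipped residual because rectifying the noise floor measurably
heavies the tail of the detection statistic.

Detection computes a two-frame temporal difference of the spatially
smoothed stack and standardises it with a per-pixel noise SD: the raw
difference variance is estimated robustly per pixel (temporal MAD, per
~10 s epoch so that slow variance drift is tracked) and propagated through
the smoothing weights exactly. Local maxima above 5 robust SDs are kept;
candidates within 1 µm and 1 s are merged, as are same-instant secondary
maxima within 2.5 µm (the released-pool halo of a single fusion).
Calibration is Monte Carlo tested: fewer than ~1 false positive per
60 s movie at the default threshold.

Traces use the study's ROI geometry: spot = per-frame maximum in a 4 µm²
box (13×13 px), surround = mean over the 16 µm² box minus the spot box.
The background level `B` is the pre-onset median (10 frames, minimum 3),
guarded by the whole-trace lower quartile against a neighbour decaying
through the pre-onset window. When classifying detected events the
pipeline reads a 1 µm² spot box and excludes pixels within 3 px of other
detections — at the simulated density a 4 µm² max-ROI would conflate
neighbouring events' PSF skirts. Rise times are 10–90% linear
interpolations; values below one frame interval are reported as the frame
interval, the resolution limit at 10 Hz.

# Kinetics

The decay model is a plateau followed by one-phase exponential decay,

$$F(t) = F_0 \;(t < t_0), \qquad
  F(t) = (F_0 - B)\,e^{-k (t - t_0)} + B \;(t \ge t_0),$$

with half-life $\ln 2 / k$. For fixed $(t_0, k)$ the model is linear in
$(F_0, B)$, so the fit profiles $k$ by 1-D minimisation with a linear
solve inside, over a $t_0$ grid (0.5 s steps over the first half of the
window, refined at frame resolution). This is deterministic, needs no
starting values, and recovers noiseless generating parameters to
machine-level accuracy; the non-negativity of the asymptote is enforced by
re-solving with $B = 0$ when needed. A fit is flagged unconverged when the
rate sits at the search boundary or the amplitude does not decay; no
half-life is reported then.

Classification measures the dwell from the initial maximum (searched
within 1 s of the event's own onset — anchoring on the global trace
maximum would latch onto later co-located events, and on flat plateaus
noise would place the argmax arbitrarily) to the first crossing of a
3-frame-median-smoothed trace below 2 × `B`. Events with dwell ≤ 4 s are
transient, longer are persistent; the 4 s boundary and the factor 2 are
configuration constants. Traces that never return below threshold are
right-censored: persistent if more than 4 s of post-peak data was
observed, otherwise unclassified — a censored trace shorter than the
boundary carries no evidence either way. A persistent event is reported
as biphasic (the bafilomycin phenotype) when the plateau model beats the
immediate decay by more than 6 BIC units with $t_0 > 1$ s and a fast
post-plateau half-life; the margin of 6 ("strong evidence" on the usual
BIC scale) is our choice, as no selection criterion is stated for the
original fits.

Note one documented inheritance: because the dwell rule thresholds at an
absolute multiple of background, its outcome depends on peak amplitude,
not only on kinetics. The simulator's cargo range keeps both classes well
away from the boundary; dim events in real data would not be so obliging.

# The spatial null model

The question: if $N$ events land independently and uniformly on the cell
footprint with a random time order, and exactly
$\operatorname{round}(0.1N)$ of them are persistent, how often does some
persistent event have a *later* event within 1 µm² of it? The footprint is
a binary mask $I_t(i,j) = 1 \iff I(i,j) \ge T$; "within 1 µm²" is realised
as sharing a 2×2-pixel block of the mask grid — the mask pitch is not
stated alongside its 15,318-pixel count, and a 2×2 block (effective pitch
≈ 0.5 µm/px) is the unique window size whose closed-form approximation
$1 - (1 - w/M)^{n_{\text{pairs}}}$ (with $w = 4$, $M = 15{,}318$,
$n_{\text{pairs}} = 4 \times 39/2$) reproduces the reported ≈ 0.02 at
$N = 40$. Both the window and the exact-count versus Bernoulli persistent
labelling are configuration knobs. The Monte Carlo estimator is seeded,
reports $\sqrt{\hat p(1-\hat p)/R}$ as its standard error, and is tested
against exhaustive enumeration (all $M^N$ placements × persistent subsets)
on tiny masks, where enumeration is exact and the closed form is visibly
approximate.

The observed counterpart searches, for each persistent event, for any
later event within a 1 µm square at acquisition pitch; with the
generator's defaults (15% of persistent events paired) the recovered rate
matches after subtracting the coincidental-neighbour rate, which is
non-negligible at the simulated density and measured by a
zero-consecutive-fraction control.

# Group statistics

Per-cell values (not per-event) are the statistical unit. The two-sample
comparison is the classical pooled-variance Student's t-test, written from
its textbook formulas and verified against `t.test(var.equal = TRUE)` to
1e-10; a Welch variant is available. Normality is checked per group with
the D'Agostino–Pearson $K^2$ omnibus statistic (transformed skewness +
kurtosis, $\chi^2_2$ reference), implemented from the moment formulas and
frozen-value tested against an independent reference implementation; it
requires $n \ge 8$ and is skipped with a warning below that. No
multiple-testing correction is applied, matching the source analysis; the
report says so.

# Problem sizes and numerical choices

The shipped tests and the acceptance script use 10-movie batches of
128×128 × 600-frame single-channel movies, 200-trace fitting ensembles and
$10^5$ null-model replicates; these sizes give Monte Carlo errors
comfortably below the tolerances being checked while keeping a full run in
the minutes range on one core. Degenerate inputs are handled explicitly:
zero-area masks and events off the mask are errors, empty detection lists
and empty classes propagate as empty results, zero-variance groups flag
the comparison as degenerate, and ROIs clipped by more than half at the
frame border are refused.

# Known limitations

* No evanescent-field depth profile: vesicle approach exists only as the
  mCherry pre-fusion appearance step.
* No subpixel localisation, drift correction or particle tracking.
* The released pool decays exponentially rather than by an explicit 2-D
  diffusion solution — the same single-exponential description used for
  the fitted data.
* Reacidification and any slow release are not separated; the 17 s
  fluorescence half-life models their combined effect.
* Event timing is uniform with no refractory period except within
  kiss-and-run pairs.
* The classification's amplitude dependence is inherited from the
  2 × background rule and documented rather than removed.
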