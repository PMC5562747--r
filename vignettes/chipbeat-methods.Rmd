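---
title: "Methods: beat kinetics, viability and drug-interaction simulation for organ-on-a-chip data"
author: "chipbeat authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beat kinetics, viability and drug-interaction simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipbeat)
```

Multi-tissue microphysiological systems couple liver, cardiac and lung tissue
models in one recirculating perfusion circuit, so that a drug dosed into the
shared medium is metabolized by the liver while acting on the heart, and an
insult to the lung can injure the heart through secreted factors. The
quantitative readouts of such experiments are modest in kind but demanding in
detail: beat rates extracted from video of contracting cardiac organoids,
live/dead cell ratios from two-channel fluorescence images, and percent
changes in beat rate across dosing conditions. `chipbeat` implements that
analysis chain, together with a mechanistic simulator of the liver--heart
drug-interaction and lung-cytokine experiments that doubles as a
ground-truthed synthetic-data generator. This vignette documents the models,
the tunable parameters and the numerical choices, and states plainly what the
synthetic validation does and does not demonstrate about real recordings.

## Motion quantification

A video is reduced to a contraction signal by thresholded pixel-movement
counting: consecutive frames are differenced pixelwise, the absolute
differences are thresholded, and the number of supra-threshold ("moving")
pixels is recorded per frame pair:

$$ m_i \;=\; \#\{(y,x) : |F_{i+1}(y,x) - F_i(y,x)| > \tau\}, \qquad i = 1, \dots, n-1 . $$

The count, not the summed difference intensity, is the primary statistic
(the summed intensity is carried along as a secondary column). Counting is a
*strict* inequality; a difference exactly equal to $\tau$ is not a moving
pixel.

**Threshold.** By default $\tau$ is set automatically to
$\mathrm{mean} + k\,\mathrm{SD}$ (sample SD, $k = 3$) of all pooled
difference values in the clip. For difference values dominated by symmetric
camera noise this admits roughly 0.1--1% of static pixels per frame — a
stable, low noise floor against which genuine motion (hundreds to thousands
of pixels along the moving organoid boundary) stands out. When every
difference is exactly zero the threshold is the sentinel 1.0 so that a
static clip reports an all-zero trace rather than a degenerate cutoff. A
fixed threshold mode bypasses the rule entirely. All frames are normalized
onto the 8-bit range on read (16-bit input is rescaled by its own maximum),
so thresholds always live on one scale.

**Smoothing.** Each beat produces *two* motion bursts — the fast contraction
and the slower relaxation — separated by roughly half the contraction-pulse
width. The default moving-average window of 0.25 s is chosen to span that
separation for rates down to 30 BPM, merging the pair into one hump per
beat, while remaining below the 0.4 s beat period of the fastest rates seen
in these platforms (150 BPM). Smoothing preserves trace length by symmetric
edge padding. Setting the window to 0 disables it.

Counts are invariant to adding a constant to every pixel (differences are
unchanged), and raising $k$ can only lower counts — both properties are
enforced by tests.

## Beat detection and kinetics

Beats are local maxima of the smoothed trace that satisfy two conditions:

* **prominence** at least `prominence_frac` (default 0.2) of the trace
  dynamic range. Prominence is topographic: from each candidate, extend left
  and right to the first strictly higher sample (or the trace edge), take
  the minimum of each span, and subtract the higher of the two minima from
  the peak. Range-relative prominence makes the same setting work across
  magnifications and organoid sizes; a constant trace has zero range and
  therefore no beats. Plateaus of equal values count once, at their middle
  sample.
* **refractory spacing** of at least `refractory_s` (default 0.25 s,
  capping detection at 240 BPM). When two candidates are closer than this,
  the more prominent one is kept, ties resolving to the earlier time.

The implementation is verified, on every random trace up to 200 samples that
the tests generate, against an exhaustive brute-force enumerator that tests
every index against these definitions independently.

**Rate estimates.** The primary BPM estimate is interval-based,
$60/\overline{\mathrm{IBI}}$, which is unbiased by partial beats at the clip
edges; the count-based estimate $60\,n_{\mathrm{peaks}}/T$ is reported
alongside. Inter-beat-interval mean, SD and coefficient of variation
summarize rhythm regularity. With fewer than two peaks the rate is 0.
Windowed rates split the trace into non-overlapping windows and apply the
same interval estimator per window.

**Cessation.** A clip is flagged `ceased` when *either* no qualifying beat
falls in the trailing `cessation_window_s` (default 10 s), *or* the raw
(unsmoothed) counts are indistinguishable from noise:
$\max - \mathrm{median} \le 5 \times 1.4826\,\mathrm{MAD}$. The second
criterion matters because range-relative prominence will happily find
"beats" in pure noise; the robust floor is computed on the raw counts, where
genuine beats are sparse excursions above a quiet baseline (heavy smoothing
would turn a fast beat train into a near-sinusoid and defeat the
median/MAD logic). A ceased clip reports BPM 0.

## LIVE/DEAD viability

Live cells are stained green (calcein AM), dead cells red (ethidium
homodimer). Each channel is segmented independently: global Otsu threshold
(or fixed per-channel cutoffs), 8-connected component labeling, and removal
of objects below `min_object_px` (default 20 px, about half the area of the
smallest nuclei-scale disk expected at these magnifications). A blank
channel yields zero objects with a warning rather than an error, since
all-live and all-dead images are legitimate.

Viability is computed by **object count**:
$100 \times \mathrm{live}/(\mathrm{live}+\mathrm{dead})$; a stained-area
ratio is provided as a secondary statistic. An object detected in both
channels (the centroid of a green object falls inside a red object, or vice
versa) is one physical cell counted once — as *dead* by default, because
ethidium entry indicates a compromised membrane; the resolution is
configurable. Images are treated as single 2-D projections; there is no 3-D
segmentation.

## Pharmacological readouts

Percent change from baseline, $100\,(b_t - b_0)/b_0$, is the platform's
universal drug readout. Dose--response series are fitted with a Hill model
through the origin,

$$ r(c) \;=\; R_{\max}\,\frac{c^{\,n}}{c^{\,n} + \mathrm{EC}_{50}^{\,n}}, $$

with the Hill coefficient free. No intercept is fitted: the zero-dose point
constrains the curve through its model form. Initialization is a multistart
grid over $n \in \{0.5, 1, 2, 4\}$ and $\mathrm{EC}_{50}$ over the positive
dose range, on log-parameters, keeping the best residual sum of squares
(ties toward the smallest starting $n$); all-zero responses return
$R_{\max} \approx 0$ with the EC50 flagged unidentifiable rather than a
spurious estimate.

Blockade analysis reports per-dose inhibition fractions
$1 - r(d)/r_{\mathrm{control}}$ with a monotonicity flag; note that when an
antagonist suppresses basal tone the response can fall below baseline and
the fraction can exceed 1. Recovery is the ratio of the treated to the
control percent change.

Time courses of percent change are classified into
`stable`, `sustained_increase`, `increase_then_decrease`,
`sustained_decrease` or `ceased` by threshold rules with a no-effect band of
±15 percent points by default — wide enough that a ~10% antagonist-alone
effect sits inside the band. The rules overlap at their edges, so precedence
is fixed: `ceased` (any zero-BPM point) first, then `stable`, then
`increase_then_decrease` (the decline rule is more specific than sustained
increase and therefore tested before it), then `sustained_increase`, then
`sustained_decrease` (taken as max below the band with min below −band, so
that trajectories mixing small positive excursions with deep declines still
receive a label).

## The chip simulator

**Pharmacokinetics.** The recirculating medium (10 µL/min over organoid
chambers of a few hundred µL) mixes fast relative to hours-long dosing
experiments, so drug concentration is modeled as a single well-mixed
compartment with first-order hepatic elimination, $C(t) = C_0 e^{-k t}$.
The default $k = \ln 3 / 48 \approx 0.0229\ \mathrm{h^{-1}}$ is calibrated
so the antagonist concentration falls 3-fold over 48 h, the fold-change
measured by LC-MS in the liver--heart platform. Modes without functional
3-D liver tissue (`cardiac_only`, and `hepatocyte_2d`, since 2-D hepatocyte
cultures showed no effective metabolism) use $k = 0$. An explicit
consequence worth noting: an 18 h pre-incubation reduces the antagonist by
$3^{18/48} \approx 1.51$-fold at the moment the agonist is added. The
agonist (epinephrine) is treated as uncleared over its short (< 2 h)
response window — a documented simplification. No partition coefficients,
protein binding or metabolite pharmacology are modeled; glucuronide
metabolites are pharmacologically inactive and not tracked.

**Pharmacodynamics.** Beat rate follows a Gaddum/Schild competitive-
antagonism model with basal adrenergic tone $E_b$ expressed as an
equivalent agonist concentration:

$$ \mathrm{bpm}(E, P) \;=\; B_0 \left( 1 + R_{\max}
   \frac{A^n}{A^n + \bigl(\mathrm{EC}_{50}(1 + P/K_i)\bigr)^n} \right),
   \qquad A = E + E_b . $$

The antagonist shifts the apparent EC50 without lowering the attainable
maximum (surmountable block), and basal tone is what lets the antagonist
alone depress the rate below baseline. The shipped defaults are
**calibrated, not measured**: a deterministic multistart least-squares fit
to four percent-change anchors — +40% at 0.5 µM agonist alone, −10% at
0.1 µM antagonist alone, +25% at 0.5 µM agonist after the antagonist has
been hepatically cleared for 18 h, and (at half weight) +5% for the fully
blocked heart-only condition. The fit is essentially exact (total weighted
SSE ~1e-13); parameters and per-anchor residuals ship in
`inst/extdata/pd_default_params.json` and are reproduced by
`calibrate_pd_defaults()`. The Hill coefficient is left free because a
purely competitive $n = 1$ model cannot simultaneously produce
near-complete block at 0.1 µM antagonist and substantial recovery after a
mere 1.5-fold clearance; the calibrated optimum is steep
($n \approx 5.4$), which should be read as a phenomenological description
of the anchor set, not a receptor-level measurement. $B_0$ cancels out of
percent changes and is fixed at 54 BPM so that the drug-free rate
(with basal tone) is ≈ 60 BPM.

```{r pd}
pd <- default_pd_params()
round(c(epinephrine_0.5 = pd_percent_change(pd, 0.5, 0),
        propranolol_0.1 = pd_percent_change(pd, 0, 0.1),
        liver_cleared   = pd_percent_change(pd, 0.5, 0.1 * 3^(-18/48)),
        full_block      = pd_percent_change(pd, 0.5, 0.1)), 2)
```

**Cytokine scenario.** The lung-injury cascade is phenomenological, not
receptor-mechanistic, because the observations are effects (an early
~60% beat-rate increase, a late decline) rather than rates. After a
bleomycin event, and only when the lung module is present, IL-8 and IL-1β
accumulate at zero-order rates (2 and 0.5 pg/mL/h — ELISA-scale
placeholders that do not feed the beat-rate effect). The beat rate follows
a piecewise-linear IL-1β effect curve: rise to +60% by 24 h post-exposure,
plateau through 96 h, then linear decline completing at 144 h. The decline
endpoint depends on the exposure regime: under sustained on-chip production
the heart stops entirely (multiplier 0 — exposure on day 3 therefore ceases
beating by day 9), whereas a single recombinant-IL-1β bolus ends depressed
~30% below baseline but still beating. IL-8 has no beat-rate effect, and in
a heart-only system bleomycin itself has none; a zero-dose bleomycin event
serves as the vehicle control.

## The synthetic-data generator

The generator is first-class, tested code; it is the ground truth against
which every analysis stage is validated.

**Videos.** A beating organoid is rendered as a bright disk (default rest
radius 30 px on a 128×128 frame) whose radius contracts by
`amplitude_frac` (default 10%) following an asymmetric raised-cosine pulse:
the contraction occupies the first 12% of the pulse and the relaxation the
remainder, approximating fast calcium-driven contraction (tens of
milliseconds) against a several-fold slower relaxation; the pulse is active
for 30% of each beat period, and the beat phase integrates the
instantaneous rate so time-varying trajectories (steps, ramps, simulator
output) are supported. The disk edge is rendered with 1-px soft
anti-aliasing so sub-pixel radius changes still move intensity. Additive
Gaussian pixel noise (default SD 2 on the 8-bit scale) and an optional
linear background drift emulate camera noise and illumination drift.
Frames are quantized to 8-bit integers, making written videos bit-exactly
reproducible from their seed. A Nyquist guard requires
$\mathrm{fps} \ge 4 \times \mathrm{bpm}/60$.

Defaults (128×128 px, 30 fps, 30 s) give realistic counting statistics —
hundreds of moving pixels per burst over a noise floor of tens — at
second-scale runtimes; tests use shorter or smaller clips where the
property under test allows it.

**Images.** Live and dead cells are soft-edged disks (radius 4--6 px) at
disjoint positions drawn by rejection sampling (a capacity error is raised
when the requested count cannot be placed), optionally Gaussian-blurred
(σ = 1 px in the recovery studies) and noise-corrupted (SD 3). Channel
assignment is exact, so recovered counts can be compared to truth.

**What passing means.** Recovery on these synthetics demonstrates that the
analysis chain is correct *given its model of the data*: radial motion of a
single convex object over a clean background, stationary illumination,
well-separated near-circular cells. Real recordings add organoid texture,
non-radial deformation, focus drift, debris, uneven staining and touching
cells; none of these are emulated (no microscope PSF beyond Gaussian blur,
no photorealistic texture), so synthetic recovery bounds algorithmic error,
not end-to-end error on microscope data. The viability ranges reported for
real organoid experiments are not reproduced here for the same reason —
the recovery study is on synthetic images only.

## Numerical and interface choices

* Pixel coordinates are 0-based, row-major, origin top-left; ROI rectangles
  are half-open $[y_0, y_1) \times [x_0, x_1)$.
* TIFF is the supported container (8/16-bit, multi-page); frame rate is
  mandatory input because TIFF carries none, and BPM is meaningless
  without it.
* Grayscale conversion uses the standard video luma weights
  0.299/0.587/0.114 and is idempotent.
* JSON reports are schema-versioned and stamped with the package version,
  resolved parameters and seed; doubles are written with 17 significant
  digits so reports round-trip bit-exactly.
* All randomness flows from explicit per-artifact seeds; identical seeds
  give bit-identical artifacts.
* Optimizers (PD calibration, Hill fits) are deterministic multistarts;
  non-convergence raises an error with the best residual rather than
  returning it silently.

## Worked example

```{r loop}
gen <- generate_beating_video(video_truth(bpm_trajectory = 90, seed = 7,
                                          duration_s = 10, size_px = 64))
res <- analyze_video(seq = gen$seq)
c(bpm = res$metrics$bpm, n_peaks = res$metrics$n_peaks,
  truth = gen$truth$n_pulses)
```

## Known limitations

* Motion is summarized by a scalar count; there is no optical flow,
  deformation field or contraction-relaxation velocity decomposition, so
  arrhythmias that change waveform shape without changing peak timing are
  invisible.
* The beat detector's refractory period caps detection at 240 BPM and, with
  the default smoothing, rates below ~30 BPM risk burst-splitting; both
  ends are outside the regime these platforms exhibit.
* The PD model is a four-anchor phenomenological calibration; its
  parameters, especially the steep Hill coefficient, should not be
  interpreted mechanistically, and the simulator inherits the well-mixed,
  agonist-uncleared simplifications above.
* The cytokine cascade is an effect curve with a fixed timetable, not a
  dose-dependent mechanism; bleomycin dose (beyond zero versus nonzero)
  does not change the outcome.
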