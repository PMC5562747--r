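# chipbeat

Analysis and simulation toolkit for multi-tissue organ-on-a-chip
experiments that couple liver, cardiac and lung tissue models in one
recirculating perfusion circuit. It is written for the people who run such
platforms: the raw data are videos of beating cardiac organoids, two-channel
LIVE/DEAD fluorescence images, and dosing protocols, and the scientific
readouts are beat rates, viability percentages, and percent changes in beat
rate across drug conditions.

The package provides four connected layers:

1. **Motion quantification** — the contraction signal of a video is the
   per-frame-pair count of "moving" pixels,
   `m_i = #{(y,x) : |F_{i+1} − F_i| > τ}`, with τ set automatically to
   mean + 3 SD of the pooled frame differences.
2. **Beat kinetics** — peaks of the smoothed motion trace with
   range-relative prominence ≥ 0.2 and refractory spacing ≥ 0.25 s;
   BPM = 60 / mean(inter-beat interval), IBI statistics, windowed rates,
   and a dual-criterion cessation flag.
3. **Viability and pharmacology** — Otsu-segmented, 8-connected object
   counts per channel with dead-wins dual-positive resolution;
   Hill dose–response fits `r(c) = Rmax·cⁿ/(cⁿ + EC50ⁿ)`, competitive
   blockade and recovery fractions, and time-course classification.
4. **Chip simulator / synthetic-data generator** — first-order hepatic
   clearance `C(t) = C0·e^(−kt)` (default k = ln 3 / 48 h⁻¹, i.e. a 3-fold
   drop over 48 h) coupled to a Gaddum/Schild beat-rate response
   `bpm = B0·(1 + Rmax·Aⁿ/(Aⁿ + (EC50·(1 + P/Ki))ⁿ))`, A = E + E_basal,
   plus ground-truthed renderers for beating-organoid videos and
   stained-cell images so every stage can be validated without any
   experimental download.

The methods vignette (`vignettes/chipbeat-methods.Rmd`) documents the
models, defaults and numerical choices in detail.

## Worked example

Generate a synthetic 90 BPM organoid video, analyze it, and query the
shipped pharmacodynamic model:

```r
library(chipbeat)

gen <- generate_beating_video(video_truth(bpm_trajectory = 90, seed = 7))
res <- analyze_video(seq = gen$seq)
res$metrics
#> <beat_metrics> bpm = 90.00, n_peaks = 44, ibi_cv = 1.82e-15, ceased = FALSE

pd <- default_pd_params()
round(c(epi_0.5       = pd_percent_change(pd, 0.5, 0),
        prop_0.1      = pd_percent_change(pd, 0, 0.1),
        liver_cleared = pd_percent_change(pd, 0.5, 0.1 * 3^(-18/48)),
        blocked       = pd_percent_change(pd, 0.5, 0.1)), 2)
#>       epi_0.5      prop_0.1 liver_cleared       blocked
#>            40           -10            25             5

g <- generate_livedead_image(image_truth(80, 20, blur_sigma_px = 1,
                                         noise_sd = 3, seed = 1))
count_live_dead(g$img)
#> <viability_result> live = 80, dead = 20, viability = 80.0%
```

Reading the numbers: the 30-second clip contains 45 contraction pulses and
the detector recovers 44 peaks (one lands on the clip edge) at exactly
90 BPM with essentially zero inter-beat variability. The pharmacodynamic
defaults reproduce their calibration anchors: +40% beat rate at 0.5 µM
epinephrine, −10% under 0.1 µM propranolol alone (blockade of basal
adrenergic tone), +25% when epinephrine follows 18 h of hepatic propranolol
clearance, and +5% (blocked) when no liver is present. The LIVE/DEAD image
with 80 live and 20 dead rendered cells is recovered exactly, giving 80.0%
viability.

A thin command-line wrapper ships at `inst/cli/chipbeat.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","chipbeat.R",package="chipbeat"))')" \
  analyze-video --input clip.tif --fps 30 --out-dir out/
```

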