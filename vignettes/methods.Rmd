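---
title: "From fin-mounted magnets to daily energy budgets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From fin-mounted magnets to daily energy budgets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(squidgait)
```

## The measurement principle

Squid propel themselves with two spatially separated propulsors: paired
muscular fins and the pulsed mantle jet. A biologging tag on the mantle
measures body acceleration, but fin movement happens elsewhere on the body.
The trick this package supports is a small permanent magnet mounted on one
lateral fin: as the fin beats, the magnet moves toward and away from the
tag's magnetometer, so the magnetic field magnitude oscillates at the
fin-beat frequency. The fin-magnet coupling is not calibrated to fin angle,
so all fin-position quantities are relative; only the timing and frequency
content of the modulation is analysed.

From that principle the pipeline proceeds in four stages, each an
independent module:

1. **Fin-stroke detection** — condition the magnetometer signal, detect
   individual fin strokes with a trainable peak detector, and remove
   orientation-change artefacts.
2. **Gait classification** — label 1 s windows active/inactive, extract
   glides, and classify active 5 s windows into metachronal finning, jets
   and "other" movements by dominant frequency and surge acceleration.
3. **Respirometry** — convert swim-tunnel dissolved-oxygen declines into
   mass-specific routine metabolic rates and fit a log–log mass-scaling
   model.
4. **Bioenergetics** — cost the classified behaviour with the scaling
   model, a gliding proxy and a Q10 temperature transfer, integrate to a
   24 h oxygen budget, and convert to prey-equivalent foraging needs.

A synthetic tag-signal generator with ground-truth labels sits underneath
all of it, so every stage is testable without deployed tag data.

## Fin-stroke detection

The three magnetometer axes are combined as `|x| + |y| + |z|` and smoothed
with a 30-sample moving average (0.3 s at 100 Hz). The smoother is
*centered*, with shrinking windows at the record edges: a centered window
introduces no phase lag, so detected stroke times are unbiased; a trailing
window would shift every event by 0.15 s.

Fin strokes are local maxima of the conditioned signal filtered by three
parameters: minimum topographic prominence, and minimum/maximum width.
Width is measured at half-prominence height — the conventional reference
level — because only the parameter names, not the reference level, are
fixed by the procedure this reproduces. One upstroke–downstroke cycle of a
clean sinusoid yields exactly one detected peak, and the detected count on
noise-free sinusoids equals the rising-zero-crossing count of the
detrended signal (a property the test suite checks across 0.5–2 Hz).

The detector is *trained*: on manually annotated segments, a Cartesian
grid of parameter settings is swept and every setting that marks 100% of
the annotated crests (one-to-one, nearest-first matching within 0.25 s) is
indexed as successful. Successful settings pooled across segments are
averaged field-wise to give the deployed setting. Two judgement calls are
configurable:

* **False positives do not disqualify a setting** by default
  (`require_no_extra = FALSE`): the training criterion is recall of
  annotated crests, and precision of the returned setting is always
  reported so a user can tighten the grid.
* **The annotation-matching tolerance defaults to 0.25 s**, roughly a
  quarter of a fin cycle at the typical 1.1 Hz beat; matching is greedy by
  nearest time and one-to-one.

Averaging recall-1 settings does not automatically give a recall-1
setting, so the per-segment recall of the averaged setting is recomputed
and reported; the test suite requires it to stay at or above 0.95.

Slow body rotations also move the magnetometer baseline and can produce
isolated peaks that would masquerade as single fin strokes — and, worse,
would flip a glide into an active state. Because genuine fin strokes come
in sequences, any detected event whose inter-fin interval exceeds 4 s
*both* before and after the event is removed. Record edges count as an
infinite gap on the open side. The filter is idempotent and removes
exactly the injected artefacts on synthetic data.

## Gait classification

Dynamic surge acceleration is separated from the gravitational/postural
component by subtracting a 0.5 s centered moving average from the surge
axis. The 0.5 s scale passes fin-beat (~1 Hz) and jet-pulse (sub-second)
movements essentially unattenuated while removing the quasi-static gravity
projection; the window length is configurable.

Each whole 1 s window is **active** if it contains at least one detected
fin stroke or its maximum absolute dynamic surge exceeds 0.10 g, otherwise
**inactive**. Maximal inactive runs of at least 5 s are **glides**;
glides in this system are passive, descending intervals (no bottom-sitting
was observed in the study population). Two boundary policies were genuinely
open:

* *Inactive runs shorter than 5 s.* Inactivity only counts as a
  behavioural state when it persists for 5 consecutive seconds, so
  sub-5 s lulls flanked by activity are folded into the surrounding active
  run (the fins of a slow, low-frequency cycle are still "working" between
  crests). Without this, low-frequency gaits whose crest spacing exceeds
  1 s fragment into unclassifiable slivers. Short inactive runs at the
  record edges have no surrounding activity and stay `unclassified`. Set
  `merge_short_inactive = FALSE` to keep them unclassified everywhere.
* *Active-run remainders.* Active runs are tiled with non-overlapping 5 s
  windows from the run start; a trailing remainder shorter than 5 s is
  `unclassified` and is kept in the time-budget denominator.

Each active 5 s window is mean-removed, Hann-tapered, zero-padded with
10,000 samples and Fourier-transformed; the dominant frequency is the
maximum-magnitude non-zero-frequency bin, giving a frequency resolution of
100/10500 ≈ 0.0095 Hz. Pooled dominant frequencies are bimodal — a
higher-frequency metachronal finning mode and a lower-frequency jet/other
mode — and the split frequency is the density minimum between the two
largest modes of a kernel density estimate (Silverman bandwidth). Two
numerical guards matter in practice: candidate modes closer than 0.2 Hz
are treated as one mode (sampling ripples inside a tight cluster are not
gaits), and when the inter-mode valley is flat its midpoint is used. If
bimodality is absent the function warns and falls back to a configured
default (0.75 Hz, midway between the typical jet-cycle and fin-beat
frequencies).

Windows at or above the split are **finning** (with a `jet_overlap` flag
when surge also exceeds 0.10 g — high-amplitude jets do co-occur with
metachronal finning); windows below the split are **jets** when surge
exceeds 0.10 g and **other** when it does not. Thresholds compare the
absolute value of dynamic surge.

### Accuracy limits of the 5 s window

The dominant-frequency estimator is resolution-accurate (error below
0.01 Hz) for any sinusoid of at least ~2 cycles per window, i.e. 0.4 Hz
and above. Below 0.4 Hz the negative-frequency image of the sinusoid
overlaps the Hann mainlobe of a 5 s window and biases the magnitude peak
— up to ~0.07 Hz at 0.2 Hz, at every phase; this is a property of the
transform, not of the implementation (an independent FFT implementation
reproduces the bias to four decimals). The bias is immaterial for gait
*classification*, because the split frequency (~0.75 Hz) sits far from
both modes relative to the worst-case bias; it only limits how precisely
the frequency of very slow movements is reported.

## The synthetic generator

`simulate_recording()` turns a scripted sequence of gait states into a
100 Hz accelerometer + magnetometer stream and a 1 Hz depth/temperature
stream, with ground-truth fin-event times and state intervals. What it
emulates, and how:

* **Finning**: an additive sinusoid on the field magnitude at the scripted
  fin-beat frequency (default 1.12 Hz, the population mean; the
  between-animal spread is 0.19 Hz and per-deployment frequencies are
  scriptable). The fin–magnet coupling is modelled as additive modulation
  proportional to fin elevation; a full dipole model adds nothing when
  only relative fin positions are used.
* **Jets**: large, slow fin cycles (default 0.4 Hz) plus one Gaussian
  surge pulse per cycle, peaking at the end of the fin downstroke
  (default 0.2 g, above the 0.10 g threshold).
* **"Other"**: the same slow cycles without supra-threshold surge
  (default 0.45 Hz).
* **Glides**: flat fin signal, sub-threshold surge, monotone descent at
  the scripted sink rate.
* **Orientation**: the 1 g gravity vector is rotated by a slow random
  walk in pitch/roll, so dynamic-surge extraction is non-trivial; the
  magnetometer baseline performs a smooth low-pass-filtered random walk.
  Both drifts are scaled so the per-0.3 s baseline change is far below a
  fin-stroke amplitude.
* **Stroke amplitude and mean offset**: amplitudes are arbitrary units
  (the coupling is uncalibrated); actively beating fins additionally ride
  on a small positive mean-field offset (30% of stroke amplitude) relative
  to the flat glide posture, reflecting the magnet's elevated mean
  position during work. Sensor noise defaults to 5% of stroke amplitude
  per channel.
* **State transitions** use a 0.3 s half-cosine envelope so the modulation
  is continuous across boundaries.

Ground-truth fin counts equal the number of completed cycles, and
`simulate_orientation_artefacts()` injects isolated baseline excursions
into glides with >4 s clearance from every true event and from each
other — exactly the geometry the inter-fin-interval filter removes.

What the generator deliberately does *not* emulate: amplitude variability
within a bout, hydrodynamic thrust, swimming speed, light, or dive-phase
structure beyond per-state vertical rates. Passing recovery tests on this
generator therefore demonstrates that the pipeline's logic is correct
under its stated signal model, not that the signal model captures every
property of deployed tags.

## Respirometry

Each trial's dissolved-oxygen decline is fitted by ordinary least squares;
a sealed system gives linear traces, and r² < 0.98 raises a QC warning.
The microbial background slope (no-animal control) is subtracted and the
difference scaled by the system volume:
`M = (|animal slope| − |control slope|) × V`, then divided by wet mass.
The animal's own displacement volume (mass / 1.06 kg l⁻¹ tissue density)
can optionally be deducted from V; for a ~1 kg squid in a 1485 l system
the correction is below 0.1% and it is off by default. Samples below 75%
air saturation are flagged using the Benson–Krause solubility relation
(salinity default 35); trials were managed to stay above that floor so
oxygen limitation never depresses the measured rate.

The scaling model is `log(rate) = a + b·log(mass)` with a per-animal
random intercept (animals contribute 1–3 trials each), fitted with
lme4/lmerTest; natural logarithms are used (predictions are
base-independent). When every animal has a single observation, or the
mixed fit fails, the model falls back to ordinary regression with a
warning. The marginal r² is the fixed-effect variance over the total
variance. Predictions are clamped to the fitted mass range with an
extrapolation warning — a two-parameter power law has no support outside
its data.

## Bioenergetics

Laboratory rates transfer to ambient temperature via
`Mcorr = M × q10^((T2 − T1)/10)` with q10 = 2 (laboratory reference
18.8 °C; ambient at squid depth averages 14.5 °C, so field rates are about
74% of laboratory rates). The correction is multiplicative and exactly
invertible.

Per-segment costing:

* **Finning** segments are costed at the scaling model's mass-specific
  prediction, Q10-corrected to the segment's mean ambient temperature
  (nearest-neighbour joined from the 1 Hz stream).
* **Glides** could not be elicited in the swim tunnel; their cost is the
  mean of previously measured standard (86) and hovering (183) rates,
  134.5 mg O₂ kg⁻¹ h⁻¹. The proxy is used as-is — its source rates were
  measured on the same field population at field temperatures, so a
  second Q10 transfer would double-correct.
* **Jets, "other" and unclassified** time is excluded from the costed
  total: no respirometry calibration exists for those gaits, and charging
  them at the finning rate would be invention. Their durations are always
  reported, so the budget is explicitly partial.

Daily budgets rescale the recorded per-state costs to 24 h by recorded
time fractions (not calendar-day splitting; recordings here are of order
hours). The prey conversion uses 1 ml O₂ ≡ 4 mg fish with an O₂ gas
density of 1.428 mg ml⁻¹ at standard temperature and pressure to move
between the mass and volume conventions; both constants are exposed as
arguments.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to exercise every code path while staying quick: 10-minute
deployments for detection recovery (five to ten replicates), 600 s
scripted deployments for time-budget recovery (three to five seeds),
training grids of 10⁴–10⁵ combinations (the grid sweep is cheap because
peak prominence and width are computed once, parameter settings are mere
filters on the candidate table), 30-minute respirometry traces, and 100
replicate fits for interval-coverage checks. Degenerate inputs error
early and explicitly: zero-duration scripts, non-finite parameters,
constant FFT segments, controls declining faster than animal trials,
all-equal masses.

## Known limitations

* Costed budgets cover finning and gliding only; jet and "other" time is
  reported but uncosted, so totals are lower bounds on movement cost.
* The gliding proxy assumes no postural cost, which can be non-negligible
  for negatively buoyant animals.
* Dominant frequencies below 0.4 Hz carry a window-induced bias (see
  above).
* The synthetic generator's fixed per-state frequencies and amplitudes
  make classification on synthetic data easier than on real tags, where
  amplitude and frequency drift within bouts; recovery results on
  synthetic data are necessary, not sufficient, evidence for field
  performance.
* Oxygen debt repayment, digestion, growth and reproduction are outside
  the energy model.
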