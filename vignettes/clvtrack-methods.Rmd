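---
title: "Quantifying collecting lymphatic vessel contractility with clvtrack"
author: "clvtrack authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying collecting lymphatic vessel contractility with clvtrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clvtrack)
```

## The measurement problem

Collecting lymphatic vessels (CLVs) move lymph by rhythmic contractions of
their smooth-muscle wall, gated by one-way valves. A single recording of a
tracer-perfused vessel under a near-infrared (NIR) fluorescence
stereomicroscope contains two readouts of the same pumping process:

* the **inner diameter** of the lumen over time, visible because the NIR
  tracer fills only the lumen, and
* the **mean fluorescence intensity** (MFI) over a region of interest (ROI)
  on the vessel, which scales with the amount of tracer in the imaging
  column and therefore with lumen *volume*.

`clvtrack` turns either readout into four physiological outcome measures:

| measure | definition | units |
|---|---|---|
| frequency $f$ | detected contraction peaks per minute | min$^{-1}$ |
| % amplitude $A$ | mean per-cycle $(P_i - T_i)/\mu_i \times 100$ | % of instantaneous mean |
| pumping score | $f \times A$, exactly | min$^{-1}$·% |
| tone | post/pre ratio of window mean level $\times 100$ | % of baseline |

where $P_i$, $T_i$ are the values of the $i$-th peak and its immediately
following trough, and $\mu_i$ is the instantaneous mean of the trace at the
cycle midpoint. Tone below 100% means sustained constriction: a constricted
vessel holds less tracer, so its mean fluorescence falls.

## Diameter tracking

The analyst supplies a `vesselGeometry()`: a point on the vessel centreline,
the unit normal to the vessel axis, a vessel-ROI radius $r$ (pixels) and the
µm/pixel scale. Everything else is derived:

* the **background ROI** (radius $0.5r$) sits at distance $2r$ from the
  centre along the normal;
* the **measurement line** (length $3r$, sampled at unit-pixel spacing with
  bilinear interpolation) runs from the background-ROI centre through the
  vessel to the far edge of the vessel ROI.

Each frame is processed independently with a **moving threshold**
$T = \bar I_\mathrm{vessel} / \bar I_\mathrm{background}$ (disc means over
pixels whose centres fall inside each ROI). The line profile is normalized
by the mean of its first ten samples (which lie in background tissue), the
samples with normalized intensity strictly above $T$ are counted, and the
count times the µm/pixel scale is the inner diameter. By default every
supra-threshold sample counts, with no contiguity requirement (the
spreadsheet-COUNTIF semantics of the original workflow);
`contiguous = TRUE` counts the longest contiguous run instead, which we
recommend for noisy recordings — a single low excursion of the ten-pixel
normalizer can otherwise push scattered background samples over the
threshold in one frame.

**Choosing $r$.** Both the threshold and the profile normalization are
ratios, so diameters are invariant to global intensity scaling. The only
systematic bias is geometric. For a cylindrical lumen of radius $R$ (pixels)
the chord profile is $2\sqrt{R^2 - y^2}$, and the threshold cuts where the
chord equals the vessel-ROI mean chord $\langle c \rangle \approx 2R^2/r$.
Because the chord has a vertical tangent at the edge, the resulting
underestimate of the radius is only
$\langle c \rangle^2 / (8R) \approx R/(2\rho^2)$ pixels with $\rho = r/R$.
With $\rho = 4$ (vessel ROI radius twice the lumen *diameter*) this stays
below half a pixel across lumen diameters of 10–60 px, which is why the
package's phantom analyses use that convention and why we recommend it on
real data. Placing the geometry centre a fraction of a pixel off the exact
lumen axis is harmless and even desirable: perfectly symmetric sampling
quantizes counts in steps of two pixels.

Frames whose background mean or profile normalizer is non-positive are
marked missing rather than interpolated; more than 10% missing frames
aborts the run.

## Peak and trough detection

Contractility traces are quasi-periodic with drifting baselines, so simple
thresholding is unreliable. `clvtrack` re-implements automatic
multiscale-based peak detection (AMPD): after removing the least-squares
line, a local-maxima scalogram $M$ is built over scales $k = 1..L$,
$L = \lceil N/2 \rceil - 1$, with $M[k, i] = 0$ where
$x_i > x_{i-k}$ and $x_i > x_{i+k}$ (both neighbours in range) and the
constant $1.5$ otherwise. The row sums $\gamma_k$ are minimized to select
the dominant scale $\lambda$ — in practice about half the contraction
period — and a sample is a peak when it is a local maximum at *every* scale
up to $\lambda$, i.e. it dominates all samples within $\pm\lambda$.
Troughs are peaks of the negated trace; a final pass enforces strict
peak/trough alternation, keeping the most extreme event of any same-type
run. Where the original formulation fills non-maximum scalogram entries
with $1 + U(0,1)$, we use the deterministic constant 1.5: only the
zero/non-zero pattern matters, and determinism makes runs reproducible
bit-for-bit.

Three boundary/tie rules matter in practice and are deliberate:

* **Plateau ties.** Comparisons are left-strict and right-non-strict
  ($x_i > x_{i-k}$, $x_i \ge x_{i+k}$), so tied plateaus — routine on
  integer-quantized diameter traces — resolve to their leftmost sample.
  On tie-free signals this is identical to the strict rule.
* **Record edges.** At scales whose neighbour would fall outside the
  record, the comparison is treated as satisfied (the $k = 1$ scale always
  requires both neighbours). Without this, every extremum within
  $\lambda$ of either end would be silently dropped.
* **The final sample** is admitted as an event only if it dominates every
  in-range lag *and* the last three steps contain a strict downward
  reversal. A smooth noiseless signal approaches the boundary monotonically
  over those steps, so on clean data the detector equals a brute-force
  interior local-maxima scan; on noisy data this rule counts the real event
  whose noisy maximum happens to land on the last sample. The first sample
  is never reported: a recording that opens high cannot be distinguished
  from the tail of an extremum that occurred before acquisition began.

Detection operates on the detrended signal; reported indices refer to the
original samples, and amplitudes are measured on raw values.

## From events to outcome measures

The **instantaneous mean** is a centred moving average whose window is
`roundToOdd(1.5 × median inter-peak interval)` — long enough to average out
the phasic oscillation, short enough to follow tonic drift. Half-window
margins at both ends are flagged as excluded ("calibration" regions):
frequency still counts events there, but per-cycle amplitudes are only
measured on interior cycles, where the local mean is trustworthy.

Per-cycle extremum values are *not* read as the raw samples at the detected
indices by default. The detected index is the largest of several nearly
equal noisy samples, so the raw readout is biased upward by the expected
maximum of that noise — about +9% relative at 5% noise, which is larger
than the quantity's own acceptance tolerance. The default
`valueMethod = "apex"` instead reads

* peaks from a least-squares parabola over $\pm\max(2, \mathrm{period}/12)$
  samples (suppressing selection bias on the broad diastolic maximum), and
* troughs from a three-point parabolic interpolation (recovering part of a
  sharp contraction nadir that falls between samples at 2.5 frames/s).

`valueMethod = "raw"` restores the literal readout. Percent amplitude
averages the per-cycle ratios by default; `amplitudeMethod = "global"`
instead divides the mean raw peak–trough difference by the window mean (an
alternative normalization some workflows use).

Quiescent convention: no detected peaks means frequency 0, undefined (NA)
amplitude and pumping score 0 — a vessel that does not pump has zero
pumping efficiency, not an undefined one.

**Treatment comparisons** follow the two-window design: an 8-min recording
with the agent applied at $t$ = 2 min is summarized over a 0–2 min baseline
window and a 3–6 min post-treatment window, and every measure is expressed
as percent of its baseline (`analyzeTreatment()`; windows are arguments,
the defaults encode that design). Group statistics across vessels are out
of scope by design: summaries are exported per vessel (with an optional
two-vessels-per-limb averaging convenience in the CLI) for external
statistical software.

## The vessel phantom

Because real recordings come from live animals and are not generally
available, every stage of the pipeline is validated against a synthetic
phantom whose ground truth is known in closed form.

**Waveform.** The default phasic waveform is a powered raised-cosine
constriction train: one dip per cycle whose full width at half maximum is
`pulseDuty` (default 0.3) of the cycle, on a linear diastolic refill ramp
(default 15% of the contraction excursion) whose sawtooth reset is hidden
at the dip centre. The refill matters for testability, not only realism: a
pulse train with a perfectly flat inter-pulse baseline has no well-defined
ground-truth peak time (every plateau sample ties), so peak *location*
recovery could not be scored. A pure sinusoid is retained for closed-form
tests. The `depth` parameter is calibrated so that peak-to-trough excursion
divided by the cycle mean equals `depth` exactly — the same quantity the
percent-amplitude metric estimates. The default start phase (0.75 cycles,
i.e. the record opens mid-diastole) keeps both record boundaries away from
diameter maxima at the canonical durations; an extremum straddling a record
boundary is genuinely undecidable from the samples, and a default that
manufactured one in every run would measure that ambiguity rather than
detector performance. Piecewise-constant tone and frequency multipliers
emulate treatment responses (e.g. a tone step to 0.66 with a 1.6-fold
frequency rise at $t$ = 2 min); phase stays continuous across switches.

**Rendering.** A frame is
$I(x, y) = B + b \cdot \ell(y) \otimes G_\sigma + \varepsilon$, with
background $B$ (default 100), brightness $b$ per µm of tracer path length
(default 10), and the chord path length
$\ell(y) = 2\sqrt{(D/2)^2 - y^2}$ integrated exactly over each pixel row —
so background-subtracted column sums equal $b\,\pi (D/2)^2 / s$ and the
conservation property can be asserted to better than 1%. The Gaussian PSF
(default $\sigma$ = 1 px) is a normalized discrete kernel truncated at
$4\sigma$, hence integral-preserving. Noise is additive Gaussian by
default (EMCCD recordings at short exposures are read-noise dominated, and
additive noise gives direct variance control in tests); a Poisson option
exists. Defaults (d0 = 100 µm, 2 µm/px, 2.5 frames/s, 180 s, 448 × 64 px)
give a vessel-to-background ratio comfortably above the 6-fold regime of
real NIR recordings. 1-D shortcuts (`generateTraces()`) bypass rendering:
the diameter model returns $D(t)$ directly and the fluorescence model
returns $F = \mathrm{offset} + k\,D^2$, the volume-proportional MFI of a
cylinder.

**What the phantom does not emulate** — and hence what passing tests do
not establish about real data: breathing and tissue motion, photobleaching,
scattering through skin, valve structures, multi-lymphangion propagation
waves, vessel curvature, and spatially correlated noise. The tracking
accuracy figures in particular assume a motion-free, straight vessel.

## Numerical choices and edge cases

* Scale-selection ties break toward the smallest $k$ (finest scale).
* Signals shorter than 10 samples are rejected, not padded.
* A signal that is flat after detrending (constant or exact line) has no
  events; an explicit floor keeps floating-point residues from being
  scanned for "maxima".
* Fewer than two peaks: the instantaneous mean falls back to the
  whole-window mean with no edge exclusion.
* Degenerate apex fits (near-zero curvature) fall back to the window mean,
  clamped to the observed extremum.
* All detection and rendering is deterministic given the seed; phantom
  noise uses an isolated RNG state that does not disturb the caller's.
* Pixel coordinates are 1-based (x = column, y = row), matching R's
  matrix indexing; sample indices are 1-based.

The test suite exercises the pipeline at deliberately modest problem sizes
— 180-s traces at 2.5 samples/s, rendered phantoms of 448 × 48 px with up
to 450 frames, 20 noise replicates per condition — chosen so the complete
suite documents the method's behaviour in minutes while still covering the
full frequency (4–12 min$^{-1}$), depth (10–50%) and diameter (10–60 px)
ranges of interest.

## Known limitations

* The ten-pixel profile normalizer is faithful to the original workflow but
  fragile at high noise; prefer `contiguous = TRUE` counting (and, where
  possible, a brighter tracer) on noisy data.
* Frequency counts all detected peaks in the window, including edge-region
  events; with very short windows the boundary rules above still leave a
  one-count uncertainty when an extremum straddles the window edge.
* Amplitude at 2.5 frames/s systematically misses a small part of sharp
  contraction nadirs; the apex readout recovers most but not all of it
  (worst-case bias under 2 percentage points across the tested grid).
* The geometry is user-supplied; `suggestGeometry()` is a starting point
  only and assumes a roughly horizontal vessel.
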