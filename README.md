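# clvtrack

Quantification of collecting lymphatic vessel (CLV) contractility from
near-infrared (NIR) fluorescence time-lapse imaging.

Collecting lymphatic vessels pump lymph through rhythmic smooth-muscle
contractions. When a vessel is perfused with an NIR tracer, a time-lapse
recording carries two readouts of that pumping: the inner diameter of the
lumen, and the mean fluorescence intensity (MFI) of a region of interest
over the vessel, which scales with lumen volume. `clvtrack` implements the
full analysis chain for both:

* **Diameter tracking.** Per frame, a *moving threshold*
  `T = mean(vessel ROI) / mean(background ROI)` is applied to a
  background-normalized intensity profile along a line bisecting the
  vessel; the number of supra-threshold pixels times the µm/pixel scale is
  the inner diameter (`trackDiameter()`, `extractMFITrace()`).
* **Automatic multiscale-based peak detection (AMPD).** A local-maxima
  scalogram over scales `k = 1..⌈N/2⌉−1` is reduced by its row sums
  `γ_k`; the scale `λ = argmin γ` selects the dominant rhythm, and samples
  that are local maxima at every scale up to `λ` are the contraction peaks
  (troughs: same on the negated trace). Deterministic, with documented
  plateau and record-boundary handling (`detectPeaksTroughs()`).
* **Outcome measures.** Contraction frequency `f` (peaks/min), percent
  amplitude `A` (per-cycle peak−trough as % of the instantaneous mean),
  pumping score `f × A`, vessel tone (post/pre mean level, % of baseline),
  plus trace comparison statistics (Pearson r, mean absolute and
  root-mean-square deviation) and baseline-normalized treatment effects
  over the standard 0–2 min / 3–6 min windows (`summarizeTrace()`,
  `analyzeTreatment()`).
* **A synthetic vessel phantom** with closed-form ground truth — a
  tracer-filled cylinder rendered with exact per-pixel chord integrals,
  Gaussian PSF and seeded noise, driven by a calibrated contraction
  waveform — so every stage is testable without animal data
  (`generateMovie()`, `generateTraces()`).

The methods vignette (`vignettes/clvtrack-methods.Rmd`) documents the
models, parameter choices and limitations.

## Worked example

Simulate a 3-minute phantom recording (100 µm vessel, 30% contraction
depth, 6 contractions/min, 2.5 frames/s, 5% noise), track it, and
quantify:

```r
library(clvtrack)

wave   <- contractionParams(d0 = 100, depth = 0.3, frequency = 6)
optics <- phantomOptics(noiseSigma = 50, duration = 180, seed = 42)
movie  <- generateMovie(wave, optics)

geo <- vesselGeometry(center = c(32, 308.3), angle = -90, r = 100, scale = 2)
trk <- trackDiameter(movie$stack, geo, frameRate = 2.5, contiguous = TRUE)
summarizeTrace(trk$trace)
#> ContractilitySummary over [0, 180] s
#>   frequency        6.000 /min
#>   % amplitude     28.173 % of instantaneous mean (n = 16 cycles)
#>   pumping score  169.035
#>   mean level      90.369 (trace units)

pearsonCorrelation(trk$table$diameter_um, movie$truth$true_diameter_um)
#> [1] 0.975424
```

The recovered frequency equals the simulated 6/min exactly; the percent
amplitude (28.2%) sits within two points of the simulated 30% depth (part
of each sharp contraction nadir falls between samples at 2.5 frames/s);
mean level is in µm. The MFI readout of the same movie
(`extractMFITrace()`) yields the same frequency with a larger percent
amplitude — fluorescence tracks lumen *volume*, so its relative excursion
is roughly twice the diameter's.

The same pipeline is scriptable from a shell:

```sh
exec/clvtrack simulate --out sim --duration 180 --freq 6 --depth 0.3 --noise 50 --seed 42
exec/clvtrack track --stack sim/phantom.tif --center-x 32 --center-y 308.3 \
    --normal-deg -90 --r 100 --scale 2 --out trk
exec/clvtrack quantify --trace trk/diameter_trace.csv --out quant
```

For treatment experiments, `quantify --baseline 0,120 --post 180,360`
produces the percent-of-baseline treatment table.

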