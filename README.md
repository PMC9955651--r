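# complexhrv

Nonlinear complexity analysis of heart rate variability (HRV) for
paced-breathing and resonance-breathing studies: fractal dimensions,
heart-rate asymmetry, and permutation entropy, with the preprocessing,
spectral assessment, statistics, and synthetic-data generation a complete
study pipeline needs.

## Who this is for

Researchers analysing RR-interval (RRi), respiration, or electrodermal
recordings from slow-paced-breathing protocols — in particular resonance
breathing assessments, where a participant breathes at several fixed rates
(7, 6.5, 6, 5.5, 5 breaths per minute) and the rate maximising the
low-frequency heart-rate oscillation is selected as their resonance
breathing rate (RBR).

## What it computes

**Fractal dimensions** of a signal's graph, between 1 (smooth) and 2
(plane-filling): Higuchi (−slope of ln L(k) on ln k over delays k = 1..kmax),
Katz and Castiglioni's calibration-free variant
FD = ln n / (ln n + ln(d/L)) with L the total variation and d the maximal
excursion, Petrosian's three binarisation variants
FD = log₁₀N / (log₁₀N + log₁₀(N/(N + 0.4·NΔ))), Sevcik's unit-square length,
box counting over dyadic grids, normalized-length-density (NLD) with
Weierstrass-fitted linear and power-law calibrations, and Maragos'
morphological multiscale profile with its mFD_M summary.

**Heart-rate asymmetry** on the lag-m Poincaré plot (xᵢ, xᵢ₊ₘ): SD1/SD2 and
lagged variants, the deceleration/acceleration variance split obeying
SD1up² + SD1down² = SD1², SDNNup² + SDNNdown² = SDNN² exactly, Ehlers',
Guzik's and Porta's indices, the slope and area indices, the asymmetric
spread index, and the complex correlation measure.

**Permutation entropy** over ordinal patterns of order m and lag τ:
Shannon/Rényi/Tsallis/min-entropy functionals (normalized to [0, 1]),
amplitude-aware and edge-weighted variants, the composite index CPEI, the
Jensen–Shannon statistical complexity, and multiscale forms (mPE, ImPE,
mPM_E) via coarse-graining.

**Around the measures**: detrending, deduplication, shape-preserving
tachogram resampling (4/10 Hz), nested and equal-fifths segmentation,
finegrid interpolation, coloured-noise addition at a target SNR,
normalisation/binarisation, the reverse-arrangement stationarity test,
breath-interval extraction (IN/OUT/peak-to-peak) from respiration waveforms;
Welch/Burg/Lomb–Scargle spectra with LF/HF band metrics; the six-quantity
resonance-breathing scorecard and RBR selection by peak LF power; Friedman +
Kendall's W, Conover all-pairs post-hoc with divide-by-maximum
standardisation and 0.8 top-slicing, consistency ICC(3,1), Mann–Whitney
effect sizes |Z|/√n, direction counts with the 0.795/0.205 consistency rule,
robust CV and Theil–Sen slope, and a four-strategy parameter tuner; plus
generators for fractional Brownian motion, Weierstrass graphs, breathing
pacers, electrodermal activity, and a full synthetic paced-breathing cohort
with respiratory sinus arrhythmia resonance.

## Worked example

Score one synthetic subject whose resonance frequency is 0.1 Hz across the
five paced trials, then characterise the resonant trial:

```r
library(complexhrv)

spec <- cohort_spec(n_subjects = 1, f0 = 0.1, seed = 5)
trials <- lapply(c("5", "5.5", "6", "6.5", "7"), function(l) {
  g <- gen_rri_trial(spec, 1, l)
  list(rri = g$rri, rsp = g$rsp)
})
names(trials) <- c("5", "5.5", "6", "6.5", "7")

sc <- rba_scorecard(trials)
print(sc, digits = 4)
#>   trial LFBP PLFP LF_nu HRMaxMin   phase comfort
#> 1     5 3783 3721 98.69    13.27 104.581      NA
#> 2   5.5 5056 4972 98.58    15.58  53.235      NA
#> 3     6 5659 5573 98.57    16.30 104.353      NA
#> 4   6.5 4025 3852 98.05    13.85  -6.769      NA
#> 5     7 2261 2162 97.79    10.28  73.674      NA
select_rbr(sc)
#> [1] "6"
```

The peak LF power (PLFP, ms²) and the within-cycle heart-rate excursion
(HRMaxMin, bpm) are both largest at 6 breaths per minute — the paced rate
matching the subject's 0.1 Hz resonance — so that trial is selected as the
RBR.

```r
rri <- trials[["6"]]$rri
rri
#> <event_series:RRi> 352 intervals (ms), span 314.4 s, mean 893.2 ms

fd_higuchi(rri$intervals, kmax = 8)$value   # 1.448: between line and noise
cpei(rri$intervals)                         # 0.816: strong RSA lowers PE

lagged_poincare(rri, 1)
#> <poincare m=1> SD1 = 30.587, SD2 = 104.489, SDNN = 76.985, r = 0.842 (351 points)
asymmetry_decomposition(rri)
#> <asymmetry> up/down/on = 176/175/0
#>   SD1 up/down = 21.350/21.842  SD2 up/down = 74.003/73.556
#>   SDNN up/down = 54.462/54.257  C1a = 0.489  C2a = 0.503
```

SD2 ≫ SD1 reflects the slow sinusoidal RSA dominating the plot's long axis,
and the near-equal up/down split (C1a ≈ 0.49, Guzik's index 48.9, Porta's
49.9) is what a time-symmetric generator should produce.

A thin command-line front end is installed at `inst/cli/complexhrv`
(`complexhrv measure|preprocess|rba|synth`); see the header of that script
for invocations.

## The methods vignette

`vignettes/complexity-measures.Rmd` documents the models and their
assumptions, every tunable parameter with units and defaults, the numerical
conventions (tie-breaks, degenerate inputs, calibration ranges), what the
synthetic cohort does and does not emulate, and known limitations.
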