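---
title: "Complexity measures for heart rate variability: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complexity measures for heart rate variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complexhrv)
```

# Scope

This package implements three families of nonlinear descriptors for
physiological interval and waveform series — fractal dimensions (FD),
heart-rate-asymmetry indices (HRA) built on the Poincaré plot, and
permutation-entropy (PE) measures on ordinal patterns — together with the
machinery a paced-breathing heart-rate-variability (HRV) study needs around
them: preprocessing and data-modification operators, frequency-domain
resonance-breathing assessment, a nonparametric repeated-measures statistics
pipeline, and synthetic-data generators that let every stage be exercised
without recordings.

Two data containers carry everything. An `event_series` holds physiologically
timed intervals (RR intervals in ms, breath intervals in s) with event times
reconstructed as cumulative sums; a `uniform_signal` holds an evenly sampled
waveform with its sampling rate. Interval series can be analysed directly in
beat order ("non-resampled") or interpolated onto a uniform grid with
`resample_uniform()`; both routes are deliberately supported, because FD and
PE measures turn out to be usable on beat-ordered data even though equal
sampling is the theoretically clean substrate.

# Fractal dimensions

All FD estimators treat the series as the graph of a function and ask how its
measured "length" or box occupancy scales with resolution; a smooth curve
gives 1, uncorrelated noise approaches 2, and fractional Brownian motion
(fBm) with Hurst exponent H sits at 2 − H.

**Higuchi** (`fd_higuchi`): mean normalized curve length L(k) over the k
phase-shifted subsampled curves, for delays k = 1..kmax; the FD is the
negative slope of ln L(k) on ln k, fitted by ordinary least squares over all
k. The default kmax = 8 sits inside the 2–15 range commonly swept for
RR-interval data; `kmax` is the main tunable and is exposed to the parameter
tuner. The fit's R² is returned as a diagnostic.

**Katz** (`fd_katz`) embeds the series as a planar curve with unit abscissa
steps. Its value depends on the amplitude/time calibration, which is exactly
the flaw the **Castiglioni** variant (`fd_castiglioni`) removes: it evaluates
Katz's formula on amplitudes alone — L is the total variation, d the maximum
excursion from the first sample — so the d/L ratio is dimensionless and the
index is invariant under any rescaling of the recording. Two properties are
worth knowing: a constant series is a flat line and scores exactly 1, and on
uncorrelated noise the index saturates *above* 2 (total variation vastly
exceeds excursion); it is a roughness index monotone in dimension, not an
estimator confined to [1, 2]. We chose the amplitude-only realization over a
"per-sample-unit abscissa" normalization after observing that the latter
makes fBm(H = 0.5) and white noise statistically indistinguishable (their
normalized steps share one distribution), defeating the purpose of the index.

**Petrosian** (`fd_petrosian`) counts changes NΔ in a binarized copy of the
series — variant a thresholds at the mean, b takes signs of successive
differences, c flags large differences — and applies
FD = log₁₀N / (log₁₀N + log₁₀(N/(N + 0.4·NΔ))). The three binarisations are
also exposed directly through `transform_amplitude()`.

**Sevcik** (`fd_sevcik`) maps the curve into the unit square and uses the
normalized length; it tends to 1 as N grows for any fixed smooth curve, so
values are only comparable at a fixed length.

**Box counting** (`fd_boxcount`) embeds the graph in the unit square and
counts occupied boxes on dyadic grids with between 4 and N/4 boxes per side
(the `mvdl` variant fits only the middle half of those scales). A box column
is counted from the column's minimum to its maximum occupied cell *including
the carry-over from the previous column's last sample*, so the count respects
the continuity of the curve; without the carry-over the fine scales
undercount and the slope is biased low. The choice of scaling region matters
for any box counter, which is why both fit windows are exposed.

**Normalized length density** (`fd_nld`): the mean absolute successive
difference of the min–max-normalized series (NLD), mapped to an FD through a
calibration fitted on Weierstrass graphs of known dimension at the exact
length analysed (`nld_calibration()`, cached per length). Two maps are
provided, both anchored at NLD = 0 → FD = 1: a linear map fitted over — and
only valid for — the low-dimension range (FD ≲ 1.5; it overestimates
beyond), and a power law fitted by direct least squares in dimension space
across D = 1.1..1.9. The rigid power-law family still carries a residual
bias of up to ±0.1 at the extremes of that range; held-out Weierstrass
validation at D = 1.5 lands within ±0.1 for both maps. The `w` variants
(`wL`, `wP`) evaluate per non-overlapping window and report the mean; the `i`
variants use the whole series.

**Maragos morphological FD** (`fd_maragos`): cover areas A(s) from dilation
and erosion with a flat structuring element of half-width s samples; the
local dimension over a sliding window of log-scales is the slope of
ln(A(s)/s²) on ln(1/s), and `mFD_M` reduces the profile (mean by default;
median and max are options, since the single-number reduction is a
convention, not a definition). The default scale set is log-spaced from
half-width 3 to 45: half-widths 1–2 are dominated by discrete-range bias —
on fBm of known dimension they drag the summary visibly below 2 − H — so
the fit starts at 3. For short RR series pass a smaller set
(e.g. `scales = c(3, 4, 6, 8, 11, 16)`).

# Heart-rate asymmetry

The lag-m Poincaré plot scatters (xᵢ, xᵢ₊ₘ). `lagged_poincare()` returns SD1
and SD2 — the sample standard deviations across and along the line of
identity (LI) — with SDNN defined through SDNN² = (SD1² + SD2²)/2, for lags
1..7.

Throughout, **"up" means above the LI**, i.e. decelerations (RR lengthening).
Some of the literature writes the same quantities with an "a/d" notation and
the opposite pairing; the naming here follows the SD1up/SDNNup usage.

`asymmetry_decomposition()` splits the variance into up/down parts with the
conventions that make the conservation identities *exact* rather than
approximate: SD1 components use second moments about zero (not about the
mean), on-LI points are excluded from the SD1 split (their transverse
distance is zero) and given half weight to each side in the SD2 split. Then
SD1up² + SD1down² = SD1₀², SD2up² + SD2down² = SD2₀²,
SDNNup² + SDNNdown² = SDNN₀², and the contributions C1a + C1d = C2a + C2d = 1
hold to machine precision, which the test suite checks on hundreds of random
series. How on-LI points are shared between the SD2 halves is a genuine
convention choice; half-weighting is the one that preserves the identity.

The classical indices are `classical_indices()` (Ehlers' ΣΔ³/(ΣΔ²)^{3/2};
Guzik's percentage of squared transverse distance above the LI; Porta's
percentage of points below it), `karmakar_indices()` (slope index on angular
deviations from the LI, area index on circular-sector areas),
`asymmetric_spread_index()` (RMS transverse spread above vs below, as a
percentage — 50 for mirror-symmetric clouds, reversal-antisymmetric, and
strictly increasing in the deceleration spread; the exact formula is our
documented realization of a paywalled definition, and the tested surface is
this contract), and `ccm()` (mean absolute triangle area through consecutive
plot points, normalized by π·SD1·SD2 — zero for collinear plots).

Asymmetry is a beat-ordering property; computing it on an interpolated
tachogram mixes interpolation artefacts into the up/down split, so passing a
`uniform_signal` to these functions warns.

# Permutation entropy

`ordinal_patterns()` maps every delay window of order m and lag τ to the
permutation sorting its values (defaults m = 3, τ = 1; natural logarithms
throughout). Ties are broken by original position by default — the common
toolbox convention — with an explicit tie-patterns policy (one pooled tie
slot) used by the composite index. `entropy_functional()` provides Shannon,
Rényi (α, default 2), Tsallis (q, default 2) and min-entropy forms, each
normalized to [0, 1] by its maximum over m! states; the Rényi/Tsallis orders
are exposed rather than fixed since no single convention dominates.

The amplitude-aware variant `aape()` weights each window by
A·mean|values| + (1−A)·mean|increments| on the z-scored series;
`edge_pe()` weights by the window's total edge magnitude. Both reduce to
plain PE when weights are equal, and both deliberately lose the monotone-
transform invariance that plain PE has (the tests check the invariance and
its deliberate absence). `cpei()` pools order-3 counts at lags 1 and 2 —
pooled by summation — with near-equal samples (within `tie_threshold`)
diverted to the tie slot. `pjsc()` multiplies normalized Shannon PE by the
normalized Jensen–Shannon divergence from the uniform pattern distribution,
with the divergence maximum computed exactly from a point mass.
`multiscale_pe()` coarse-grains by non-overlapping block means; `ImPE`
averages the ordinal distributions over all graining offsets before taking
one entropy; `mPM_E` applies min-entropy per scale.

# Spectra and the resonance-breathing scorecard

`psd_estimate()` provides Welch (Hann taper, 150 s segments, 50% overlap)
and Burg (order 16) one-sided densities in ms²/Hz. Welch segments are
zero-padded to at least four times their length: without padding, the
±0.5 bin scalloping loss of the Hann window (up to ~1.4 dB) dwarfs the few-
percent power differences the resonance assessment must resolve between
adjacent breathing rates. `lomb_psd()` evaluates the classic phase-shifted
Lomb–Scargle periodogram on the raw beat times — no resampling — scaled so
that it matches the classic periodogram on an even grid; its resolution
bandwidth is 1/T (the frequency grid is 4-fold oversampled).

`band_metrics()` integrates the density over a band (LF 0.04–0.15 Hz,
HF 0.15–0.40 Hz by default, both configurable), reports the peak frequency,
converts peak density to peak power (ms²) via the spectrum's equivalent
noise bandwidth, and expresses band power in normalized units of LF + HF.
`rba_scorecard()` assembles, per trial, the six-quantity assessment — LF
band power, peak LF power (PLFP), LF in normalized units, HRMaxMin (mean
within-cycle heart-rate excursion), the cross-spectral phase of heart rate
against respiration (positive when HR lags), and an optional comfort rating —
and `select_rbr()` picks the resonance breathing rate as the paced trial
with the highest PLFP, breaking exact ties toward the slower rate (the
clinical tie-breaking protocol requires judgement and is out of scope; the
scorecard reports the conflicting quantities instead).

The scorecard's default spectral route is the Lomb periodogram on the
beat-ordered intervals. The reason is measurable: shape-preserving
interpolation of the tachogram attenuates the respiratory-sinus-arrhythmia
sinusoid more at faster breathing rates, because the beat rate undersamples
it, and that systematic attenuation biases the PLFP argmax toward the slower
neighbouring rate. The Lomb estimate needs no interpolation and has no such
bias; Welch and Burg remain available for comparison.

# Nonparametric statistics

`friedman_kendall()` wraps the tie-corrected Friedman chi-square (k − 1 df)
and reports Kendall's W = χ²/(N(k−1)) as the effect size (0.1 small,
0.3 medium, above 0.5 strong); a fully tied table returns χ² = 0, W = 0.
`conover_posthoc()` implements the all-pairs comparison after Friedman with
S = |Rᵢ − Rⱼ| / √(2N(A1 − B1)/((N−1)(k−1))) on (N−1)(k−1) degrees of
freedom, Bonferroni-adjusted; perfectly concordant rankings have zero
residual rank variance and S is rightly infinite there. `standardized_S`
divides by the maximum over the reported set, and `standardize_topslice()`
applies the same divide-by-maximum rule with a retention threshold
(default 0.8) to any statistic set. `icc_consistency()` is the two-way
mixed, single-measures, consistency form ICC(3,1) — invariant to fixed
column offsets. `mannwhitney_es()` reports |Z|/√n with midranks and tie
correction, no continuity correction. `direction_counts()` applies the
0.795/0.205 consistency proportions (at n = 44: 35 or more increases, or 9
or fewer). `robust_descriptors()` gives the MAD-based robust CV and the
Theil–Sen slope against sample index — exact over all pairs, with inputs
beyond 2000 samples thinned evenly first (the intended inputs are short
per-recording series; the cap only touches raw 32 Hz waveforms).

`tune_parameter()` scores a swept parameter grid with four group strategies —
greatest pooled robust CV, greatest absolute difference of group medians,
greatest absolute median of paired differences, and most per-participant
maximal-difference wins — and takes the modal selection as consensus. An
unresolved mode falls back to the strategy whose increase/decrease ratio is
farthest from 1.0 (measured as |log ratio|, which treats 4:1 and 1:4
symmetrically), and reports `"ambiguous"` only if that still cannot
discriminate. All tie-breaks are deterministic in grid order.

# Synthetic data: what it emulates and what it does not

`gen_fbm()` synthesizes exact fractional Gaussian noise by circulant
embedding and cumulates it; `gen_weierstrass()` sums γ^((D−2)k) cosines with
seeded phases. These are the FD calibration targets: graph dimension 2 − H
and D respectively.

The cohort generator reproduces the design of a paced-breathing study:
44 subjects, seven trials of 5 min 15 s (Baseline at 12–16 BrPM, self-paced
near 6 BrPM, and external pacing at 7, 6.5, 6, 5.5, 5 BrPM with a 40/60
inhalation/exhalation pacer, `gen_pacer()`). Respiratory sinus arrhythmia is
modelled as a second-order resonance: the RR modulation amplitude is
A(f_b) = G/√((1 − (f_b/f0)²)² + (f_b/(Q·f0))²), peaking at the subject's
resonance frequency f0 (drawn on the paced-rate grid), with quality Q = 3 —
a moderate resonance, standing in for the baroreflex loop without modelling
it — and gain G = 35 ms, chosen so the within-cycle heart-rate excursion at
resonance is ≈ 15 bpm, mid-range of what slow-breathing assessments report.
Beat times follow integrate-and-fire on RR(t) = RR₀ + A·sin(2πf_b t + φ) +
1/f noise (sd 15 ms, a realistic low-frequency HRV background). `gen_eda()`
adds a tonic exponential decay, Poisson-arriving phasic responses and white
noise at 32 Hz.

What passing tests on this cohort do show: the full chain — generation,
resampling, spectra, measure computation, Friedman/Conover — is wired
correctly, recovers known effect directions, and identifies the generating
resonance rate in about 92% of subjects under these conditions. What they do
not show: performance on real recordings with ectopic beats, movement
artefacts, non-stationary breathing, or RSA that is not a clean sinusoidal
modulation; artefact correction is explicitly out of scope (recordings are
assumed cleaned upstream). Note also that with Q = 3 the resonance curve is
flat on its low side — the amplitude difference between the resonant rate
and its slower neighbour is a few percent, comparable to the in-band 1/f
noise over a 315 s record — so per-subject recovery is intrinsically capped
near 92%, and recovery rates should be read over pooled cohorts, where the
binomial noise of a single 44-subject draw (~4%) averages out.

# Numerical choices and degenerate inputs

Times are 0-based seconds with half-open segment convention [start, end).
Interval files are unitless; the declared kind fixes the units. Monotone
(shape-preserving) piecewise-cubic interpolation guarantees the resampled
tachogram never overshoots the input range. Constant inputs error in
operations whose normalization degenerates (z-score, min–max, Sevcik, NLD)
and return flagged undefined values where the estimator itself degenerates
(Higuchi on a constant, CCM with SD1·SD2 = 0). Breathing extrema are located
on a 1 s moving-average-smoothed copy with a 2 s minimum separation
(breathing rates of interest are ≤ 30 BrPM) and a prominence floor of 20% of
the range, then refined on the raw waveform within half a smoothing window —
the refinement matters because smoothing shifts the extrema of asymmetric
breathing cycles. The reverse-arrangement stationarity test uses the exact
count statistic with its normal approximation, two-sided at α = 0.05 by
default.

Problem sizes used by the test suite and the acceptance script — fBm and
noise calibrations at n = 10⁴ over 20 seeds, PE calibration at n = 2¹⁴,
2000 Friedman null simulations at 44 × 7, and resonance recovery pooled over
ten 44-subject cohorts — were chosen as the smallest designs at which the
quantities under test are stable to well within their stated tolerances.

# Known limitations

The NLD calibration transfers between signal families only approximately
(its constants are texture-dependent; values on noise-like signals
extrapolate beyond the fitted range and can exceed 2). The Castiglioni index
saturates above 2 on uncorrelated noise. Kendall's W is reported from the
tie-corrected χ², so tables with heavy ties can print W slightly different
from untied-formula expectations. The Burg spectrum degenerates on noiseless
deterministic tones (the prediction variance collapses); it is intended for
stochastic tachograms. The clinical resonance-rate tie-breaking protocol is
reported, not automated.
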