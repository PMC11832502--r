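---
title: "Entropy and complexity features for channel-wise EEG group comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy and complexity features for channel-wise EEG group comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`eegcomplexity` implements a channel-wise quantitative analysis of
resting-state EEG for two-group studies. For every channel of every
participant it computes eight scalar features — brain rate, spectral
entropy, permutation entropy, sample entropy, Rényi entropy, Tsallis
entropy, Higuchi fractal dimension and Lempel–Ziv (LZ76) complexity — and
compares the two groups channel by channel with two nonparametric tests
under a Bonferroni-corrected significance level. Because no real cohort is
bundled, the package ships a synthetic two-group generator whose structure
mirrors the contrasts such studies report; every stage of the pipeline is
exercised end-to-end against it.

## Segment selection

Time-domain features require an uninterrupted artifact-free stretch of
signal. Artifact marking is accepted as a per-sample boolean mask (visual
review cannot be codified; the mask is the interface). `longest_clean_run()`
returns the maximal run of clean samples, ties broken by earliest start, and
`trim_to_common_length()` cuts all participants to the cohort-wide minimum
so every participant contributes a window of identical duration. Windows are
addressed 0-based and half-open, `[start, start + n)`. At 250 Hz a 43 s
common window is 10,750 samples per channel, 204,250 values over a
19-channel montage.

Acquisition-chain filtering (0.53 Hz high-pass, 50 Hz low-pass, 45–55 Hz
notch) is available behind a flag but off by default: the synthetic
generator produces band-limited signals, and re-filtering them would only
color the comparison. Filters are zero-phase Butterworth, with the channel
mean removed and 2 s of reflective padding so the forward–backward pass does
not leak edge transients; the low-pass stage is 8th-order because a 4th-order
roll-off from 50 Hz leaves a 60 Hz component at ~11% RMS, which defeats the
purpose of a recording-chain emulation.

## Spectral features

The PSD is a Welch average of mean-detrended, Hann-tapered 2 s windows with
50% overlap (0.5 Hz resolution at 250 Hz). Welch rather than one long
periodogram because a 43 s single-shot FFT has per-bin variance equal to the
squared spectrum itself; averaging ~42 windows stabilizes the band ratios
the features feed on. Window length and overlap are exposed in
`feature_params()`.

Five classical bands are used: delta 0.5–4, theta 4–8, alpha 8–12, SMR
12–15, beta 15–20 Hz, half-open `[lo, hi)` so shared edges are unambiguous.
Relative band power divides each band's power by the total over the five
bands. Brain rate is the power-weighted mean of the band representative
frequencies, taken as band midpoints (2.25, 6, 10, 13.5, 17.5 Hz); it is a
coarse arousal index — the heavier the low-frequency bands, the lower the
value. Spectral entropy is the Shannon entropy (natural log, reported
un-normalized in nats) of the PSD normalized over 0.5–20 Hz, the range the
band analysis covers. The hz-by-hz spectrum aggregates PSD bins into 1 Hz
bins `[k, k+1)` and normalizes, which shows narrow features (an alpha peak
at 10–11 Hz) that whole-band averages wash out.

## Time-domain features

*Permutation entropy* (embedding `D = 3`, delay `tau = 1`) is the Shannon
entropy of the ordinal-pattern distribution, in nats, bounded by `log(D!)`.
Ties inside a window are broken by order of appearance (stable sort); EEG
amplitudes rarely tie, but the rule must be fixed for bit-reproducibility.

*Sample entropy* (`m = 2`, tolerance `r = 0.2` of the per-channel segment
SD) uses Chebyshev distance with strict matches and self-match exclusion;
template starts are restricted so every length-`m` template has a
length-`m+1` extension. A constant series returns 0 by convention; if no
templates match at all the value is undefined and an error is raised rather
than a silent sentinel.

*Rényi entropy* (order `alpha = 2`) is the differential collision entropy of
the amplitude distribution: a Gaussian-kernel density estimate (Silverman
bandwidth, 1,024-point grid padded three bandwidths past the data range),
integrated by trapezoid. Being differential it can be negative for sharply
concentrated amplitude distributions and shifts by `log(c)` under amplitude
scaling by `c` — which is precisely why it responds to group differences in
amplitude variance.

*Tsallis entropy* (`q = 1.5`) is computed on a 100-bin equal-width amplitude
histogram. For `q > 1` it saturates at `1/(q-1) = 2` as the histogram
flattens over many occupied bins, so its dynamic range near the ceiling
depends on the bin count; 100 bins keeps the saturation behaviour visible
without making the estimate noisy, and the count is exposed in
`feature_params()`.

*Higuchi fractal dimension* (`k_max = 10`) follows the canonical
offset-averaged curve-length algorithm with the standard normalization
`(N-1)/(floor((N-m)/k) k)` and a least-squares fit of `log L(k)` on
`log(1/k)`. The one-line `log(L/k)/log(k)` formulation is not computable as
written; the canonical algorithm is what the field's implementations use.

*LZ76 complexity* binarizes at the signal mean (strictly above → 1, ties →
0) and counts words in the exhaustive-history left-to-right parse, trailing
incomplete word included. This variant reproduces the standard worked count
of 6 for `011001011110`. A length-normalized variant
`c(n) log2(n) / n` is reported alongside the raw count for cross-length
comparability.

All logs are natural except the LZC normalization (base 2, as conventional
for binary sequences). Every estimator is deterministic; the test suite
checks each against an independent brute-force oracle (naive pattern
counting, O(n²) template loops, literal substring parsing, plain-loop
integration) on at least 100 random inputs.

## Group statistics

Normality is screened per feature with Shapiro–Wilk and a Lilliefors-
corrected one-sample Kolmogorov–Smirnov test (parameters estimated from the
sample); the feature distributions involved are generally non-normal, which
motivates nonparametric group tests. Each (feature, channel) cell is
compared with the two-sample Kolmogorov–Smirnov test and the Mann–Whitney U
test, two-sided; the U test is exact when both groups have at most 20
observations and no ties, and otherwise uses the normal approximation with
continuity and tie correction. A cell is flagged significant only when
*both* p-values fall below the Bonferroni-corrected level — the correction
divides the 0.05 level by the number of channels (19 → 0.0026), treating the
channels of one feature as the hypothesis family, not all 152 tests.
Group-mean 95% t-intervals are exported for error-bar plots; these are
confidence intervals of the mean, not prediction intervals — the narrower,
conventional choice for such plots.

## The synthetic cohort

`generate_cohort()` builds 39 "TD" and 49 "ASD" participants, 19 channels
(10/20 montage) at 250 Hz, 43 s each — the cohort geometry the analysis is
designed around. Each channel is composed of three parts:

* **Background**: Gaussian noise spectrally shaped to `1/f^beta` inside
  0.5–50 Hz. Outside that band the shaping gain plateaus (the frequency is
  clamped to the band edges) rather than being cut to zero: a strict
  band-limit at 50 Hz would leave even `beta = 0` noise strongly
  autocorrelated at 250 Hz, whereas the clamped design reduces exactly to
  white noise at `beta = 0`. DC is removed and the output standardized.
* **Alpha component**: a 10.5 Hz carrier under slow random amplitude and
  phase modulation (two spline-interpolated Gaussian quadrature envelopes,
  ~1 Hz bandwidth). The envelope is raised to a burstiness exponent
  (default 2), giving spindle-like waxing and waning separated by
  near-silent stretches, which is how resting alpha actually behaves; a
  constant-amplitude sinusoid would make the signal's threshold crossings
  metronomic and its amplitude histogram arcsine-flat, both unrealistic.
* **Spike-wave train** (ASD parameterization only): epileptiform
  spike–slow-wave complexes — a sharp ~70 ms biphasic spike followed by a
  rounded ~400 ms wave of opposite polarity — at quasi-periodic times
  (period jittered ±10%, per-complex amplitude ±15%).

Group parameter defaults: TD `beta = 1.0`, alpha gain 3.0 (RMS relative to
background SD), amplitude scale 1.0; ASD `beta = 1.6`, alpha gain 0.3,
amplitude scale 1.8, spike rate 2/s, spike amplitude 4 background SDs. The
channel signal is standardized and scaled so its SD is `amplitude_scale ×
20 µV` — the scale parameter is an SD multiplier, so the ASD group has
larger amplitude variance by construction. Per-participant gains and scales
vary uniformly by ±15% and per-channel alpha gain by ±10%, giving
within-group and across-channel variance. A single integer seed drives
arithmetically derived per-participant, per-channel substreams, so cohorts
are bit-reproducible and independent of generation order.

These choices make the generated contrasts behave like the contrasts
two-group resting-state studies report, for mechanistic reasons:

* TD's alpha peak pulls the power-weighted mean frequency up → higher brain
  rate.
* ASD's larger SD shifts the differential Rényi entropy up by about
  `log(1.8)`, reinforced by TD's bursty (heavy-tailed, hence more
  concentrated) amplitude distribution.
* TD's bursty alpha concentrates the amplitude histogram (high kurtosis →
  few heavily-occupied bins plus wide tails), pushing Tsallis entropy well
  below the near-ceiling values of the flatter ASD histogram — the ASD
  group sits close to the `q = 1.5` saturation value of 2 with little
  between-subject variability.
* ASD's regular spike-wave alternation dominates its mean-threshold
  crossings, so the binarized sequence is repetitive → low LZ76 count;
  TD's crossings are driven by broadband noise and fading alpha → high
  count.

What the generator does **not** emulate: volume-conduction correlation
between channels (channels are independent), topographic structure, eye or
movement artifacts, age effects, nonstationarity beyond the alpha envelope,
and any genuine neurophysiology. Passing the pipeline's direction-recovery
checks on this cohort therefore demonstrates that the estimators and the
statistical battery respond correctly to the engineered signal structure —
it says nothing about discriminating real clinical recordings.

## Numerical choices and degenerate inputs

* Welch PSD requires at least one full 2 s window; shorter input errors.
* `spectral_entropy` treats `0 log 0` as 0 and errors on an empty band.
* `sample_entropy` returns 0 for constant input, errors when `B = 0`, and
  returns `Inf` with a warning when `A = 0 < B`.
* `amplitude_histogram` puts a constant series entirely in one bin.
* KDE grids span the data range ±3 bandwidths; the Rényi integral uses the
  trapezoid rule on that grid.
* The Higuchi slope is an ordinary least-squares fit over `k = 1..10`.
* The EDF writer quantizes to 16 bits over each channel's padded range and
  requires whole-second recordings (1 s records); the delimited-text format
  is lossless at double precision and is the fixture format of choice.

## Problem sizes used by the test suite

The direction-recovery check runs the full default cohort (88 participants
× 19 channels × 43 s, seed 0). The null calibration — identical group
parameters, so every flag is a false positive — runs 20 seeds at full group
sizes but 10 s segments: the type-I behaviour of the channel-wise tests
depends on the number of participants, not on segment length, and the
shorter segments keep the 20-cohort experiment proportionate. Two
properties of the joint-flag rule are worth knowing when reading these
counts. First, the KS and Mann–Whitney p-values computed on the same data
are strongly correlated, so requiring both below the corrected level does
*not* square the false-positive rate; it roughly halves it relative to a
single test. Second, features computed from the same channel segment are
themselves correlated, so the rare null flags tend to arrive in clusters on
a single chance-aberrant channel rather than independently. Expect a
handful of joint flags per few thousand null tests, not zero. Estimator
oracle checks use at least 100 random series of length up to 500 each.
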