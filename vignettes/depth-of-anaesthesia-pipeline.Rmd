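---
title: "Classifying depth of anaesthesia from single-channel EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying depth of anaesthesia from single-channel EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anesdepth)
```

## The problem

General anaesthetics induce a regulated loss of consciousness whose
depth must be monitored continuously: too light risks intra-operative
awareness, too deep prolongs recovery and is associated with cognitive
side effects. The bispectral index (BIS) is the most widely used
EEG-derived depth-of-anaesthesia (DoA) monitor — a proprietary 0–100
score, 100 fully awake, 0 iso-electric — but its internals are not
public and its tracking degrades under some anaesthetic agents.

`anesdepth` implements a patient-specific alternative: classify short
windows of single-channel frontal EEG (128 Hz, microvolts) into four
discrete consciousness states defined by BIS bins —

| state       | BIS bin   | typical EEG character                     |
|-------------|-----------|-------------------------------------------|
| AWAKE       | [80, 100] | low-amplitude, fast (beta-dominated)       |
| SEMI_AWAKE  | [60, 80)  | growing theta/alpha, moderate amplitude    |
| OPERATIVE   | [40, 60)  | high-amplitude slow delta plus alpha       |
| VERY_LOW    | [0, 40)   | burst suppression                          |

— using a BIS-like trace (one value per 5 s) only as the ground-truth
label. Bins are half-open with 100 included in AWAKE, which makes the
labelling total and deterministic; each BIS value labels the 5 s of
signal that precede it.

The windowing protocol takes the first 20,000 samples of each class
from a session and cuts them into four non-overlapping 5000-sample
(~39 s) windows, giving 16 labelled windows per subject. Models are
fitted per subject — the premise being that neural circuitry, and hence
the EEG signature of sedation depth, varies enough across individuals
that a personalised classifier is the better fit.

## The four processing routes

Each route turns a window into a fixed-length feature vector for a
linear discriminant classifier.

**RAW.** The untouched window feeds the handcrafted feature set (17
features, below). This is the baseline that treats sedation information
as spread across the whole broadband signal.

**NA-MEMD.** Noise-assisted multivariate empirical mode decomposition:
the window is stacked with three independent white-noise channels of
matching standard deviation (noise intensity 1) into a 4-channel
multivariate signal, decomposed by joint sifting with 8 projection
directions (twice the channel count) and the three-parameter stop
vector (0.075, 0.75, 0.075). The noise channels impose a quasi-dyadic
filter-bank structure that aligns modes and mitigates mode mixing. Only
the signal channel's modes are kept; modes 2 and 3 — empirically the
informative mid-frequency band for sedation — feed the handcrafted
features per mode (34 values).

Implementation choices the method leaves open: projection directions
are Hammersley low-discrepancy points mapped to the unit hypersphere
via the inverse-normal transform and normalisation; envelopes are cubic
splines through the multichannel samples at each projection's extrema,
with up to two extrema mirrored beyond each end; extrema are strict
(both neighbours smaller/larger); sifting is capped at 100 iterations
per mode to guarantee termination. The stop vector is interpreted as
the standard three-parameter (sd, sd2, tol) envelope-amplitude
criterion, the common reading of a three-element tolerance. Sifting of
mode *k* never depends on later modes, so pipeline stages that only
consume modes up to an index *k* cap the decomposition there; the
retained modes are identical.

**LSDL.** The linear series decomposition learner separates a window
into amplitude bands with dyadically iterated thresholds anchored at
half the absolute maximum: upper thresholds halve the gap to the
maximum each iteration (`T_up_k = (max + T_up_{k-1})/2`), lower
thresholds halve toward zero (`T_lo_k = T_lo_{k-1}/2`); four iterations
by default. Each band is the time-ordered subsequence of samples at or
beyond its threshold (gaps closed up). A learning pass scores every
candidate iteration with a performance index over the whole training
set and selects one upper and one lower band; features are then
extracted from the two selected bands of each window (34 values).

The performance index here is a Fisher-style separability score — the
between-class variance of per-class feature means over the mean
within-class variance, averaged over features — chosen because it is
classifier-free, cheap, and invariant to a common rescaling of all
windows. The scorer is pluggable and its sense (maximise/minimise)
configurable. Ties resolve to the earliest iteration. An optional
peak-identification mode restricts band membership to local extrema of
the rectified signal; it is off by default.

One practical wrinkle: on burst-suppression windows a single extreme
peak can push the upper thresholds so high that almost no samples
qualify, leaving fewer than the 100 samples the nonlinear features
need. Under the default `"pad"` policy a short band is extended with
the next samples in amplitude rank (largest first for upper bands,
smallest first for lower) until the floor is met — keeping "the
highest-amplitude content of the window" semantics while making every
iteration scoreable; an `"error"` policy is available where silent
augmentation is unacceptable.

**DWS.** A two-layer Gabor wavelet scattering transform: zero order is
the signal averaged by a low-pass at the 1 s invariance scale; first
order is the wavelet modulus re-averaged (8 wavelets per octave);
second order re-analyses each first-order envelope with a 1
wavelet-per-octave bank along frequency-decreasing paths. Filters are
Gaussian bumps on the FFT grid, normalised so the Littlewood–Paley sum
is bounded by 1, which makes the transform non-expansive. Coefficients
are critically subsampled at the invariance scale and each path is
time-averaged to one number (166 paths plus the zero-order mean at
128 Hz and 5000 samples), in stable lexicographic path order. Raw
(not log) coefficients are used. Two layers suffice because virtually
all energy resides in orders 0–2; the tests verify ≥95% against a
three-layer computation.

## Handcrafted features

Seventeen features per series, in fixed order: mean absolute value,
waveform length, thresholded zero crossings, RMS, the four Burg AR(4)
coefficients, thresholded peak count, simple squared integral,
variance; maximum real-cepstrum coefficient (zeroth quefrency
excluded — it is a trivial energy proxy) and periodogram median
frequency; sample entropy, maximum fractal length
(`log10` RMS first-difference energy), Higuchi fractal dimension, and
the DFA scaling exponent.

Parameters and conventions: 1 uV is the threshold wherever one is
needed (zero crossings count sign changes only when both neighbours
exceed it; peaks are strict local maxima above it). "4th-order
autoregressive coefficient" is read as all four AR(4) coefficients,
the standard usage in the biosignal feature literature. Sample entropy
uses template length m = 2, tolerance r = 0.2 × SD of the analysed
series (the universal SampEn convention, rather than 0.2 uV absolute),
Chebyshev distance, self-matches excluded; when no template match
extends, the value is undefined and is capped at `log(B) + log(2)`
with a warning so no window is silently dropped. Higuchi uses delays
k = 1..10. DFA integrates the centred series, detrends order-1 over
log-spaced boxes from 4 to N/4, and reports the log–log slope: 0.5 for
white noise, 1.5 for its cumulative sum — both verified against a
brute-force fluctuation computation in the tests.

## The classifier

A pooled-covariance linear discriminant:
`D_c(x) = mu_c' S^-1 x − (1/2) mu_c' S^-1 mu_c + log pi_c`, with
features standardised by training-set statistics, uniform priors (the
protocol is class-balanced), and argmax prediction with ties to the
earlier class. Validation is a single stratified 10-fold
cross-validation; standardisation and fitting happen inside each
training fold.

The consequential numerical choice: with 16 windows and 17–34 features
the pooled covariance is rank-deficient, so it is shrunk toward its
diagonal, `S ← (1−λ)S + λ diag(S)`, λ = 1e-3 by default. This is the
smallest intervention that makes the discriminant well-defined at this
sample size; it leaves well-conditioned problems essentially untouched
(the tests verify ≥99% agreement with an explicit shared-covariance
Bayes rule on a well-posed problem with λ = 0). How the original
protocol inverted the singular pooled covariance is unknowable from
the outside; shrinkage is this package's documented answer.

## The synthetic session generator

Clinical recordings cannot ship with the package, so `simulate_session`
generates sedation sessions with the statistical structure the
pipeline assumes: per-state band-limited Gaussian noise (white noise
shaped by raised-cosine-edged band masks in the frequency domain —
filtering rather than sinusoid sums, so the nonlinear features are
non-degenerate), with amplitude rising and median frequency falling as
depth increases, and a two-state renewal burst-suppression process for
the deepest state (gamma-distributed dwell times, shape 4; 6
cycles/min; suppressed fraction 0.5; a 1.5 uV RMS noise floor under
suppression; burst edges softened over ~60 ms). The BIS-like trace
draws one value per 5 s uniformly within the active state's bin, so
binning the trace recovers the generating state exactly. Everything is
a pure function of its seed; sessions derive per-segment child seeds
from a master seed.

The default spectra are engineering choices, not clinical claims: no
quantitative per-state amplitudes are established for this protocol,
so values were picked once to reproduce the qualitative
neurophysiology (beta-dominated 10 uV awake; theta/alpha 20 uV
semi-awake; delta-dominated 40 uV operative; 45 uV bursts). What the
generator deliberately does not emulate: EMG/ocular artifacts,
electrode drift, pharmacokinetic dynamics, gradual state transitions,
or inter-subject variability in spectral signatures beyond the seed.
Consequently the synthetic four-state problem is much more separable
than clinical data — cross-validated accuracies near 100% on synthetic
subjects demonstrate that the pipeline recovers the structure the
generator put in, not that any route attains clinical-grade accuracy.
Relative route behaviour on clinical recordings (e.g., whether
decomposition helps or hurts) cannot be inferred from these tests
either.

## Problem sizes and numerical conventions

The package's own test and benchmark scale: 10 synthetic subjects at
the full protocol (4 × 160 s per subject, 16 windows of 5000 samples)
for the analysis-level checks, with module-level tests on shorter
windows (640–2560 samples). Reconstruction of NA-MEMD is exact to
~1e-15 relative (a telescoping identity of sifting; asserted at 1e-8).
Degenerate inputs are rejected loudly: empty state sequences, BIS
values outside [0, 100], windows too short for a feature's minimum
length (100 samples for the nonlinear features), constant series where
a spectrum or AR fit is undefined, and per-state sample shortfalls in
the windowing, which are reported naming the state.

## Interfaces and limitations

Records read and write as plain CSV (`time_s, eeg_uv` plus a
`*.bis.csv` companion with `time_s, bis`); signal values round-trip
within 1e-6 uV. EDF export is not provided in this version. The
benchmark report mirrors the structure of a method-comparison study —
per-subject accuracy, mean ± SD, joint-best rank counts (ties credit
every tied route), and per-stage wall-clock timing — but timing is
reported only, never asserted, being hardware-dependent. A ResNet-style
deep-feature route is out of scope.

```{r example, eval = FALSE}
rec <- simulate_session(c("AWAKE", "SEMI_AWAKE", "OPERATIVE", "VERY_LOW"),
                        durations = 160, seed = 1, subject_id = "demo")
split <- extract_class_windows(rec)      # 16 windows, 4 per class
run_route("RAW", split, seed = 1)        # features + 10-fold CV
```
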