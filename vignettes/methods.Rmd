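---
title: "Methods: soundscape features, TRF/GED estimation, and the synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soundscape features, TRF/GED estimation, and the synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures the package implements,
the assumptions behind them, the parameters that matter, and what the
synthetic-data module does and does not emulate. It states no empirical
result beyond what the test suite and `scripts/acceptance.R` compute.

## The analysis problem

A listener performs a demanding bimanual task while a continuous,
task-irrelevant operating-room soundscape plays, with spoken-letter tokens
embedded every 3 s. Mobile 24-channel EEG (10–20 layout, 500 Hz) is
recorded. Three questions drive the analysis: (1) does the brain track the
ongoing soundscape, and which acoustic representation — raw envelope,
noise-reduced envelope, or sparse onsets — predicts the neural response
best; (2) do the evoked (ERP) and tracking (TRF) responses change with
cognitive demand or with time on task; (3) can those changes be measured
without per-channel cherry-picking, via a generic spatial filter.

## Acoustic features

**Envelope.** The magnitude of the analytic (Hilbert) signal is squared,
averaged over consecutive non-overlapping windows of `fs / target_rate`
samples, and compressed by a power nonlinearity (default exponent 1/3,
configurable; 1 disables compression). The cube root is a standard loudness
compression; the exponent is exposed because only the general construction,
not the exact compression, is canonical. Feature rates must divide the
audio rate exactly, avoiding fractional-window interpolation.

**Wiener noise reduction.** The audio is high-pass filtered at 1 Hz, then
processed in the STFT domain (32 ms Hann frames, 8 ms hop): the noise power
spectral density is the mean frame power over the first second of the
signal, assumed to contain only the stationary floor; each frame/bin is
scaled by `max(0, 1 − PSDnoise/PSDframe)` and the signal is rebuilt by
weighted overlap-add. Two numerical choices matter. First, the raw
single-frame periodogram is exponentially distributed around the true PSD,
so using it directly leaks about half the stationary noise through the
gain; the per-frame PSD is therefore smoothed with a 25-frame (200 ms)
moving average before the gain is computed. Second, samples at the signal
boundary with negligible window coverage cannot be reconstructed after
spectral modification and are zeroed rather than divided by a near-zero
overlap norm.

**Onsets.** A spectral-flux novelty curve (half-wave-rectified
frame-to-frame magnitude increase, summed over bins) is thresholded
adaptively (running median over 1 s plus 4 median-absolute-deviations) and
peak-picked with a 50 ms minimum inter-onset interval. The detector is
evaluated by planted-event recovery, not by equivalence with any particular
closed-source tool: on isolated clicks it is expected to time onsets within
one STFT hop (8 ms, tested at ±20 ms), and at 10 dB SNR over a stationary
floor to keep recall and precision at or above 0.9.

**Marker timing.** All sound markers carry a constant hardware delay
(default 30 ms) that is corrected by shifting; letter markers are further
refined to the first energetic peak within 20 ms after the nominal onset
(short-time energy, 4 ms window smoothed over 1 ms, first local peak above
10% of the window maximum), because a token embedded in a continuous
soundscape becomes audible only once it clears the floor. A marker already
at ≥95% of the window's maximum energy is left untouched — without this
tolerance the carrier ripple of a tone would produce spurious sub-millisecond
shifts on instant-attack tokens.

## EEG preprocessing

Filtering uses Hamming-window FIR designs with the conventional orders for
500 Hz data — 3300 taps for the 0.5 Hz high-pass (0.5 Hz transition), 220
for the 30 Hz low-pass (7.5 Hz transition), rescaled proportionally at
other rates. Each linear-phase filter is applied once by FFT convolution
with exact group-delay compensation; this is zero-phase for a symmetric
kernel and preserves the designed magnitude response, whereas
forward-backward filtering would square it. The high-pass kernel is
mean-corrected to place an exact null at DC.

Bad channels are detected by reconstructing each channel per 5 s window
from a random subset (6 of the 10 nearest by montage distance) of its
neighbors by least squares, over 10 seeded passes; a channel whose
reconstruction correlation falls below 0.8 in more than half the windows is
flagged, channels flagged in at least half the passes are rejected, and at
most 5 channels can be removed (worst first). The randomized neighbor draw
stands in for RANSAC sampling; the vote over passes absorbs its
stochasticity.

Epoch rejection estimates a per-channel amplitude density (histogram,
Scott's rule — the reference implementation's kernel is unspecified, and at
the sample sizes involved the histogram is equivalent), computes each
epoch's joint negative log-probability per channel and summed over
channels, and rejects epochs exceeding the mean by 5 SD at the ICA stage
and 3 SD for ERP epochs. Identical epochs (zero variance on both measures)
trigger a warning and no rejection.

ICA is fit on a 1 Hz high-pass copy (order 825 at 500 Hz) cut into 1 s
epochs and cleaned at 5 SD; components are estimated by FastICA with the
logcosh contrast in deflation mode. Deflation was chosen over symmetric
updates deliberately: the strongly non-Gaussian artifact components
(blinks, muscle) converge first and reliably, whereas the trailing
components spanning the near-Gaussian background have no identifiable
rotation — symmetric updates oscillate there, deflation simply accepts a
stable orientation. An error is raised only when no component stabilizes.
Components are classified by heuristics: blink = frontal-dominant
topography (Fp1/Fp2/AFz at more than twice the mean absolute loading) with
more than 60% of spectral power below 2 Hz; muscle = temporal/mastoid-edge
topography with a high >20 Hz power fraction; horizontal eye movement = an
opposed F7/F8 dipole pair. A manual-override list is honored. Flagged
components are zeroed and the mixing back-projected onto the original,
unfiltered data. Rejected channels are then rebuilt by spherical-spline
interpolation (stiffness m = 4, 30 Legendre terms) and all channels
re-referenced to the linked mastoids.

The stage order — filter, restrict to sound, channel rejection, ICA,
interpolation, re-reference — is recorded in each recording's append-only
history.

## TRF estimation

EEG is scaled by 0.0313, decimated to a common analysis rate after the
30 Hz low-pass (125 Hz by default; the rate is a free choice, and 125 Hz
keeps the 0–450 ms design at 57 lags), and regressed on the lag-expanded
stimulus feature with ridge shrinkage. The penalty is normalized by the
mean diagonal of `XᵀX`, which makes the dimensionless `10⁻⁸…10⁸` grid
meaningful regardless of feature scale. The intercept is handled by
centering and never penalized.

Cross-validation partitions the blocks into 10 contiguous segments (with 28
blocks: eight of 3 and two of 2, remainders to the earliest segments). Each
segment is held out once; the shrinkage parameter is chosen on the training
segments alone by inner leave-one-segment-out (correlation averaged over
folds and channels), so no held-out sample ever enters the solve that
predicts it — verified by a test that corrupts a held-out segment and
checks the selected lambdas are unchanged. Per-fold correlations are
averaged into one prediction value per participant and feature. Per-block
models use the modal lambda across folds (ties broken toward stronger
shrinkage) over lags −220…500 ms, and weights are z-scored jointly across
time, channels and blocks within participant so amplitudes are comparable
across participants. All solves run on per-block sufficient statistics
(`XᵀX`, `XᵀY`, sums, and `Σy²`), with an eigendecomposition per training
set shared across the lambda grid; held-out correlations are computed from
the same statistics, which makes the 17-point grid essentially free.

## GED spatial filtering

Per response type and deflection, the search windows are fixed: N1 80–150,
P2 150–250, N2 200–300 ms for ERPs and onset-TRFs; N1 50–120, P2 120–220,
N2 220–320 ms for envelope-TRFs, which peak earlier. The peak is the
polarity-consistent extremum inside the window (negative for N1/N2,
positive for P2; a flat or wrong-signed response falls back to the absolute
extremum and is flagged), and the amplitude window is the peak ±25 ms (N1)
or ±50 ms (P2/N2). Signal and reference covariances come from mean-centered
window and baseline samples; per-participant matrices farther than 3 SD
(Frobenius distance, the natural matrix Euclidean norm) from the grand mean
are excluded — jointly for S and R, since a participant whose signal
covariance is corrupt should not contribute a reference either — and the
means are recomputed once. The reference matrix is shrunk toward
`mean(eig(R))·I` with λ = 0.01 and the pencil solved through a Cholesky
whitening, guaranteeing real eigenvalues. Forward topographies are `S·w`,
normalized to unit maximum absolute value.

The largest-eigenvalue component is used by default, but largest variance
contrast does not guarantee physiology. An automatic plausibility check —
correlation of the absolute topography with a smooth fronto-central prior
(auditory responses project fronto-centrally), and a sustained-deflection
check requiring the window mean to exceed both the window's and the
baseline's standard deviation (a zero-mean oscillation can dominate the
variance contrast without being an evoked deflection) — can promote the
second component when the first fails both; an explicit override is also
supported. Signs are set so the window mean matches the expected polarity.
Amplitudes are the window means of the filtered per-block responses; the
whole amplitude path is linear in the data, which the tests exploit.

## Statistical layer

Outcomes are modelled by the nested sequence
`y ~ condition + (1|participant)`, `+ time`, `+ condition:time`, with
condition coded 0/1 and time the raw block number (1–28; centering is
available but off by default, matching the convention of reporting raw
per-block slopes). Models are compared by likelihood-ratio tests on ML
fits, stepwise: time is only added if it improves model 1, the interaction
only if time improved. Reported coefficients come from REML fits with
Satterthwaite degrees of freedom (via lmerTest); Wald-z tests are available
as a faster fallback for simulation studies. Counts use a Poisson GLMM
(log link, Laplace approximation; a plain GLM is a config fallback, and an
overdispersion ratio above 3 warns). Memory scores — `1 − d/L` with `d` the
unit-cost Levenshtein distance, `L` the longer sequence length, and the
placeholder "X" never matching — are ordinal, and are fit with a
cumulative-logit random-intercept model estimated by adaptive Gauss-Hermite
quadrature (11 nodes by default; the per-group posterior modes are found by
damped Newton steps vectorized across groups, and the quadrature is
mode-centered and curvature-scaled). The two-category case reduces to
random-intercept logistic regression, which the tests exploit as an
equivalence oracle against `lme4::glmer`.

The signed-rank test uses the smaller of the positive- and negative-rank
sums, drops zero differences, enumerates the exact two-sided null for
n ≤ 12 and otherwise uses the normal approximation with tie and continuity
corrections. Bonferroni thresholds are exposed with a display value rounded
to two significant digits (0.05/3 displays as 0.017, 0.05/6 as 0.0083), as
corrected thresholds are conventionally printed.

## The synthetic testbed

The generator fixes the study conditions: 22 participants, 28 blocks (14
per demand condition, balanced 7/7 within each session half), 3 s letter
spacing from the 12-consonant set with the block's memory letters excluded,
48 kHz audio, 500 Hz 24-channel EEG, and a 30 ms planted marker delay.
Block duration is exposed rather than fixed, because task duration varies
in the motivating setting; tests use 30–120 s blocks and the acceptance
script 60 s (audio) and 5 min (TRF-only) blocks — sizes chosen so each
check measures what it needs at comfortable precision.

The soundscape is pink noise (the stationary ventilation-like floor) plus
Poisson-scheduled transients — monitor-beep tone pips with fast 5 ms ramps
and impulsive, exponentially decaying clatter bursts — with a 500 ms linear
fade-in and sample-accurate event logging. Two generator choices encode the
acoustic regime the analysis is about. Transient attacks are fast because
real beeps and clatter have fast attacks; onset detection rests on that
property. The floor is loud (RMS 0.4 of the transient peak) because the
regime of interest is one where the stationary floor dominates the raw
envelope — that is precisely what makes noise reduction and sparse onsets
informative; with a quiet floor the three features would be nearly
equivalent by construction. Letter tokens are formant-like two-partial
chirps with 10 ms ramps, not speech: only their onset timing and energy
matter downstream.

EEG is generated forward: each planted lag kernel (N1/P2/N2-like Gaussian
deflections) is convolved with its stimulus feature and projected through a
unit-norm fronto-central topography; evoked templates are added at letter
onsets; demand scales the kernels multiplicatively (default 1, i.e. no
neural demand effect — matching the motivating finding — but settable for
recovery studies) and a per-block linear drift models time-on-task.
Background noise is built from per-channel 1/f sources with slow amplitude
modulation, mixed through smooth random topographies plus 5% sensor noise.
The modulation makes the sources weakly non-Gaussian and the mixing gives
the spatial correlation of volume conduction — both properties of real EEG
that the bad-channel detector and ICA rely on; with white, spatially
independent noise those stages would be unidentifiable. Optional planted
faults (50 Hz line noise, frontal blink bursts, flat or noisy channels)
make the cleaning stages testable.

Behavioral tables plant realistic effects: demand effects of 3.7/2.7/1.3
rating points on effort/frustration/distraction (0–20 scales, residual SD
about 2, participant-intercept SD 1.5), an exponential duration learning
curve, binomial mistakes in 0–3 with a slow decline, Poisson tissue-damage
counts with a mild negative time trend, and item-wise memory responses with
load-dependent error probability (3% low, 25% high demand, 40% of errors
blanks), scored downstream.

What passing tests show — and what they do not. The generator's EEG is
linear in its features and its artifacts are caricatures; real EEG has
nonstationary, nonlinearly coupled sources, real blinks vary in shape, and
real soundscape events overlap densely. Recovery of planted kernels,
topographies and effects therefore validates the estimators and their
plumbing (alignment, hygiene, scaling, selection), not the biological
fidelity of any particular fitted value on real data. The paper-scale
effect sizes on real recordings are explicitly out of reach: the motivating
data are not public.

## Calibration checks and problem sizes

The acceptance-level checks run at these sizes, chosen as the smallest that
measure each property cleanly: TRF kernel recovery on 10 participants × 8
five-minute blocks at 0 dB SNR and 125 Hz; GED oracle equivalence on
3-channel pencils against a 121 × 241 Rayleigh-quotient grid plus 100-seed
topography recovery on the full montage; the feature-ordering property on
10 participants × 4 one-minute blocks of 8 kHz OR-like audio; mixed-model
bias at the study's 22 × 28 layout over 200 simulations (the bias bound
allows two Monte-Carlo standard errors on top of 5% of the estimate SD,
since with 200 draws the bias of an exactly unbiased estimator is itself
uncertain at about 7% of that SD); likelihood-ratio type-I error over 1000
simulations; and 10⁴ random string pairs against a dynamic-programming
edit-distance oracle plus full enumeration of the signed-rank null for
n ≤ 8.

## Known limitations

Reading EDF/BrainVision/XDF is out of scope here — recordings enter as
in-memory objects or the package's own text formats, and audio as PCM WAV.
The ICA classifier is heuristic; it targets the caricatured artifacts the
generator plants and will not match a trained classifier's behavior on real
data. The Wiener implementation is a standard STFT gain, parameterized by
frame/hop/smoothing defaults rather than equivalence with any particular
toolbox. `fit_clmm` supports random intercepts only (no random slopes), and
the GED filters are generic (cross-participant) by design — per-participant
filters are a non-goal. Whether prediction accuracies are averaged over
channels before or after blocks is ambiguous in general; the implementation
averages channels within each held-out block, then blocks and folds.
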