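---
title: "Quantifying frequency-tagged expression-change responses: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying frequency-tagged expression-change responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

In a fast periodic visual stimulation (FPVS) experiment, neutral faces are
presented at a base rate $f = 6$ Hz and an expressive face of the same
identity replaces every fifth stimulus, so expression changes occur at
$f/5 = 1.2$ Hz. Because the stimulation is strictly periodic, the EEG
response concentrates at the tag frequencies and their harmonics: energy
at multiples of 6 Hz indexes general visual processing of the face
stream (*base response*), while energy at multiples of 1.2 Hz that are
not multiples of 6 Hz can only arise from neural discrimination of the
expressive deviant (*expression-change* or *oddball response*). Two task
layouts are supported: `max-int` (full-intensity expressions, four 40 s
sequences, 160 s total) and `grad-int` (expression intensity ramped
20–100 % in 20 % steps of 20 s each, twenty 20 s steps, 400 s total).

## Frequency-domain quantification

Epochs are cropped to start exactly at the onset of the first expressive
face and must contain an integer number of oddball cycles, so every tag
frequency falls on an exact FFT bin; the FFT uses a rectangular window
and no zero padding, which is exact under cycle-locking. The single-sided
amplitude spectrum is normalized so a sinusoid of peak amplitude $A$
yields $A$ at its bin. Resolution is the reciprocal epoch duration
(0.05 Hz for a 20 s epoch; 0.025 Hz for 40 s — note that the quantity
printed as "0.0125 Hz" in some descriptions of 40 s epochs is
inconsistent with $1/40\,\mathrm{s}$ and is not reproduced here).

For a target bin with amplitude $x$, the noise is estimated from the
surrounding bins: $n_\text{side}$ candidates on each side after skipping
one immediately adjacent bin per side, with the single largest and
single smallest candidate amplitude excluded, leaving $2 n_\text{side} -
2$ bins (18 for the 10-per-side window used with 40 s sequences, 8 for
the 5-per-side window recommended for sequences of 30 s or less). With
noise mean $m$ and standard deviation $s$ (computed with the $n-1$
denominator; the convention is not specified upstream, and the unbiased
form is adopted),

$$Z = \frac{x - m}{s}, \qquad \mathrm{BCA} = x - m, \qquad
\mathrm{SNR} = \frac{x}{m},$$

with $Z > 1.64$ (one-sided 5 %) as the significance criterion. The
oddball response sums the baseline-corrected amplitudes of the first
five usable oddball harmonics (1.2, 2.4, 3.6, 4.8, 7.2 Hz — the fifth
multiple, 6 Hz, coincides with the base rate and is excluded); the base
response sums 6, 12 and 18 Hz. The significance of a summed response is
assessed on the aggregate itself: candidate noise amplitudes are summed
position-wise across the harmonics' windows (same offsets, same extreme
trimming), and the summed target amplitude is z-scored against those
summed noise values. This keeps the criterion aligned with the quantity
being summed; the mean per-harmonic Z is reported alongside. Group-level
harmonic selection walks consecutive harmonics on the grand-average
spectrum while $Z > 1.64$; for the gradual-intensity task the criterion
is bypassed and the full-intensity sets are reused, because the response
is expected to be near-absent at low intensities.

### A note on BCA bias

BCA is *not* an unbiased estimator of the injected amplitude under
incoherent background noise. At a signal bin the noise adds in
quadrature, $E|A + n| \approx A + \sigma^2/2A$, while the correction
subtracts the full mean noise amplitude $E|n| \approx 1.25\,\sigma$
(Rayleigh mean), so BCA under-estimates by roughly the per-bin noise
floor. Both this bias and the Monte-Carlo standard error of a mean over
seeds scale linearly with $\sigma$, so the bias never becomes negligible
*relative to the SE*, at any noise level. The amplitude-recovery
validation in the regular test suite therefore runs in a documented
high-SNR regime where the bias is below a 3 % tolerance; the stricter
2-SE acceptance criterion is asserted as stated at a realistic noise
level and fails, which is the mathematically honest outcome. Group
contrasts are unaffected: the bias is common to conditions compared at
equal noise.

## Time-domain oddball components

The base response and its harmonics are removed with an FFT notch
(zeroing bins within ±1 bin of 6, 12, 18, 24, 30 Hz on the
whole-recording spectrum — exact at the tag frequencies), followed by a
zero-phase 4th-order 30 Hz Butterworth low-pass. Epochs span −167 ms
(one base cycle, the pre-stimulus baseline) to +667 ms around each
expression change; at 500 Hz this is realized as 84 + 1 + 332 = 417
samples (half-sample window edges round down). Epochs with any sample
exceeding ±100 μV on an analysis channel are rejected automatically
(the upstream procedure was semi-automated; full automation is a
documented deviation that makes rejection deterministic). The averaged
waveform exhibits a triphasic deflection — C1 (positive, 120–200 ms),
C2 (negative, 220–300 ms), C3 (positive, 350–450 ms); each component is
quantified as the mean amplitude in a 20 ms window centred on the
within-window extremum of the expected polarity (earliest sample on
ties; if no extremum of the required polarity exists the window extremum
is used and flagged). Peak search operates on condition averages per
participant. The medial cluster is excluded from gradual-intensity
time-domain analysis by default.

## Preprocessing

Fixed order, logged on the recording: 0.01–100 Hz band-pass (4th-order
Butterworth, zero-phase to preserve component latencies; the upstream
description is silent on phase), interpolation of listed bad channels,
ocular correction, average re-reference over EEG channels. Ocular
correction is least-squares regression of every EEG channel on the EOG
channels — a deterministic, testable substitute for ICA component
selection, validated on simulated blinks (≥ 50 % blink-window RMS
reduction). Channel interpolation uses inverse great-circle-distance
weighting over the four nearest good channels on an idealized spherical
10-10 montage rather than full spherical splines; the simplification is
recorded in the log. Since the filter-design and EDF libraries common in
other ecosystems are unavailable offline, the Butterworth biquad cascade
and a minimal EDF writer/reader (16-bit, 0.1 μV resolution, single data
record, TSV events sidecar) are implemented in-package and verified
against closed-form magnitude responses and round-trip tests.

## Statistics

Responses are analyzed with linear mixed models (lme4, REML) with a
participant random intercept and full-factorial fixed effects; intensity
is an ordered five-level factor. lme4 provides no denominator degrees of
freedom, so the residual approximation
$n_\text{obs} - \mathrm{rank}(X) - (n_\text{participants} - 1)$ is
reported (and used for p-values) but never asserted against published
dfs, which follow several conventions upstream. Effect size is partial
eta-squared, $\eta_p^2 = F\,df_1 / (F\,df_1 + df_2)$ — validated against
the one self-consistent published row ($F = 6.09$, df 1/225 → .026);
other published rows are internally inconsistent and are not used as
anchors. Intensity profiles are tested with orthogonal polynomial
contrasts for five equally spaced levels (linear −2 −1 0 1 2; quadratic
2 −1 −2 −1 2; cubic −1 2 0 −2 1), either as within-participant contrast
scores with a one-sample t-test or descriptively on means. Pairwise post
hocs compute estimated marginal means on a balanced factor grid from the
fixed-effect coefficients and adjust p-values with the studentized range
distribution (`ptukey`); for two levels this reduces to the unadjusted
two-sided test.

## The synthetic world

The generator models the stimulation only through its steady-state
outcome: pure sinusoids at the tag harmonics (no image rendering — the
analysis consumes EEG, not frames). Base harmonics default to
1.0/0.6/0.2 μV with a medial-occipital Gaussian topography (peak Oz);
oddball harmonics scale with expression intensity (linear gain
$I/100$ by default, matching the reported linear trend; a sigmoid is
available) under a right occipito-temporal topography (peak PO8). The
relative phase of base and oddball responses is not constrained by the
source material and is exposed as a parameter (default 0). Oddball
multiples coinciding with base harmonics are injected as base only,
mirroring the analysis-side exclusion. Background noise is $1/f$
(amplitude exponent α = 1) at 2 μV RMS per channel by default — a
plausible occipital background for pediatric EEG; blinks are a
stereotyped 400 ms biphasic waveform at Poisson times (8/min, 120 μV on
the vertical EOG) with a frontally-weighted propagation, enabling the
EOG-regression test without ICA. All randomness derives from one seed
recorded in the manifest, which also stores every injected amplitude.

What a green test establishes is correctness of the *quantification
machinery* under this stated world; the generator does not emulate
non-stationary artifacts, alpha rhythm, volume-conduction correlation
structure between channels, or attention-dependent amplitude drift, so
green tests do not certify performance on real recordings.

Two worlds required explicit construction choices. The
amplitude-recovery suite injects oddball amplitudes
0.2/0.1/0.05/0.05/0.02 μV (sum 0.42 μV). The individual-threshold
cohort uses amplitudes 0.325/0.195/0.13/0.13/0.065 μV at 100 %
intensity under the *sigmoid* intensity gain (midpoint 50 %, slope
0.12/%), two sequences per condition and 2 μV pink noise. A
threshold-like physiology needs a threshold-like gain: under the linear
default the expected-Z profile rises too gradually for any single
intensity step to be the ground truth (recovered thresholds straddle
40/60 symmetrically), whereas the sigmoid makes the response effectively
absent at 20–40 % and clearly significant from 60 %, so the cohort's
true threshold *is* 60 %. These settings were calibrated once against
the noise model when the world was constructed; the recovery test then
reproduces 60 % as the modal estimate over 200 simulated participants.

ERT (explicit emotion-recognition) blocks contain 50 expressive trials
(10 per intensity) plus 10 neutral trials; expressive-trial accuracy
follows $\gamma + (1 - \gamma - \lambda)\,
\mathrm{logistic}(\beta(I - \theta))$ with guess rate γ = 0.5 (binary
neutral/expressive choice), lapse λ, slope β and threshold θ; reaction
times are Gaussian around a linearly intensity-dependent mean, truncated
at 150 ms, with draws beyond the 3 s deadline flagged as timeouts.

## Numerical choices and degenerate inputs

Cycle-locked crops must also contain a whole number of samples; at
500 Hz and 1.2 Hz this restricts cycle counts to multiples of 3, and
segment spectra use the largest such count fitting the segment (45
cycles/37.5 s of a 40 s step; 21 cycles/17.5 s of a 20 s step). Noise
windows near the spectrum edge raise errors rather than truncating.
Zero noise SD flags the Z as undefined instead of returning ±Inf; zero
noise mean does the same for SNR. Singular mixed-model fits fall back to
fixed-effects ANOVA with a warning. EDF export clips beyond ±3276.7 μV
(with a warning) and rejects non-finite samples. PDI is the RMS pixel
difference inside the face oval divided by 255 (mean-absolute-difference
selectable); the upstream definition is deferred to prior work, so this
operative definition is the package contract, and the synthetic morphs
quantize their difference field to multiples of 5 grey levels so that
20 % intensity steps are exact.

## Known limitations

No ICA, no spherical splines, no BrainVision/FIF dialects, no modelling
of the attention catch trials beyond schedule placeholders, and no
attempt to reproduce published grand-average amplitudes (those depend on
the study recordings). Denominator dfs are approximate. The EDF layer
targets round-tripping this package's own recordings, not arbitrary
multi-rate EDF+ files.
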