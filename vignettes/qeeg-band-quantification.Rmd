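---
title: "Quantifying EEG band amplitudes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying EEG band amplitudes: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qeegband)
```

## The measurement model

`qeegband` quantifies eyes-closed resting-state EEG on the nine-lead 10-20
montage (frontal Fz/F3/F4, central Cz/C3/C4, parietal Pz/P3/P4) into
per-band amplitudes. Six canonical bands partition 0.5-35 Hz as half-open
intervals `[low, high)`: Delta 0.5-4, Theta 4-8, Alpha 8-12, SMR 12-15,
Beta1 15-20 and Beta2 20-35 Hz. The half-open convention resolves the
shared printed edges (4, 8, 12, 15, 20 Hz would otherwise belong to two
bands); a component at exactly 12 Hz is SMR, not Alpha.

The analysis chain is:

1. **Re-referencing.** Each channel has the arithmetic mean of the three
   midline leads (Fz, Cz, Pz) subtracted sample-wise. A midline reference
   is a linear combination convention; the text description of such
   transforms rarely pins down the combination, so single-electrode
   referencing is available through the same interface, and the operation
   is recorded in the recording's provenance. The transform is idempotent:
   after one application the midline trio's mean is identically zero.
2. **Epoching.** Fixed-length analysis buffers, default 8.2 s with no
   overlap. The buffer length sets the spectral resolution `r = fs/N`
   (equivalently `1/T`): a 1 s epoch gives 1 Hz, a 4 s epoch 0.25 Hz, and
   the 8.2 s buffer 0.122 Hz -- 0.12 at the two decimals conventionally
   printed. At the default 250 Hz sampling rate an 8.2 s epoch is 2050
   samples. Trailing data that does not fill a whole epoch is discarded;
   a 600 s session yields 73 epochs.
3. **Artifact removal by blind source separation** (below).
4. **Residual-artifact guard.** Epochs whose any-channel peak-to-peak
   range exceeds 200 µV (configurable) are flagged and excluded from
   spectral averaging. At least one epoch must survive; otherwise the
   pipeline stops with the observed ranges in the error.
5. **FFT amplitude quantification.** Per epoch and channel, the one-sided
   complex spectrum `A(z) + jF(z)` on the grid `k*fs/N`. Amplitude scaling
   is `2|X_k|/N` zero-to-peak for interior bins (DC and Nyquist unscaled
   by 2); peak-to-peak amplitude is twice that, and per-bin power is the
   squared peak-to-peak magnitude. All reported band amplitudes are
   peak-to-peak microvolts, the unit in which clinical QEEG analyzers and
   normative scales are expressed.
6. **Constrained peak detection.** Local maxima of the amplitude-frequency
   curve are kept if they reach 0.5 µV, and thinned to a minimum mutual
   distance of 0.5 Hz -- of two closer candidates the larger survives,
   ties breaking toward the lower frequency. Both constraints are
   configuration, defaulting to the conventional FFT-panel settings.
7. **Band amplitude.** Two estimators are provided because tabulated
   "band amplitude" in desktop QEEG software is ambiguous between them:
   *dominant peak* (default) -- the largest detected peak inside the
   band -- and *integral average* -- the mean per-bin peak-to-peak
   amplitude across the band. The mode is recorded in every output table.
8. **Subject table and group statistics.** Per lead and band, the
   arithmetic mean over unrejected epochs; then descriptive statistics
   (mean, min, max, type-7 quartiles, n-1 SD), normative classification,
   homologous-pair asymmetry, and region-wise repeated-measures ANOVA.

### Leakage correction of dominant peaks

A raw peak-bin amplitude underestimates an off-grid sinusoid by up to 36 %
(rectangular-window scalloping). The dominant-peak estimator therefore
integrates energy over ±3 bins around the detected peak
(`sqrt(sum(amplitude^2))`, a Parseval argument), which is exact for
bin-centered tones and bounds the worst-case off-grid error at roughly
4 %. The raw single-bin reading remains available
(`spectral_config(peak_correction = FALSE)`). The window is rectangular by
default -- consistent with exact peak-to-peak recovery of bin-centered
components -- with Hann available; Hann amplitudes are corrected by the
window's coherent gain of 0.5, so bin-centered tones are again exact.

## Normative profiling

The adult eyes-closed normative ceilings are Delta 20, Theta 15, Alpha 10,
SMR 6, Beta1 6 and Beta2 6 µV (peak-to-peak), overridable per band. An
amplitude is flagged only when *strictly above* its ceiling, because the
norm is phrased as "normal below the ceiling"; a value exactly at the
ceiling is normal. Flag magnitude is `max(0, amplitude - ceiling)`.

Worked against the built-in reference cohort statistics (the published
group means of an 18-athlete eyes-closed cohort that also parameterize the
default simulation; see `reference_cohort_stats()`): the SMR table flags
exactly F4 (6.31 µV, 0.31 µV above the 6 µV ceiling), the Beta2 table
flags all nine leads (means 6.70-9.56 µV), and the Delta table flags none
(all means below 20 µV). For Beta1, F3, F4 and P3 are flagged -- and so is
C3, whose printed mean of 6.04 µV also exceeds 6 µV even though narrative
summaries of such tables typically name only the three most prominent
leads. The classifier follows the arithmetic.

Inter-hemispheric asymmetry between homologous pairs (F3/F4, C3/C4, P3/P4)
is `100 * |right - left| / d`, with the denominator `d` selectable: the
pair mean (default; symmetric and bounded at 200 %), the smaller, or the
larger amplitude. A 20 % criterion flags asymmetric pairs. The published
frontal Alpha pair (7.81 vs 10.13 µV) exceeds 20 % under all three
conventions (25.9 %, 29.7 %, 22.9 %), which is why the choice of
denominator -- which the conventional phrase "a difference of 20 %" leaves
open -- does not affect that finding. Two zero amplitudes make the index
undefined; it is reported as missing, never as 0.

## Blind source separation

Artifact removal is FastICA (tanh contrast, symmetric decorrelation,
seeded deterministic initialization) on the concatenated epochs,
implemented in the package. Estimated sources are scored against three
documented signatures, each score in [0, 1]:

* **blink** -- the product of the source's low-frequency power fraction
  (< 5 Hz), a spikiness term derived from excess kurtosis
  (`1 - exp(-(kurt - 3)/5)`), and the frontal fraction of its absolute
  scalp loadings;
* **ecg** -- envelope periodicity (maximal autocorrelation of the squared
  source over lags 0.4-2 s, the physiological beat range) times the
  spikiness term;
* **emg** -- high-frequency power fraction (>= 20 Hz) times spikiness.

A source exceeding any class threshold (defaults: blink 0.2, ecg 0.5,
emg 0.5) is zeroed and the data reconstructed from the remainder. The
thresholds are deliberately explicit configuration: no published defaults
exist for this scoring, and the margins observed on synthetic data are
wide (blink sources score ~0.5-0.7 against ~0.0 for rhythmic or noise
sources). Continuous (non-bursty) EMG has near-Gaussian kurtosis and is a
documented blind spot of the spikiness term.

Two numerical safeguards matter in practice:

* **PCA dimensionality selection.** Before ICA the data are reduced to the
  components explaining 99.9 % of variance. Full-rank data are left
  unreduced -- reconstruction with an empty rejection set is then exact to
  floating-point -- but near-degenerate noise dimensions are dropped,
  because symmetric FastICA cannot settle inside a degenerate Gaussian
  subspace (the update rotates forever).
* **Gaussian-subspace convergence rule.** Convergence is declared when the
  update delta falls below 1e-6, or when every component still moving
  (per-component delta >= 1e-3) is statistically indistinguishable from
  Gaussian (|excess kurtosis| < 0.15): ICA directions are non-identifiable
  for Gaussian sources, so further rotation is arbitrary. Anything else at
  the iteration cap is a hard error with diagnostics, as is rank-deficient
  input (reported with the names of the collinear channels).

## The synthetic cohort generator

Raw recordings behind published group tables are rarely deposited, so the
generator is a first-class module: it produces recordings whose per-band
peak-to-peak amplitudes are known exactly, cohorts whose per-lead
amplitude distributions follow specified means and SDs, and artifact
injections whose added waveforms are returned sample-exactly.

Design choices, in the package's own words:

* **Narrow-band components.** Each band contributes one fixed-frequency
  sinusoid (default) at a mid-band carrier chosen on the 1/8.2 Hz grid, so
  the default epoch analyzes bin-centered tones and the amplitude oracle
  is closed-form. Band-passed Gaussian noise of matched RMS and a slow
  random-walk frequency jitter are options; both trade oracle sharpness
  for realism.
* **Peak-to-peak units.** Profile and cohort amplitudes are peak-to-peak
  microvolts -- the unit of the analyzer output and of published tables --
  so a profile value of 10.30 µV at Cz-Alpha is recovered as 10.30 by the
  pipeline. The sinusoid's zero-to-peak coefficient is half the profile
  value.
* **Truncation at zero.** Cohort amplitudes are drawn from normal
  distributions truncated at zero (rejection sampling): published SDs
  would otherwise permit negative amplitudes. For distributions with
  mean/SD ratios near 1 (e.g. an SMR lead with mean 4.86, SD 5.31) the
  truncated mean exceeds the nominal mean by up to ~1.7 µV; this bias is
  inherent to the stated distribution model, and the recovery checks use
  3-standard-error bands that accommodate it.
* **Phase structure.** By default every channel draws its own phase per
  band, making channels mutually independent -- the sharpest possible
  per-lead ground truth. For testing blind source separation this default
  is the *wrong* regime: nine independent channel signals plus two
  artifacts are eleven latent sources in nine sensors, and no linear
  unmixing can isolate them (we measured the best achievable blink
  correlation at 0.94, capping frontal post-cleaning correlation at
  ~0.85 whatever the algorithm). Real scalp EEG is not like that: volume
  conduction makes nearby leads coherent, keeping the effective source
  count below the sensor count -- which is the premise ICA rests on.
  `phase_mode = "shared"` reproduces that regime (each band's oscillator
  time course shared across leads; per-lead amplitudes, and hence the
  ground truth, unchanged), and the BSS validation scenarios use it with
  a 1 µV noise floor to keep the data full-rank.
* **Artifact templates.** Blink: smooth biphasic 0.3 s transient,
  frontal-dominant topography, default 12/min at 100 µV. ECG: strictly
  periodic biphasic spike train (fundamental at the beat rate, default
  66/min at 20 µV, diffuse topography). EMG: 20-45 Hz noise bursts of
  ~0.8 s under a raised-cosine envelope, lateral-frontal weighting. Jaw:
  slower 0.6 s monophasic bump. Respiration: a continuous slow sinusoid.
  Rates, amplitudes and per-lead gains are all parameters; the classes
  and shapes are fixed documented templates.

What the generator does **not** emulate: head-model (leadfield) mixing,
1/f background spectra, nonstationary drowsiness or state changes, and
per-epoch amplitude fluctuation. Passing tests on this synthetic model
therefore demonstrate correctness of the quantification arithmetic, the
averaging chain, the classification rules and the separation machinery --
not field performance on clinical recordings.

## Statistics

The region-wise battery runs one one-way repeated-measures ANOVA per band
and lead triplet (frontal, central, parietal): 18 tests for six bands,
each on an n-subjects x 3 matrix. The F statistic uses the within-subject
decomposition on (2, 2(n-1)) degrees of freedom, computed by direct sums
of squares (and cross-checked in the test suite against `aov` with an
`Error(subject/lead)` stratum). Effect size is partial eta-squared,
`SS_cond / (SS_cond + SS_err)`, labeled as such in every output, since
desktop statistics suites conventionally report the partial variant. No
sphericity correction is applied by default and no multiple-testing
correction across the 18 tests (per-test alpha = 0.05), matching the
convention of the tables this layout mirrors. Shapiro-Wilk p-values per
lead and a Brown-Forsythe Levene p-value are attached to every result and
never used to switch tests silently.

Under 1000 null simulations (n = 18, three leads, standard normal) the
test's rejection rate at alpha = 0.05 falls inside [0.03, 0.07], and
partial eta-squared stays in [0, 1]; both are asserted in the acceptance
suite. Quartiles use linear interpolation (R type 7) -- quartile
conventions differ across software, so the validator for externally
supplied descriptive tables (`validate_descriptive_table()`) accepts a
0.05 µV slack before flagging a row as internally inconsistent. The
built-in reference table itself carries two SMR rows whose printed order
statistics violate `min <= Q1 <= Q3 <= max` (an apparent column shift in
the source); the validator flags exactly those, and the simulation uses
only their means and SDs.

## Problem sizes and reproducibility

The validation scenarios are sized to make every check cheap enough to run
routinely: amplitude-recovery sweeps use one 16.4 s two-epoch recording
per case (band amplitudes of noiseless narrow-band signals are
duration-invariant, so longer recordings add nothing but runtime); BSS
scenarios use 60 s recordings, where seven epochs give the decomposition
ample samples; and the cohort-recovery study runs 100 seeds of 18 subjects
at 16.4 s each, pooling 5400 (lead, band) cells. Ten-minute sessions
remain the generator default for realistic use. The cohort-recovery runs
disable re-referencing: the generator synthesizes signals already in the
analysis reference, and subtracting the midline mean would alter the very
amplitudes whose recovery is being measured.

Every random element -- phases, cohort draws, artifact jitter, ICA
initialization -- is governed by explicit integer seeds, and identical
(configuration, seed) pairs produce byte-identical pipeline outputs; the
run manifest records the seed and an MD5 hash of every file written.

## Known limitations

* EDF storage quantizes to 16 bits of the per-channel physical range
  (< 0.01 µV for typical EEG amplitudes); round trips are tested to that
  bound, but extreme-amplitude channels widen the quantization step.
* The dominant-peak estimator reports the single largest rhythm per band;
  multi-peaked bands are better served by the integral-average mode.
* Artifact scoring targets transient/bursty signatures; tonic EMG and
  slow drifts other than respiration are outside the current heuristics.
* With nine leads, a diffuse low-amplitude artifact whose topography is
  nearly parallel to the dominant rhythms' spatial pattern cannot be
  separated by any linear method; the pure-contamination tests document
  the regimes where separation is well-posed.
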