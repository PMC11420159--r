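---
title: "Methods: quantifying in-ear EEG signal quality against scalp EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying in-ear EEG signal quality against scalp EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earqc)
```

## The problem

Dry-electrode in-ear EEG devices record a single bipolar channel from
electrodes in the two ear canals. Before such a device can be trusted for
wakefulness or sleep monitoring, its signal must be benchmarked against a
clinical-grade scalp system recorded simultaneously. `earqc` implements
that benchmark as a reusable pipeline: synchronization of the two
independently clocked recorders, rate harmonization, band-limiting,
amplitude-threshold artifact rejection, RMS and bad-data summaries, an
alpha-band signal-to-noise statistic, relative spectral power by sleep
stage, lag-tolerant cross-correlation against contralateral scalp
derivations, and block-permutation inference with FDR control.

Because paired human recordings of this kind are not freely available, the
package ships a synthetic paired-recording generator that reproduces the
two study protocols — a 5-minute eyes-closed/eyes-open "alpha test" and a
staged nap — with known ground truth. Every downstream stage is exercised,
and several are *validated*, against that ground truth.

## The measurement model

Both devices observe the same underlying cortical sources. The pipeline's
statistics formalize "the in-ear channel sees what the scalp sees":

* **RMS per 10-s epoch** (after a 0.3–35 Hz zero-phase FIR) summarizes
  amplitude; a right-tail Wilcoxon rank-sum test compares the in-ear and
  scalp distributions.
* **Artifact rule**: an epoch is rejected when at least 10% of its samples
  exceed ±100 µV. The same rule drives the bad-data percentage, with a
  strict >10%-of-recording quality verdict. For paired statistics the
  *union* of both devices' flags is used, so both sides are always
  evaluated on identical time ranges. (Whether to pool or intersect the
  two masks is genuinely open; the union is the conservative choice —
  a segment corrupted on either device tells us nothing about agreement.)
* **SNR(alpha)** = mean spectral power over 8–12 Hz divided by mean power
  over 5–35 Hz excluding 7–13 Hz, computed from a time-averaged Gabor
  wavelet spectrogram over clean eyes-closed data. A ratio above 1.5 — a
  3.52 dB amplitude difference, `20*log10(1.5)` — declares a "clear alpha
  peak". The dB conversion uses the amplitude convention; it is the only
  convention consistent with the 1.5 ↔ 3.52 dB anchor.
* **Relative spectral power (RSP)**: per clean 10-s window, a
  Hann-tapered FFT periodogram; band power over total power in
  0.3–35 Hz, for delta (0.3–4), theta (4–8), alpha (8–12), beta1 (12–18)
  and beta2 (18–35 Hz). Band membership is half-open `[low, high)` with
  the last band closed, so the five bands exactly partition 0.3–35 Hz and
  every RSP row sums to one — a property the test suite asserts to 1e-6.
* **Correlation**: Pearson cross-correlation maximized over integer-sample
  lags within ±0.1 s. The tolerance window absorbs residual inter-clock
  drift: 20 ppm over an hour accumulates 72 ms, which a fixed lag would
  miss but ±0.1 s covers. Alpha-band (8–12 Hz) correlations against every
  contralateral bipolar derivation produce the topographic map; broadband
  correlations per 10-s window, grouped by the containing 30-s hypnogram
  epoch, produce the per-stage summary. Window means are reported both as
  plain means and Fisher-z-averaged means (variance stabilization; both
  are emitted because plain means are what the field usually prints).
* **Amplitude ratio**: the least-squares slope (intercept included) of
  per-epoch `sqrt(scalp alpha power)` against `sqrt(in-ear alpha power)`.
  On the amplitude scale a device pair with twice the scalp gain yields a
  slope of 2. The intercept is included deliberately: broadband noise
  floors on either device otherwise bias the slope.

## Inference

Serial dependence makes sample-level permutation invalid, so the
correlation null is built by cutting the second signal into consecutive
10-s blocks and permuting whole blocks only; within-block autocorrelation
is preserved. p-values are two-sided on |r| with the add-one convention
(1 + #exceedances)/(1 + #permutations), which keeps p > 0; 1600
permutations by default, significance at p < 0.01. When the permutation
space is small (3 blocks → 3! orderings; two groups of 4 → C(8,4) label
assignments) the null is enumerated exhaustively instead of sampled, and
the test suite checks the sampled implementation collapses to exact
enumeration there. Mean differences (e.g. scalp vs in-ear RSP per band)
use the same machinery with group-label permutation. Across derivations
or bands, false discoveries are controlled with the Benjamini–Hochberg
step-up procedure (`stats::p.adjust`; decisions equal `adjusted <= q`).
Type-I calibration — empirical rejection rate at the nominal 1% under
white-noise nulls, 500 replicates — is part of the acceptance suite.

## Synchronization

Both recorders receive the same hardware pulse train on a trigger
channel. Onsets are detected where the absolute trigger crosses 0.5 × its
maximum, with a 200 ms refractory window collapsing each pulse to one
event (the threshold and refractory defaults are ours; only "peak
detection on absolute values" is prescribed by the protocol). The
inter-device offset is the *median* of paired event-time differences —
robust to a single missed pulse — with greedy nearest-neighbor pairing
anchored on the first event. An all-zero trigger channel raises a
synchronization-impossible error rather than guessing. Recovery of a
2.345 s offset to within one sample of the slower device, and the 72 ms
drift bound above, are acceptance checks.

The scalp stream (2000 Hz) is harmonized to the in-ear rate (250 Hz) by a
windowed-sinc anti-alias low-pass (cutoff 0.45 × target rate, transition
0.1 × target rate) followed by interpolation at the new sample times.
Upsampling is refused. The broadband FIR is built as a difference of two
Hamming-windowed sinc low-passes so the two transition widths differ:
0.3 Hz at the low edge (slow electrode drifts must die without eating
delta) and 5 Hz at the top. Kernels are symmetric; the group delay is
removed exactly, so filtering is zero-phase in one pass. All epoch and
window timestamps are half-open intervals on the common post-alignment
timeline, and analysis windows are snapped to the 30-s grid so 10-s
windows always nest inside trials and hypnogram epochs.

## The synthetic generator

The generator is first-class, tested code, not a fixture. Its shared-source
model is what makes recovery tests meaningful:

* in-ear = z + σ₁·e₁ + background, scalp derivation = a·(z + σ₂·e₂) +
  background difference, with a the scalp/in-ear amplitude ratio
  (default 2.0, matching the ~2× scalp amplitudes seen in this kind of
  dual recording).
* The noise SDs σ₁, σ₂ are *calibrated* against the empirically measured
  band SDs of the realized source and backgrounds so that the
  in-ear-vs-derivation correlation equals a target ρ exactly in
  expectation (ρ = 0.5 for the alpha band by default; per-stage broadband
  targets Wake 0.45, N1 0.50, N2 0.50, N3 0.62, REM 0.48 for naps,
  mirroring the ordering reported for real naps). Correlation recovery is
  therefore a genuine parameter-recovery exercise, not a tautology.
* During eyes-closed trials the shared source is 8–12 Hz band-limited
  Gaussian noise plus a 10 Hz sinusoidal carrier with random phase per
  trial. Eyes-open trials contain 1/f background only (the protocol says
  nothing about eyes-open content beyond the absence of alpha; 1/f is our
  choice). Alpha power waxes and wanes in *bouts*: each 10-s span is
  alpha-poor or alpha-rich (amplitude factors ~U(0.25,0.55) or
  ~U(2.0,2.6)), shared coherently across devices, as resting alpha
  blocking does. This bounded bimodal modulation matters: with weak
  modulation the amplitude-ratio regression is attenuated by
  per-epoch power-estimation noise (classic errors-in-variables), and
  with heavy-tailed modulation a couple of extreme epochs dominate the
  fit; bounded bouts keep the OLS slope estimator both nearly unbiased
  (≈1.95–2.0 for a = 2) and stable. Nap stage oscillations use a gentler
  ~U(0.7,1.3) modulation — bouts are a waking-alpha phenomenon.
* Stage templates (band SDs in µV): Wake is alpha-dominant (~10 Hz), N1
  theta (4–7 Hz), N2 spindle-band (12–16 Hz), N3 slow-wave (0.5–2 Hz)
  plus theta, REM mixed theta. Each stage's loudest template band is the
  loudest band of the generated segment (asserted by an independent
  periodogram oracle).
* Scalp channels beyond the temporal pair mix the shared bundle with a
  per-pair independent alpha source as g·shared + √(1−g²)·own, g
  declining with distance from the temporal sites (T7/T8 1.0, FT11/FT12
  0.85, …, 0.2). Pure gain scaling would leave Pearson r unchanged; the
  mixture makes the map's expected r ≈ g·ρ, so the topography peaks at
  T7-T8 with FT11-FT12 close behind — the pattern these dual recordings
  show.
* The in-ear stream is sampled through a warped clock: sample k at device
  time τ corresponds to true time offset + τ·(1 + drift·1e-6), with
  0.5 s offset and 20 ppm drift by default. Both streams carry the same
  rectangular 40 ms trigger pulses at 10× background amplitude.
* Artifacts: Gaussian-windowed transients at a Poisson rate with peak
  amplitude `artifact_amp_factor` (default 10, the top of the 5–10×
  range such devices show) × the channel RMS — above 100 µV by
  construction at realistic amplitudes — and whole-epoch contact-loss
  events (large 0.7 Hz swings) with a per-epoch probability. Ground-truth
  intervals are returned, and the contact-loss epochs are exactly the
  epochs the ±100 µV / 10% rule flags.

### What the generator does and does not emulate

It reproduces the protocol structure, stage-dependent spectra, amplitude
scaling, clock behavior, trigger trains, bout-structured alpha reactivity
and intermittent artifacts. It does **not** model head geometry or
forward solutions, spatially correlated scalp noise, transient (rather
than continuous) sleep spindles, eye-movement or cardiac artifacts, or
the broadband cortical background that dominates real temporal-site
recordings in the 5–35 Hz range. That last simplification means synthetic
SNR(alpha) values run far above the 1.4–1.9 typical of real in-ear/scalp
recordings — the synthetic alpha-to-background contrast is higher. Tests
passing on synthetic data therefore demonstrate correctness of the
*computations* (alignment, masking, estimators, inference calibration),
not field performance of any device.

## Numerical choices and degenerate inputs

* Trailing partial epochs/windows/blocks are discarded everywhere.
* Epoch flagging uses ≥ for "at least 10% of the time"; the bad-data
  verdict uses strict > 10%.
* Wavelet cycles default to 7 (constant-Q); kernels are unit-energy, so a
  flat-spectrum signal gives a flat time-averaged wavelet profile (an
  amplitude-normalized kernel would tilt it ∝ f and bias SNR on
  featureless signals). Edge samples within one wavelet half-length are
  marked invalid and excluded from time averages.
* The SNR noise band leaves 5–7 and 13–35 Hz; means are taken over bins
  of the uniform frequency grid.
* Zero-variance inputs (flat signals) raise explicit errors in
  correlation and SNR rather than returning NaN; "all epochs flagged"
  returns an explicit no-clean-data status.
* Agreement categories on |r|: poor < 0.2, fair 0.2–0.4, moderate
  0.4–0.6, substantial 0.6–0.8, almost perfect ≥ 0.8. (The sometimes
  quoted "poor < 0.02" bound is inconsistent with the next category's
  0.2 start and is treated as a typo for 0.2.)
* Whether FDR should be applied within subject across the derivation map,
  or across subjects, is not prescribed; the default is within-subject
  across derivations, configurable by calling `bh_fdr()` on any p-vector.
* No drift re-estimation is attempted within a recording beyond the
  constant offset; the ±0.1 s correlation lag search is the budget for
  residual drift.

## Problem sizes

The test suite and the acceptance script run the generator at reduced but
statistically adequate sizes, chosen once: 5-minute alpha sessions
(extended to 16–36 trials where ≥100 or ≥150 clean eyes-closed windows
are required), 600–900 s naps with all relevant stages, two-channel scalp
montages where only the temporal derivation is consumed, 400–1600
permutations, and 500 replicates for type-I calibration. Full-scale
defaults (64-channel montages, 1-hour naps, 1600 permutations) remain the
package defaults for real use.

## Known limitations

* EDF/BDF ingestion is not provided; recordings enter as in-memory
  objects or the package's plain-text CSV interchange format with a JSON
  ground-truth sidecar.
* Hypnograms are inputs; no sleep staging is performed.
* Artifacts are rejected, never corrected — no ICA or regression cleanup,
  matching the benchmarking philosophy that contaminated segments should
  simply not enter agreement statistics.
* Correlation is linear (Pearson); nonlinear similarity measures
  (mutual information, coherence, phase metrics) are out of scope.

## A worked run

```{r, eval = FALSE}
cfg <- sim_config("alpha_test", seed = 1)
rep <- run_alpha_report(cfg, n_perm = 400, seed = 1)
rep$snr               # SNR(alpha) per device with clear-peak flag
rep$correlation_map   # r, best lag, permutation p, BH-FDR decision
rep$amplitude_ratio   # scalp/in-ear amplitude slope
```

`scripts/acceptance.R` re-runs the full set of recovery checks from a
single seed and writes the recovered quantities as JSON; see the README
for how to invoke it.
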