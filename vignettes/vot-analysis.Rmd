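---
title: "Analysing vascular occlusion tests with votkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing vascular occlusion tests with votkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(votkit)
```

## The measurement and the model

A vascular occlusion test (VOT) probes muscle microvascular function at
rest. After a baseline period (BA), a pneumatic cuff inflated well above
limb occlusion pressure arrests blood flow to the forearm; during this
occlusion (OC) the closed tissue compartment consumes its oxygen, so
oxyhemoglobin (O₂Hb) falls and deoxyhemoglobin (HHb) rises almost linearly.
On release, reactive hyperemia (HY) floods the muscle: blood flow overshoots
baseline several-fold and the chromophores rebound past their baselines
before relaxing.

Two optical modalities observe this. Continuous-wave NIRS yields O₂Hb and
HHb concentration changes (arbitrary µM) at 50 Hz, from which the tissue
saturation index is the oxygenated fraction of total hemoglobin,
TSI = 100·O₂Hb/(O₂Hb + HHb) (%). Diffuse correlation spectroscopy yields a
blood flow index (BFI, cm²/s) at about 38.5 Hz, analysed as relative blood
flow, rBF = 100·BFI/BA-BFI (% of its baseline mean).

`votkit` turns one such recording into the standard parameter set
(`vot_feature_names`, 30 values): four baseline means; occlusion slopes
over the first 20 s after inflation, occlusion extrema with their
release-relative times, and the rBF floor (mean of the last 10 s before
release); and, for each signal during hyperemia, the peak, time-to-peak,
initial slope (10 s for NIRS signals, release-to-peak for rBF), and the
half-time to recovery (HTR) — the time from release until the signal first
crosses half the height of its hyperemic response. All times are reported
relative to cuff release, so occlusion times are ≤ 0 and hyperemia times
≥ 0.

## Preprocessing

Cardiac pulsation (≈ 1.1–1.7 Hz at rest) rides on every channel and must
not leak into slopes or extrema. `apply_lowpass()` uses a Kaiser-window FIR
low-pass with passband edge 1.0 Hz, stopband edge 1.3 Hz and ≥ 60 dB
stopband attenuation (605 taps at 50 Hz). The filter is applied zero-phase:
the symmetric kernel is FFT-convolved with the group delay compensated
exactly, and edges are odd-reflection padded, so no feature time is shifted
by filtering. Taps are normalised to an exactly unit DC gain. The stopband
edge of 1.3 Hz was fixed as the tightest transition band that keeps the
design practical at both sampling rates while leaving the sub-1 Hz
physiology untouched; the testable contract (unity below 1 Hz, ≥ 60 dB at
and above 1.3 Hz) is what downstream accuracy relies on, not the specific
design method.

The BFI stream is additionally averaged into non-overlapping 1 s bins
(`bin_average()`, stamped at bin centres) to tame shot noise and residual
pulsatility; every rBF feature is therefore defined on this 1 Hz stream.
TSI is computed sample-wise from the *filtered* chromophores by default
(`tsi_stage = "post_filter"`); computing it before filtering is available
as an option and differs only at the numerical-noise level, since the ratio
of two low-passed signals with a stable denominator is itself smooth.

## Segmentation and baseline placement

Phase windows come from the cuff annotations: OC = [inflation, release],
HY = [release, release + 180 s]. The baseline mean uses a 60 s window. The
protocol ends the baseline with a 5 s light contraction just before
inflation, so when a contraction is annotated the window ends 15 s before
inflation (guard configurable), keeping the contraction transient out of
the baseline; otherwise it ends at inflation.

## Parameter definitions worth spelling out

* Slopes are ordinary least squares on all samples inside the closed
  window (at least 5 non-missing samples required).
* Extrema searches cover the whole phase; plateau ties break to the
  earliest sample.
* The rBF occlusion "minimum" is a 10 s pre-release mean rather than a
  single lowest sample — a deliberate robustness choice, since the binned
  rBF floor is noisy.
* HTR interpolates linearly between the two samples bracketing the
  half-height crossing; the value at release is the first non-missing
  sample at or after release. For falling responses (HHb) the crossing is
  downward; the code handles both via a sign flip. A response with
  (numerically) zero height cannot define a half-level: the subject's HTR
  is recorded missing with a finding rather than failing the run.
* Degenerate or absent channels propagate as missing features, never as
  silent drops: a NIRS-only recording yields missing rBF features, and the
  extraction attributes carry one finding per problem.

## The synthetic generator

`simulate_trace()` builds a continuous noiseless model per channel, samples
it at the native rates, and adds a cardiac sinusoid (default 1.2 Hz,
1 µM on O₂Hb, counter-phased at half amplitude on HHb, 10% of baseline on
BFI) plus white noise (default SD: 5% of each channel's dynamic range).
The model is deliberately the *simplest* geometry consistent with every
extracted parameter:

* Occlusion chromophores: an exact linear segment at the nominal 20 s
  slope, a gentler linear drift reaching the extremum exactly at its
  nominal time, then a mirrored linear recovery until release.
* Hyperemia: a saturating-exponential rise whose time constant is solved
  (`solve_rise_constant()`, bracketing root search to 10⁻⁶ s) so the
  half-height crossing lands exactly on the nominal HTR; a rise with
  HTR ≥ time-to-peak/2 degenerates to the linear limit and is flagged.
  After the peak, an exponential relaxation toward baseline whose initial
  slope matches the rise's end slope, capped at a 60 s time constant.
* BFI collapses exponentially (τ = 12 s) to the rBF floor and recovers
  through the same hyperemia geometry toward 100%.

Every extremum corner is replaced by a quadratic cap (half-width 1.5 s for
NIRS, 1 s for rBF) with equal slope magnitudes on both sides, and the
vertex is pre-compensated so the capped maximum equals the nominal peak at
the nominal time. Local symmetry is the point: the zero-phase filter's
symmetric kernel then leaves extremum times unmoved, and the low cap
curvature bounds the peak-value distortion to far below 0.1%.

TSI is *not* drawn — it emerges from the chromophores. Its ground-truth
features (and, for rBF, the slope and HTR, which are defined on the 1 Hz
bin grid) are computed from the continuous model itself: dense-grid
evaluation with parabolic refinement of extrema, exact OLS for slopes, and
for the rBF features the same 1 s bin means the analysis stream would
contain. The returned truth is therefore the definitional value of each
feature for the noiseless trace, which is what extraction should recover.

`simulate_cohort()` draws each subject's parameters from independent
normals with the two groups' published summary means and SDs
(`reference_group_params()`; climbers n = 17, non-climbers n = 15), jointly
resampled until the piecewise model is well posed (extremum deeper than the
20 s slope implies, extremum time inside the occlusion with room for the
cap, HTR below the concave-rise limit, capped peak above the relaxation
level). Two consequences are documented rather than hidden: cross-feature
correlations are not reproduced (only marginals are published), and
truncation shifts some realized means — most visibly the long-tailed
occlusion time-to-minimum and the rBF HTR, whose published mean sits close
to the concavity limit HTR < (time-to-peak)/2 intrinsic to a
saturating-exponential rise. Recovery checks therefore always compare
extraction against each subject's *realized* truth, and group contrasts
against realized group means.

What the generator does not emulate: motion artifacts, probe-coupling
drifts, correlated physiological oscillations (Mayer waves), heteroscedastic
DCS noise, or the g₂-autocorrelation layer beneath BFI. Passing round-trip
tests show the pipeline recovers what the model encodes; they do not
certify robustness to those real-world effects.

## Accuracy: what the design guarantees

On noise-free, cardiac-free traces the pipeline recovers slopes to well
under 1%, NIRS/TSI extremum values to under 0.1%, and rBF extrema to under
2% (the peak bin mean of a sharply peaked signal sits slightly below the
continuous peak). Times and HTRs are recovered to within 1 s — one sample
of the 1 Hz analysis resolution at which these quantities are reported.
Sub-sample accuracy at 50 Hz is *not* claimed: the ~12 s filter kernel's
tails bound time localisation near phase boundaries to a few tenths of a
second, and the release value entering HTR is itself smoothed over the
kernel's main lobe (~±0.5 s).

Under the default noise model, cohort-mean recovery of most features is
unbiased to well within 5% of the generator mean. The exceptions are
instructive and inherent to argmin/argmax extraction, not to this
implementation: the expected extremum of a noisy, near-flat trace
systematically overshoots the true extremum (occlusion O₂Hb minimum and
HHb hyperemic minimum, a few tenths of a µM), and the timing of a shallow
occlusion plateau inherits an asymmetric jitter of seconds. Real VOT data
show the same behaviour — published occlusion time-to-minimum SDs of tens
of seconds reflect exactly this plateau ambiguity.

## The statistical layer

`run_family_analysis()` mirrors the study design: three multivariate
Hotelling's T² family tests (occlusion NIRS: 9 variables; hyperemia NIRS:
12; hyperemia DCS: 4), with
T² = (n₁n₂/(n₁+n₂))·(x̄₁−x̄₂)ᵀS⁻¹(x̄₁−x̄₂),
F = T²(n₁+n₂−p−1)/(p(n₁+n₂−2)) on (p, n₁+n₂−p−1) degrees of freedom and
partial η² = T²/(T²+n₁+n₂−2). The lone occlusion DCS variable (the rBF
floor) is compared by a single Student's t-test. Pairwise comparisons use
the pooled-variance t-test under a per-variable transform policy — log for
the right-skewed flow variables (rBF floor, rBF peak, rBF slope) and the
TSI hyperemic peak, the Mann–Whitney U test for the rBF HTR, which resists
transformation — with Cohen's d (pooled SD) computed on the same scale as
the test, so a log-scale test reports a log-scale d. Bonferroni correction
is scoped to each family's planned comparisons (m = family size; the
baseline block forms its own family of four, the lone t-test a family of
one); scoping is configurable because the total-comparison alternative is
defensible too. Hotelling tests use listwise deletion within their family,
pairwise tests per-variable deletion; the canonical multivariate F degrees
of freedom are reported as derived above.

## Problem sizes used in validation

The test suite exercises the full chain at the study's own scale: single
660 s recordings (3 min BA, 5 min OC, 3 min HY) at 50 Hz / 38.5 Hz, and
50 independent 32-subject cohorts for the noisy-recovery check. The
Hotelling null calibration uses 10,000 replicates of two 16-subject
5-variate samples. `scripts/acceptance.R` recomputes all headline
quantities from scratch at these sizes.

## Known limitations

* Events come from annotations; no automatic release detection from TSI
  stabilisation is attempted.
* Chromophores are consumed as provided — no multi-distance
  reconstruction, and BFI is relative (no absolute g₂ fitting).
* The generator's independent-marginal draws understate the correlation
  structure of real cohorts; significance rates from simulated cohorts are
  indicative, not calibrated to the real covariance.
* Extremum-based features carry the noise biases discussed above; users
  comparing groups should prefer the slope and peak parameters, which are
  unbiased here and were the discriminating parameters in practice.
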