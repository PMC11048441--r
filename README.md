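# votkit

Analysis of forearm-muscle **vascular occlusion tests** (VOT) recorded with
near-infrared spectroscopy (NIRS: oxyhemoglobin O₂Hb, deoxyhemoglobin HHb,
tissue saturation index TSI = 100·O₂Hb/(O₂Hb+HHb)) and diffuse correlation
spectroscopy (DCS: blood flow index BFI, analysed as relative blood flow
rBF = 100·BFI/BA-BFI). It is written for physiologists and sport scientists
comparing microvascular reactivity between groups — e.g. trained climbers
versus active non-climbers.

A VOT has three phases: baseline (BA), arterial occlusion (OC, cuff above
limb occlusion pressure) and reactive hyperemia (HY, after release). From
one recording `votkit` extracts the standard 30-parameter set:

* **BA**: mean O₂Hb, HHb, TSI, BFI over a 60 s baseline window;
* **OC**: 20 s post-inflation slopes of ΔO₂Hb/ΔHHb/ΔTSI (oxidative
  consumption), their extrema and release-relative times (≤ 0), and the rBF
  floor (mean of the last 10 s before release);
* **HY**: peaks and times-to-peak (≥ 0) of ΔO₂Hb, ΔHHb, ΔTSI, rBF; 10 s
  NIRS slopes and the release-to-peak rBF slope; and half-times to recovery
  (HTR — time from release to half the hyperemic response height).

Preprocessing removes the cardiac band with a zero-phase FIR low-pass
(unity gain below 1 Hz, ≥ 60 dB above 1.3 Hz) and averages DCS to 1 Hz.
Group comparison mirrors the standard design: Hotelling's T² family tests
(T² = (n₁n₂/(n₁+n₂))·(x̄₁−x̄₂)ᵀS⁻¹(x̄₁−x̄₂), F on (p, n₁+n₂−p−1) df,
partial η²), pooled-t pairwise comparisons with per-variable log /
Mann–Whitney fallbacks, Bonferroni correction scoped per family, and
Cohen's d with pooled SD. A synthetic-trace generator with exact ground
truth makes the whole pipeline testable without any data download.

## Worked example

```r
library(votkit)

# a climber-like subject with realistic cardiac pulsation and noise
sim <- simulate_trace(vot_ground_truth(seed = 7))
rec <- preprocess_recording(sim$recording)   # filter, TSI, 1 Hz rBF
f   <- extract_features(rec)
round(unlist(f)[c("ba_tsi", "oc_d_o2hb_slope", "oc_rbf_min",
                  "hy_d_o2hb_max", "hy_rbf_max", "hy_rbf_slope",
                  "hy_d_o2hb_htr")], 3)
#>          ba_tsi oc_d_o2hb_slope      oc_rbf_min   hy_d_o2hb_max      hy_rbf_max
#>          63.657          -0.098          10.888          16.828         867.576
#>    hy_rbf_slope   hy_d_o2hb_htr
#>          67.626           4.934
```

Reading these numbers: resting saturation sits near 64%; during occlusion
O₂Hb falls at ~0.1 µM/s while flow collapses to ~11% of baseline (a full
occlusion); on release, flow overshoots to ~8.7× baseline climbing at
~68 %/s, O₂Hb peaks ~17 µM above baseline, and reaches half of that
response 4.9 s after release.

For a full two-group study:

```r
cohort <- simulate_cohort(seed = 1)          # 17 climbers vs 15 non-climbers
feats  <- extract_cohort(lapply(cohort$recordings, preprocess_recording))
run_family_analysis(feats)                   # family T2 tests + pairwise table
```

or on a directory of recordings (`read_recording()` documents the
CSV + JSON layout):

```r
run_pipeline("cohort_dir/", "results/")      # features.csv, report.csv, run.log
```

A thin CLI wrapping the same functions ships in `inst/cli/votkit`
(`votkit validate|simulate|extract|stats|run`).

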