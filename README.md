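# hemovalid

Agreement and trending statistics for validating continuous hemodynamic
monitors against invasive reference measurements.

## The problem

Cuffless, wearable monitors (e.g. PPG-based devices estimating blood
pressure and cardiac output from the pulse contour) need to be validated
against the clinical gold standards — an arterial line for SBP/DBP/HR and
a pulmonary-artery thermodilution catheter for CO — and that validation
must hold while the circulation is *unstable*, not just at rest. The
standard design records paired (reference, device) observations across a
controlled hemorrhagic-shock protocol in an animal model: a baseline
phase, a controlled bleeding phase, and a long untreated follow-up.

`hemovalid` implements the complete analysis for such a study as a
tested, reusable pipeline, plus a synthetic-cohort generator that
emulates the protocol so the whole pipeline can be exercised and
validated without animal data.

## What it computes

For paired observations \\((x_i, y_i)\\) (reference, device), per
variable and per phase stratum:

* **Outlier screen** — per series, the percentage differences of each
  point from its preceding and following neighbours,
  %Δ⁻ᵢ = 100·(xᵢ−xᵢ₋₁)/xᵢ₋₁ and %Δ⁺ᵢ = 100·(xᵢ−xᵢ₊₁)/xᵢ₊₁; per variable
  a cutoff T = k·SD of the pooled |%Δ| values (default k = 2); a point is
  eliminated only when **both** |%Δ⁻| > T and |%Δ⁺| > T (single pass,
  reference channel, paired device value dropped with it).
* **Pearson r** and the OLS regression of device on reference, with
  tests that slope and intercept equal zero.
* **ICC(A,1)** — two-way random-effects, absolute-agreement,
  single-measurement intraclass correlation from the ANOVA mean squares,
  with the **standard error of measurement** SEM = SD·√(1−ICC).
* **Bland–Altman** — bias = mean(y−x), 95% limits of agreement
  bias ± 1.96·SD(y−x).
* **Percentage error** (CO) — 100·1.96·SD(y−x)/mean(x); ≤ 30% is the
  conventional acceptability bound for CO monitors.
* **Error bins** (BP) — % of pairs within ±5/±10/±15 mmHg.
* **Four-quadrant trending** — successive changes (Δx, Δy) per animal
  series; pairs with both |Δ| inside the exclusion zone (±2 mmHg BP,
  ±0.5 l/min CO) are excluded; concordance rate = % of surviving pairs
  whose changes share a strict sign, plus Pearson r of the changes.

## Worked example

```r
library(hemovalid)
report <- run_pipeline(sim_config(seed = 11))
report
```

```
Hemodynamic monitor validation report (schema 1.0)
  provenance: simulated
  observations: 1527 (1516 after outlier screening; 11 removed)

Agreement (all phases combined):
  SBP n= 394  r=0.965  ICC=0.963 (SEM 4.29)  bias=-1.16  LOA [-12.85, 10.52], within 15 mmHg 99%
  DBP n= 389  r=0.938  ICC=0.923 (SEM 4.23)  bias=+2.08  LOA [-8.96, 13.12], within 15 mmHg 98%
  HR  n= 390  r=0.960  ICC=0.958 (SEM 4.15)  bias=-0.20  LOA [-11.71, 11.31]
  CO  n= 343  r=0.911  ICC=0.908 (SEM 0.34)  bias=-0.02  LOA [-0.95, 0.92], PE 35.9%

Trending (four-quadrant):
  SBP changes= 383 excluded= 27 concordance=79.5% change_r=0.776
  DBP changes= 378 excluded= 66 concordance=76.3% change_r=0.750
  CO  changes= 332 excluded=204 concordance=75.0% change_r=0.499

Flags: CO percentage error ok: FALSE; BP within-15 ok: TRUE
```

Reading it: 1527 paired observations were simulated for 11 animals; the
2·SD screen removed 11 points (0.7%). Pooled across phases, device and
reference correlate at r = 0.91–0.97 with ICCs of 0.91–0.96; SBP shows a
−1.2 mmHg bias with 95% limits of agreement of about ±12 mmHg, and 99%
of SBP pairs fall within ±15 mmHg of the reference. CO trending
concordance is 75% after excluding the 204 small (≤ 0.5 l/min) changes.
The CO percentage error of 35.9% exceeds the 30% acceptability bound —
expected for this cohort, whose shock phases pull the mean CO down
(see the methods vignette).

## Analysis workflow

The `analysis/` directory decomposes the same pipeline into numbered
stages, each writing its output under `results/` so any stage can be
re-run from the previous stage's file:

```sh
Rscript analysis/01_simulate.R    # results/cohort.csv
Rscript analysis/02_screen.R     # results/cohort_screened.csv, outlier_report.json
Rscript analysis/03_agreement.R  # results/agreement.csv, figures
Rscript analysis/04_trending.R   # results/trending.csv, figures
Rscript analysis/05_report.R     # results/validation_report.json
```

## Scope

The package analyses paired numeric observations. It does not model the
monitor's internal signal processing (PPG waveforms, pulse-wave transit
time), resuscitation, or clinical-event outcomes, and it deliberately
pools pairs across animals within a stratum (no repeated-measures
correction) — see the methods vignette for the reasoning and
limitations.
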