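---
title: "Validating a continuous hemodynamic monitor: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a continuous hemodynamic monitor: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemovalid)
```

## The analysis

A method-comparison study for a continuous hemodynamic monitor produces
long-format paired observations: per animal, per variable (SBP, DBP, HR
in the usual clinical units, CO in l/min), a time-ordered series of
(reference, device) value pairs spanning three protocol phases —
pre-bleeding baseline, controlled bleeding, and post-bleeding follow-up.
`hemovalid` runs the canonical analysis over such data:

1. **outlier screening** on the invasive reference channel,
2. **static agreement** per variable × stratum (each phase and all
   phases combined),
3. **trending agreement** of successive changes (four-quadrant
   concordance),
4. a structured **validation report** with acceptability flags.

Because studies of this kind rarely deposit their raw series, the
package includes a synthetic-cohort generator with the full protocol
structure, used by every test and by `scripts/acceptance.R`.

## Outlier screening

For each interior point of a series the percentage differences from the
preceding and following values are computed; per variable, all absolute
differences are pooled across animals, and the cutoff is `k = 2` sample
SDs of that pooled set. A point is eliminated only when it differs from
*both* neighbours by more than the cutoff — a spike criterion: a genuine
step change (hemorrhage onset) leaves one side small, while a transient
artifact (flushing, catheter motion, signal dropout) is isolated on both
sides.

The screen is deliberately **single-pass**: differences and cutoffs are
computed once on the unscreened data, so the removal count has a fixed
meaning and re-screening already-screened spike-free data removes
nothing. Endpoints are never removed (they have only one neighbour).
Screening decisions are made on the reference channel only — the
invasive catheters are the channel subject to flushing/motion artifacts
— and the paired device value is dropped with the point so downstream
pairs stay aligned.

Two readings of the cutoff were possible: an SD of per-point *sums* of
the two differences, or an SD of the pooled absolute differences applied
to each side. We use the pooled-absolute-differences reading with a
common per-variable cutoff, the simplest rule consistent with
per-variable screening and a both-sides elimination condition; the
multiplier `k` is exposed for sensitivity analysis. Degenerate cases are
defined explicitly: constant series give a zero cutoff and no removals
(elimination requires a *strict* exceedance); series shorter than three
points are never screened; a zero-valued neighbour makes that side's
percentage difference undefined and the point is skipped with a flag.

One consequence of the 2·SD rule worth knowing: on a perfectly smooth
ramp sampled at a constant step, all differences are equal, the SD of
the pooled absolute differences is 0, and *every* interior point exceeds
the cutoff on both sides. The rule presumes data in which typical
point-to-point variation has spread comparable to its level — true of
real monitored series, and of the package's synthetic cohorts.

## Static agreement statistics

All pairs within a variable × stratum are pooled across animals (the
stratum sample sizes reported are pooled pair counts). Statistics:

* **Pearson r** and OLS of device on reference (`stats::cor.test`,
  `stats::lm`), with two-sided tests that slope and intercept are zero.
* **ICC** in the two-way random-effects, absolute-agreement,
  single-measurement form — ICC(A,1) — computed from the two-way ANOVA
  mean squares (subjects = pairs, columns = methods):
  \[
  \mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},
  \qquad k = 2 .
  \]
  Absolute agreement (rather than consistency) is the right form for
  method interchangeability: it penalizes a systematic offset between
  methods. Negative estimates, possible in small or degenerate samples,
  are clamped to 0 and flagged.
* **SEM** is implemented as the *standard error of measurement*,
  SEM = pooled SD × √(1 − ICC), the measurement-unit companion of the
  ICC. (The phrase "standard error of the mean" shares the acronym but
  has no natural pairing with an ICC and carries no measurement unit;
  the standard-error-of-measurement convention is used throughout.)
* **Bland–Altman**: differences are taken device − reference; bias is
  their mean and the 95% limits of agreement are bias ± 1.96·SD with the
  n−1 sample SD. The multiplier is fixed at 1.96 (no small-sample t
  correction): strata here have dozens to hundreds of pairs, where the
  correction is negligible.
* **Percentage error** (CO only): 100 · 1.96 · SD(differences) / mean
  reference CO. It is scale-invariant and ≤ 30% is the conventional
  clinical acceptability bound for CO monitors.
* **Error bins** (SBP/DBP only): percentage of pairs within ±5, ±10 and
  ±15 mmHg, inclusive boundaries.
* **Normality** of the differences is described by Lilliefors-corrected
  Kolmogorov–Smirnov (`nortest::lillie.test`) and Shapiro–Wilk p-values.
  They are reported, never used as a gate: the agreement statistics are
  computed regardless.

Strata with fewer than `min_n = 3` pairs are skipped with a warning
(regression and ICC need at least 3).

## Trending analysis

Successive changes are computed per animal series on both channels over
identical intervals, *after* screening, so intervals may be unequal
where a point was removed. Changes chain across phase boundaries: the
trending question — does the device move when the patient moves — does
not stop at a protocol label, and the pooled plot is the standard
presentation. HR is not trended (agreement for HR is a beat-counting
problem, not a trend-following one); SBP, DBP and CO are.

A change pair is excluded when **both** changes lie inside the central
exclusion square (±2 mmHg for BP, ±0.5 l/min for CO; inclusive
boundary). The square is the common reading of the exclusion-zone
practice; an either-channel (OR) rule is available via
`zone_rule = "either"`. Among surviving pairs, a pair is concordant only
when the two changes have the same *strict* sign — a zero change lies on
an axis, belongs to no quadrant, and counts in the denominator but never
as concordant. The concordance rate divides by surviving pairs
(consistent with the purpose of the exclusion zone: removing noise from
both numerator and denominator); `denominator = "all"` gives the literal
all-changes denominator for comparison. The correlation of changes is
computed over the surviving pairs.

## The synthetic cohort

The generator (`sim_config()` + `simulate_experiment()`) emulates the
protocol and statistical structure of an 11-animal controlled
hemorrhagic-shock study; its defaults are the package's definition of
that study's conditions:

* **Protocol**: a 30-min baseline sampled every 5 min; a bleeding phase
  whose per-animal duration is drawn from 20–60 min on the 5-min grid
  (the observed range of bleeding durations in such protocols), sampled
  every 5 min; a 7-h follow-up sampled every 20 min.
* **Phase target levels** (invasive channel, mean ± SD):
  SBP 79 ± 14 / 51 ± 20 / 58 ± 12 mmHg, DBP 57 ± 18 / 32 ± 12 /
  30 ± 18 mmHg, HR 96 ± 20 / 99 ± 20 / 125 ± 25 bpm, CO 3.8 ± 1.0 /
  2.4 ± 1.1 / 2.2 ± 0.5 l/min for pre-bleeding / bleeding /
  post-bleeding respectively.
* **Reference trajectories** are piecewise latent paths. Each animal
  carries a stable level (fraction `between_frac = 0.4` of the phase
  variance; a plausible mid-range split of animal-to-animal versus
  within-animal variation) plus an AR(1) fluctuation with lag-1
  correlation 0.9 — at 5–20-min sampling, physiological variation is
  dominated by slow drift, and smoother paths also reproduce the very
  low outlier-screen removal fractions (< 1–2%) characteristic of real
  screened catheter data. During bleeding the target declines from the
  animal's own baseline in at most two linear segments to a nadir,
  with the breakpoint chosen so the phase mean equals the configured
  target exactly; post-bleeding drifts linearly to the mirror point of
  its start level about the phase mean (partial BP/CO recovery, HR
  climbing), again preserving the phase mean. Pre-bleeding marginal
  SDs are matched exactly; bleeding/post-bleeding SDs arise mostly from
  the path geometry and are matched only approximately.
* **MAP floor**: bleeding in the emulated protocol is rate-controlled so
  mean arterial pressure, (SBP + 2·DBP)/3, never falls below 30 mmHg;
  the generator rescales the (SBP, DBP) pair upward at any bleeding
  sample that would violate the floor.
* **Device channel**: device = reference·(1 + proportional_bias) +
  offset + AR(1) noise, with the offset drawn once per animal — the
  one-time baseline calibration-by-offset of such monitors means any
  calibration error persists as a per-animal constant. Default noise SDs
  (5/4/4 units for SBP/DBP/HR, 0.4 l/min for CO; offsets 4/4/2/0.3) give
  pooled difference SDs of roughly 5–7 mmHg for BP and 0.5 l/min for CO,
  the error magnitude reported for validated monitors of this class.
  The calibration offsets are zero-mean: the generator reproduces error
  *spread*, not a particular device's signed bias (the `biased` fixture
  covers that pathway deterministically).
* **Realism of the record**: CO observations are independently thinned
  (probability 0.15) in bleeding/post-bleeding, reproducing the lower CO
  sample counts of thermodilution under instability; animals drop out
  (probability 2/11) at a uniform time in post-bleeding, truncating all
  their series; rare spike artifacts (probability 0.004 per observation
  and channel) multiply a value by 1.5.
* **Reproducibility**: a single root seed; per-animal substreams are
  drawn from it deterministically, and `simulate_experiment()` restores
  the caller's RNG state.

One known consequence of these conditions: with phase-level CO means of
3.8/2.4/2.2 l/min, the pooled mean reference CO is ≈ 2.7 l/min, so a
device error SD of ≈ 0.5 l/min yields a percentage error of ≈ 35% — the
CO acceptability flag *fails* on the default cohort even though the
absolute error is modest. That is a real property of percentage error in
deep shock (the denominator collapses), not a pipeline defect.

### What the generator does not emulate

No PPG waveforms or pulse-wave-analysis internals; no pharmacology,
resuscitation or clinical events; no blood-volume bookkeeping; no
heteroscedasticity of device error with signal level; no correlated
missingness. Passing tests therefore demonstrate that the *statistics
pipeline* is correct and well-calibrated on data with the study's
protocol and error structure — they do not certify any physical device.

## Numerical and degenerate-input choices

* Values are floored at small positive physiological bounds
  (20/10/20 mmHg-or-bpm, 0.3 l/min) so the strict-positivity invariant
  holds even in deep simulated shock.
* ICC denominators of exactly zero (all measurements identical) return
  ICC = 1 with SEM = 0; negative estimates clamp to 0 with a flag.
* Zero variance on either channel makes correlation/regression an error,
  not a silent NA; constant differences give a degenerate normality flag.
* All-excluded trending strata return `NA` rates with an `all_excluded`
  flag rather than dividing by zero.
* Ties at the exclusion-zone boundary are excluded (≤, inclusive); ties
  at error-bin boundaries are within (≤, inclusive).

## Problem sizes

The test suite and acceptance checks run default-size cohorts
(11 animals, ≈ 1,300–1,500 paired observations — the scale of the
emulated study), one 120-animal cohort for parameter-fidelity checks,
2,000-pair Bland–Altman and 1,000-subject ICC recovery simulations, and
5,000-change concordance recoveries; the oracle-equivalence checks use
100 random tables of n ≤ 20. These sizes make every statistical
tolerance a multiple of its analytic standard error while keeping the
whole suite under half a minute.

## Limitations

* Pairs are pooled across animals within strata; repeated-measures
  corrections (clustered Bland–Altman, mixed-effects ICC) are out of
  scope by design, matching the standard presentation of such studies.
* No confidence intervals on the ICC or the concordance rate.
* The screen's pooled-SD reading is one defensible interpretation of a
  rule whose exact SD definition (signed vs absolute, per-sum vs
  per-side, pooling scope) admits alternatives; `k` and the rule are
  parameterized so sensitivity is easy to check.
* Percentage error is undefined for non-positive mean reference values
  and misleading when the reference mean is far below the normal range —
  see the CO flag discussion above.
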