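---
title: "Free-living actigraphy in ataxia cohorts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-living actigraphy in ataxia cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actiwear)
```

## The measurement problem

Clinical rating scales for Friedreich ataxia (SARA, mFARS) are
administered in clinic, a few times a year, by an examiner. Wearable
accelerometers worn during everyday life offer a complementary signal:
how much a patient actually moves, hour by hour, over a week. `actiwear`
implements the full analysis chain for such a protocol — two triaxial
devices (non-dominant wrist, waist over L5), worn during waking hours for
7 consecutive days at a baseline visit and again one year later, with a
paper diary of on/off times.

The chain has three layers:

1. **Wear processing.** Epoch counts → non-wear detection → diary
   reconciliation → valid-day selection.
2. **Digital measures.** Seven per-recording summaries: MET rate, number
   of MVPA bouts, % sedentary / light / MVPA time, mean triaxial vector
   magnitude (VM3), steps per wear minute.
3. **Cohort statistics.** Patient-control comparison, correlation with
   clinical severity, paired longitudinal change, split-half reliability
   (ICC → SEM → MDC95), responsiveness (SRM → trial sample size).

Devices export counts; the conversion of raw 30 Hz accelerations into
counts (including any low-frequency-extension filtering) happens on the
device side and is out of scope here, as is the proprietary step
detector: steps enter as an input column.

## Wear processing

**Epochs.** All analysis runs on 60-s epochs. Sub-minute exports are
summed into 60-s windows by `aggregate_epochs()`, which conserves totals
exactly. Timestamps are local wall clock; days are calendar days from
local midnight, matching how participants fill in diaries. Waking-hour
exports with no overnight records are accepted: gaps must simply be whole
numbers of epochs.

**Non-wear.** `detect_nonwear_choi()` classifies an epoch as non-wear iff
it lies in a run of at least `min_nonwear_window` (default 90) minutes of
zero counts on the vertical axis, where a nonzero spike of up to
`spike_tolerance` (default 2) consecutive minutes is absorbed into the
run provided it is immediately flanked on both sides by at least
`spike_flank_window` (default 30) minutes of zeros. These are the
published defaults of the Choi algorithm. Two conventions needed fixing:

* *Per-spike tolerance.* The tolerance caps the length of **each**
  artifactual-movement interval, not the total nonzero time in a run.
  Two 1-minute spikes 30+ minutes apart can both be absorbed. This
  matches the algorithm as published and as implemented in the
  field's standard packages.
* *Boundary.* Exactly 90 minutes of zeros **is** non-wear (≥, not >),
  and runs are evaluated over the recording as ordered, so a non-wear
  run may span midnight and is then cut by calendar day for the wear-day
  ledger.

Whether the original protocol ran Choi on the vertical axis or on the
vector magnitude is not stated anywhere we could rely on; the vertical
axis is the default and `choi_params(axis = "vector_magnitude")` flips
it.

**Diary.** `apply_diary_correction()` forces epochs outside the diary's
worn intervals to non-wear and never overrides the algorithm inside
them — the diary can only remove wear. This makes the correction
idempotent and monotone, which the tests assert as invariants.

**Valid days.** A calendar day enters the analysis iff its wear time is
at least `min_wear_hours` (default 8, inclusive). All seven measures are
computed from the same mask: wear epochs on valid days. Appending
non-wear or invalid-day data to a recording changes nothing downstream.

## The seven digital measures

Intensity is classified on vertical-axis CPM with the Freedson adult
cut-points, half-open bins `[0,99]`, `(99,1951]`, `(1951,5724]`,
`(5724,∞)` CPM. The protocol we emulate cites "published cut-offs on the
vertical axis" without printing them; Freedson is the standard choice for
this device worn at the waist, and `cut_points()` makes them fully
configurable. The same scheme is applied at the wrist, where absolute
counts run higher; wrist summaries are therefore interpreted strictly
per placement and never pooled with waist values.

* **MET rate** — per-epoch energy expenditure relative to rest (1 MET =
  3.5 mL O₂/kg/min). Epochs above the light/moderate cut-point are
  scored with the Freedson regression `1.439008 + 0.000795 × CPM`;
  everything at or below it gets the 1.0 MET resting floor, so the
  summary (mean over wear epochs) is bounded below by 1. The source
  protocol names MET estimation but not an equation; this is the
  equation its cut-points came from. Published group values (patients
  ≈ 1.02 at waist) are used as plausibility bands in tests, never as
  fitting targets.
* **MVPA bouts** — maximal runs of ≥ `min_duration` (default 10)
  consecutive wear minutes above the moderate cut-point; each maximal
  run counts once. By default no sub-threshold minutes are absorbed
  (`drop_tolerance = 0`); the ActiLife-style 2-min drop-time is
  available behind the flag since the original setting is unstated.
  Recording gaps and non-wear always break a bout.
* **% sedentary / light / MVPA** — shares of wear time; moderate and
  vigorous pool into MVPA. The three sum to 100 exactly. Wear time (not
  full protocol time) is the denominator — the robust choice when wear
  varies across subjects.
* **VM3** — mean over wear epochs of `sqrt(axis1² + axis2² + axis3²)`;
  a raw measure with no model behind it.
* **Steps/min** — total device-reported steps over wear minutes.

## Cohort statistics

**Group comparison** (`compare_groups`) mirrors the two-stage convention
of the emulated study: Shapiro–Wilk on each group at α = 0.05; Welch's
t-test if both pass, Mann–Whitney otherwise (constant samples take the
rank path by definition). **Longitudinal change**
(`paired_change_test`) applies the same gate to the change scores, with
the Wilcoxon signed-rank test as the tie-break. **Bonferroni** families
have size 7 — one slot per measure, waist and wrist pooled, because the
two placements are highly correlated versions of the same construct.

**Reliability.** Baseline weeks are split into odd (Mon/Wed/Fri) and even
(Tue/Thu/Sat) valid days — Sundays excluded to keep the halves balanced —
and each half is summarized independently. `icc21()` estimates ICC(2,1):
two-way random effects, absolute agreement, single measures, from the
ANOVA mean squares. The form is not stated in the emulated protocol;
ICC(2,1) is the standard for test-retest of continuous measures. From the
ICC, `SEM = sd·√(1−ICC)` (ICC clipped at 0) and
`MDC95 = 1.96·√2·SEM`.

**Responsiveness.** `srm()` is mean change over SD of change;
`sample_size_from_srm()` sizes a two-arm trial at two-sided α = 0.05 and
80% power:

```
n/arm = ceil( 2 (z_{1−α/2} + z_{power})² / (δ·SRM)² )
```

Two deliberate decisions here. First, `delta` defaults to **1.0** even
though trial descriptions of this design often speak of "50% reduction in
progression": the published sample sizes this package checks itself
against are numerically consistent only with effect = SRM (e.g. SRM 0.09
→ 1940 ≈ 2·(2.80)²/0.09²); `delta = 0.5` is one flag away. Second, the
published numbers sit 0.1–7% above this normal-approximation closed form;
whether they came from a t-distribution iteration or unrounded SRMs is
unknowable from the outside, so the package exposes both solvers
(`method = "normal"` and `method = "t"`) and its tests assert only a
±10% band on rows with SRM ≤ 0.46. The one published row that is
internally inconsistent (a scale with printed SRM 0.98 but mean±SD change
1.5±1.5, which implies 1.0) is not used as a numeric target.

## The synthetic cohort

Participant-level data from such studies are typically not public, so the
generator is a first-class module: it must produce cohorts on which the
entire pipeline is testable and which reproduce the *structure* — group
separation, severity linkage, decline — of the real study, without
claiming to reproduce individual recordings.

**Activity model.** Each waking minute is in one of four active states
(sedentary, light, moderate, vigorous); non-wear is overlaid as explicit
blocks. The minute chain is the exchangeable mixture
`P = ρI + (1−ρ)·1πᵀ` (keep the state with probability ρ = 0.85, else
redraw from the stationary mix π), so the stationary occupancy equals π
exactly and simulation vectorizes. Dwell times are geometric — a
simplification; real activity has heavier-tailed bouts, which is one
reason generated bout counts should be read qualitatively, not as
calibrated quantities.

**Counts.** Per state, vertical-axis counts are log-normal truncated to
that state's cut-point band, drawn by inverse CDF and ceiling-rounded, so
every generated count classifies back to its generating state — the
intensity layer can be tested with zero label error, and sedentary draws
are ≥ 1 so zero runs occur only where non-wear was inserted. Lateral
axes are scaled, noised copies of axis1 (scales 0.55/0.45, log-normal
noise, SD 0.3 on the log scale). Non-wear blocks of 90–150 min (and
rarely a 10-h block that invalidates the day) are inserted with zero
counts, occasionally containing a 1–2-min artifact spike with proper
30-min flanks, giving the Choi layer true positives with known ground
truth.

**Calibration.** Group × placement occupancy anchors are the published
group means of the emulated study (e.g. waist sedentary share 81.3%
patients / 67.7% controls; MVPA share of active time derived the same
way). Two logits parameterize each profile — sedentary share, and MVPA
share of non-sedentary time — each the sum of a calibration base, a
severity effect, a subject effect and a day effect. The base is solved
numerically so that the *population mean* of the logistic-normal lands on
the anchor. Severity is SARA ~ N(17.2, 6.0) (truncated to the ambulatory
range); the linkage slopes (0.49 and 0.30 log-odds per SARA SD) and
subject SDs (0.38, 0.40) were chosen once so that between-subject spread
matches the published group SDs (≈ 9 percentage points of sedentary time
in patients) and the severity–sedentary Spearman correlation falls in the
published neighborhood (ρ ≈ 0.7–0.8). Day-level SDs (0.35, 0.30)
are a synthetic choice tuned only to keep odd/even split-half ICCs in a
realistic 0.8–0.9 range; true day-to-day variance of this population is
unknown. Step rates solve
`rate_light·p_light + 3·rate_light·p_mvpa = target steps/min` at the
group-mean occupancies (`steps_calibration()`), with targets 7.7/16.0
(waist) and 14.0/20.2 (wrist) steps/min.

**Decline.** At follow-up, patients gain ΔSARA ~ N(1.5, 1.5) points,
which propagates through the linkage, plus small direct shifts
(+0.08 / −0.03 log-odds) so the net sedentary increase matches the
published ≈ +2.8 percentage points. Controls are unshifted. Subject
effects persist across visits, so change scores carry day-level and
severity-progression noise only.

**What passing tests do and do not show.** The generator reproduces
occupancy means and SDs, severity linkage, decline direction and
split-half reliability. It does not model circadian structure,
weekday/weekend asymmetry, semi-Markov dwell times, device noise floors,
or wrist-waist correlation beyond the shared latent effects. Pipeline
correctness on synthetic data therefore validates the *algorithms*, not
device behavior on real patients. Published VM3 levels are matched only
to first order (the generated control waist VM3 runs ≈ 20% high), since
VM3 was not used as a calibration anchor — only its group ordering and
decline direction are asserted.

## Numerical choices and degenerate inputs

* Fully tied rank tests return p = 1 rather than NaN; all-zero change
  vectors short-circuit to "no change, p = 1".
* Constant groups cannot be declared normal and take the rank path.
* ICC requires ≥ 5 complete pairs and errors on zero total variance;
  negative ICCs are kept (they are informative) but clipped at 0 inside
  the SEM.
* SRM errors on zero change variance; sample sizing errors on SRM = 0.
* Recordings with no valid wear day summarize to `wear_days = 0` with
  `NA` measures and are excluded from every cohort statistic, mirroring
  the exclusion of insufficient-wear participants in the emulated
  protocol.
* The odd/even split errors if either half has no valid day, rather than
  returning a half-defined reliability estimate.

## Problem sizes

The test suite validates the wear layer against a brute-force reference
on 1,000 random days, the metric layer against counting oracles on 1,000
random series, estimator recovery at n = 200 subjects (ICC) and 10⁵
draws (SRM), and parameter recovery on 100 replicate cohorts of 26 + 13
subjects × 7 days × 2 placements × 2 visits; the acceptance script runs
the same battery with 50 replicate cohorts. These sizes were chosen so
the whole battery runs in minutes on a laptop while keeping Monte-Carlo
error well inside the asserted bands.

## Known limitations

* First-order Markov dwell times; no circadian or weekly structure.
* One cut-point scheme at both placements; wrist cut-points from the
  literature differ and wrist absolute values should be read
  per-placement.
* Steps are consumed, never detected; count-to-step consistency is the
  device's problem.
* The generator's clinical sub-scores are noisy monotone maps of one
  latent severity; real scales have multidimensional structure.
* MDC and sample-size formulas are normal-theory; small-sample exactness
  is not claimed (the noncentral-t solver is provided for the latter).
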