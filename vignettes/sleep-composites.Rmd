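---
title: "From ankle actigraphy to infant sleep composites: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ankle actigraphy to infant sleep composites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Infant sleep is usually quantified by combining an ankle-worn accelerometer
with a parent-completed 24-h diary. Both sources are imperfect: the sensor
sees movement, not sleep; the diary is coarse (15-min intervals) and
subjective. The pipeline in this package turns these two streams into a
registry of 48 operationalised sleep variables per assessment, and then
compresses them into five composite scores. Every stage is an explicit,
tested contract, because the main reproducibility hazard in this field is
not the statistics but the silent operational choices (what counts as
"sleep onset", which days are valid, what a "nap" is).

## Time conventions

All computation happens on an absolute minute grid: minute $m$ (0-based)
belongs to calendar day $\lfloor m/1440\rfloor + 1$ at clock minute
$m \bmod 1440$. The grid is half-open; "a minute asleep" is an epoch whose
scored state is SLEEP. Evening events are mapped to an *extended clock*
(`clock_to_extended`): clock times before 04:00 occurring as evening events
get +1440 min, so every night is monotone in time. The 04:00 cutoff is our
choice (the source conventions only demonstrate the +1440 rule for
post-midnight bedtimes); no infant bedtime plausibly falls between 04:00
and noon, and the cutoff is exposed as an argument.

Two derived conventions matter downstream:

* **Inclusive epoch counts.** Sleep period and sleep opportunity are
  counted as `last − first + 1` epochs, which makes
  `TST + WASO = Sleep Period` hold minute-for-minute and keeps sleep
  efficiency in $[0, 100]$ by construction.
* **Midsleep on the extended clock.** Midsleep is the arithmetic midpoint
  of onset and offset on the extended clock, reported as minutes after
  midnight. It is *not* reduced modulo 1440: a night whose midpoint falls
  just before midnight must yield a small negative value, not ~1440.
  (Reducing it is a real trap: the wrap makes cohort distributions bimodal
  and, in our development runs, manufactured a spurious sixth principal
  component out of Midsleep and its cross-day SD.) Clock strings are
  reduced only for display.
* **The 7 am-anchored analysis day.** Fixed-clock variables use a 24-h
  span from 07:00 to 07:00 split at 19:00, so *Sleep Duration Day* +
  *Sleep Duration Night* equals *Sleep Duration 24 h* exactly. Daytime
  variables (naps, longest wake) instead use the individual window from
  one night's sleep offset to the next night's sleep onset.

## From acceleration to states

`accel_to_counts` band-passes each axis at 3–11 Hz (4th-order Butterworth,
applied forward-backward so the phase response is zero — the band is given
by the protocol, the realisation is our documented choice), rectifies,
compresses to 15-s bins (per-axis sum of absolute filtered values by
default; sum/mean/max are configurable because the compression statistic
is not fixed by the protocol), fuses axes by sum of squares per bin, and
sums four bins per minute. Recording gaps become missing minutes, never
zeros. Because no DSP package is available in the target environment, the
filter design (bilinear transform of the analog prototype) is implemented
in-package and was verified coefficient-exact against an independent
reference implementation during development.

`score_sleep` is a windowed linear classifier in the Sadeh tradition. The
published infant coefficient set is not reproduced in our sources, so the
scorer is an engine: features are the mean count in a ±5-min window, the
number of window epochs above a count level (80), and log activity of the
epoch itself; a configuration file can encode any published coefficient
set. Two deliberate choices: ties (score exactly 0) classify as SLEEP, and
the optional window-SD feature defaults to weight 0 because it is
non-monotone in activity and would break the guarantee that adding
movement can never flip a minute from wake to sleep. The refinement pass
splits minutes into high/low activity at `mean(activity) × 0.72` (the one
constant the protocol does fix) and demotes high-activity sleep minutes;
ordered run-length smoothing rules (fill short wake islands, delete short
sleep islands; both idempotent, both conservative at series edges and next
to missing data) stand in for the unavailable six-step modification and
are fully configurable.

## Screening and the variable registry

Days fail per variable *family*, not wholesale: device removal is
tolerated up to 1 h for partial-day variables, 3 h for entire-day
variables and 5 min for movement-count variables; clock-time variables
fail when any removal intersects a 30-min window centred on the reported
on-/offset; sick days fail everything. The actigraphy/diary agreement
cutoff defaults to 0.80 — the original appendix criterion is not available
to us, so this is a labelled stand-in, set conservatively below typical
agreement of healthy recordings (≈ 0.95 in the synthetic cohort).
Assessments need ≥ 3 valid days for base variables and ≥ 5 for the 22
cross-day variability SDs (sample SD, $n-1$ denominator).

Operational rules worth naming because they are easy to get subtly wrong:
sleep onset is the first minute of the first sleep run of ≥ 10 consecutive
minutes at/after bedtime, walking back to the run start if already asleep
at bedtime (offset mirrors this at get-up); *Longest Nocturnal Wake*
counts only wake runs followed by ≥ 15 min of sleep; nap counting uses a
strict "> 20 min" rule; wake frequency counts every maximal wake run in
the sleep period (the follow rule is worded only for the longest-wake
variable; a switch applies it if desired); latency is clamped at 0 when
onset precedes bedtime; unreported bedtimes fall back to the first
diary-reported sleep minute and are flagged.

## Composites

The 48-slot assessment matrix is pooled across all participants and
timepoints, z-scored, and decomposed by PCA on the correlation matrix
(mixed units make covariance PCA indefensible) with promax rotation
(power 4, the conventional default). Missing and excluded cells are first
completed by chained predictive mean matching: each incomplete variable is
regressed on its most correlated companions, assessment age, and the
participant's observed mean (a pragmatic single-equation stand-in for a
two-level PMM); donors are the 5 nearest predictions. Defaults are
m = 20 × 10 iterations at desk scale; production analyses used 100 × 100,
and the component structure is insensitive to m.

Component count comes from parallel analysis: observed eigenvalues against
the 95th percentile of eigenvalues from uncorrelated normal data of the
same dimensions, counting leading components until the first failure.
Variables whose largest absolute loading falls below 0.512 (the
recommended cutoff for samples above 100) are pruned, *Sleep Duration
24 h* is dropped for interpretability (it loads with daytime sleep,
blurring the day/night split), and the PCA is refit on the retained set
(a flag keeps the original loadings instead; whether the original analysis
refit is not recorded). Each retained variable is assigned to its
largest-|loading| component; composite scores are unweighted averages of
the z-scored variables times their assignment sign. Components are
labelled by majority membership against the published reference solution,
and each labelled component is oriented so that its signed agreement with
the published loadings is positive — this pins down score directions
(larger *Sleep Activity* = more nocturnal wake) that would otherwise be
arbitrary up to reflection.

Inference over imputations uses Rubin's rules (pooled mean, within +
between variance, adjusted df). Stability analyses use Spearman
correlations with Bonferroni families of 15 (5 composites × 3 timepoint
pairs → threshold 0.05/15 ≈ 0.0033) and 10 (composite pairs); percentiles
are `rank/(n+1) × 100` with mean ranks for ties; within-subject stability
is the range of a participant's percentile across timepoints, computed on
one imputation by default (pooling is exposed). ASQ outcomes are modelled
with lme4 as `outcome ~ composites + exact age + sex +
(1 + timepoint | participant)`, downgrading to a random intercept on
singular fits; outliers are flagged per variable within timepoint by the
1.5 × IQR rule and reported both ways.

## The synthetic cohort: what it is and is not

The generator is a *stated world*, not a tuning knob: 150 participants ×
3 timepoints, recording lengths ~N(11.13/10.60/10.55, 1.17/1.91/1.93)
days, ages uniform in the 2.43–3.39 / 5.42–6.28 / 11.47–12.26 month
windows. Five correlated latent factors (Activity, Variability, Day,
Timing, Night; anchor correlations 0.50, 0.48, −0.26, −0.25, remaining
pairs modest values of plausible sign) decompose into a participant-level
share (0.25/0.33/0.27/0.62/0.50 — chosen to reproduce the published
cross-timepoint stability ordering) and a timepoint-level remainder, plus
within-window age drift (−0.15, −0.08, −0.21, −0.07, +0.03 SD/month) and
female shifts (−0.29 Activity, −0.17 Variability). Nights are generated at
the bout level — anchors, latency, wake bouts (Poisson counts × lognormal
lengths), naps (all > 21 min by construction, placed in jittered slots) —
because run-length statistics are exactly what the sleep variables
measure; per-timepoint location parameters track the published 3/6/12-month
descriptive columns. Day-to-day jitter is scaled by a lognormal
transform of the Variability factor (mean 1, σ = 0.45); a `jitter_scale =
0` override realises the degenerate identical-anchors case. The ASQ
Collective score carries a −6.65 effect of the Day factor plus age/sex
terms and participant random intercepts; the subscales carry no composite
effect. Missingness: 3% sick days, 0.3 removal episodes/day (lognormal
durations, median 45 min), 5% diary misreporting, 2% absent diary blocks,
3% unreported bedtimes, per-timepoint assessment dropout 1.3/2.6/5.9%,
5% missing ASQ. Within- vs between-infant variance splits are our choice
where only cohort-level moments are published (documented above); they are
set once and not revisited.

What the generator does **not** emulate: scorer error on worn minutes (the
measured states equal the generated states except where removals force
diary fallback — so green recovery tests validate the pipeline from states
onward, while the scorer itself is validated on constructed traces);
circadian physiology beyond bouts; seasonal/light effects; correlated
missingness (sickness clusters). Consequently, a green end-to-end test
establishes that the pipeline recovers a known five-factor bout-level
world through realistic screening, diary quantisation and missingness —
not that the scorer reproduces polysomnography.

## Numerical and degenerate-input choices

* Edge scorer windows are truncated, never padded; all-missing recordings
  raise an error at the activity-threshold step.
* Smoothing islands flanked by missing data or a series edge are left
  untouched; smoothing is idempotent (tested).
* Onset search fails (→ clock-time family invalid, night variables NA)
  when no ≥ 10-min sleep run exists before get-up.
* `pool_rubin` with zero between-imputation variance returns the within
  SE with infinite df; single imputations pass through with a warning.
* Paired stability contrasts with zero-variance differences are flagged
  degenerate instead of returning t = ±∞.
* Duplicate/constant columns: z-scoring guards zero variance; duplicated
  variables produce identical loading rows (tested).
* All stochastic stages (imputation donors, parallel-analysis simulations,
  the generator) are deterministic given their seed arguments; the cohort
  flows from a single master seed.

## Known limitations

* The scorer ships engine defaults, not validated infant coefficients;
  studies should supply their own coefficient configuration.
* Clock-time means are linear (no circular statistics), as in the source
  conventions; cohorts with midsleep distributions straddling a clock
  boundary would need circular treatment.
* The chained PMM is single-equation-per-variable; it approximates, not
  implements, a full two-level imputation model.
* Parallel analysis at the default 95th percentile is itself stochastic
  near the retention boundary; the diagnostics (eigenvalues and
  thresholds) are returned so the scree can be inspected rather than
  trusted blindly.
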