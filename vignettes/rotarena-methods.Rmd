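---
title: "Models and methods behind rotarena"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rotarena}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotarena)
```

## The task and its geometry

In the active allothetic place avoidance (AAPA, "Carousel maze") task a rat
moves freely on a circular arena (82 cm diameter) that rotates slowly about
its center while an unmarked 60° sector, fixed in the coordinate frame of
the *room*, is punished: entering it triggers a mild foot shock (0.5 s),
repeated after a 1.5 s pause for as long as the animal stays inside. Because
the arena surface — and any scent marks on it — rotates, local cues are
useless for locating the sector; the animal must rely on distal room cues
and must also keep moving, or the rotation itself will carry it into the
punished region. Solving the task therefore requires *separating* two
reference frames:

* the **room frame**, the fixed laboratory frame in which the sector is
  defined, and
* the **arena frame**, co-rotating with the surface, related by
  $\theta_{\text{arena}}(t) = \theta_{\text{room}}(t) - \omega t \pmod{360}$.

All positions are stored in room-frame Cartesian coordinates with origin at
the arena center; angles are degrees, counter-clockwise positive. The
rotation rate $\omega$ is signed and configurable; its default of 6°/s
(1 rpm) is pinned by an internal consistency argument: a fully immobile
subject's longest interval outside a 60° sector must equal
$(360 - 60)/\omega$, and the reference value for that interval is 50 s,
which forces $\omega = 6$°/s. The rotation *direction* is not constrained;
every room-frame measure is invariant to the sign of $\omega$ (tested), so
the choice is inconsequential.

Sector membership uses a half-open interval,
$[\text{center} - w/2,\ \text{center} + w/2)$, so that entrance events are
unambiguous when a sample lands exactly on a boundary.

## Per-session measures

For one session the package computes:

* **Total distance** (m) — the sum of straight-line distances between
  points selected every 1 s (the only measure defined on a resampled path;
  the resampler takes the nearest sample at or before each whole-second
  tick). Note that a rat immobile *on the surface* still accrues distance,
  because the rotation carries it on a circle through the room; at radius
  $r$ the accrual is $T \cdot 2r\sin(3^\circ)$ per $T$ seconds at 6°/s.
* **Maximum time avoided** (s) — the longest continuous interval without an
  entrance into the to-be-avoided sector, the primary avoidance measure.
  Ceiling 1200 s for a 20-min session; immobile-subject reference 50 s.
* **Mean distance from center** (cm) — the thigmotaxis (wall-hugging)
  index, a time-weighted mean radius, necessarily below the 41-cm arena
  radius.
* **Entrances** and **time in sector** — a session that *starts* inside the
  sector counts an entrance at $t = 0$, because the shock logic fires on
  initial placement; the apparatus behaves this way and the convention
  keeps the entrance count equal to the shock-entrance count.
* **Proportion of time in the opposite sector** — occupancy of the
  same-width sector 180° away, divided by total time *not* spent in the
  avoided sector, so the measure is independent of avoidance ability. It
  indexes perseverance during reversal (when the opposite sector is the
  previously punished place). Immobile-subject reference: 10 s of each
  rotation's 50 s outside the avoided sector fall in the opposite one,
  i.e. 0.2. Undefined (NA) if the animal never leaves the avoided sector.
* **Median absolute post-shock angular speed** (°/s) — per shock, the
  median absolute angular speed over the second following the onset;
  session value is the mean over shocks. Measured **in the arena frame**:
  in the room frame every animal is carried at $\omega$, so only the arena
  frame makes freezing read as ≈ 0°/s while an active escape reads far
  above it. (The frame is a config flag for users who want the room-frame
  variant.) Angles are unwrapped before the two-point forward difference,
  avoiding ±360° spikes.

Occupancy quantities use sample-and-hold weighting at the native sampling
rate: each sample owns the interval up to the next one, the last sample
holds to the declared session end. Occupancy of a partition of the arena
therefore sums to the session duration *exactly*, and the immobile-subject
references come out exact on sampling grids whose points sit clear of the
sector boundaries.

Shock events logged in a tracking file take precedence over the
reconstructed schedule; reconstruction (`shock_schedule()`) exists for
synthetic data and validation, and returns nothing in habituation and
retrieval sessions, which are unpunished by design.

## The cohort pipeline

Performance drifts across training days, so raw session values are not
directly comparable and a plain mean over a rat's *available* sessions
would depend on which sessions it happens to be missing. The pipeline
therefore (1) z-scores each metric within every session across rats
(sample SD, all rats pooled — session standardization is a common affine
transform per session and leaves two-sample statistics invariant), (2)
averages the z-values per rat within each phase over non-missing sessions,
and (3) re-standardizes the averages across rats within phase. With no
exclusions every phase-score column has mean 0 and SD 1 by construction —
which is also why the *phase* main effect of the downstream ANOVA is
degenerate and only the group effect and the group × phase interaction are
informative; the implementation suppresses the degenerate row.

Missing values (the generator plants them at 0.6% by default, emulating
occasional tracking failures) are never imputed for analysis. A separate
plotting table fills each hole with the closest valid value from the same
phase, averaging the two neighbors when both adjacent sessions are valid;
an equidistant tie farther away is resolved toward the earlier session
(the rule needs *some* deterministic completion and earlier sessions are
the more conservative donor under a learning trend).

**Non-solver exclusion.** Animals that respond to the task with freezing
rather than escape produce uninterpretable avoidance scores. The package
operationalizes the published exclusion reasoning as a dual criterion: a
rat is flagged when its combined-phase standardized total distance falls
below a z-cut (default −1.0) **and** its mean median absolute post-shock
speed is below 2°/s. The speed criterion is the discriminating one (active
animals score above 8°/s, freezing animals near 0); the z-cut is a guard
against flagging a merely slow but responsive animal. To keep the design
balanced, the same number of rats is then removed from the *other* group —
those with the lowest mean (acquisition, reversal) standardized maximum
time avoided, ties broken by rat id and logged.

**Tests.** The group × phase mixed ANOVA runs as a univariate
`aov(y ~ group*phase + Error(rat/phase))`; with a two-level within factor
the F tests are exact and need no sphericity correction. Effect sizes are
generalized eta squared with no observed factors:
$\eta_G^2 = SS_{\text{effect}} / (SS_{\text{effect}} + \sum SS_{\text{error}})$,
summing both error strata. Group comparisons outside the ANOVA use Welch's
unequal-variance t with $r = \sqrt{t^2/(t^2+df)}$ signed by $t$ as effect
size. Step-through latencies (two habituation trials plus the acquisition
trial, each capped at 300 s; a never-crossing subject scores the cap) are
analyzed with orthonormal polynomial contrasts: per-rat linear and
quadratic scores tested against the pooled within-subject error (df
$= 2(N-2)$), their interactions with group, per-group follow-ups against
each group's own error (df $= 2(n_g-1)$), and per-trial Welch tests.
Saccharin preference uses the ratio of saccharin to total liquid consumed
(removing intake differences) and reuses the mixed-ANOVA machinery with
session as the within factor. No multiple-testing correction is applied
across metrics; this mirrors the original analysis style and is
deliberately left to the user.

## Actigraphy

Activity is recorded as per-minute counts under a light schedule —
by default 29 days of LD12:12 followed by 16 days of constant darkness
(DD). The module provides:

* **Double-plotted actograms** — row $d$ shows days $d$ and $d{+}1$, so a
  free-running period $\tau \ne 24$ h appears as onset drift of
  $60(\tau - 24)$ min per row; the final row is single-plotted with NA
  padding.
* **LD activity profiles** — per-bin mean across LD days, aligned to
  lights-on.
* **Chi-square periodogram** (Sokolove–Bushell). For a candidate period of
  $P$ bins the series is folded over $K$ complete cycles and
  $Q_P = K \sum_h (M_h - \bar M)^2 / \hat\sigma^2 \sim \chi^2_{P-1}$ under
  the no-rhythm null. The search range is 20–28 h in one-bin steps. The
  significance line uses the chi-square quantile at
  $\alpha / n_{\text{candidates}}$ (default familywise $\alpha = 0.001$):
  with ~480 candidate periods a *pointwise* line would be crossed
  somewhere by roughly a quarter of rhythm-free recordings, so the
  Bonferroni form — the convention in standard actigraphy software — is
  the default. $\hat\tau$ is the most significant candidate; planted
  periods of realistic amplitude are recovered to the exact search step
  (the signal's $Q$ exceeds the line by an order of magnitude, so the
  correction costs no sensitivity).
* **Activity onset** per cycle: the first bin where the 29-min moving
  average rises strictly above its cycle mean and stays there ≥ 30 min.
  The odd window width centers the average on a 1-min grid; both settings
  are configurable.
* **Activity/rest ratio** — under LD, dark-phase over light-phase counts
  per day, averaged across days; under DD, the subjective night is
  $[\text{onset}, \text{onset} + \tau/2)$ anchored at each cycle's own
  estimated onset. The symmetric onset-anchored split is a documented
  stand-in for the unstated convention of commercial toolboxes. Zero
  denominators make the ratio NA rather than infinite.
* **Group comparison** — Student's equal-variance t for total activity and
  the ratio, and an exact-permutation Mann–Whitney test for $\tau$
  (enumeration handles the ties that 0.1-h-precision period estimates
  produce routinely; it matches exhaustive rank enumeration up to the
  sample sizes used here).

## The synthetic generators

The generators define the study conditions the pipeline is validated
under; they are first-class, tested code.

**Trajectories** follow a discrete-time correlated random walk: gamma step
speeds (mean 8 cm/s, shape 3 — an actively exploring rat), wrapped-normal
turning (SD 40°/√s), a reflective wall, and additive steering terms for
wall attraction (toward 80% of the arena radius) and sector avoidance
(tangential steering away from the punished region, weighted by an
`avoidance_skill` in [0,1]). Shocks are produced online by the apparatus
rule and trigger a 2-s tangential escape at a configurable arena-frame
rate; freezing phenotypes suspend active movement in random bouts while
the rotation keeps carrying the animal. Avoidance *learning* is modeled as
a per-session schedule of `avoidance_skill`, not as in-simulation learning
dynamics — the analysis needs session-level contrasts, not a learning
theory. This is the simplest model that expresses all phenotypes the
pipeline must distinguish (active avoider, freezer, thigmotactic
wall-hugger); it does not attempt biophysically realistic rat locomotion,
home-base behavior, or grooming pauses, so passing recovery tests shows
the *statistics* behave correctly under the assumed structure, not that
real rats are a correlated random walk.

**Cohorts** lay out the full design (two groups of 9; 5 habituation, 5
acquisition, 1 retrieval at 5 min, 5 reversal sessions of 20 min) with
per-group phenotype assignment, Poisson defecation counts,
truncated-normal saccharin/water masses and capped step-through latencies,
plus planted missingness (default 0.6%). A manifest records every planted
parameter so recovery tests can check against ground truth. A companion
*metric-level* simulator draws the session-metrics table directly (normal
values with session-specific day means and SDs and optional group shifts
in SD units); Monte-Carlo studies of the statistical pipeline (type-I
error, power) use it because trajectory simulation would add cost but no
information about the statistics under study.

**Activity series** are Poisson counts about a square (default) or
sinusoidal waveform: entrained at 24 h under LD with light masking
(multiplicative suppression of the light-bin rate, default coefficient
0.3), free-running at $\tau$ (default 24.2 h) under DD, phase-continuous
at the transition. Defaults — mesor 10, amplitude 8 counts/min, 29 LD +
16 DD days at 1-min bins — represent a robustly rhythmic rodent recording.

## Numerical choices and problem sizes

* Sample SD ($n-1$) everywhere; small cohorts, and consistency with common
  statistical software.
* Radius tolerance 0.5 cm beyond the wall for tracking jitter; positions
  farther out are rejected with the offending row named.
* Validation suites run at reduced problem sizes chosen to exercise every
  code path while keeping the full suite fast: trajectory-level cohort
  checks use 300-s sessions at 1 Hz and 3 sessions per phase (the
  flagging/exclusion logic is scale-free because it operates on
  standardized scores), periodogram recovery uses 16-day DD simulations at
  the four planted periods 23.8/24.0/24.2/24.5 h, and pipeline type-I
  error uses 2000 metric-level null cohorts at the full 9 v 9 layout.
* The acceptance script (`scripts/acceptance.R`) draws the immobile
  subject's radius and starting azimuth randomly (the start kept clear of
  the measure-zero grid alignment with the sector boundary) and recomputes
  its maximum time avoided from the sampled trajectory.

## Known limitations

* The correlated random walk is a statistical stand-in, not a locomotion
  model; absolute values of distance or entrance counts should not be read
  as predictions for real animals.
* The mixed ANOVA requires complete phase scores per rat (as the design
  intends after averaging); unbalanced missingness at the phase level is
  an error, not silently dropped.
* The periodogram assumes stationary noise within the analyzed segment;
  split LD and DD portions (`split_regimes()`) before estimating $\tau$.
* The DD activity/rest ratio depends on the onset estimator; arrhythmic
  cycles yield NA and are excluded from the cycle average.

```{r example, eval = FALSE}
# a compact end-to-end run on synthetic data
co <- simulate_cohort(n_per_group = 9, seed = 1,
                      duration_s = 300, dt_s = 1, sessions_per_phase = 3)
fl <- flag_nonsolvers(co$metrics)
ex <- matched_exclusion(fl, co$metrics)
ph <- phase_average(standardize_sessions(
  co$metrics[co$metrics$rat_id %in% ex$analysis_rats, ],
  "max_time_avoided_s"))
mixed_anova_group_by_phase(ph)
```
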