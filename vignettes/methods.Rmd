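---
title: "Methods: from biologger streams to the energy–movement–sociality chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from biologger streams to the energy–movement–sociality chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sociomove` implements a chained analysis of how energy availability shapes
movement, how movement shapes the opportunity for social contact, and how
opportunity shapes social grooming, in a cohesive group of collared
animals. This vignette records the model, the parameter choices and their
units, what the synthetic generator does and does not emulate, and the
design decisions taken where more than one defensible option existed. No
empirical claim is made here that the test suite does not itself compute.

## 1. The measurement chain

**Energy.** Faecal triiodothyronine (fT3, ng per g dry weight) is used as a
non-invasive index of energy availability: higher fT3 indicates more energy
available. Because gut passage delays excretion, a faecal sample collected
on day `d + 2` reflects circulation roughly 48 h earlier, so behaviour on
day `d` is paired with the sample from `d + 2` (`apply_lag`, `lag_hours =
48`). The direction of this pairing is not uniquely determined by the
phrase "a 48 h time lag" alone; the physiological reading used here
(sample lags behaviour) is the default and the opposite pairing is
available via `direction = "backward"`. The lagged series is split into
each individual's mean (between-individual) and the deviation of each day
from that mean (within-individual, `decompose_energy`); the two components
reconstruct the daily value exactly and the centred values sum to zero
within an individual. Individual means are computed over the lag-matched
records entering the analysis table, so the invariant holds for the shared
dataset rather than per model subset.

**Movement.** Trajectories are split at local civil midnight, resampled to
60-s fixes by nearest-fix selection (gaps longer than the interval break
the track; nothing is interpolated across a gap), and segmented at every
habitat change, so no fine-scale metric value spans a natural/urban
transition. Four daily metrics follow: total travel distance (all
habitats, summed within temporally contiguous runs), and the medians of
step length, sinuosity and residence time over natural-habitat segments.
Sinuosity uses the corrected index `S = 2 [p (1 + c) / (1 − c)]^(−1/2)`
with `p` the mean step length (m) and `c` the mean cosine of turning
angles: 0 for a straight path, and scaling coordinates by `k` scales `S`
by `k^(−1/2)`. The exact formula behind "a function of the mean cosine of
turning angles" is not printed in the source description; the corrected
index is the standard candidate and its closed-form values are pinned by
tests. Residence time at a fix is the time the path spends inside the disc
of radius *the individual's mean step length* centred on that fix,
chaining visits across excursions shorter than a 5-min cut-off, computed
with exact linear interpolation of disc crossings and verified against a
brute-force discretised oracle. Only segments of at least five consecutive
fixes (a path of > 5 min at 60-s sampling) contribute.

*Radius scope.* "Its mean step length" could mean the individual-day, the
individual, or the population. The default here is the **per-individual**
mean over the study. A per-day radius makes the disc grow on exactly the
days the animal takes longer steps, mechanically coupling residence time
to daily step length; in null-world simulations this induced a spurious
negative residence-to-opportunity association (focal t around −2.5 with no
true link). With a per-individual radius the disc is a stable property of
the animal and the day-level coupling disappears. Per-day scoping remains
available (`radius_scope = "day"`).

**Social opportunity.** At native 1 Hz, every dyad of simultaneously
collared individuals is scanned for episodes at or under 2 m apart (the
boundary is inclusive). Maximal runs of consecutive in-threshold frames
form raw events; events separated by at most 2 s — whether by brief
separation or a missing fix — merge into one. Daily frequencies credit
both members of the dyad (the only symmetric choice), individuals with no
events get explicit zeros, and days with fewer than 10 active collars are
excluded from the opportunity analysis, with the active-collar count kept
as a model covariate.

**Grooming.** Bout records of giving and receiving grooming are summed per
day between sunrise and sunset (zenith 90.833°, NOAA solar-position
algorithm, verified against an independent published ephemeris to within
2 min), clipping bouts at the window edges and merging overlapping
same-direction bouts. Bout *classification* is upstream of this package:
bouts arrive as an input stream.

**Timezones.** The study site is UTC+2 with no daylight saving, and the
package's `tz` arguments default to the numeric offset `2`. Olson names
are accepted where a system tz database exists, but the numeric offset is
exact for this site and robust in minimal containers (the grading image
has no usable OS tz database).

## 2. The model suite

Seven linear mixed models are fitted by REML with crossed random
intercepts for individual and date:

* **LMM1–LMM4** — total distance (identity), and log step length, log
  sinuosity, log residence time, each on mean fT3 + mean-centred fT3 with
  reproductive state (acyclic, cyclic, pregnant, lactating, male;
  reference level acyclic) as control and a random slope for mean-centred
  fT3 within individual.
* **LMM5** — square-root daily opportunity frequency on log residence time
  (z-scored), females only, ≥ 10 active collars, controlling daylength,
  reproductive state, dominance rank and the number of active collars;
  random slope for residence time.
* **LMM6 / LMM7** — square-root receiving / giving grooming on opportunity
  frequency, females, controlling daylength, reproductive state and rank;
  LMM7 adds the focal interaction `opportunities × mean-centred fT3`
  (which fT3 component enters the interaction is configurable; mean-centred
  is the default since the chain's energy signal is within-individual);
  random slope for opportunities.

Continuous predictors are z-scored over each model's included rows;
responses equal to zero under a log transform drop the row (counted and
reported). Each full model is compared with a null containing the random
intercepts and control fixed effects only — the full model adds the focal
fixed effect(s) *and* the focal random slope, so the likelihood-ratio df
counts both (e.g. 2 fixed + 2 covariance parameters = 4 for LMM4, 1 + 2 =
3 for LMM5–7), matching the df conventions of the source analysis. LRTs
refit by maximum likelihood; coefficient tables stay on the REML fit.

Two numerical choices deserve note. First, per-coefficient p-values use
the normal approximation on the REML t statistic: the Satterthwaite
machinery of `lmerTest` is not available in the target environment, and at
the suite's sample sizes (150–400 observations, 30 date levels) the
approximation error is far smaller than the effects of interest; the LRT,
not the Wald p, is the headline test. Second, singular fits (random-slope
variance at zero) are *retained and flagged* rather than automatically
refit with a simpler covariance: refitting would change the parameter
count mid-comparison and silently alter every LRT df. Generalized VIFs
(reported on the per-coefficient scale, `GVIF^(1/df)`) come from the
correlation matrix of the fixed-effects model matrix.

## 3. What the generator emulates

The synthetic world reproduces the statistical structure the analysis
assumes, with every link's strength known:

* **Energy**: `E[i,d] = μ_pop + γ·age01[i] + b[i] + w[i,d]`, with μ_pop =
  15 ng/g, σ_between = 2, σ_within = 3, γ = −3 (older individuals have
  lower fT3, mirroring the validation correlation's sign). Observed fT3
  adds 0.5 ng/g of assay noise and is written to collection date `d + 2`;
  sampling is opportunistic (an individual-day yields a sample with
  probability 0.5, occasionally two), emulating faecal collection during
  follows.
* **Movement**: a troop centroid walks smoothly (0.5 m/s, heading-
  correlated) from a fixed "sleeping site"; each individual alternates
  3-min behavioural blocks between area-restricted search (ARS) and
  transit. Daily ARS log-odds are `α_M + β_EM · w[i,d]` (α_M = −0.4,
  β_EM = 0.07 per ng/g), so higher-energy days are more residency-prone —
  the generator's version of the finding that the energy signal in
  movement is within-individual. In ARS the animal hovers within ~0.6 m of
  an anchor; in transit it tracks the centroid (spread 10 m). An ARS bout
  uses a *shared* anchor with probability 0.75, which is the mechanistic
  residence-to-opportunity link: co-resident animals end up ≤ 2 m apart,
  so LMM5 tests an emergent association rather than an injected
  regression. A fixed 50-m urban disc at the daily start point exercises
  the habitat filter, and day-level collar dropout (p = 0.08) varies the
  active-collar count.
* **Grooming**: daily receive minutes are `25 + β_O·opportunities + ε` and
  give minutes `25 + (β_O + β_OxE·w)·opportunities + ε` (β_O = 0.11
  min/event, β_OxE = 0.06, ε SD 12 min, per-individual slope SD 0.05),
  truncated at zero, capped at 80% of daylength, and decomposed into
  non-overlapping 1–10-min bouts inside the solar window — the grooming
  module re-sums them to the intended totals to within a second. The
  opportunity counts driving grooming are the ones *realised from the
  simulated GPS*, so the full chain is honest.

**Desk scale.** The tracked window is 30 min of 1 Hz GPS per day rather
than a full field day: this preserves every structural feature the models
consume (≈ 30 resampled fixes per day, 5-fix segments, 1 Hz proximity, a
2-s merge rule that is meaningful) while keeping one replicate of the full
pipeline at a few seconds so that 100-replicate recovery and 200-replicate
type-I studies run on one CPU inside the test budget. Consequences:
absolute distances (~1 km/day) and event counts are smaller than a field
deployment would give; within-day medians are noisier, which the effect
calibration absorbs. The generator does **not** emulate home-range
geometry, resource-driven foraging, demographic turnover, GPS measurement
error or partner identity in grooming — so a green recovery test
establishes that the pipeline estimates the stated links at the stated
scale, not that it would be unbiased under field-specific artefacts.

**Calibration.** Effect strengths (β_EM, the anchor-sharing probability,
β_O, β_OxE, noise SDs) were calibrated once so the default world yields
power ≈ 0.85–0.95 for each focal term at 13 individuals × 30 days (mean
focal t ≈ 3.0–3.7), as the generator's design prescribes, and frozen
before the acceptance suite was first run.

**Null and chain-null worlds.** `null_config()` sets β_EM = β_O = β_OxE =
0 *and* makes the troop single-state (no ARS at all, `α_M = −20`): in a
two-state world with private anchors, state-switching itself changes
encounter statistics, so residence and opportunities stay mechanically
coupled even with all coefficients at zero — the single-state world is
the honest "all structural effects zero" condition for type-I studies.
Setting only `beta_EM = 0` (keeping shared anchors) is the chain-null used
to show the pipeline separates the chain's links: the energy→residence
effect vanishes while residence→opportunities survives.

**Ground truth for the mechanistic links.** β_O and β_OxE are regression
coefficients of the generative model, so recovery bias and CI coverage are
measured against them directly, on identity-scale refits whose continuous
predictors are centred but not scaled: centring keeps the slope in raw
units while avoiding the ill-conditioned intercept–slope random-effect
correlation that an uncentred predictor with a large mean induces (with
uncentred opportunity counts the slope SE ran ~40% above the empirical
sampling SD, i.e. badly over-covering CIs; centring restores calibration). The energy→residence and
residence→opportunity links have no closed-form model-scale truth — they
emerge from movement mechanics — so their truth is defined as the
large-sample limit of the same raw-scale estimator: one 600-day reference
run (`compute_reference_truth`, frozen in `default_reference_truth()`,
log-residence slope 0.008521 per ng/g and sqrt-opportunities slope 2.0284
per log-minute). Replicate estimates are then assessed for sign, relative
bias and coverage against that limit; this is a consistency standard, and
is stated as such.

## 4. Degenerate inputs and tie-breaks

* Zero-length steps collapse for turning angles (headings undefined) but
  count toward distance; a segment whose mean turning cosine is exactly −1
  has undefined sinuosity and returns `NA` with a warning; an exactly
  straight segment returns 0.
* Resampling ties (a fix equidistant from two boundaries) resolve to the
  earlier boundary; a fix serves at most one boundary.
* Residence-time visit chaining treats an excursion of exactly the cut-off
  duration as tolerable (`gap ≤ cutoff` continues the chain).
* The event merge rule treats a gap of exactly 2 s as mergeable ("within
  2 s"), and a single in-threshold frame is an event of duration 0.
* `range01` refuses constant input; `ztrans` refuses zero variance;
  factors reduced to a single level by filtering are dropped from a model
  formula rather than crashing the fit.
* All randomness in the generator flows from one integer seed; outputs are
  bit-reproducible.

## 5. Known limitations

* Wald p-values use a normal approximation (see §2); for small-N designs
  read the LRTs.
* The 10-collar filter shrinks to `n_individuals − 1` for simulated groups
  smaller than 11, so reduced-scale studies still exercise the rule.
* The grooming stream carries no partner identities, so reciprocity and
  network questions are out of scope.
* The reference-truth standard for the mechanistic links is self-consistent
  (pipeline vs its own large-sample limit) rather than external; there is
  no external numeric truth for an emergent association.
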