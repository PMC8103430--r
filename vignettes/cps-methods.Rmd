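---
title: "Scoring and reliability methods for the Children's Play Scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and reliability methods for the Children's Play Scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(playscale)
```

## The instrument and its data model

The Children's Play Scale (CPS) is a parent-report questionnaire for
children aged 5–11. For each of seven places — inside at home, outside at
home, playground, green spaces, street, near water, and indoor play
centres — a parent reports, separately for Autumn/Winter and Spring/Summer,
how often the child plays there (seven ordered categories from *never* to
*every day*) and for how long on a day they play there (four ordered
categories from *less than half an hour* to *4 hours +*, with a *not
applicable* option). A supplement rates how adventurously the child plays in
each place on a 1–5 scale, where adventurous play means exciting, thrilling
play involving age-appropriate fear, challenge and risk. Up to three
free-text "other places" may be added, and a parent can instead flag that
the child may play elsewhere unsupervised.

`playscale` represents a dataset as one wide tibble row per informant ×
timepoint. This tabular shape, rather than a tree of record objects, is
deliberate: every downstream operation (scoring, pairing informants, pairing
timepoints) is a join or a grouped summary, and a flat schema keeps the CSV
interchange format and the in-memory object identical. Two consequences
worth knowing:

* the three "other place" slots are fixed columns, so the at-most-three
  invariant is enforced at the schema boundary (`read_cps()` rejects
  `other4_*` columns) rather than by a runtime check;
* `validate_cps()` never raises — it returns a tibble of issues with a
  severity per row, so a batch of survey exports can be triaged in one pass.

An inconsistent pair — frequency *never* with a concrete duration — is a
hard validation error. The converse, a positive frequency with a missing or
*not applicable* duration, is only a warning: no defensible imputation
exists, so scoring assigns that place–season 0 hours and the validator
points at it. The unsupervised flag is stored but contributes no hours,
since the informant by construction cannot report where or how long.

## From categories to hours

Scoring first converts categories to numbers. The conversions for the
anchors are fixed by the instrument's design: *every day* is 182.5 days
(half the year, matching the half-year reporting window), and ranged
categories take the centre of their range over a 26-week half-year, e.g.
*4–6 times a week* → 5 × 26 = 130 days, *2–3 hours* → 2.5 hours. The package
extends the same midpoint rule to the remaining categories:

| frequency | days/half-year | duration | hours/day |
|---|---|---|---|
| never | 0 | less than ½ h | 0.25 |
| less than monthly | 3 | ½–2 h | 1.25 |
| 1–3 per month | 12 | 2–3 h | 2.5 |
| once per week | 26 | 4 h + | 4.0 |
| 2–3 per week | 65 | | |
| 4–6 per week | 130 | | |
| every day | 182.5 | | |

*4 hours +* has no upper anchor; we floor it at 4.0 rather than invent one,
which makes all hour metrics conservative lower estimates for long players.
All values live in a `cps_mapping` object (serialisable as JSON), so a
study that fixed different numeric mappings can drop its table in verbatim;
the mapping validator only insists on rank-monotonicity, `never = 0`, and
the canonical place-group definitions.

Seasonal hours per place are `days × hours/day`; annual hours add the two
seasons. Six metrics summarise a response:

* `total_hours` — all seven places;
* `outdoor_hours` — outside home, playground, green spaces, street, water;
* `nature_hours` — green spaces and water (a subset of outdoor, so
  `nature ≤ outdoor ≤ total` holds identically);
* `adventurous_place_hours` — playground, green spaces, indoor centres,
  water;
* `adventurous_play_hours` — hours summed over only the places this child
  was rated as playing in at or above the adventure threshold (default 2,
  *mild*); a place without a rating never counts;
* `mean_adventure` — the unweighted mean of the present ratings. Averaging
  over rated places only (not all seven) reflects that a rating exists only
  where the child actually plays; if no place is rated the metric is
  missing, never imputed as 1.

Two scope decisions were genuinely open and are resolved as follows.
"Other place" entries are **excluded** from all metrics by default: the
metric definitions enumerate the canonical places, and free-text places are
too heterogeneous to classify into the groups. A sensitivity flag
(`include_other_places`) adds them to `total_hours` and, when rated at or
above threshold, to `adventurous_play_hours`; since the instrument asks
their frequency once rather than per season, their half-year days value is
assumed to apply to both halves (hours × 2). They never enter the
place-group metrics or `mean_adventure`. Hours are kept at full precision
throughout; rounding (2 dp) happens only in the report writers.

## Agreement and reliability statistics

**Concordance.** Cross-informant agreement (mother vs father, same child,
time 1) and test-retest reliability (same informant, ~3 weeks apart, per
role) both use Lin's concordance correlation coefficient,

$$\rho_c \;=\; \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},$$

which scales the Pearson correlation down by any location or scale bias
between the two measurements. It is preferred here over an intraclass
correlation because the hour metrics are strongly right-skewed and the CCC
makes no distributional assumption. Implementation conventions, stated
because packages differ:

* moments use the **1/n** (biased) convention of Lin's original estimator;
* the default CI applies the Fisher z-transform to $\hat\rho_c$ with Lin's
  asymptotic variance and back-transforms; a nonparametric percentile
  bootstrap is available via `ci = "bootstrap"`;
* pairs with a missing value in either member are deleted pairwise, within
  each metric; fewer than 3 complete pairs makes a metric *not-estimable*
  (a flagged row, not an exception, so one sparse metric cannot abort a
  table);
* both vectors constant is an undefined statistic and errors; when
  $\hat\rho_c = 1$ exactly (duplicated informants) the z-variance is
  degenerate and the interval collapses to the point;
* no multiple-testing adjustment is applied across the six metrics — the
  tables report unadjusted coefficients, as is standard for reliability
  studies — and the qualitative bands (poor < 0.5, moderate ≤ 0.65, good)
  are reporting conventions, not tests.

**Internal consistency.** Cronbach's alpha,
$\alpha = \frac{k}{k-1}\bigl(1 - \sum_i s_i^2 / s_T^2\bigr)$ with sample
(n−1) variances and listwise deletion. For the CPS it is most meaningful on
the seven per-place adventure ratings; for the hour metrics it is expected
to be low, since time spent in one place mechanically displaces time in
another.

**Stability.** Each metric is compared between timepoints with a two-sided
paired t-test per role, reported alongside the timepoint means and SDs. A
zero-variance difference vector is a documented degenerate error (the
statistic is ±∞); `stability_table()` converts it to an `NA` row with a
warning so the full table still prints.

## The synthetic cohort generator

`simulate_cps()` exists so that every scoring and psychometric operation can
be exercised, and its calibration behaviour demonstrated, without real
respondents. The generative model:

1. For each child and place, latent Autumn/Winter play days and hours per
   play day are drawn log-normally around per-place medians; Spring/Summer
   days get a log-scale boost (+log 1.3) for outdoor places. Log-normal
   latents reproduce the right skew that motivates the CCC in the first
   place.
2. Each informant sees the latent through a persistent multiplicative bias
   (SD `informant_noise_sd` on the log scale) — this is what limits
   cross-informant agreement — and each timepoint adds transient occasion
   noise (`occasion_noise_sd`), which is what limits test-retest agreement.
   Because the bias persists across timepoints, test-retest concordance
   exceeds cross-informant concordance, the pattern reliability studies of
   parent-report measures typically find.
3. Observed days and hours are discretised to the **nearest numeric value**
   in the mapping tables (ties to the lower category). Inverting the same
   tables the scorer uses means zero-noise data reproduce the latent
   intensities up to the instrument's resolution — the documented source of
   the below-1 ceiling on recovered concordance.
4. Adventure ratings combine a per-place profile, a per-child latent
   adventurousness shared across places (which is what gives the ratings
   their internal consistency), place-level residual, the same
   informant/occasion noise, and an additive drift `adventure_drift_t2` at
   time 2, then round and clamp to 1–5. A place never played in either
   season carries no rating.

Defaults describe the instrument's evaluation cohort: 154 children, 59%
with both parents reporting (and single reporters mostly mothers), two
timepoints, a +0.2 drift in time-2 adventure ratings, and per-place medians
chosen so the scored metrics land where UK parent reports land (total play
≈ 1300–1500 h/year, most play at home, least near water and in indoor
centres, mean adventure ≈ 2.5). Randomness uses R's default
Mersenne-Twister stream under `withr::with_seed`, so a config's `seed`
fully determines the dataset across platforms and the caller's RNG state is
untouched.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: attrition between timepoints (every informant
responds twice), demographic structure and covariates, seasonal recall
bias, response styles (e.g. end-aversion), and any dependence of noise on
play volume. Recovery results validate the pipeline's statistical
machinery, not the field behaviour of the questionnaire.

## Numerical and testing choices

* Discretisation ties (a latent exactly midway between two category values)
  go to the lower category; with continuous latents these are measure-zero.
* `recovery_experiment()` derives per-replicate seeds from the base seed
  (kept below 2³¹), sweeps an informant-noise grid, and warns if the mean
  recovered concordance is not monotone in the noise — the package's main
  self-calibration check.
* Test problem sizes were chosen as the smallest that make the stochastic
  assertions stable: 1,000+ scored rows for the metric-algebra property,
  50 random vectors against a naive loop oracle for the CCC (tolerance
  1e-10), n = 2,000 cases for the compound-symmetry alpha check
  (closed form $k\rho/(1+(k-1)\rho)$), 100 replicates per noise level for
  recovery, and 200 replicates for drift detection at 150 paired
  informants.

## Limitations

The scoring is only as good as the numeric mapping: the midpoint rule is an
approximation, and the 4-hour floor truncates heavy players. The CCC's
asymptotic interval can be anticonservative below ~30 pairs (use the
bootstrap there). Free-text "other place" matching is exact after
case-folding — no fuzzy matching — and the unsupervised response
contributes zero hours by design, which understates play for genuinely
independent children.
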