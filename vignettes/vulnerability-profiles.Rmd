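---
title: "Vulnerability indicators, weighted k-prototypes and the pandemic shock: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vulnerability indicators, weighted k-prototypes and the pandemic shock: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vulnprofiles)
```

This vignette documents the statistical choices behind `vulnprofiles`:
what each stage computes, which parameters matter, why the defaults are
what they are, and what the bundled synthetic data can and cannot tell
you about real survey data.

## 1. The composite indicators

Both indicators follow the additive binarization design common in the
deprivation-index literature: raw survey variables are dichotomised
against published cutoffs, summed within thematic subindicators, and
the subindicator total is linearly rescaled to 0–10.

**Binarization cutoffs.** Every rule is a hard threshold on a raw
variable: poverty is a *strict* `<` against the national
at-risk-of-poverty line (income exactly at the line is not poor);
financial distress fires on the two hardest answers of the 4-level
"ends meet" ordinal; weekly consumption on a summed food-frequency code
of at most 2; general health on fair-or-worse self-perceived health and
on ≥ 2 chronic diseases; mental health on EURO-D ≥ 5, life
satisfaction < 7 and happiness rarely/never; physical health on any
GALI/mobility/ADL/IADL limitation and on BMI outside the half-open
normal band [18.5, 25.0); health care on 0 or ≥ 52 doctor contacts and
on ≥ 1 hospital night. The EURO-D cutoff deserves a note: the "4 or
less is not depressed" convention implies *vulnerable iff EURO-D ≥ 5*,
although parts of the gerontology literature use ≥ 4; the cutoff is a
parameter of `score_mental_health()` / `build_indicators()`
(`eurod_cutoff`, default 5).

**Rescaling.** "Rescaled to 0–10" admits several readings; we anchor
the maximum: economic = raw × 10/4 (attainable values 0, 2.5, 5, 7.5,
10) and health = raw × 10/12. This keeps the indicator linear in the
number of deprivations and makes a single economic deprivation worth
exactly 2.5, which is consistent with the discrete medians the
indicators produce. Each subindicator contributes proportionally to its
component count — no reweighting between subthemes.

**Equivalisation.** Household income is divided by the OECD-modified
scale (head 1, additional adults 0.5, children under 14 0.3). Household
member counts are taken as given in the data (`n_adults`,
`n_children`), not derived, since member ages of non-respondents are
unobserved in this kind of survey. The poverty threshold table is an
*input*: in real analyses it should be the published Eurostat lines,
never recomputed from the analysis sample. The synthetic path computes
it as 60% of the weighted median equivalised income per country, which
is the same definition applied to the synthetic population.

**Missing data.** The pipeline is complete-case: readers drop records
with missing mandatory fields (with row-indexed diagnostics) and reject
files with out-of-range codes outright. The single optional field is
the occupation code, which retirees typically lack; a missing code only
removes that person from the sector-job-loss shock rule.

## 2. Survey-weighted statistics

All descriptive statistics treat the calibration weight `w_i` as the
number of persons represented. Three conventions matter:

* **Quantiles** use the left-continuous inverse CDF (no interpolation):
  the smallest observed value whose cumulative normalized weight
  reaches `q`. On integer weights this equals the type-1 quantile of
  the weight-expanded list, which is the property the tests exploit;
  and on a discrete indicator the quartiles always land on attainable
  values (with an atom-heavy distribution, Q1 = Q2 = Q3 is possible and
  meaningful).
* **The SE of the weighted mean** is the design-based form under
  independent weighted sampling, `sqrt(Σ w_i²(x_i − x̄_w)²)/Σ w_i`. No
  replicate-weight or linearization machinery for multi-stage designs
  is attempted.
* **Boxplot summaries** use Tukey fences at 1.5 IQR on the weighted
  quartiles; whiskers are the most extreme observations inside the
  fences, and the outlier count is reported.

All statistics are invariant to splitting a record's weight across
duplicates — the basic sanity property of anything claiming to be
"weighted".

Demographic bands are fixed to four age groups (`[50,60)`, `[60,70)`,
`[70,80)`, `80+`) and an education grouping (0–9, 10–12, > 12 years,
plus `never_in_school` and `still_studying` kept as their own
categories). The country-to-region map (southern / eastern / northern /
Scandinavian + Switzerland) is a plain data.frame argument; the default
places each country exactly once, with straddling cases (Finland,
Czechia, Slovenia, Slovakia) assigned to a single region rather than
duplicated.

## 3. Weighted k-prototypes

The dissimilarity between a record and a prototype is squared Euclidean
on the numeric block plus λ times the categorical mismatch count — no
square root, so the numeric part behaves like the k-means objective.
The weighted extension is the natural one: assignments minimise
`w_i d(x_i, proto)` (equivalently `d`, since `w_i > 0`), numeric
centers are weighted means, categorical modes are weight-sum-maximising
categories, and the model cost is `Σ w_i d(x_i, proto(x_i))`. With all
weights equal this reduces exactly to plain k-prototypes, and with
λ = 0 to weighted k-means on the numeric block — both reductions are
enforced by tests against independently coded references.

Choices a user should know:

* **λ** (default: estimated) is the ratio of the average weighted
  numeric variance to the average categorical Gini diversity
  `1 − Σ f_c²`. At this value a typical squared numeric deviation and a
  typical mismatch contribute comparably. The estimate scales as `c²`
  when the numeric block is scaled by `c`, matching the quadratic
  numeric term. The indicators already share a 0–10 scale, so the
  numeric block is used as-is with no internal standardization.
* **Initialization** samples k pairwise-distinct records with
  probability proportional to weight; the seed is stored in the model.
* **Ties.** Assignment ties go to the lowest cluster index; mode ties
  to the lexicographically smallest category. Both are deterministic
  across platforms.
* **Empty clusters** are reseeded with the record farthest (in weighted
  dissimilarity) from its current prototype, so a fitted model always
  has k non-empty clusters.
* **Restarts** default to 10 (5 in the heavier examples here); the
  best-of-restarts cost is returned together with the within-run cost
  trace, which is non-increasing by construction (each assignment and
  each update step can only lower the objective).
* **k selection**: `elbow_scan()` reports the best-of-restarts cost for
  each k and suggests the k maximising the discrete second difference
  `cost[k−1] − 2·cost[k] + cost[k+1]`. To guarantee a monotone curve,
  each k also warm-starts one run from the best (k−1) model plus one
  extra prototype seeded at the worst-served record — an extra
  prototype can never raise the optimal cost, so best-of-restarts cost
  is non-increasing in k. The full curve is always returned: a knee
  criterion is a suggestion, not a decision; with a shallow elbow a
  human should inspect the curve (and may prefer a neighbouring k if
  the smaller k yields profiles too broad to interpret).

Profiles are ordered by the within-cluster weighted mean of
economic + health indicators (ties: economic mean, then cluster id),
rank 1 = least vulnerable. Post-shock populations are assigned with
`predict()` against the *pre-shock* prototypes — the profiles are held
fixed and only the population moves between them. Refitting after the
shock would conflate changed profiles with changed membership;
sensitivity analyses that refit should do so explicitly.

## 4. The pandemic shock

The shock is a deterministic rule cascade on raw variables. The
sequence defines *eligibility*; all *edits* happen simultaneously on
the pre-shock snapshot:

1. **Chronic trigger** (`chronic ≥ 1` by default): employed chronic
   sufferers become unemployed, and chronic sufferers' self-perceived
   health worsens to `fair` if currently better. The trigger count is
   deliberately decoupled from the indicator's ≥ 2 vulnerability
   cutoff: one chronic condition already carries elevated pandemic
   risk, while the indicator's threshold follows the comorbidity
   literature.
2. **Sector job loss**: employed persons with occupation-code prefixes
   in the shock set (default 51/52 — personal services and sales, i.e.
   tourism and retail) become unemployed.
3. **Economic knock-on** for the *newly* unemployed: financial distress
   is set to 2 ("some difficulty") if they previously made ends meet
   easily, and food-frequency codes drop to (1, 1) if consumption was
   not yet vulnerable — the minimal edits that flip each binary, chosen
   fixed for determinism.
4. **Mental-health knock-on**: the newly unemployed who are (post-step
   3) both distressed and consumption-vulnerable, and the chronic
   sufferers whose health perception actually worsened in step 1, get
   `lifehap = never`, `eurod = max(eurod, 5)`, `lifesat = min(lifesat,
   6)` — again minimal raw-variable edits, so the ordinary indicator
   pipeline re-scores shocked data without any special path.

Consequences that are enforced as invariants: no rule ever decreases a
subindicator; applying the shock twice equals applying it once (every
rule sets a state that disables its own precondition); and the audit
trail (fired rules + field diffs per person) reconstructs the record
diff exactly. Job-loss rules apply only to the employed by default —
in a 50+ population retirees dominate and cannot lose a job — but this
is a flag (`apply_to_employed_only`) because other populations may
warrant the broader reading. BMI is *not* shocked: weight change is a
plausible pandemic effect but has no operative rule in this cascade,
and silently inventing one would change the health indicator's
interpretation.

## 5. What the synthetic generator emulates — and what it does not

`generate_microdata()` exists so the full pipeline is exercisable
without access-restricted survey data. It emulates:

* **Scale and design**: near-equal national sample sizes across 17
  countries in 4 regions; lognormal weights ratio-calibrated per
  country so weight sums match national 50+ population totals exactly
  (the real calibration is a logit specification against demographic
  margins — only its *effect*, matching totals, is emulated).
* **Regional heterogeneity**: each region has its own subindicator
  prevalence vector (defaults follow the published regional ordering of
  European survey data: the eastern archetype dominates the Nordic one
  on every health subindicator, with financial distress by far the most
  prevalent economic deprivation everywhere), an income level, an
  employment rate and a tourism/retail share.
* **A planted latent structure**: four profiles with mixing proportions
  ¼ each. A profile scales every subindicator component probability by
  a severity multiplier (0.30, 0.75, 1.25, 1.70 by default), clipped at
  1 with the excess redistributed so the *regional* mixture mean stays
  exactly at the archetype prevalence — the profile structure and the
  regional prevalences are planted simultaneously, not traded off. Each
  profile also has modal demographics (e.g. the most vulnerable
  profile: single women in their seventies with at most 9 years of
  education), shown with probability 0.85. These two defaults — the
  multiplier spread and the 0.85 concentration — *are* the documented
  default separation at which the planted four-profile structure is
  recoverable by the weighted clustering (adjusted Rand index ≥ 0.7)
  and visible to the elbow criterion; they were fixed once as part of
  the generator's design.
* **Self-consistent poverty**: poor incomes are drawn well below, and
  non-poor incomes well above, 60% of the country's design median, with
  the non-poor distribution pinned so that its mixture median sits at
  the design median. Thresholds computed from the generated data
  (`generate_thresholds()`) therefore land near the design value and
  reproduce the planted poverty prevalence; the density gap around the
  threshold keeps median noise from flipping classifications at
  moderate national sample sizes.
* Raw variables are synthesised backwards from the binary component
  states (e.g. a mentally-vulnerable draw yields EURO-D in 5–12,
  life satisfaction in 0–6), with fixed within-class distributions.

It does **not** emulate: item nonresponse or imputation, panel
structure, interview-mode effects, realistic within-class raw-variable
distributions (only the binarized margins are calibrated), correlation
between components beyond what the shared profile induces, or
age-dependence of employment and health beyond the profile
demographics. Passing the recovery tests therefore shows the *pipeline*
is correct and well-conditioned at survey scale — not that real data
carry a four-profile structure this clean. `planted_moments()` exposes
the exact per-region means and per-record variances implied by a
configuration, which is what the prevalence-recovery tests compare
against (within 3 Monte-Carlo standard errors of the weighted mean).

## 6. Numerical conventions and problem sizes

* Weighted-quantile searches guard the cumulative-weight comparison
  with a `1e-12` slack so exact atoms are not skipped by floating-point
  undershoot; equality tolerances in invariant checks are `1e-9`.
* Degenerate inputs fail loudly: empty samples, non-positive weights,
  countries without thresholds, k above the number of distinct records,
  all-constant blocks in λ estimation (which suggest supplying λ
  explicitly).
* JSON artifacts are written with full numeric precision
  (`digits = NA`); CSV round-trips are exact on doubles.
* The pipeline manifest records the configuration (minus the output
  location), the package version and the MD5 of every artifact, so a
  run is reproducible from its manifest alone.
* Default analysis sizes used throughout the documentation and tests:
  n = 20,000 records for prevalence and indicator summaries (a
  desk-scale stand-in for a ~73k-respondent survey wave), n = 5,000 ×
  3 seeds for planted-profile recovery, and exhaustive enumeration at
  n ≤ 8 for clustering optimality oracles. These sizes keep every
  statistical check well-powered while the whole suite runs in minutes
  on one core.

## 7. Known limitations

* The weighted k-prototypes objective is non-convex; restarts mitigate
  but do not eliminate local minima. The tiny-instance oracle quantifies
  this: with 20 restarts the global optimum is reached in ≥ 90% of
  random instances, not all.
* The elbow suggestion uses a single second-difference statistic;
  on cost curves without a sharp knee it can be unstable between
  adjacent k — which is why the full curve is part of the return value.
* Variance estimation assumes single-stage independent weighted
  sampling; clustered or stratified designs need external machinery.
* The shock is a scenario, not a forecast: rule thresholds
  (chronic trigger, sector set) are stylised and configurable, and no
  probabilistic infection process is modelled.
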