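---
title: "Age-stratified signal detection in spontaneous adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-stratified signal detection in spontaneous adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersage)
library(data.table)
```

## The problem

Spontaneous adverse-event reporting systems such as FAERS collect
post-marketing reports of suspected drug toxicity. They have no denominator
population, so incidence is not estimable; what *is* estimable is
disproportionality — whether an event is reported more often with a drug
than with everything else. `faersage` implements a complete
disproportionality workflow for the question of how the toxicity profile of
the CDK4/6 inhibitors (palbociclib, ribociclib, abemaciclib) in women with
breast cancer shifts across older age strata: report ingestion,
deduplication, cohort construction, mapping of reaction terms to
Standardised MedDRA Queries (SMQs), reporting-odds-ratio (ROR) screening,
and an age-stratified logistic-regression cascade producing adjusted odds
ratios (aORs).

Because the statistical machinery is only trustworthy if it can be checked
against known truth, the package treats its synthetic FAERS-like generator
as a first-class module: every downstream stage is validated against
effects that the generator plants on (drug, SMQ, age-group) triples.

## The pipeline stage by stage

### Deduplication

FAERS distributes successive versions of the same case under one `CASEID`
with distinct `PRIMARYID`s. Following FDA guidance, `deduplicate()` keeps,
per `CASEID`, the report with the latest `FDA_DT`, breaking date ties by
the higher `PRIMARYID`. A missing `FDA_DT` sorts lowest — a dated version
always supersedes an undated one; this convention is ours, since the
guidance does not address it. The operation is idempotent and independent
of input row order, and the remaining five tables are filtered to the
surviving versions.

### Cohort construction

`build_cohort()` retains reports that are female; carry a primary-suspect
drug normalizing to a CDK4/6 inhibitor; have a breast-cancer indication;
have a reported age in [18, 100] years after unit normalization
(`YR`/`DEC`/`MON`/`WK`/`DY`/`HR`, with the week and hour divisors 52.1775
and 8766); and fall in the 2015-01-01 to 2025-03-31 receipt window. Each
exclusion is tallied under the first failing filter. A case with two
*distinct* CDK4/6 inhibitors as primary suspects is excluded as
`ambiguous_exposure`: per-drug models need a single exposure assignment,
and such records cannot support one. Indication matching prefers the
primary-suspect drug's own `INDI` rows (linked by drug sequence number) and
falls back to any indication on the case, tolerating the linkage gaps
common in FAERS.

Age strata are `<65`, `65–74`, `75–84`, `≥85`. The three adjustment
covariates — concomitant endocrine therapy, chemotherapy, and other
targeted therapy — are set only by drug rows with co-administration roles
(secondary suspect, concomitant, interacting), matched through an editable
ingredient lexicon shipped with the package. Immune-checkpoint co-exposure
is tallied descriptively but is not a model covariate, since the cascade
adjusts for exactly three co-medication classes plus age.

### SMQ mapping

SMQs group MedDRA preferred terms (PTs), possibly hierarchically, with
each term carrying narrow or broad scope. `expand_smq_hierarchy()` rolls
descendants' terms up into their ancestors, preserving child scope (narrow
dominating when a term reaches an SMQ by several paths), and
`map_case_smqs()` flags a case at most once per SMQ. The default scope
policy uses the full (narrow + broad) term set; a `narrow` policy is
available, since published analyses vary in which convention they use and
the workflow should be able to reproduce either. Boolean-algorithm SMQs
(category A/B/C combinations) are out of scope. The official MedDRA
dictionary is licensed, so the package ships a small fictitious
12-SMQ/54-term dictionary in the same tabular layout; the loader accepts
any file pair in that layout, including exports of a licensed MedDRA
installation.

### Disproportionality screen

For each drug–SMQ pair the 2×2 table contrasts the drug's cohort with a
comparator universe, by default every deduplicated report *not* in that
cohort ("rest of database"); a `within_cohort` option restricts the
comparison to the breast-cancer cohort itself. Then

\[
\mathrm{ROR} = \frac{a\,d}{b\,c}, \qquad
\mathrm{CI}_{95} = \exp\!\left(\ln \mathrm{ROR} \pm z_{0.975}
\sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\right),
\]

with the Haldane–Anscombe correction (+0.5 to all four cells, flagged)
whenever a raw cell is zero, keeping every table computable. A pair is a
*signal* when the lower bound strictly exceeds 1. Pairs with fewer than
`min_case_count = 3` exposed events are reported as `insufficient` rather
than estimated. The screen deliberately applies no multiple-testing
correction — it is a sensitivity-first triage stage — but a
Benjamini–Hochberg column is emitted for users who want it.

### The regression cascade

Signals feed a per-drug univariate→multivariate logistic cascade. Each
co-medication covariate is screened alone; it enters the multivariate
model iff its Wald p-value is strictly below 0.05. The age block (three
dummies against the `<65` reference) is tested by likelihood ratio — a
block-level test avoids the ambiguity of judging three dummy p-values —
and is included in every model by design regardless of its p-value. A
`dummy` mode is available because term-wise testing is the other defensible
reading. Pairs with fewer than 60 outcome events in the drug's cohort are
skipped (the ten-events-per-variable rule with six modelled variables);
the count is per drug cohort, since that is where the model is fitted.

The fitter is iteratively reweighted least squares on the exact Bernoulli
likelihood: convergence when the maximum absolute score drops below
`tol = 1e-8` or the relative log-likelihood change does, within 100
iterations; rank-deficient columns (constants, collinear dummies, empty
strata) are dropped and recorded; a coefficient beyond 15 on the log-odds
scale with a non-vanishing gradient raises a separation flag instead of
returning a silent estimate. Wald intervals and p-values are reported per
term; the tests cross-check coefficients against an independent
Newton–Raphson solver and against `glm`, and the saturated single-binary
fit against the closed-form 2×2 odds ratio.

## What the synthetic generator emulates

`generate_bundle()` draws unique cases with one primary-suspect exposure
drug (three CDK4/6 inhibitors inside a 30% exposure share, a background
pool forming the comparator), age strata, sex, co-medication rows,
indication rows, therapy start dates, onset-lagged event dates, outcome
and dechallenge codes, and a configurable fraction of superseded report
versions (same `CASEID`, earlier or tied `FDA_DT`, lower `PRIMARYID`,
perturbed age — so dedup mistakes are observable). Reactions are drawn
per SMQ: each case's probability of reporting SMQ $s$ is
$\operatorname{logit}^{-1}(\beta_{0s} + \delta_{d,s,g})$ where
$\beta_{0s}$ is the SMQ's baseline log-odds (default $\mathrm{logit}(0.08)$)
and $\delta$ the planted log-odds shift for the case's drug $d$ and age
group $g$. Because baseline and shift act on the same logit, the planted
value *is* the true stratum odds ratio, which is what makes exact recovery
oracles possible.

Default marginals follow the published descriptive profile of CDK4/6
inhibitor breast-cancer reports: age strata 45.8/31.0/18.8/4.4%, drug mix
77.2:12.8:10.0 within the exposed share, endocrine/chemotherapy/targeted
co-medication 42.8/0.8/1.2%, report-version duplication 10%, age
missingness 10%, 5% of ages coded in `MON`/`DY`/`DEC` units, onset delays
log-normal around a 73-day median. One seeded RNG drives all draws, so a
configuration is a complete specification of its bundle.

What the generator does **not** emulate: reporter behaviour and stimulated
reporting, report narratives, country and reporter-type fields, dosing,
drug–drug interaction structure, correlated events within a case beyond
the shared covariates, or FAERS's real (much sparser and dirtier) marginal
distributions. Passing recovery tests therefore demonstrates that the
*statistical machinery* is correct and calibrated, not that conclusions
from real FAERS extractions are unbiased — reporting bias and confounding
in real spontaneous data are untouched by any of this.

## Validation on planted truth

The test suite ships simulation checks at sizes chosen to keep the whole
suite within a few minutes on one core while leaving Monte-Carlo noise
well below the tolerances tested:

* **Null calibration** — 20 bundles of 50,000 cases with no planted
  effects (42 drug–SMQ pairs each): the strict lower-CI signal rule fires
  at the one-sided Wald error rate, ≈2.5%, within exact binomial 99%
  bounds.
* **Screen recovery** — a log(3) effect planted on one pair at 200,000
  cases: the screen's ROR lands within ±15% of 3 and is flagged, in at
  least 18 of 20 seeds.
* **aOR recovery** — stratum effects {1, 2, 3, 4} planted on one SMQ at
  100,000 cases, 40 seeds: mean aORs within ±15% of truth and 95% CI
  coverage within exact binomial bounds.
* **Closed-form oracles** — 10,000 random 2×2 tables (including zero
  cells) against an independent log-space evaluation to 1e-12; 50 random
  designs against an independent Newton solver to 1e-6.

## Numerical and degenerate-input choices

* Quantiles in descriptive summaries use R's default linear interpolation
  (type 7).
* Unknown age-unit codes and unparseable values yield missing, not errors:
  exclusion is an analysis decision, not a parse failure.
* `exposed = universe` produces a degenerate comparator; the table is
  constructed but `ror_wald()` refuses it with an explicit error.
* An empty cohort summarizes to an explicit empty table; an empty
  regression table is still written by the pipeline, which succeeds.
* The pipeline writes no timestamps, so identical inputs and configuration
  reproduce byte-identical outputs.

## Limitations

The shipped drug lexicon and indication term list are deliberately small,
editable stand-ins for the full WHO ATC L01 ingredient lists and a
complete breast-cancer PT list; real analyses should supply their own via
the `lexicon` and `indication_pts` options. Real FAERS quarters have more
columns than the six-table subset modelled here; extra columns are
ignored, not round-tripped. The headline case counts and effect estimates
of any specific published FAERS analysis depend on the full multi-million
report download and a licensed MedDRA dictionary, and are not reproducible
from the packaged fixtures; what this package reproduces is the method,
validated end to end on planted truth.
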