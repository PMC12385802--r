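---
title: "A risk-stratified prostate screening pathway: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A risk-stratified prostate screening pathway: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psascreen)
```

## The programme being modelled

`psascreen` models an organized, risk-adapted prostate cancer screening
programme of the kind Lombardy activated for men turning 50: voluntary
digital enrollment through a questionnaire, a free PSA test for eligible
men, and a multilevel pathway in which only men at elevated risk proceed
to resource-intensive steps. The package implements the programme's
decision rules exactly and surrounds them with a synthetic-cohort
generator, so every stage can be exercised, tested, and projected without
any individual-level data (which are not public; only aggregate tables
are).

The pipeline is: `generate_cohort()` (or a fixture) →
`triage_table()` → `run_pathway()` → `compute_metrics()` /
`category_table()`, with `scenario_grid()` and `compare_proportions()`
operating on scenario and count inputs directly, and `full_run()`
orchestrating everything into a written report bundle.

## Triage model

Eligibility follows the questionnaire logic: a "yes" to prior prostate
cancer or a known pathogenic high-risk mutation excludes a man
permanently; otherwise a "yes" to a PSA test within 2 years or a prostate
diagnostic procedure within 5 years defers him temporarily; "unknown" is
treated as "no" everywhere. Permanent exclusion dominates temporary when
both apply (the protocol does not state a precedence; permanence is the
only order under which re-eligibility labelling stays coherent).

First-level risk stratification combines PSA with first-degree family
history (FH):

| condition | category | recall |
|---|---|---|
| FH-positive, any PSA | refer to urology | — |
| PSA > 3.0 ng/mL | refer to urology | — |
| 1.0 ≤ PSA ≤ 3.0 ng/mL | intermediate | 2 years |
| PSA < 1.0 ng/mL | low | 5 years |

Boundary choices: referral is triggered only by PSA *strictly above*
3.0 ng/mL, so 3.0 exactly is intermediate; 1.0 exactly is also
intermediate — the conservative reading (shorter recall) of the 1–3 band,
whose endpoints the programme's documents describe both inclusively and
exclusively. Both thresholds live in `protocol_defaults()` rather than in
the code.

An FH-positive man whose PSA also exceeds 3.0 keeps a single category
(referral) plus a `psa_over_3` flag; summary tables count him in the
family-history row only, matching the programme's reporting convention.

## Specialist pathway

The second level is a small state machine. The urology visit has five
outcomes — routine surveillance with a 1-year PSA, MRI indicated, a direct
high-risk MRI+biopsy indication, refusal, and programme exit — sampled
from `pathway_probabilities()`. Defaults follow the frequencies observed
among the programme's first completed visits: 91% no concerning findings,
7% MRI indicated, with the small remainder split between refusal and
exit.

The MRI decision table combines PI-RADS v2 with PSA density
(PSA / MRI-estimated volume, ng/mL/cc):

* PI-RADS 4–5 → biopsy indicated;
* PI-RADS 3 → biopsy if density ≥ 0.10, otherwise follow-up at 1 year;
* PI-RADS 1–2 → surveillance at 1 year if density < 0.20, otherwise
  "consider biopsy" despite the negative scan.

The PI-RADS 3 density cut-off appears as both 0.10 and 0.15 in programme
documents; the operational rule lists use 0.10, so that is the default,
and it is a named constant (`density_biopsy`) rather than a resolved
question. "Consider biopsy" is kept as its own terminal state — the
protocol leaves it to clinical judgement, so the simulator does not
auto-convert it into a biopsy. Scans scoring PI-RADS ≥ 3 also produce a
urologist-reassessment event in the log, mirroring practice, without
adding a stochastic branch. The urologist's option to repeat PSA before
deciding is *not* in the state graph; it is a known simplification.
Biopsies, when indicated, return a positive result with a configurable
probability (default 0.30, the positivity assumed for MRI-targeted
biopsies); histological grading is out of scope — the model ends at a
terminal biopsy-result flag.

Every simulated run asserts conservation: referred men partition exactly
across terminal states.

## Synthetic cohort: what it emulates and what it does not

The generator reproduces the *statistical shape* of the activation-phase
cohort:

* **Uptake** 8.7% of the no-recent-PSA target population completes the
  questionnaire (passive invitation conditions).
* **Exclusions** ~29.1% of respondents in total; the published totals are
  consistent with essentially all of these being temporary, while the
  narrative says permanent exclusions were "<1%", so the defaults use
  28.6% temporary + 0.5% permanent.
* **Family history** 13.8% by default — the prevalence among tested men,
  which is what the downstream stratification consumes. The programme
  also reports 10.6% among all eligible respondents; the difference
  arises from FH-positive men completing testing more often, a selection
  the generator does not model (FH and test completion are sampled
  independently). Both values are documented on the argument.
* **PSA** a single log-normal, calibrated by
  `calibrate_psa_distribution()` so its CDF passes through the observed
  FH-negative category fractions at the two clinical thresholds:
  P(PSA < 1) = 824/1217, P(PSA < 3) = 1188/1217, giving
  μ = −0.332, σ = 0.722 on the log scale. The probit-linear solve is exact
  and unique; tests confirm it against an independent numerical fit and
  against Monte-Carlo quantiles at n = 100,000. FH-positive men draw from
  the same distribution (their PSA "was variable" and no separate
  distribution is reported); FH affects routing only.
* **Compliance** eligible men test within the 90-day authorization with
  probability 0.233; the untested split into pending and expired according
  to how much of the window remains at the data cutoff, with questionnaire
  dates uniform over the enrollment period.

Not emulated: age structure beyond the single-age cohort, longitudinal
PSA trajectories, geography beyond the health-authority label, the
FH/testing selection effect above, and seasonality in enrollment. Passing
calibration tests therefore shows the generator matches the programme's
*marginal* rates, not that it reproduces joint or temporal structure in
real data.

Determinism: a cohort is a pure function of its `cohort_config`,
including the seed; the pathway takes its own seed (derived from the root
seed in `full_run()`).

## Yield projection

Expected screen-detected cancers over one round are closed form:

$$E[\text{cases}] = n_{\text{screened}} \times \frac{\text{incidence}}{100{,}000}
  \times \text{interval} \times \text{sensitivity},$$

with `n_screened = floor(population × participation)` when derived from a
rate (flooring reproduces the published screened counts; the published
30%-scenario count is one man higher, consistent with rounding rather
than flooring there — expected cases agree to one decimal either way),
or supplied directly for an observed cohort. Yield per 1000 screened is
invariant to population size. Defaults: 2-year interval, 87% sensitivity,
registry-based incidence (97.6/100,000/yr for ages 50–69;
21.1/100,000/yr at age 50). The model is linear in every factor — it is
an operational benchmark for resource planning, not an outcome model: no
mortality, overdiagnosis, lead time, or number-needed-to-screen.

## Two-arm comparisons

Utilization comparisons (standard care vs screening) use the absolute
difference of independent proportions with the unpooled Wald interval,
no continuity correction:

$$\hat p_1 - \hat p_2 \pm z\sqrt{\hat p_1(1-\hat p_1)/n_1 + \hat p_2(1-\hat p_2)/n_2},
\qquad z = 1.96.$$

This method was identified by verifying that it reproduces all three
published intervals from the published counts; it is the package's
documented choice, checked in tests against a brute-force re-derivation.
Fractional event counts are accepted because the screening-arm counts are
pro-rata adjusted for episodes not yet completed; `adjust_events()`
mirrors that linear adjustment and is labelled approximate. One published
headline — a 25.9% relative reduction in urology consultations — is not
reproducible from the published counts (they give 26.2%, and
`relative_reduction()` reports 26); the package reports only computed
values.

## Numerical conventions

* **Rounding** of reported percentages is half away from zero
  (`round_half_up()`): one decimal for programme metrics, two for
  comparison percentages, nearest integer for relative reductions. This
  matches the programme's printed tables, with one knife-edge: the
  eligibility rate 6072/8558 = 70.951% rounds to 71.0 while the published
  table prints 70.9 (truncation there); the package rounds consistently.
  Because each category is rounded separately, a stratification's
  percentages sum to 100 ± 0.3.
* **Degenerate inputs**: zero denominators report zero rates in metrics
  (an inactive programme) but are errors in `arm_counts()` (a comparison
  without exposure is meaningless); an empty cohort flows through the
  whole pipeline producing empty, well-formed tables.
* **Problem sizes** in the tests: Monte-Carlo checks use 100,000-man
  cohorts for calibration (binomial error ≈ 0.15 pp at the 1 ng/mL
  quantile) and 10,000 draws for pathway frequencies, with fixed seeds;
  everything else is closed form or desk scale.

## The pilot fixture

`pilot_cohort()` is a deterministic synthetic table whose *margins* equal
the programme's published eight-month aggregates (respondents,
exclusions, compliance, the 824/364/29/195 stratification, per-authority
counts); PSA values are spread evenly within bands and dates are fixed.
It exists so the triage, metrics, and comparison stages can be verified
against the published tables end to end; no individual-level values in it
are real.

## Known limitations

Beyond the generator's simplifications listed above: branch probabilities
for the specialist pathway rest on very small observed counts (133
completed visits, 7 MRIs, 2 biopsies) and should be treated as
provisional; the yield model ignores repeat-round dynamics and interval
cancers; cost figures are pass-through multiplications and no
cost-effectiveness analysis is attempted; and the comparison of adjusted
utilization counts inherits whatever bias the pro-rata adjustment and the
missing private-sector activity introduce.
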