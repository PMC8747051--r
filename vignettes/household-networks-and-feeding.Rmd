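---
title: "Household kinship networks and child-feeding indicators: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Household kinship networks and child-feeding indicators: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinfeed)
```

## The problem and the data model

Complementary feeding — what and how often a 6–23-month-old child is fed
— happens inside a household, and the people who share that household
shape it: they feed the child, advise the mother, compete for food, or
bring in outside knowledge. `kinfeed` operationalises this idea on
standard household-survey rosters. The interviewed woman is the **ego**;
every other household member is an **alter**. The ego is tied to all
alters by construction (they live together); ties *among* alters are
inferred from kinship alone, because a DHS-style roster records only
each member's relationship to the household head.

Two table types drive everything (see `?"roster-dialect"`): a
member-level roster (relationship code, sex, age, education, de jure /
de facto status, respondent flag, plus survey design columns) and a
child-level feeding recall (eight food-group flags and previous-day
feed counts). Both are plain CSV (or Parquet) with a published column
dictionary; all functions take and return tibbles.

## Kinship ties

Alter–alter ties carry the coefficient of relatedness: 0.5 for
parent–child and full siblings, 0.25 for grandparent–grandchild, 0.125
for nephew/niece-type links, 0 for pairs not related by blood
(in-laws, adopted/foster/step members, non-relatives). Raw coefficients
are divided by 0.5, so tie weights live on {1, 0.5, 0.25, 0} and the
strongest kin tie has weight 1 — Burt's measures work with tie
*proportions*, and this normalisation makes the printed endpoint
contracts (clique → constraint 1, ES 1) hold exactly.

Because relationship-to-head codes under-determine some pairs (is the
head's grandchild the child of *this* son or another?), the package
ships an explicit 13 × 13 rule table
(`inst/extdata/relatedness_v1.csv`, `relatedness_table()`) that
resolves every pair deterministically. The defaults for ambiguous pairs
take the grandparent-type value 0.25 (e.g. child × grandchild, sibling
× niece/nephew, two grandchildren) or the niece-type value 0.125 (e.g.
child × sibling, cousins); any pair involving a non-relative, an
adopted/step member or an unspecified code scores 0. The table is a
*contract of this package*, not a fact about any particular pedigree;
it can be overridden by supplying a CSV of the same layout, and an
optional `marriage_ties` switch additionally ties the two
code-identifiable spouse pairs (head–spouse, child–child-in-law) at
weight 1 for analyses that treat marriage as a bond rather than a hole.
Alters default to de jure members (usual residents), switchable to de
facto.

## Structural measures and their conventions

All measures are computed on the weighted ego network (ego row all
ones) and restricted to the alters. With `p` the row-proportional tie
strengths and `m_jq` alter j's tie to q scaled by j's strongest tie:

* **effective size** `ES = Σ_j [1 − Σ_q p_iq m_jq]`, the number of
  non-redundant kinship contacts, in [1, degree];
* **constraint** `C = Σ_j c_j`, `c_j = (p_ij + Σ_q p_iq p_qj)²`;
* **hierarchy** is the Coleman–Theil concentration
  `Σ_j (c_j/c̄) ln(c_j/c̄) / (N ln N)` of the dyadic constraints;
* **density** is the mean alter–alter weight; **efficiency** is
  `ES/degree`.

Raw Burt constraint does not meet the conventional 0/1 endpoints: an
empty alter graph gives `1/n` and small complete cliques can approach
0.6, not 1. The package therefore also reports a per-degree affine
rescaling, `C' = (C − C_empty(n)) / (C_complete(n) − C_empty(n))`
clamped to [0, 1], where the reference values are computed by running
the same constraint code on the empty and complete alter graphs of the
same degree. Both columns (`constraint_raw`, `constraint`) are kept:
the rescaled one satisfies the endpoint contract; the raw one is what
classical ego-network software prints, and it is the scale on which
survey-typical households cluster in the 0.44–0.65 band (a complete
clique of 3–6 alters has raw constraint 0.593–0.463). The package's own
calibration checks therefore compare the *raw* median against that
band, while endpoint contracts are asserted on the rescaled metric.

Degenerate inputs follow documented conventions: degree 1 gives ES 1,
rescaled constraint 1, hierarchy 0, density 0. At degree 2 the raw
constraint is algebraically blind to the single alter–alter tie (the
indirect-path sum is empty), so the affine rescaling is 0/0 there; the
rescaled value is defined as the single tie weight, which meets both
endpoints. Floating-point drift at the ES endpoints (a complete clique
can evaluate to 1 ± 1e−16) is snapped to the exact bound within 1e−10.

Effective size is dichotomised at 3 (`classify_effective_size()`,
`high` iff ES > 3), the survey-typical median; the cutoff is an
argument. Because the six measures overlap, `reduce_structural_set()`
offers a principal-component reduction: Kaiser criterion (eigenvalue
> 1, with a 1e−8 numerical epsilon) on the correlation matrix, keeping
per qualifying component the variable with the largest absolute
loading, ties broken by a fixed variable order. When no component
qualifies — uncorrelated inputs carry no structure worth summarising —
the function falls back to the conventional trio {degree, effective
size, constraint}. The retention rule is a design choice of this
package; nothing downstream depends on it.

## Compositional measures

The index of qualitative variation `IQV = K/(K−1)(1 − Σ p_k²)` is used
for sex (K = 2), education (K = 2) and kinship category (K = 12 by
default). `K` is the *codebook* category count, not the observed count:
this keeps single-category households defined (IQV 0) and makes
diversity comparable across attributes with different numbers of
categories. Values are clamped to [0, 1] (observing more than K
categories can push the unclamped value marginally above 1). Age
diversity is the sample SD of alter ages (n − 1 denominator; one alter
gives 0). The respondent's own attributes are excluded throughout —
these variables describe her network, not her.

Residence turnover gives two more IQVs: de jure diversity (usual
resident vs visitor, over all listed members) and de facto diversity
(slept here vs away, over usual residents). Both are heavily
zero-inflated in household data, so they are dichotomised by a
*weighted median split* computed on the analysis cohort — per survey
round by default (`diversity_flags()`), poolable by argument. With ~85%
zeros the median is 0 and the flag marks any positive diversity, which
is the behaviour the tests pin down.

## Outcome coding

`code_mdd()` sums the eight food-group flags (breast milk counts as a
group; a 7-group variant without it uses the 4-group cut) and applies
the 5-of-8 rule; any missing flag makes the outcome missing, and
missing outcomes are counted, not silently dropped. `code_mmf()`
applies the 2/3/4 rule described above and is only defined for ages
6–23 completed months. `apply_round_availability()` masks indicators in
rounds whose questionnaires lacked the items — by default MDD in the
2000 round and MMF in 2005; the map is configurable because the
source descriptions of round availability are not fully consistent, and
the conservative reading (mask both) is taken as the default.

Eligibility (`select_eligible()`) keeps last-born children aged 6–23
completed months in households with a completed respondent. The upper
bound is configurable; 23 completed months is the default because the
meal-frequency age bands end there, making "6–24 months" operationally
6–23.

## Estimation

Per-round models are logistic regressions fit by IRLS with sampling
weights normalised to mean 1 and robust sandwich variance clustered on
the primary sampling unit — the standard design-based approximation
when a full survey-design object is unnecessary. Listwise deletion is
counted; coefficients above 15 in absolute value raise a separation
flag; categorical covariates that collapse to a single level in a
subset (common in small rounds) are dropped from that fit and recorded
in `dropped_terms` rather than crashing the design matrix.

The pooled model adds a random intercept per survey round, integrated
by adaptive Gauss–Hermite quadrature (15 nodes by default; Laplace
fallback with a warning if quadrature fails). With only 3–4 rounds the
variance component is boundary-prone; a near-zero estimate sets
`re_boundary = TRUE` instead of failing, and the fixed effects then
coincide with the plain pooled logistic. Sampling weights enter the
pooled model, when requested, as normalised pseudo-likelihood scaling;
because survey practice is divided on weighting cluster-level random
effects, the suite emits both the weighted (`overall`) and unweighted
(`overall_unweighted`) pooled fits. `marginal_loglik_grid()` evaluates
the same marginal likelihood by dense trapezoid integration and is the
cross-check used in the tests (agreement to 1e−4 on a 90-observation
fixture).

Average marginal effects are discrete: for a continuous exposure, the
mean change in predicted probability when each observation's value is
shifted up by one weighted SD (not a derivative times SD — the discrete
shift matches how the effect is described to practitioners); for a
categorical exposure, the mean change from the reference level.
Intervals are delta-method with the fit's robust (or model-based, for
mixed fits) coefficient variance; mixed-model predictions set the
random intercept to zero.

`run_association_suite()` ties it together: per outcome × exposure, one
model at a time (the exposures are correlated by construction), crude
and adjusted per round, pooled overall, and the AME, with significance
stars at 0.05/0.01/0.001 and outcome-rounds masked by design reported
as unavailable. `run_pipeline()` adds the weighted descriptive table
(mean ± SE for approximately normal variables, median (Q1, Q3)
otherwise, weighted percentages for categories), the exclusion-flow
log, and a manifest with configuration and checksums; two runs with the
same configuration and seed write identical tables.

## What the synthetic generator emulates — and what it does not

`generator_config()` defaults describe a plausible four-round national
survey of households with one eligible last-born child each: round
shares (0.30/0.13/0.28/0.29) and per-round urban fractions
(6.6%–37.6%) proportioned like the published analytic samples; rural
households predominantly three-generation (eldest couple, married sons,
sons' wives — one of whom is the respondent — and grandchildren), urban
households predominantly nuclear; "peripheral" members (fostered
relatives' children, nieces/nephews, step children, hired help) drawn
on top, because surveyed rosters are never pure kin cliques; visitor
and absentee rates of 2.5% and 3.2% per member chosen so that roughly
10–15% of households show residence-turnover diversity; log-normal
weights (σ_log = 0.35, mean 1) and block cluster ids to exercise the
clustered variance. Outcomes are drawn from a logistic model on
standardised exposures with per-round intercepts matched to the
published indicator prevalence pattern (MDD ≈ 4–12% depending on round,
MMF ≈ 44–50%) and default exposure effects in the direction the
substantive literature reports (constraint raising both indicators,
degree lowering meal frequency). These archetype and size choices were
fixed once, from a design-space exploration of what reproduces the
published structural medians (median degree 5; median raw constraint in
the 0.44–0.65 band), and are asserted — not tuned — by the calibration
tests.

The generator deliberately does **not** emulate: the true two-stage
sampling frame and regional strata (clusters are synthetic blocks),
polygynous or female-headed household structures, item non-response,
age heaping, seasonality of diets, or any correlation between wealth
and network structure. Passing tests on synthetic data therefore show
that the *pipeline* is correct and well-calibrated under the stated
conditions — they do not reproduce, and cannot be compared against, the
restricted survey's substantive estimates.

## Problem sizes used by the checks

The oracle-equivalence suites run 1,000 random networks of degree ≤ 8
and 1,000 random multisets; the IYCF coder is enumerated over all 2⁸
food-group patterns and every (age, breastfeeding, feed, solid-feed)
cell; parameter recovery and CI coverage use 500 replicated outcome
draws on a fixed 1,500-household design; the mixed-model likelihood
cross-check uses 3 rounds × 30 observations; generator calibration uses
one 2,000-household run at default settings. These sizes keep every
quantity's Monte-Carlo error comfortably below the asserted margins.

## Known limitations

Kinship inference is pairwise code lookup, not pedigree reconstruction:
within-code heterogeneity (full vs half siblings, whose child a
grandchild is) is invisible and resolved by the published defaults.
The rescaled constraint is a per-degree affine transform, so its values
are comparable across households only in the sense of the 0/1 contract,
not as raw Burt scores (both are reported). Random-intercept variance
estimated from 3–4 rounds is intrinsically noisy and often on the
boundary; treat `re_sd` as descriptive. The AME delta-method intervals
assume approximate normality of the coefficient estimator, which can be
optimistic under separation — separation is flagged on the fit for
exactly that reason.
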