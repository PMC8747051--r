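# kinfeed

Household social networks and complementary feeding practices.

`kinfeed` asks how the *structure* and *composition* of the household a
young child grows up in relate to whether that child is fed adequately.
It treats the interviewed woman in a household survey as the centre
(ego) of a personal network whose alters are her co-resident household
members, derives the ties among those alters from their kinship, and
relates the resulting network variables to the two WHO infant- and
young-child-feeding indicators:

* **MDD** (Minimum Dietary Diversity): the child consumed ≥ 5 of 8 food
  groups the previous day;
* **MMF** (Minimum Meal Frequency): age- and breastfeeding-specific
  minimum daily feeds (2 for breastfed 6–8 months, 3 for breastfed 9–23
  months, 4 including ≥ 1 solid feed for non-breastfed children).

Because household rosters record each member only by their relationship
to the household head, alter–alter ties are scored through a published
coefficient-of-relatedness rule table (r = 0.5 parent–child/sibling,
0.25 grandparent–grandchild, 0.125 niece/nephew, 0 unrelated),
normalised so the strongest kin tie has weight 1. On the weighted ego
network Z the package computes Burt's structural-hole measures over the
alters:

* degree *n* (number of alters),
* effective size `ES = Σ_j [1 − Σ_q p_iq m_jq]` ∈ [1, n],
* aggregate constraint `C = Σ_j (p_ij + Σ_q p_iq p_qj)²` — reported raw
  and affinely rescaled per degree to [0, 1] so that an all-unrelated
  alter set scores 0 and a complete nuclear-family clique scores 1,
* density, efficiency `ES/n`, and the Coleman–Theil hierarchy of the
  dyadic constraints,

plus the compositional diversity of the alters: the index of
qualitative variation `IQV = K/(K−1) · (1 − Σ p_k²)` for sex, education
and kinship category, the age SD, and median-split de jure/de facto
(visitor/absentee) diversity flags.

Associations are estimated the way household-survey analysts do it:
per-round survey-weighted logistic regression with cluster-robust
(sandwich) standard errors, a pooled multilevel logistic model with a
random intercept per survey round (adaptive Gauss–Hermite quadrature),
and average marginal effects — the mean change in predicted probability,
in percentage points, for a +1 SD shift of a continuous exposure or a
reference-to-level change of a categorical one, with delta-method
intervals.

Real DHS microdata are access-restricted, so the package ships a
calibrated synthetic generator (`simulate_survey()`) producing
DHS-like rosters — three-generation rural and nuclear urban household
archetypes, visitors and absent members, two-stage-style clusters and
log-normal weights, and outcomes drawn from a configurable logistic
model — so every stage of the pipeline is testable end to end.

## Worked example

```r
library(kinfeed)
library(dplyr)

svy <- simulate_survey(generator_config(n_households = 800, seed = 2024))
tab <- build_analysis_table(svy)   # eligibility + metrics + outcomes

tab |> select(household_id, round, degree, effective_size,
              constraint, constraint_raw, mmf_met)
#> # A tibble: 800 × 7
#>   household_id round degree effective_size constraint constraint_raw mmf_met
#> 1 hh00001      2016       5           4.4       0.374          0.367 ...
#> 2 hh00002      2005       6           4.75      0.479          0.355 ...
#> 3 hh00003      2011       4           2.5       0.646          0.583 ...

suite <- run_association_suite(tab, outcomes = "mmf_met",
                               exposures = c("constraint", "es_class"))
format_association_table(suite)
#>   outcome exposure   term         ... overall_aor           marginal_effect_pct
#> 1 mmf_met constraint constraint   ... 8.67*** (3.24, 23.15) 8.36 (4.82, 11.90)
#> 2 mmf_met es_class   es_classhigh ... 0.54*** (0.40, 0.74)  -14.94 (-22.41, -7.48)
```

Reading the output: each row is one exposure analysed in its own model
(crude and covariate-adjusted odds ratios per survey round, a pooled
random-intercept adjusted odds ratio across rounds, stars at
0.05/0.01/0.001). Here the generator was configured so that closer-knit
kin networks raise meal frequency: a 1 SD increase in constraint raises
the probability of meeting MMF by 8.4 percentage points (95% CI 4.8,
11.9), while high effective size (> 3 non-redundant kinship contacts)
lowers it by 14.9 points. `autoplot(suite)` draws the forest plot;
`describe_cohort(tab)` produces the weighted participant-characteristics
table and `eligibility_flow(tab)` the exclusion cascade.

On the default generator settings the synthetic cohorts reproduce the
survey-typical structure: median degree 5 and median raw Burt
constraint ≈ 0.54.

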