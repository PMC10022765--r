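# rqit

Scoring the importance of clinical research questions, and the statistics
used to build and validate such scoring instruments.

Clinical trial networks have to decide which proposed studies deserve
scarce funding and platform support. The ANZMUSC Research Question
Importance Tool (ANZMUSC-RQIT) reduces that judgement to a transparent
multi-attribute score: a research question is described by choosing one
level in each of five dimensions — (A) stakeholder importance, (B) patient
burden, (C) social burden, (D) anticipated intervention effect, (E) health
equity — and its score is the sum of calibrated *element utilities*

> S(profile) = Σ_d u(e_d),   scaled so S ∈ [0, 1000],

with a standard error propagated through the joint uncertainty of the
utility estimates,

> SE² = Σ_e Σ_e′ ρ_(e,e′) σ_e σ_e′

over the 25 ordered pairs of the profile's five elements. The utilities
were calibrated from a best-worst scaling survey fitted with Thurstone's
paired-comparison probit model.

The package ships the published utility table and implements the whole
methodological pipeline so the calibration and validation can be rerun,
audited, or applied to new instruments:

- **Scoring** — `score_profile()`, `propagate_profile_se()`,
  `anzmusc_rqit()` (the packaged 18-element utility table with its
  correlation matrix).
- **Best-worst scaling** — `generate_tasks()` (anti-chain choice-task
  designs over dimension pairs), `allocate_blocks()`,
  `expand_comparisons()` (best/worst answers → implied paired
  comparisons), `fit_bws()` (Thurstone probit, common or
  respondent-specific dispersions, sum-to-zero identification),
  `rescale_fit()` (0–1000 utility table with standard errors).
- **Agreement** — `icc_two_way()` (two-way random-effects, absolute
  agreement), `gwet_ac2()`, `modal_agreement()`, `committee_icc()`.
- **Delphi analytics** — `disagreement_index()` (RAND/UCLA),
  `select_for_rerating()`, `theme_contributions()`.
- **Validity analytics** — `unweighted_rqit_score()` (0–18 sum),
  `cramers_v()`, `tertile_logistic()`, `citation_regression()`.
- **Simulators** — `simulate_bws_responses()`, `simulate_ratings()`,
  `simulate_articles()` generate every input the pipeline needs, with
  known truth, for testing and power exploration.

## Worked example

```r
library(rqit)
tab <- anzmusc_rqit()

# a question important to all stakeholders (A4), mild-symptom condition
# (B1), common condition (C3), potentially curative treatment (D3), no
# equity consideration (E1):
score_profile(c("A4", "B1", "C3", "D3", "E1"), tab)
#> Profile (A4, B1, C3, D3, E1): score 582 (SE 12.44)
```

582 sits in the upper-middle of the 0–1000 scale: 0 is the profile of
minimal importance (every dimension at its lowest level), 1000 the highest
profile (A4, B3, C4, D3, E4). The SE reflects the sampling uncertainty of
the calibrated utilities (the published table rounds utilities to
integers, so an SE recomputed from it differs slightly from one computed
from unrounded internals).

Recalibrating from (simulated) survey data end to end:

```r
design <- generate_tasks(tab)                       # 73 anti-chain tasks
resp <- simulate_bws_responses(design, tab$utilities / 250,
                               n_respondents = 200, seed = 1)
fit <- fit_bws(expand_comparisons(resp, design), tab, model = "2b", seed = 1)
rescale_fit(fit)                                    # new 0-1000 table
```

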