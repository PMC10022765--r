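---
title: "Methods behind rqit: scoring, calibration and agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind rqit: scoring, calibration and agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rqit)
```

This vignette is the package's own account of the statistical machinery it
implements: the additive utility model behind the 0–1000 research-question
importance score, the Thurstone paired-comparison estimator that calibrates
it, the agreement and Delphi statistics used during instrument development,
and the simulators the test suite relies on. It also records the design
decisions taken where more than one defensible convention exists.

## The additive scoring model

An instrument is a list of dimensions, each with ordered levels; a
*profile* picks one level (an *element*) per dimension. The ANZMUSC-RQIT
has five dimensions with 4, 3, 4, 3 and 4 levels — 18 elements, 576
profiles. The model is additive on an interval scale:

$$S(\text{profile}) = \sum_{d} u_{e_d},$$

with the identification convention that the lowest level of every
dimension has utility 0 and the highest profile scores 1000. The zero
point therefore means "minimal importance", not "no importance"; the unit
is arbitrary. Additivity is a modelling assumption, not a finding: it
implies no interactions between dimensions (e.g. the value of a curative
treatment is the same for rare and for highly prevalent conditions). The
choice-task design below is built so that this assumption is at least
internally consistent with how the data are collected — both options in a
comparison always share the levels of all non-varied dimensions.

The score's standard error treats the 18 utility estimates as jointly
normal with standard errors $\sigma_e$ and correlations $\rho_{e,e'}$ (the
packaged table carries both) and propagates them through the sum:

$$\mathrm{SE}^2 = \sum_{e} \sum_{e'} \rho_{e,e'}\, \sigma_e \sigma_{e'}$$

over the 25 ordered pairs of the profile's five elements. The correlations
matter: calibration makes within-dimension estimates strongly negatively
correlated, so ignoring them would overstate the SE considerably. No
respondent-level (committee-level) rating uncertainty is included; this is
the sampling error of the calibration survey only. The packaged table
stores the published integer utilities, so the worked example in the
README reproduces exactly; recomputing the worked-example SE from those
rounded entries gives ≈ 12.44, slightly below the published 13.46 which
was computed from unrounded internals. Fitted tables produced by
`rescale_fit()` keep full precision so their scale anchors are exact.

## Best-worst choice-task designs

Each choice task shows three options built from the same two dimensions.
The default *anti-chain* rule takes three distinct levels of each
dimension and pairs them in opposite orders — e.g. (A1,B3), (A2,B2),
(A3,B1) — so that whenever within-dimension utilities are increasing, no
option dominates another coordinate-wise and the two dimensions rank the
options in exactly opposite orders. This forces every answer to trade one
dimension off against the other. `generate_tasks()` enumerates all
rule-conforming triples over all dimension pairs: 73 tasks for the
ANZMUSC-RQIT structure. The catalogue used for the original survey was
assembled by a related but not fully published rule, so the rule here is
pluggable (`rule =` accepts a function) and the task count is exposed as
data, not asserted. A dimension with only two levels cannot provide three
distinct levels for its side; the rule then relaxes to one repeated level
on that side, with a message.

`allocate_blocks()` reproduces blocked administration: a small set of
common tasks that everyone answers plus, in partition mode (the default),
disjoint random shares of the remaining tasks. Partitioning is the natural
reading of "a random selection of k tasks" when the non-common tasks
divide evenly among the blocks; non-partition sampling is available.
Option display order is shuffled per block and task, a standard
discrete-choice guard against position effects. All allocation randomness
is seeded and restorable.

## From best-worst answers to Thurstone's model

A best-worst answer to a three-option task implies the full ranking
best ≻ middle ≻ worst, hence three paired comparisons (best ≻ middle,
best ≻ worst, middle ≻ worst); a single-ended answer implies two. Counts
are exact by construction: $3 n_\text{both} + 2 n_\text{single}$.

Thurstone's model treats an option's perceived utility as its true utility
plus normal perception error with respondent standard deviation $s_r$ (the
standard error of measurement, SEM). With independent errors on the two
options of a comparison,

$$P(\text{winner} \succ \text{loser}) =
  \Phi\!\left(\frac{U_w - U_l}{s_r\sqrt{2}}\right),$$

where $U$ is the sum of the option's two element utilities. The
independence default is a choice: a shared error component between the two
options of one task would cancel in the difference, and the within-task
error correlation is not identifiable from choice data alone, so a
correlation parameter is exposed (`error_correlation`) but defaults to 0.

Three variants are implemented:

* **Model 2b** (default): a single common SEM, fixed at 1 because only
  $u/s$ is identified — the probit scale is the unit. Utilities are
  identified by a within-dimension sum-to-zero constraint, removing the
  per-dimension location invariance of the likelihood (adding a constant
  to all levels of one dimension changes nothing, since both options in a
  task share the other dimensions). This parameterization treats the
  elements symmetrically, which is what makes the observed-information
  standard errors directly meaningful.
* **Model 2a**: the same model under a corner constraint (lowest level of
  each dimension fixed at 0) — an equivalent fit, useful as a
  cross-parameterization check: the tests verify 2a and 2b agree to
  machine precision after recentring.
* **Model 1**: respondent-specific SEMs $s_r$, with the geometric mean of
  the $s_r$ fixed at 1 to pin the scale. A weak quadratic shrinkage
  (10⁻⁴) on the log-SEMs keeps the likelihood bounded when a respondent
  answers almost perfectly consistently (their SEM would otherwise drift
  towards zero); its effect on the utilities is far below their standard
  errors.

**Optimization.** Quasi-Newton (BFGS) with an analytic gradient from three
seeded starts (the first at zero), followed by damped Newton polishing
with backtracking; convergence requires a gradient norm below 10⁻⁶, and
non-convergence is an error carrying the achieved norm. The likelihood is
globally concave in the utility parameters for fixed dispersions, so
multi-start is belt-and-braces rather than a necessity. Standard errors
and correlations come from the inverse observed information at the
optimum, mapped through the sum-to-zero contrast. If an element wins or
loses every comparison it appears in (separation — its maximum-likelihood
utility is infinite), a ridge penalty $10^{-4}\sum u^2$ keeps the estimate
finite; the fit is flagged and a warning raised.

**Rescaling.** `rescale_fit()` applies the publication convention: per
dimension, translate the lowest *level's* utility to zero (not the
minimum — for a noisy, non-monotone fit these can differ, and the
convention keeps level 1 as the anchor), then scale so the top-level
profile scores exactly 1000. Standard errors scale by the same factor;
correlations are unchanged. Translation is treated as exact, matching the
convention of reporting a single SE per element after anchoring.

## Agreement statistics

`icc_two_way()` computes the two-way random-effects, absolute-agreement
intraclass correlation from the ANOVA mean squares:

$$\mathrm{ICC}(2,1) =
  \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$

with the average-measures version replacing the rater terms accordingly.
Rater main effects count as disagreement, the right notion when raters are
interchangeable committee members rather than fixed judges. Confidence
intervals use the F-based method; the average-measures interval applies
the Spearman–Brown step-up to the single-measures bounds. Raters with any
missing rating are dropped (listwise), matching the estimator's
complete-grid derivation; if between-subject variance does not exceed
error, the estimate is reported as 0 with a warning rather than negative.

`gwet_ac2()` implements the weighted multi-rater AC2 with Gwet's
chance-agreement term, which remains stable under skewed category
prevalences where kappa collapses. The weighting scheme for ordinal
categories is not uniquely standard, so it is an argument: quadratic
weights $w_{ij} = 1 - (i-j)^2/(K-1)^2$ by default (sensible for ordered
levels), identity ("nominal") weights reducing AC2 to AC1 exactly.
Missingness is handled pairwise (subjects need at least two raters); the
variance is the subject-level jackknife.

`committee_icc()` addresses the question the instrument actually poses —
how reliable is a *committee's* consensus rather than an individual's: it
randomly partitions the complete-data raters into committees of given
sizes (seeded), averages ratings within committee, and computes ICC(2,1)
on the committee-level matrix. Averaging suppresses rater noise, so
committee reliability exceeds individual reliability whenever rater noise
dominates; the tests verify this in ≥ 95% of seeded replicates under heavy
noise. No CI is reported: the partition is itself random, and a CI for one
arbitrary partition would be misleading. Because the partition seed used
in the original study is unknown, published committee values are patterns
to match qualitatively, not reproduction targets.

## Delphi analytics

The RAND/UCLA disagreement index for 1–9 panel ratings is
$DI = IPR / IPRAS$ with $IPR = P_{70} - P_{30}$ and
$IPRAS = 2.35 + 1.5\,|5 - (P_{30}+P_{70})/2|$, the constants from the
RAND/UCLA appropriateness manual; $DI > 1$ flags disagreement. Percentile
conventions differ across implementations and $DI$ near 1 is sensitive to
them, so the quantile type is an argument (default: type 7, linear
interpolation between order statistics — R's default). Items are selected
for re-rating when the median lies in 4–6 (uncertain opinion) or $DI > 1$;
the rule is idempotent and order-independent. Medians of even-length
vectors use the midpoint convention. `theme_contributions()` reports each
theme's share of the summed item medians among items at or above the
consensus floor (default median ≥ 7); shares sum to 100 up to rounding.

## Validity analytics

The pre-calibration instrument is scored by an unweighted sum with every
dimension mapped linearly onto 0–3 (a 3-level dimension maps to 0, 1.5,
3), giving a 0–18 range for six dimensions. Cramér's V is
$\sqrt{\chi^2 / (n \cdot \min(r-1, c-1))}$ — the min term sits inside the
denominator, as it must for $V \in [0,1]$ — with Pearson's $\chi^2$ and a
Fisher-exact p-value when any expected count is below 5. Tertile logistic
regression cuts scores at the empirical 1/3 and 2/3 quantiles
(right-closed; ties that empty a tertile shift the boundary to the nearest
distinct value) and regresses the binary journal-impact group on tertile
indicators; with no covariates the model odds ratios equal the collapsed
2×3 table's, which the tests verify to 10⁻⁶. Citation counts are analysed
as $\ln(c + 1)$ — the offset handles zero counts, which the source
analyses did not need to specify — and the standardized slope is reported.

## Simulators and what the tests show

The generators produce every input with known truth:

* `simulate_bws_responses()` draws perceived utilities per respondent-task
  and marks the argmax/argmin as best/worst — exactly the fitting model,
  used generatively. Respondent SEMs are either common or log-normal
  (positive support, heavy enough tail to separate the model variants).
  Single-ended answers can be injected at a rate or an exact count.
* `simulate_ratings()` discretizes subject effects plus rater noise at
  equal-probability cutpoints; the latent ICC
  $\sigma_s^2/(\sigma_s^2+\sigma_e^2)$ is recorded. Discretization
  attenuates the observed ICC slightly below the latent value, which the
  recovery test acknowledges with a small allowance.
* `simulate_articles()` draws profiles uniformly per dimension, assigns
  the journal group by a logistic link on the score's tertile indicators —
  so the configured tertile-3 log-odds is the estimand itself, with the
  tertile-2 effect set to half — and draws citations log-normally with a
  configurable standardized score effect.

All generators are byte-identical under a fixed seed and never disturb the
caller's RNG state.

The test suite's simulation conditions mirror the calibration study's
scale: the full 73-task design with 200 respondents at common SEM 1 for
end-to-end recovery (20 replicates; within-dimension order recovered and
truth–estimate correlation above 0.95), 40 respondents for the Model 1
versus Model 2a comparison, and 14 subjects × ~30 raters for agreement
statistics. Oracles are independent routes: Monte-Carlo multivariate
normal draws for SE propagation, `stats::aov` mean squares for ICC,
brute-force pairwise enumeration for AC2, per-term likelihood evaluation
for the fit, and exhaustive triple enumeration for the design rule.

What passing these tests does **not** show: that real respondents behave
like the Thurstone model (no inattention, no position effects, no
stakeholder-group heterogeneity — the simulators draw all respondents from
one population), that real rating panels have normal latent structure, or
that the bibliometric association generalizes beyond the sampling scheme
emulated here.

## Known limitations

* The anti-chain enumeration yields 73 tasks for the ANZMUSC structure,
  not the 86 of the original survey catalogue, whose exact combinatorial
  rule is not public; the design module is therefore calibration-complete
  (it covers every element and identifies all utilities) but not a replica
  of the original administration.
* Model 1's respondent SEMs are the only heterogeneity supported; there is
  no mixed-logit or hierarchical-Bayes layer, and no subgroup analysis.
* The SE propagation assumes joint normality of the utility estimates — a
  large-sample approximation inherited from the observed-information
  covariance.
* `cut_tertiles()` is deterministic under ties but tie-heavy score
  distributions can make the tertile sizes noticeably unequal.
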