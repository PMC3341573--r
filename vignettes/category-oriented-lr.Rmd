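---
title: "Category-oriented likelihood ratios: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Category-oriented likelihood ratios: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catlr)
```

## The problem

Evidence-based diagnosis revises the probability of a disease with the
likelihood ratios (LRs) of observed clinical findings:

$$\mathrm{LR}(+) = \frac{se}{1 - sp}, \qquad
  \mathrm{LR}(-) = \frac{1 - se}{sp}, \qquad
  \text{post-test odds} = \text{pre-test odds} \times \prod_i \mathrm{LR}_i .$$

This works well for specific complaints with a short differential diagnosis.
For nonspecific complaints (non-acute abdominal pain, fatigue, fever, ...)
the differential list is too long to revise disease by disease, and expert
clinicians instead revise the probability of whole *categories* of disease —
organic versus non-organic, then neoplastic versus non-neoplastic — at the
branching points of a diagnostic scheme. catlr makes that strategy
quantitative through the **category-oriented likelihood ratio**: the LR of a
finding for membership in a disease category rather than for one disease.

## The category-oriented LR

Under cross-sectional cohort sampling — one disease $d$ per patient drawn
from a prevalence vector $\pi$, binary findings drawn conditionally
independently given $d$ with probabilities $p_d(f)$ — the sensitivity and
specificity of a finding $f$ for a category $C$ are prevalence-weighted
mixtures:

$$se_C(f) = \frac{\sum_{d \in C} \pi_d\, p_d(f)}{\sum_{d \in C} \pi_d},
\qquad
sp_C(f) = 1 - \frac{\sum_{d \notin C} \pi_d\, p_d(f)}{\sum_{d \notin C} \pi_d}.$$

The category-oriented LR pair is `lr_from_accuracy(se_C, sp_C)`
(`category_lr()`).  This mixture is the unique operational definition
consistent with "patients with one of the diseases of the category" under
the sampling model; the complement deliberately includes
symptomatic-but-undiagnosed entries, because they are part of the cohort a
clinician actually faces.  The category prior is the summed prevalence of
the member diseases (`category_prior()`).

Category membership is encoded as slash-separated paths
(`organic/neoplasm`), so a sub-category's members are always a subset of its
parent's.

## What is exact and what is approximate

Sequential updating with category-oriented LRs is exact in two cases, and
the package's tests pin both at 1e-10 against a brute-force enumeration
oracle (`exact_posterior()`):

* a **single finding**, any generative model;
* **multiple findings** when the finding probabilities are constant within
  $C$ and within its complement ("homogeneous categories") and findings are
  independent given the disease.

With heterogeneous categories and several findings, multiplying category
LRs is a naive-Bayes approximation: conditioning on membership side does not
make findings independent.  The package does not hide this;
`naive_vs_exact()` reports the sequential posterior, the exact posterior and
their difference on both probability and log-odds scales, and the `validate`
CLI subcommand summarises the discrepancy over a simulated cohort.  Note
also that while exact sub-category posteriors can never exceed their
parent's (they are sums over nested disease sets), the approximate
sequential update is not guaranteed to respect that ordering.

## Dependent findings

Multiplying LRs presumes independent findings.  When two findings are
statistically dependent (e.g. vaginal discharge and vaginal irritation in
the urinary-tract-infection table), only the more discriminative of the two
should contribute.  `select_lrs()` operationalises "more discriminative" as
the larger $|\ln \mathrm{LR}|$ of the *applicable* LR — symmetric for LRs
above and below 1, and consistent with preferring an LR(−) of 3.1 to one of
2.7.  Ties break to the earlier table row, and output order is table row
order, so selection is fully deterministic.  Dependence groups are data
(a `dependence_group` column), not code.

## Worked examples and printed-chain replay

The bundled fixtures transcribe three published tables: a
symptom/sign accuracy table for uncomplicated urinary tract infection, a
category-oriented LR table for organic disease in non-acute abdominal pain,
and the final-diagnosis prevalence taxonomy of a non-acute abdominal pain
cohort (33 entries totalling 99.6%; the organic rows sum to 14.1%).
Checksum tests pin the transcriptions cell for cell.

The engine always computes at full precision; rounding is applied only at
the display layer (`format_odds()`, `format_percent()`, banker's rounding).
The published worked chains, however, print truncated intermediates (a
pre-test odds of 0.14/0.86 printed as 0.16 and then *used* as 0.16).  The
acceptance tests therefore replay those chains by feeding the *printed*
intermediate values as inputs, which reproduces every printed waypoint
exactly; computing the same chains at full precision from the raw prior
gives the same values to within displayed precision.  Two quirks of the
source chains are replayed as printed rather than second-guessed: the
neoplasm sub-category prior is taken as the printed odds 0.041 (the
neoplasm-labelled prevalence rows actually sum to 3.3%, not 4%), and the
"no specific character to pain" finding contributes its LR(−) in the
history chain, so the bundled case profile marks it absent.

```{r}
uti <- read_accuracy_table(catlr_example("accuracy_uti.csv"), target = "UTI")
prof <- read_profile(catlr_example("profile_case_uti.json"))
sel <- select_lrs(prof, uti)
sequential_update(prior_odds = 0.13, lrs = as.numeric(sel),
                  finding_ids = names(sel))
```

## Scheme trees

A scheme (`read_scheme()`) is a JSON tree of branching points: *router*
nodes branch deterministically on one profile finding (acute versus
non-acute onset), *reviser* nodes revise a category probability from the
profile and branch on an explicit action threshold.  The published source
never states how a posterior maps to a branch choice, so every reviser node
carries its threshold in the scheme file (default 0.10, "pursue the
category further"); policy is visible configuration, not a hidden constant.
A reviser's prior comes from the disease table by default, can be a literal
number, or `"carry"` — continue from the running posterior of the same
category, which is how the bundled abdominal scheme chains its history and
laboratory nodes.  The bundled scheme encodes exactly the narrated
structure (onset router, organic history revision, laboratory revision,
neoplasm check) and nothing more.

## The simulator and its defaults

`simulate_cohort()` realises the program of *calculating and testing*
category-oriented LRs that the concept calls for: one disease per patient
from the prevalence simplex, findings independent given disease, a single
seeded RNG stream per cohort (the caller's RNG state is untouched).
`estimate_category_accuracy()` returns empirical sensitivity/specificity
with Wilson 95% intervals — chosen because small strata push proportions to
the boundary, where Wald intervals collapse; `empirical_category_lr()` adds
delta-method standard errors of the log LRs.

`demo_abdominal_model()` is the packaged demonstration substrate: it takes
the bundled prevalence taxonomy and inverts each published organic-category
LR pair back to a (sensitivity, specificity) pair
(`accuracy_from_lr()`), giving every finding a constant probability inside
and outside the organic category.  Its analytic category LRs therefore
match the bundled table by construction; the per-disease probabilities of
the real source cohort are not published, so the model illustrates
magnitudes, it does not reconstruct the cohort.  Real categories are
heterogeneous to an unknown degree; rather than presuming a value, the
constructor exposes `heterogeneity`, a deterministic logit-scale spread of
per-disease probabilities within each side, for studying how fast the
naive-Bayes approximation degrades.

Validation problem sizes are chosen to make sampling noise negligible
relative to the effects checked while keeping runs at desk scale: cohorts
of 200,000 patients for estimator-consistency (within 3 standard errors of
the analytic log-LR for every fixture finding) and posterior-calibration
checks (patients binned by sequential posterior in bins of width 0.1;
member frequency inside the exact binomial 99% interval of the bin's mean
posterior, on a homogeneous model where the sequential posterior is the
true conditional probability), and 10,000 for disease-frequency checks.

## Numerical and design choices

* Probabilities 0 and 1 are representable; they are absorbing under odds
  updating, and a trace note records when LRs were ignored for that reason.
  Probability 1 maps to the infinite-odds flag (`Inf`).
* Strength banding of LRs reads "5 to 10" inclusively: boundaries belong to
  the moderate band (`[5, 10]` positive, `[0.1, 0.2]` negative).
* Accuracy tables may state LRs, sensitivity/specificity, or both; both
  must agree within 5% relative tolerance, and LRs are derived from
  accuracy when only the latter is given.
* Prevalences are stored in files as the printed percentages and converted
  to fractions at load; a disease table may total at most 100% plus a 0.5
  rounding slack.
* All inputs are plain text (CSV for tables and cohorts, JSON for profiles,
  models, schemes and traces), and every reader/writer pair round-trips
  losslessly.

## Limitations

* Confidence intervals for the LRs themselves are out of scope (the source
  tables do not provide them); the Wilson intervals attach to simulated
  estimates only.
* Findings are generated conditionally independently given the disease;
  dependence is honoured only through dependence-group selection, not
  modelled generatively (no copulas).
* Continuous-valued findings and utility- or cost-based action thresholds
  are not modelled; thresholds are plain probabilities supplied by the
  scheme author.
* The generative model is specified, not fitted: estimating per-disease
  finding probabilities from raw study data is outside the package's scope.
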