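---
title: "Methods: point-of-care coeliac triage in iron deficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: point-of-care coeliac triage in iron deficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coeliactriage)
```

## The problem

Guidelines recommend coeliac serology in iron deficiency anaemia, with
duodenal biopsy reserved for seropositive patients. In practice serology
is often unavailable at the time of gastroscopy, so endoscopists biopsy
everyone. A point-of-care deamidated-gliadin-peptide (DGP) antibody test
read at the endoscopy table can fill that gap: if its negative
predictive value is high enough, biopsies can be limited to
test-positive patients, trading a cheap kit against the cost of biopsy
histology. `coeliactriage` implements the full evaluation of that
strategy: the histology-anchored case definition, exact
diagnostic-accuracy statistics, the biopsy-avoidance cost model, and a
synthetic cohort generator that makes every stage testable without
patient-level data (none are publicly deposited).

## Case definition

A patient is a coeliac case when duodenal histology shows villous
atrophy (Marsh 3a--3c) **and** at least one of IgA-EMA or IgA-TTG is
positive; the serological disjunction is taken literally as an OR. For
seronegative villous atrophy, HLA-DQ2/DQ8 decides: a negative phenotype
rules coeliac disease out (villous atrophy then has some other cause,
e.g. intestinal tuberculosis); a positive or untyped phenotype leaves
the record `INDETERMINATE`. `INDETERMINATE` is deliberately
first-class: downstream code chooses a policy (count as coeliac, count
as not, or report separately) instead of the classifier guessing.
`classify_coeliac()` is total and deterministic on biopsied, graded
records and errors on anything else -- the definition is
histology-anchored, so an ungraded record is unclassifiable, not
negative.

Two edge rules are worth stating. Missing serology counts as
*not-positive*, never as negative evidence on its own, which is what
routes a never-tested villous-atrophy record to `INDETERMINATE` rather
than `NOT_COELIAC`. And Marsh 2 with positive serology does not meet the
definition (no villous atrophy); `audit_cohort()` counts such records in
a review category rather than silently classing them, since in clinic
they would trigger repeat biopsy rather than a verdict. Supporting
clinical information (family history, response to a gluten-free diet) is
not encodable as a stated rule and is intentionally outside the
algorithm.

## Accuracy statistics

`performance_panel()` computes sensitivity, specificity, PPV, NPV and
prevalence from a 2x2 table, each with a two-sided exact
Clopper-Pearson interval in the beta-quantile form: with
$\alpha = 1 - \text{conf}$,

$$L = B_{\alpha/2}(k,\; n-k+1), \qquad
  U = B_{1-\alpha/2}(k+1,\; n-k),$$

with $L = 0$ at $k = 0$ and $U = 1$ at $k = n$. The tests cross-check
these bounds against an independent bisection inversion of the binomial
tail probabilities on every $(k, n)$ with $n \le 60$, and verify the
conservative-coverage property on simulated binomial draws. Exact
intervals were chosen because several of the panel's numerators sit on
the boundary (0 false negatives), where Wald and even score intervals
misbehave.

Likelihood ratios are prevalence-free summaries:
$\mathrm{PLR} = se/(1-sp)$ (infinite when specificity is 1 and
sensitivity positive) and $\mathrm{NLR} = (1-se)/sp$. An NLR of exactly
0 is reported without an interval -- the standard log-method interval is
undefined there -- and log-method intervals for both ratios are an
opt-in extra (`lr_ci = TRUE`), since the core panel reports none.
Metrics with a zero denominator propagate as explicitly *undefined*
rather than as 0 or an error, so partial panels on degenerate synthetic
tables remain usable. Predictive values transport to other prevalences
by Bayes' theorem (`predictive_values_at_prevalence()`); at a table's
own prevalence the transported values reproduce the table-based PPV/NPV
identically, an identity the tests assert to 1e-12.

Display convention: percentages to one decimal place, likelihood ratios
to two; raw proportions are kept at full precision internally and in the
JSON report.

## Cost model

The triage strategy tests everyone and biopsies only test-positives.
With `n_neg` test-negative patients out of `n`,

* gross saving = `n_neg` x biopsy histology cost (default £86 per
  patient's biopsy set),
* kit spend = `n` x kit cost (default £20),
* net departmental saving = gross - kit (may be negative),
* payer-level saving applies the gastroscopy-with-biopsy tariff
  difference (default £38) instead of the histology charge.

Money is held in integer pence, so cohort-level arithmetic is exact;
per-100-gastroscopy figures are exact rational rescalings rounded
half-away-from-zero to whole pounds only at display time (4908 x
100/133 = 3690.2... prints as £3690). `prevalence_sweep()` extrapolates
to other prevalences through the expected negative fraction
$(1-p)\,sp + p\,(1-se)$, computing money on fractional expected counts
rather than rounding to integer patients -- at the cohort's own
parameters this reproduces the observed economics identically.
`break_even()` returns the negative fraction at which the strategy
breaks even (`kit/biopsy` = 20/86 ≈ 0.233 at defaults), its inverse in
kit cost, and, given test accuracy, the corresponding break-even
prevalence.

One documented divergence: published low-prevalence extrapolations of
this kind of model (e.g. a department saving near £5826 per 100 at 5 %
prevalence) cannot be reproduced from the explicit expected-fraction
formula, which gives about 78.1 expected negatives per 100 at 5 %
prevalence, i.e. £4719 per 100 at default costs. Back-solving the £5826
figure implies about 91 avoided biopsies per 100, closer to rescaling
the cohort's positivity rate than to the Bayes-consistent expectation.
The package implements and documents the explicit model and does not
back-fit the printed figure; intangible savings (biopsy pots, forceps,
staff time) are left out for want of a defensible parameterisation.

## Synthetic cohorts

`simulate_cohort()` generates the kind of cohort the analysis assumes:
`n = 133` iron-deficient patients, disease prevalence 26/133 (19.5 %),
point-of-care sensitivity 1 and specificity 88/107, IgA-TTG 25/26 and
98/107, IgA-EMA 22/26 and 106/107, anaemia in 81/133, IgA deficiency at
2.6 %. Diseased patients always receive a Marsh 3 grade (the case
definition requires villous atrophy), split roughly 13:7:6 over
3a/3b/3c; non-diseased draw M0/M1/M2 at 88:15:2, the Marsh 1 stratum
emulating lymphocytic duodenosis. One non-diseased patient in 107 is
expected to be a seronegative villous-atrophy confounder -- Marsh 3
histology, forced-negative serology, HLA-negative -- exercising the
rule-out path of the classifier.

Test errors are coupled through a one-factor copula: each patient
carries a shared latent uniform, and each test reads it (instead of an
independent draw) with probability `inter_test_correlation`. Zero
recovers independent errors; the induced error correlation between two
tests with equal error rates is the square of the parameter. No joint
cross-tabulation of the three tests is published, so the parameter has
no data-anchored value; the default of 0.4 reflects that antibody
assays against overlapping antigen systems plainly do not err
independently, while leaving dependence modest. Marginal accuracies are
unaffected by the copula, so no reported statistic depends on this
choice. Titres are not simulated (tests are analysed as binary);
IgA-deficiency status is recorded but does not further modify results,
because the marginal accuracies being emulated already include any such
effect empirically.

Reproducibility contract: the same parameters and seed give a
byte-identical cohort; replicate experiments use deterministic
sub-stream seeds indexed by replicate, so they parallelise and reorder
safely, and the simulator restores the caller's RNG state.

What passing tests do and do not show: the generator reproduces the
*marginal* structure the analysis consumes (prevalence, per-test
accuracy, Marsh mixture, confounder path). It does not model titre
kinetics, site effects, spectrum bias, or the referral-centre enrichment
that makes a 19.5 % prevalence cohort unrepresentative of primary care
-- conclusions about real populations still require the prevalence
sweeps and, ultimately, real cohorts.

`recovery_experiment()` closes the loop: simulate, classify, tabulate,
estimate, and check that Clopper-Pearson intervals cover the generating
parameters at least nominally (they are conservative), flagging any
metric undefined in more than half the replicates.

## Reconstruction fixtures

Patient-level data were never deposited, so the package ships two
deterministic *synthetic* reconstructions built from published marginal
counts (`group2_cohort()`, `group3_cohort()`, also as CSVs under
`inst/extdata/`, labelled `_synthetic`). The 133-record prospective
cohort reproduces each test's 2x2 exactly -- point-of-care
(26, 19, 0, 88), IgA-TTG (25, 9, 1, 98), IgA-EMA (22, 1, 4, 106) --
with within-patient overlaps fixed by convention where the joint
distribution is unpublished (the serology tables are themselves
reconstructed from printed percentages; every derived number was
verified against an exact recomputation before being frozen into
tests). Two small source inconsistencies are worth noting: the
non-diseased Marsh counts in the published characteristics table sum to
106 rather than 107, so the fixture carries one extra M0 record; and
the reconstructed TTG specificity computes to 91.6 % (84.6--96.1),
not the printed 91.5 (84.5--96.4) -- the fixture follows the exact
arithmetic. The 153-record clinic cohort reproduces the histology
audit: 141 normal (92.2 %), 7 lymphocytic duodenosis (4.6 %), two
villous atrophy (one confirmed case, one never serotyped, hence
indeterminate), three incidental findings; counting the indeterminate
record as coeliac gives the 1.3 % prevalence figure.

For the group-3 reproduction the indeterminate policy defaults to
`count_as_coeliac` (mirroring the published stance on the unconfirmed
case); the library-wide default elsewhere is `report_separately`, which
asserts nothing it cannot verify.

## Numerical choices and scale

* Exact integer pence for money; fractional counts only where
  expectations are intended.
* Clopper-Pearson via the beta quantile (`stats::qbeta`), the exact
  closed form; the bisection inversion lives only in the test suite as
  an independent oracle.
* Degenerate inputs (zero denominators, empty usable record sets,
  all-indeterminate references) raise typed errors or explicit
  undefined markers, never silent coercion; CSV rows violating a
  vocabulary are skipped and reported with row numbers.
* Problem sizes: the validation suite uses 10 000 binomial draws for
  the coverage property, 1000 replicates of the 133-patient preset for
  simulator recovery, and n <= 60 for the exhaustive interval
  cross-check -- sizes at which every Monte-Carlo tolerance is a small
  multiple of its standard error and the whole suite runs in seconds.

## Limitations

The economics are a pure cost offset -- no QALYs, no probabilistic
sensitivity analysis, no modelling of the downstream cost of a missed
case (the observed 100 % sensitivity makes that term vanish in-sample,
but its interval lower bound is 86.8 %). The audit module does not
attribute causes to lymphocytic duodenosis (chart review in the source
setting). The serology-availability summary is a single proportion; its
published numerator is internally inconsistent between abstract and
results (361 vs 315 of 934, both printed as 33.8 %; 315/934 is 33.7 %),
which the package records but does not resolve.
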