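---
title: "Methods: dual versus single kidney transplantation, from synthetic registry to allocation counterfactuals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual versus single kidney transplantation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualkidney)
```

This vignette is the package's account of its science: the generative model
behind the synthetic registry, the estimators applied to it, the
counterfactual arithmetic, and the design decisions taken where the
underlying study leaves the construction open. Every number quoted here is
computed by the package's tests or scripts; nothing is asserted that the
code does not reproduce.

## The question

Dual kidney transplantation places both kidneys of a marginal deceased donor
into one recipient, rescuing organs that would otherwise be discarded — but
at the cost of serving one patient with two organs. A registry comparison of
dual versus single recipients on a propensity-matched cohort estimates the
graft-survival advantage of receiving two kidneys; the interesting policy
quantities are then counterfactual: how many more grafts would survive if
those pairs had been split between two recipients, and how many waitlist
deaths would the extra transplants avert?

## The synthetic registry

Real registry extracts of this kind are access-restricted, so the package
ships a generator whose output has the statistical structure the analysis
needs, with every parameter explicit and documented.

**Covariate marginals.** Each covariate has per-group (dual / single)
marginal distributions calibrated to published registry summaries:
log-normals moment-matched to "median (IQR)" for positive skewed quantities
(KDRI: medians 1.88 vs 1.21; cold ischemia 23 vs 18 h; donor-to-center
distance 137 vs 90 miles; BMI), truncated normals for bounded ones (donor
age 58 vs 40 years; recipient age 65 vs 55; EPTS 68 vs 51 on 0–100),
category probabilities equal to the published level counts
(glomerulosclerosis, dialysis vintage, renal diagnosis, HLA mismatch,
sharing, induction), and a zero-inflated Beta for cPRA (70% vs 50% at zero).
Recipient sex and race/ethnicity are not part of the published group
comparison; they carry group-invariant, typical US deceased-donor recipient
distributions and exist to support the BMI imputation model.

**Joint structure.** Covariates are coupled through a single latent
"marginality" factor via a Gaussian copula: for covariate $i$ with loading
$\lambda_i$, the sampling uniform is $\Phi(\lambda_i F + \sqrt{1 -
\lambda_i^2}\,\varepsilon_i)$ with subject-level $F \sim N(0,1)$. Marginals
are exactly the configured ones regardless of loadings. Loadings are set
proportional to each covariate's group shift (capped at 0.95): the factor
is, by construction, the axis along which dual and single transplants
differ, which mirrors how the real quantities relate (KDRI is computed from
donor age and comorbidity; EPTS from recipient age, diabetes and dialysis
history; old kidneys go preferentially to old recipients). This choice is
not cosmetic. With the published marginal shifts applied to ~20 mutually
independent covariates, the two groups become almost separable in
propensity-score space and no matching ratio can balance them — contradicting
the matched design the analysis rests on, which did achieve balance at 3:1.
Shift-proportional loadings concentrate the group difference in one
dimension, reproducing a cohort in which 1:1, 2:1 and 3:1 matching all
balance within |SMD| ≤ 0.1 (verified across seeds in the test suite).
Uniform strong loadings do *not* work: heterogeneous shifts on a common
factor amplify, rather than cancel, the residual separation.

**Survival outcomes.** The all-cause graft-failure time (first of graft
failure or death with function) is exponential,
$T \sim \mathrm{Exp}(h_{ac}\,e^{\beta_{ac} g})$, with the single-group rate
$h_{ac} = -\log(0.529)/6 = 0.106$/yr matched to the published 6-year
all-cause graft survival and $e^{\beta_{ac}} = 0.79$ the published
multivariable hazard ratio. Each event is a graft failure with group-specific
probability $q_g$, chosen so the cause-specific (death-censored)
graft-failure hazard has exactly the published ratio 0.73:
$q_{single} = h_{dcgf}/h_{ac}$ with $h_{dcgf} = -\log(0.799)/6$, and
$q_{dual} = q_{single}\cdot 0.73/0.79$. Death after graft loss follows an
exponential with rate 0.15/yr (return-to-dialysis mortality, a generator
choice). Under this construction both analyzed graft endpoints have exactly
proportional hazards at their configured ratios; patient survival is a
mixture and only approximately proportional, which is acceptable because no
quantitative target depends on it. Censoring is administrative — entry
uniform over the accrual window, so censoring time is uniform on (0, 9.33)
years — plus exponential loss to follow-up at 0.02/yr.

An alternative construction (independent latent death and graft-failure
exponentials) was rejected: the derived all-cause hazard ratio would then be
a baseline-weighted composite (≈0.81 with these baselines), not the
published 0.79, and the two endpoint calibrations could not hold at once.

**Secondary outcomes.** DGF, rejection at 6 and 12 months, 1-year
creatinine and length of stay are drawn per group at the published matched-
set rates (DGF 39.3% vs 31.7%; 6-month rejection 3.9% vs 5.4%; …), with
rejection and creatinine observed only when follow-up is long enough.
The source's running text gives the single-group DGF rate as 32.7% while its
table implies 964/3045 = 31.7%; the package follows the table.
Missingness in BMI, CIT and LOS is injected completely at random at the
published missing fractions (241, 203 and 588 out of 135,948), purely to
exercise the imputation stage.

**What the generator does not emulate.** Only marginals, the one-factor
correlation, and the group effects are in scope: the full joint correlation
structure of real registry covariates, covariate-dependent hazards
(outcomes depend on group only), informative censoring, era effects and
center effects are all absent. Passing tests therefore demonstrate the
correctness of the estimators and pipeline on data with known truth — not
that the generator reproduces the real cohort's joint distribution.

## Cohort pipeline

Exclusions are applied in a fixed documented order — recipient under 18,
living donor, en bloc, missing KDRI, missing survival data — with a record
counted once under its first failing rule, so the filter report's counts sum
exactly. Imputation mirrors the study: BMI regressed on recipient age, sex
and race/ethnicity (reference-coded indicators, reference = first level);
CIT on sharing type and donor-to-center distance; LOS by the observed
median. Group comparisons use the Wilcoxon rank-sum test with the
tie-corrected normal approximation for continuous variables (cohort sizes
make exact enumeration irrelevant) and Pearson's chi-square without
continuity correction for categorical ones.

## Propensity matching

The propensity model is maximum-likelihood logistic regression (IRLS,
deviance tolerance $10^{-12}$, ≤100 iterations) of group on the
demographic-table covariates. Continuous covariates also enter through a
quadratic — on the log scale when strictly positive and right-skewed — and
zero-inflated percent scales get a zero indicator: group differences in
spread make the true log-odds nonlinear in the covariate, and matching on a
misspecified linear score leaves residual imbalance no ratio can fix.
Perfect separation is reported as an error naming the covariate with the
largest standardized coefficient; separation is detected by boundary fitted
probabilities for *all* units of both groups, since tiny fitted scores for
some controls are expected at 0.75% treated prevalence.

Matching is greedy nearest-neighbor without replacement on the logit of the
score: treated units processed hardest-first (descending score, seeded
random shuffle breaking ties), each taking its k nearest unused controls
before the next treated unit. No caliper is applied by default. Balance is
the standardized mean difference — difference in means over the square root
of the average group variance, per-level for categorical covariates with the
maximum absolute value reported — and ratio selection walks 1:1 → 2:1 → 3:1,
keeping the largest ratio with max |SMD| ≤ 0.1 and flagging the cohort
not-balanced otherwise. One worked-example subtlety: on the logit scale a
score of 0.80 is nearer to 0.79 than to 0.81, so pairings can differ from
raw-score intuition; the tests pin the logit-scale behaviour.

## Survival estimation

Kaplan–Meier estimation, the two-group log-rank test and Cox
proportional-hazards models (Efron tie handling, Newton–Raphson) are
delegated to the `survival` package behind the module's interface; the test
suite checks them against independent oracles — a hand product-limit
computation, a hand $(O-E)^2/V$ log-rank computation, the equivalence of the
log-rank statistic with the Cox score test on tie-free data, and brute-force
maximization of the partial likelihood written out directly. Follow-up is in
years from transplant; Wald 95% intervals; death-censored graft survival
treats death with a functioning graft as censoring. The per-year p-values in
the survival tables are pointwise normal-approximation comparisons of the
two Kaplan–Meier estimates with Greenwood standard errors (the source tables
do not state their per-year test; the overall log-rank p accompanies every
table).

## The conversion counterfactual

With $S$ the single-graft death-censored survival at the horizon and
$\mathrm{HR}$ the dual-vs-single hazard ratio, converting $n_{dual}$ dual
transplants into $2 n_{dual}$ singles changes the number of grafts surviving
at the horizon from $n_{dual} S^{\mathrm{HR}}$ (the proportional-hazards
transform of the single-graft survival — the only transform consistent with
the Cox model that produced the HR) to $2 n_{dual} S$:

$$\text{additional} = 2\,n_{dual}\,S - n_{dual}\,S^{\mathrm{HR}},
\qquad
\text{percent} = \frac{\text{additional}}{n_{single}\,S}\times 100.$$

$S$ at 5 years is obtained by log-linear interpolation between the year-4
and year-6 table values (85.7%, 79.9%), giving $S_5 = 0.8275$; a Cox
baseline-survival route is available via `interpolate_survival()` on a
fitted curve. The interval evaluates the expression at the HR confidence
bounds only — no uncertainty on $S$ — which matches the narrow published
interval; the gain is increasing in HR (better dual survival shrinks it), so
the lower HR bound maps to the interval's lower end. With the 2023 volumes
(18,873 single, 184 dual) and HR 0.73 (0.58–0.93) the package computes 144
(140–150) additional surviving grafts, a 0.9% (0.9–1.0%) increase — the
published point estimate of ~140 with a 0.9% headline lands inside this
reconstruction, whose exact arithmetic the source does not spell out. The
percent increase is nearly invariant to the survival level itself (within
0.1 percentage points of the value at $S_5$ across $S \in (0.6, 0.95)$),
because $S$ approximately cancels in the ratio. A "successful transplant" is
a graft surviving, death-censored, at the horizon; a dual transplant counts
as one transplant.

## Waitlist microsimulation

A closed cohort of 100,000 candidates (no arrivals) transitions annually for
11 years among waitlist, transplanted and dead; transplanted and dead are
absorbing. Each candidate-year consumes one uniform draw compared against
cumulative thresholds in the fixed order death → transplant → remain; the
order is irrelevant in expectation but fixes the coupling. Under the
all-single pathway the yearly transplant probability becomes
$\min(1 - p_{death},\; p_{tx}(1 + f_{dual}))$ — each converted dual frees
exactly one organ-equivalent transplant. With common random numbers the two
pathways are coupled: a candidate transplanted under current allocation is
transplanted no later under the all-single pathway, and a candidate dying
under the all-single pathway dies under current allocation too, so the death
reduction is nonnegative seed by seed (a property the tests verify over 100
seeds, alongside exact agreement with the closed-form Markov expectation for
constant schedules).

The actual yearly transition probabilities for 2014–2024 are not published;
the schedule generator provides plausible stand-ins (14%/yr transplant,
5%/yr death — roughly 25,000 deceased-donor kidney transplants and 5,000
deaths against a ~90,000-person list — and a 1% dual fraction, consistent
with 184 dual among 19,057 transplants in 2023, with mild log-normal
year-to-year jitter). Under these stand-ins the default run yields a 0.51%
reduction in waitlist deaths; the published 3% figure derives from the
unpublished schedule and is therefore a documented reference value, not a
test target.

## Problem sizes, tolerances and reproducibility

The test suite generates every fixture in code. Hazard-ratio recovery uses
50 replicates of the matched-cohort size (1,015 + 3,045), asserting the mean
estimate within 3 Monte-Carlo standard errors of the generator truth and
≥90% coverage of each fit's own Wald interval; the microsimulation's
analytic check runs at 10⁵ candidates; matching correctness is verified
against a brute-force transliteration of the greedy rule on all instances up
to 12 units and at full registry scale (135,948 records) for the 3:1 balance
property. Every stochastic component takes an explicit integer seed and is
bit-reproducible given it; `run_pipeline()` writes a manifest with the
config digest and all stage seeds, and re-running a config reproduces every
CSV byte-identically.

## Known limitations

Group effects in the generator act only through the group label, not through
covariates, so the matched and unmatched hazard-ratio estimands coincide in
the synthetic world — convenient for parameter-recovery testing, weaker as a
stress test of confounding control. Patient survival is not exactly
proportional-hazards by construction. The microsimulation's three-state
design omits relisting, post-transplant death and arrivals (an arrivals
stream exists but is off by default, matching the closed-cohort design).
The counterfactual projection ignores uncertainty in the interpolated
survival and in the volumes, mirroring the published interval's
construction.
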