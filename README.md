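# dualkidney

Dual kidney transplantation — both kidneys from one deceased donor placed
into a single recipient — is used to rescue marginal organs that would not be
accepted as single transplants. Whether that is the best use of those
kidneys is an open allocation question: each dual transplant consumes two
organs for one recipient. This package implements, end to end, a
registry-style comparison of dual versus single deceased-donor kidney
transplantation and the resource-utilization analyses that follow from it,
for transplant epidemiologists and health-services researchers who want the
whole chain testable and reproducible without access to restricted registry
data.

The pipeline:

1. **Synthetic registry generation** — dual/single cohorts whose covariate
   marginals (donor age, KDRI, glomerulosclerosis, EPTS, dialysis vintage,
   …), survival structure and secondary-outcome rates are calibrated to
   published national-registry summaries. Covariates are tied to a single
   latent "marginality" factor through a Gaussian copula, so the two groups
   overlap the way real registry data do while every marginal stays exactly
   as configured.
2. **Cohort pipeline** — inclusion filters (adult recipients, deceased
   donor, not en bloc, KDRI and survival data present), single imputation
   (BMI and cold ischemia time by linear regression, length of stay by the
   median), and Wilcoxon / chi-square group comparisons.
3. **Propensity matching** — maximum-likelihood logistic propensity model,
   greedy k:1 nearest-neighbor matching without replacement on the logit of
   the score, standardized-mean-difference balance diagnostics, and
   data-driven ratio selection (1:1 → 2:1 → 3:1 at threshold |SMD| ≤ 0.1).
4. **Survival models** — Kaplan–Meier curves with log-rank tests and
   univariable/multivariable Cox proportional-hazards models for patient
   survival, all-cause graft survival and death-censored graft survival.
5. **Counterfactual projection** — additional grafts surviving at a horizon
   if all dual transplants were performed as two singles: with `S` the
   5-year single-graft (death-censored) survival and `HR` the dual-vs-single
   hazard ratio,
   `additional = 2·n_dual·S − n_dual·S^HR`, reported with an interval from
   the HR confidence bounds, and as a percent of `n_single·S`.
6. **Waitlist microsimulation** — 100,000 candidates over 11 years in a
   three-state model (waitlist → transplanted / dead), comparing current
   allocation against an all-single pathway whose yearly transplant
   probability is scaled by (1 + dual fraction), with common random numbers
   coupling the two runs.

## Worked example

The numbered scripts under `analysis/` run the full study in order. Running
`analysis/02_cohort_and_matching.R` on the default registry prints:

```
selected 3:1 matching (1015 treated, 3045 controls), max |SMD| = 0.099 -- balanced
  ratio max_abs_smd balanced
1     1  0.06270046     TRUE
2     2  0.05584644     TRUE
3     3  0.09920265     TRUE
```

All candidate ratios balance every covariate within |SMD| ≤ 0.1, so the
largest (3:1) is kept: 1,015 dual recipients matched to 3,045 singles.
`analysis/04_projection.R` then evaluates the dual-to-single conversion
counterfactual with the published 2023 volumes (18,873 single, 184 dual
transplants), hazard ratio 0.73 (0.58–0.93) and 5-year single-graft survival
interpolated log-linearly between the year-4 (85.7%) and year-6 (79.9%)
values:

```
Converting 184 dual transplants to singles (HR 0.73, S(5 y) = 0.827):
  additional successful transplants: 144 (140-150)
  increase in overall successful transplants: 0.9% (0.9-1.0%)
```

That is: splitting every dual pair into two single transplants would yield
about 144 more grafts still functioning at five years — a 0.9% increase in
overall successful transplants — because the survival advantage of a dual
graft (HR 0.73) is far smaller than the doubling of recipients.
`analysis/05_microsim.R` runs the coupled waitlist comparison; with the
default stand-in schedule (14%/yr transplant, 5%/yr death, 1% dual fraction)
it prints a 0.51% reduction in waitlist deaths and 317 additional
transplants per 100,000 candidates. A quick interactive run:

```r
library(dualkidney)
s5 <- interpolate_survival(data.frame(year = c(4, 6),
                                      survival = c(0.857, 0.799)), 5)
project_dual_to_single(n_single = 18873, n_dual = 184, hr = 0.73,
                       hr_ci95 = c(0.58, 0.93), single_survival = s5)
```

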