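---
title: "Comparing Framingham and Reynolds risk scoring across a survey population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing Framingham and Reynolds risk scoring across a survey population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvreclass)
library(dplyr)
```

## The question the package answers

Cholesterol guidelines in the United States key treatment intensity to a
subject's predicted ten-year cardiovascular risk. Two widely used
multivariate scores disagree about that risk for many people: the
Framingham hard-CHD score (FRS), which predicts myocardial infarction or
coronary death from age, lipids, systolic blood pressure, hypertension
treatment and smoking; and the Reynolds Risk Score (RRS), which predicts
a broader endpoint (adding stroke, cardiovascular death and
revascularization) and adds high-sensitivity C-reactive protein (hs-CRP),
parental family history and — in diabetic women — HbA1c. Swapping one
score for the other re-sorts the population across risk categories, which
re-assigns LDL-C treatment goals, which changes who is told to start or
intensify lipid-lowering therapy.

`cvreclass` implements that comparison end to end for a complex survey
sample: per-subject dual scoring, ATP III risk categorization and LDL-C
goal logic, the "clinically significant reclassification" statistic, and
design-based (Taylor-linearized) population estimates — plus a calibrated
synthetic cohort generator so the whole pipeline can be exercised and
tested without any external download.

## The risk equations

Both scores are ten-year Cox survival equations,

$$\mathrm{risk} = 1 - S_0^{\exp(B - M)},$$

where $B = \sum_k \beta_k \, t_k(x)$ is a linear predictor over
(possibly log-transformed) covariates, $S_0$ the ten-year baseline
survival and $M$ the linear predictor at the development-cohort means.
The package stores each equation declaratively (`cox_risk_model`): a term
is $\beta \times [\text{condition flag}] \times \prod_f
t_f(\min(x_f, \text{cap}_f))$ over zero or more factors. Zero factors
give indicator main effects (smoking, family history); two factors give
the Framingham interactions ($\ln\text{age}\times\ln\text{TC}$,
$\ln^2\text{age}$ in men, smoker $\times$ capped $\ln$ age). Coefficient
sets ship as JSON data under `inst/extdata/coefficients/`, not as code,
and `validate_coefficients()` refuses any table that does not reproduce
the built-in reference subject (below) to printed precision.

One consequence of the published Framingham interaction terms is worth
knowing: the age slope of $B$ is $31.764 - 5.061\ln\text{TC} -
2.997\,\text{smoker}$ for women (and has an extra $-5.867\ln\text{age}$
for men), so predicted risk is *locally decreasing* in age for extreme
cholesterol values (women above roughly 294 mg/dL; oldest men). This is
a property of the published equation, not of this implementation; the
property tests therefore assert monotonicity on the subdomains where the
equation guarantees it, and across the full physiological range only for
the interaction-free Reynolds models.

### The reference subject

A 64-year-old female current smoker with positive family history,
untreated SBP 130 mmHg, TC 190 mg/dL, HDL-C 46 mg/dL, LDL-C 116 mg/dL
and hs-CRP 3 mg/L:

```{r worked}
prof <- reference_profile()
round(100 * framingham_10yr_risk(prof), 1)  # 5.1
round(100 * reynolds_10yr_risk(prof), 1)    # 12.5
```

Under FRS she is low risk (goal LDL-C < 160, met); under RRS she is
moderate-high risk (goal < 100, not met at 116). Her treatment
recommendation depends entirely on which score the clinician uses —
the package's definition of a *clinically significant* reclassification.

## Categories, goals, and clinical significance

Categories cut the **unrounded** risk with half-open intervals closed on
the left: low $[0, 6\%)$, moderate $[6, 10\%)$, moderate-high
$[10, 20\%)$, high $[20\%, 100\%]$. Rounding to one decimal happens only
at display time. Each category carries an LDL-C goal; the default
`"aggressive"` policy uses the optional intensified goals
160/130/100/70 mg/dL, and `goal_policy = "standard"` the non-optional
set 160/130/130/100 (under which fewer reclassifications are clinically
significant, because adjacent categories can share a goal).

LDL-C comes from the Friedewald equation
$\mathrm{LDL} = \mathrm{TC} - \mathrm{HDL} - \mathrm{TG}/5$, which is
invalid at triglycerides $\ge 400$ mg/dL. In that case — or when
triglycerides are missing, or the fast was under 8 hours (a missing
fasting time counts as unverified and also falls back) — goal attainment
uses non-HDL-C ($\mathrm{TC}-\mathrm{HDL}$) against the category goal
plus 30 mg/dL. Attainment is a strict inequality: an LDL-C of exactly
100 does **not** meet a "< 100" goal.

A subject is clinically significantly reclassified only when attainment
differs between the two scores — their lipid value lies between the two
goals. `rrs_gt_frs` (met the FRS goal, fails the RRS goal) can only
occur on upward moves and `rrs_lt_frs` only on downward moves, because
goals are non-increasing in category; the test suite checks this
coupling on every synthetic cohort.

## Eligibility

The inclusion waterfall mirrors a primary-prevention screen of a survey
sample: women 45–79 and men 50–79 (boundaries inclusive), then — in
fixed order, so each record gets exactly one reason — pregnancy, missing
blood pressure, missing lipids (no TC or no HDL; missing triglycerides
alone is *not* an exclusion, it routes to the non-HDL fallback),
diabetes (diagnosis, hypoglycemic/insulin use, 8-hour fasting glucose
$\ge 126$, or any glucose $\ge 200$ — the random-glucose clause applies
regardless of fasting time, since a fasting 200 is also diabetic), ATP
III risk equivalents (self-reported CHD or stroke, or ankle-brachial
index < 0.9 in either leg), and chemotherapy. Missing inputs never
qualify for a clause, so the predicates are total functions.

## Survey estimation

Population claims use the design triplet (stratum, PSU, weight) with the
with-replacement first-stage approximation: PSU totals $t_{hj}$ of the
per-record contributions are combined as

$$\widehat V = \sum_h \frac{n_h}{n_h-1} \sum_j (t_{hj} - \bar t_h)^2 .$$

Proportions are domain ratio estimators, linearized to scores
$z_i = d_i w_i (y_i - \hat p) / \sum_d w_i$ before the same formula;
every record stays in the variance computation with zero score outside
the domain, which is what makes subdomain SEs correct. Confidence
intervals are Wald with $z = 1.959964$; CI bounds on proportions are
truncated to $[0,1]$ only at render time. The marginal-homogeneity test
is the Wald z on the weighted mean paired ordinal difference
(RRS minus FRS category, 1–4), with a normal reference — whether a t
reference with design degrees of freedom would be preferable is
genuinely open; the normal is the package's default because the design
df in realistic applications (dozens of PSUs) makes the difference
negligible.

Strata with a single PSU have no unbiased variance contribution; the
default is to refuse (`lonely = "error"`), with `"centre"` (deviation
from the grand PSU-total mean, conservative) and `"certainty"` (zero
contribution, anti-conservative) as explicit opt-ins. Real survey
release files avoid the situation; small synthetic designs may not.

## The synthetic cohort generator

`simulate_cohort()` emulates the *marginal* structure of an NHANES-like
primary-prevention sample:

* **Design**: records assigned uniformly to `n_strata` ×
  `psus_per_stratum` cells (default 15 × 2); gamma-distributed weights
  (shape 4) scaled so the expected weighted totals are 33.5 M women and
  20.1 M men.
* **Covariates**: positive skewed covariates (TC, HDL, SBP, hs-CRP, TG)
  are log-normal, moment-matched to the target median $m$ and IQR $r$
  via $\mu = \ln m$, $\sigma = \operatorname{asinh}(r/2m)/z_{0.75}$ —
  exact for the log-normal family. Ages follow a scaled Beta$(1, b)$ on
  the eligibility window with $b$ solved so the median matches (54.2 y
  women, 57.9 y men). Defaults reproduce the reported subject
  characteristics (e.g. hs-CRP median 2.8 mg/L women / 1.9 men; smoking
  17.2%/17.3%; family history 15.4%/7.7%).
* **Triglycerides** have no published summary in the source tables; the
  defaults (median 110/130 mg/dL, IQR 80/100, plus an explicit 1.5%
  mass at 400–800 mg/dL to exercise the Friedewald validity limit) are
  ordinary population values chosen once.
* **Planted exclusions**: each record first draws an exclusion
  assignment (defaults proportional to the published waterfall:
  diabetes 17.2%, risk equivalents 13%, missing lipids 6.3%, missing BP
  1.9%, chemotherapy 0.6%, pregnancy 0.1% of women); the baseline
  record satisfies *no* exclusion predicate, and the assigned condition
  is then realised by exactly one mechanism. The eligibility waterfall
  must therefore recover the plant exactly — a ground-truth test of the
  whole screen.
* **Seeding**: one master seed; named substreams (design, covariates,
  flags, exclusions) per sex, so changing one stream's parameters never
  perturbs the draws of another.

What the generator does **not** emulate: covariate correlation (age–BP,
lipid–lipid), household clustering within PSUs, oversampling, or
nonresponse adjustment. Covariates are independent within sex, so joint
tails are thinner than in real data and reclassification magnitudes are
smaller than the real-data analysis reports (upward reclassification of
women ~9% at the defaults rather than ~14%). Passing tests on synthetic
cohorts therefore validate the *machinery* — scoring, logic, estimation,
conservation laws, and the qualitative women-up/men-down direction driven
by the sex asymmetry in hs-CRP and family history — not the real-data
magnitudes, which require the actual survey files
(`read_cohort_xpt()` with a user-supplied item mapping; four-year
weights as half of each cycle's two-year exam weight).

## Numerical and design choices

* Risks are computed and categorized at full floating precision;
  one-decimal percentages are display-only.
* hs-CRP must be strictly positive (it is log-transformed); non-positive
  values are domain errors, not clamped.
* Weighted medians/IQRs use the lower-interpolation rule on the weighted
  empirical CDF (the smallest observed value whose cumulative weight
  reaches the target), so quantiles are always observed values.
* The worked example's published narrative labels a 5.1% score
  "moderate"; the stated 6% cutoff makes it low. The package follows the
  stated thresholds — the clinical verdict for that subject is identical
  either way, since LDL-C 116 meets both the 130 and 160 goals and fails
  the 100 goal.
* Stochastic calibration tests use a fixed seed and simultaneous 95%
  Monte-Carlo bands (Bonferroni z across the target family, design-based
  SEs), so the joint check carries the nominal coverage. Problem sizes:
  parameter-recovery checks run at n = 20,000 per sex, ground-truth
  recovery at 5,000 records, oracle equivalence on 110+ random small
  designs.
* Reports are deterministic given (config, seed): manifests carry a
  content hash of the analysis-relevant configuration and no timestamps,
  so identical runs are byte-identical.

## Limitations

Beyond the generator's independence assumption: the package implements
exactly two coefficient sets (sex-specific FRS hard-CHD and RRS);
point-based score variants, recalibration to other populations, and
discrimination/calibration assessment are out of scope. The
reclassification analysis is cross-sectional — with no outcome follow-up
there is no way to say whether a reclassification was *appropriate*, so
no net-reclassification-improvement statistic is offered. Subjects on
lipid-lowering medication are scored and goal-assessed as-is, matching
the analysis this package operationalizes.
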