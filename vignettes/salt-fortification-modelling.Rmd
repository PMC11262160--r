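---
title: "Modelling micronutrient fortification of salt: methods and design"
author: "saltfort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling micronutrient fortification of salt: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltfort)
```

## The problem

Salt reaches almost every household regardless of income, which makes
iodized salt an attractive vehicle for additional micronutrients such as
zinc and folic acid in settings where deficiency is widespread. Before a
fortification program is designed, two questions must be answered by
simulation: how much would fortified salt shift the distribution of usual
nutrient intake in each demographic group, and how high can the addition
rate go before an unacceptable share of the population exceeds the
tolerable upper intake level (UL)?

`saltfort` implements that simulation as a reusable pipeline for a
two-region Ethiopian setting (Addis Ababa and Somali; children 1–3 y,
women 15–49 y, men 19–45 y), from a single 24-hour recall per participant
through usual-intake estimation, discretionary-salt scenarios, fortified
intake, prevalence of inadequate (< EAR) and excessive (> UL) intake, and
constrained selection of addition rates.

## Usual intake from one recall: the external-variance shrinkage model

A single recall per person confounds between-person variation (what we
want: the spread of long-run average intakes) with within-person
day-to-day variation. With only one day observed, the within-person
component cannot be estimated from the data; it is imputed externally as a
ratio $r$ of within- to between-person variance on the log scale. The
packaged ratios are 0.47 (children) and 0.61 (adults) for zinc, and 0.72
and 0.89 for folate.

`fit_usual_intake()` implements the standard external-variance shrinkage:

1. transform intakes, $y_i = \log x_i$ (Box–Cox with estimated $\lambda$
   is available behind a flag; log is the default because intakes are
   strictly positive with multiplicative noise and it makes the ratio
   interpretation clean);
2. remove nuisance recall-day effects (weekend, sickness, unusual
   consumption) with a linear model and re-express each intake as
   predicted-at-reference-day plus residual. Stratifiers (region, SES,
   residence, sex) are *not* removed — they are kept for stratification;
3. decompose the observed variance: with
   $r = \sigma^2_w / \sigma^2_b$,
   $$\sigma^2_b = \frac{\sigma^2_{obs}}{1 + r}, \qquad
     \sigma^2_w = \sigma^2_{obs}\frac{r}{1 + r};$$
4. shrink each person's deviation from the stratum mean by
   $s = \sqrt{1/(1+r)}$:
   $\tilde y_i = \bar y + s\,(y_i - \bar y)$, and back-transform.

Per-person point estimates use the plain inverse transform; medians and
cut-point prevalences — the quantities reported — are invariant to any
lognormal mean correction because the back-transform is monotone. The
fitted object carries the full variance decomposition, and `predict()`,
`coef()`, `residuals()` and `simulate()` behave as for any R model object
(`simulate()` draws from the implied parametric usual-intake
distribution, which the closed-form tests use).

Numerical choices: strata need at least 30 participants (configurable);
smaller strata are pooled across regions within life stage, since the
variance ratio depends only on age class. Non-positive intakes under the
log transform are replaced by half the smallest positive value in the
stratum, with a message (configurable to an error). Whether covariate
recentring predicts at the covariate reference level or at the average
over the observed covariates is genuinely ambiguous in single-recall
workflows; both are implemented (`reference = "baseline"` or `"mean"`)
with the reference level as default.

## Prevalence of inadequate and excess intake

`prevalence_inadequate()` applies the EAR cut-point method to the
empirical distribution of per-person usual-intake estimates: the share
strictly below the person's EAR. Ties at exactly the EAR count as
adequate, and ties at the UL as not excessive (strict inequalities; the
convention is documented because sources are typically silent).
A parametric variant, `lognormal_cutpoint()`, gives the closed-form
normal-CDF value on the log scale and serves as the analytic oracle in
the tests.

EARs depend on physiological status: women's references are mapped
nonpregnant/nonlactating → low end (zinc 9.9 mg/d, folate 320 μg DFE/d),
pregnant → high end (13.7, 520), lactating → intermediate (11.8, 450).
ULs are IOM values (zinc 7 mg/d children / 40 mg/d adults; folic acid
300 / 1000 μg/d) shipped as overridable defaults. Following IOM
convention the folate UL applies to the synthetic folic-acid component
only, so the excess check for folate uses the fortificant-delivered
amount while zinc uses total usual intake; the `ul_basis` column of the
reference table encodes this per nutrient.

## Salt scenarios and fortification arithmetic

Total adult salt intake (urinary-sodium derived; sodium converts at
2.5 g salt per 2000 mg sodium, i.e. the 5 g/d equivalence, rather than
the molar 2.542 — configurable) is multiplied by the discretionary
fraction, 0.9 by default: 90% of total salt is taken to come from
discretionary salt and manufactured foods. Children have no urinary data;
their salt is proportional to energy intake relative to adults. Under the
*calculated* scenario the scaling base is the region-mean adult
discretionary salt (sex-pooled; the base is configurable because nothing
pins it down); under the *recommended* scenario every adult gets exactly
5 g/d and children get 5 g/d scaled by energy irrespective of sex and
residence. Full precision propagates internally; rounding to table
precision happens only in `round_report()`.

Fortified salt delivers `salt × rate` of each nutrient. The
`dfe_factor` converting μg folic acid to μg DFE defaults to 1.0 because
the reference delivery arithmetic this package mirrors counts fortificant
micrograms 1:1 (6.7 g/d × 22 μg/g = 147 μg DFE); the conventional 1.7 is
available by configuration. Delivered amounts are kept in their own
column so the two UL bases stay separable, and fortification adds the
delivered amount to the *adjusted usual* intake (post-adjustment
addition; a fortificant has no day-to-day variance of its own once salt
intake is treated as habitual). Adding before adjustment would shrink the
fortificant contribution along with everything else; the order matters in
the tails and the choice is deliberate.

## Rate selection

`optimize_rate()` searches a grid of addition rates (defaults: zinc
0–1.5 mg/g in 0.1 steps, folic acid 0–50 μg/g in 1 μg steps). At each
rate it runs the full fortification + adequacy machinery; the objective
is the population-weighted mean percentage-point reduction in inadequacy
across strata, and a rate is feasible when excess prevalence stays below
5%. The constraint is checked per stratum by default — the stricter
reading; a pooled option exists because the scope of "<5% of the
population" is ambiguous. Ties break to the lowest rate
(cost-conservative). A grid is exact up to its resolution because the
empirical prevalence is a step function of the rate. The two nutrients
are optimized independently: delivered amounts and constraints do not
interact across nutrients in this model. When no rate is feasible the
result says so and returns the full trace rather than throwing.

Under the default synthetic conditions the per-stratum zinc constraint
binds first for young children (their UL, 7 mg/d, sits close to the
fortified intake distribution), so the selected zinc rate is lower than
the 0.6–0.8 mg/g reference configuration; that is a property of the
constraint logic under these conditions, not a target to be recovered.

## The synthetic survey generator

The restricted survey microdata are not distributable, so
`generate_population()` emulates them with known ground truth. It
reproduces the study conditions: stratum sizes (422/722/86 in Addis
Ababa, 414/603/24 in Somali with 17% urban; Addis is urban-only), an SES
quintile mix that is heavily top-weighted in Addis, group-by-region
usual-intake medians matching the baseline medians (zinc 2.5/6.9/9.2 and
1.8/4.2/5.4 mg/d; folate 126/457/552 and 62/115/207 μg DFE/d for
children/women/men in Addis/Somali), between-person log-SD 0.5 (a
geometric SD of about 1.65, typical of single-nutrient usual intakes),
within-person noise at the imputed variance ratios, adult total salt
centred at 8.3 g/d with region-by-sex means whose discretionary 90% is
6.7–8.5 g/d, and child energy about 0.45 of adult energy — the value that
makes recommended child salt about 2.3 g/d, "almost half" of the adult
5 g/d. Recall-day covariate flags are drawn at plausible rates (weekend
2/7, sickness 0.10, unusual consumption 0.10).

Randomness uses one root seed with per-stratum substreams derived by
stable hashing of stratum labels, so adding a stratum never perturbs the
draws of others. The interpretation of the imputed variance numbers as a
within/between *ratio* on the log scale is itself a modelling decision —
their scale is not defined where they are quoted — and is pluggable
(`within_interpretation = "ratio"` or `"absolute"`); the ratio reading is
the default because a dimensionless quantity transfers across nutrients
with different units.

What the generator does *not* emulate: item-level recalls (nutrient
totals are generated directly; the recall-to-nutrient module is tested on
its own small composition-table fixtures), survey weights and design
effects, seasonality, and any correlation between salt intake and
micronutrient intake. Tests passing on this generator therefore validate
the estimation and simulation machinery, not the representativeness of
any particular survey.

## Problem sizes and tolerances in the test suite

Distributional checks run at the sizes where their Monte-Carlo error is
well inside the asserted tolerance: cut-point vs normal-CDF oracle at
n = 50,000 (±1 percentage point asserted, sampling error ≈ 0.2 pp),
variance-component recovery at n = 10,000 (±5% asserted, relative SE of a
sample variance ≈ 1.4%), covariate-effect recovery at n = 5,000. The
optimizer is checked against an exhaustive brute-force evaluation on a
200-person survey and an 11-point grid. Routine structural tests use a
down-scaled survey of a few hundred participants.

## Known limitations

- Point estimates only: no design-based or bootstrap uncertainty around
  prevalences, matching the reporting style this mirrors.
- The EAR cut-point method assumes the usual-intake distribution is
  well-characterized and requirements are symmetric; it is not the full
  probability-of-adequacy method.
- Single-recall estimation with an imputed ratio inherits whatever bias
  the imputed ratio carries; the ratio is a first-class input, not an
  estimate.
- Iodine co-fortification, premix stability, cooking losses, cost and
  sensory constraints are out of scope; rate caps are the only place such
  considerations can enter (via the grid bounds).
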