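---
title: "Model and methods: PRS-targeted type 2 diabetes prevention microsimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsmicrosim)
```

## The decision problem

Adults aged 30–79 are screened with the FINDRISC questionnaire; those
with a 10-year type 2 diabetes (T2D) risk of 10–20% form the *high-risk*
target population. The package compares two strategies over that
population:

* **Usual practice** — no further testing; since every member is below
  the 20% intervention threshold on conventional risk factors alone,
  nobody receives a preventive intervention.
* **Targeted PRS strategy** — every member is PRS-tested once (50 € by
  default, charged in year 1); the 10-year risk is re-estimated with the
  standardized polygenic score as an additional predictor, and anyone
  reaching ≥ 20% receives a lifestyle intervention, 30% of whom also
  receive medical weight-loss therapy.

Outcomes are per-person expected discounted costs (2021 €) and QALYs,
compared incrementally with dominance labelling, a cost-neutral test
price, and a full probabilistic sensitivity analysis (PSA) with CEAC and
EVPI.

## State-transition model

Four mutually exclusive states — healthy, T2D, T2D with complications,
dead — with annual cycles, simulated per individual until death or age
100. Within a cycle the engine first accrues that year's cost and
utility for the state occupied at the start of the cycle, then draws
death, then (for survivors) disease progression. This mortality-first
ordering is one reasonable convention among several; it is isolated
behind `step_state()` so a different ordering can be substituted without
touching the rest of the engine. No half-cycle correction is applied:
with annual individual-level accounting the correction would amount to
shifting every accrual half a year, affecting both arms almost equally,
and leaving the increments — the quantities of interest — essentially
unchanged.

### Incidence and extrapolation

T2D onset follows a Weibull accelerated-failure-time (AFT) model,

$$S(t \mid x) = \exp\left[-\left(t/\lambda(x)\right)^{k}\right],
\qquad \lambda(x) = \exp(\beta_0 + x\beta), \qquad k = 1/\text{scale},$$

with covariates age, sex and FINDRISC (plus the standardized PRS in the
extended model). This is the `survreg` log-time convention, declared by
the `parameterization: weibull_aft_logtime` tag in the coefficient
files, so externally estimated coefficients can be dropped in directly.
Annual transition probabilities are conditional survival ratios
$p_t = 1 - S(t+1)/S(t)$, which telescope back to $S(T)$ exactly (a
property the tests assert to 10⁻¹²). Beyond the 10-year follow-up window
the fitted curve is extrapolated unchanged, with baseline covariates
fixed and only $t$ advancing; re-evaluating age and FINDRISC annually
would double-count ageing already captured by the time-dependence of the
Weibull hazard. Both arms share one *natural-history* incidence process
(the with-PRS model by default, since the PRS carries real signal); the
strategies differ only in what the screening step observes.

Complication onset reuses the same machinery with the clock reset at T2D
diagnosis (time measured from onset), covariates age and sex.

### Mortality

All-cause annual death probabilities $q(\text{age}, \text{sex})$ come
from a life table (CSV: `age`, `sex`, `qx`). Diseased states apply
hazard ratios on the probability scale via the constant-within-cycle
rate conversion $q' = 1 - (1-q)^{\text{HR}}$: women with T2D 2.47, men
1.93, complications 2.36. The complications HR is interpreted as
*relative to the general population* (applied alone in that state); the
source is ambiguous on whether it stacks on the T2D HR, so a
`complications_on_top` switch implements the multiplicative reading.
Note that under the default reading a woman with uncomplicated T2D has a
slightly higher mortality multiplier (2.47) than a woman with
complications (2.36) — a direct consequence of taking both published
ratios at face value.

### Interventions

Intervention effects act multiplicatively on the annual onset
probability through the same rate-scale conversion: HR 0.74 (lifestyle)
or 0.51 (combined), for 15 years from screening (cycle 1), with full
adherence by default. The effect clock starts at simulation year 1
because screening and intervention start are simultaneous in this
design. PSA draws of these HRs are allowed to exceed 1 (the published
lifestyle-effect interval itself crosses 1), so the PSA honestly
represents the possibility of a null or harmful intervention.

## Economics

Annual state costs (all 2021 €): T2D = primary care (562 men / 542
women) + medication (584) + secondary care (3315) + productivity loss
(7632, only while under age 65 and only under the societal perspective);
complications add 4401. The lifestyle intervention costs 650 € once
(year 1); the medical therapy 1965 €/year for `medical_cost_years`
years. The source does not state how long the therapy cost runs; the
default is 1 year, matching the stated 1-year weight-loss window, and
results are sensitive to this choice — it is deliberately a single
prominent policy field. Similarly, the 650 € lifestyle cost is taken as
one-off rather than annual.

Utilities are EQ-5D-3L population baselines by sex and age band
(30–44, 45–54, 55–64, 65+), resolved from the *current* simulated age
each cycle, minus additive disutilities (T2D 0.041; complications
additionally 0.119), floored at 0. An alternative `replace` rule
(complications disutility replaces the T2D one) is available; additive
is the default because the complications weight was constructed as an
increment over uncomplicated disease.

Discounting is 3%/year for both costs and QALYs, applying from the
second year onward: year $t$ carries $(1+r)^{-(t-1)}$.

## Synthetic data

The original analysis rests on restricted registry data, so the package
generates its own: the cohort generator draws age from a truncated
normal (mean 61.5, SD 10 — only the mean is published, the SD is a
realistic choice for a screened older population) over 30–79, sex with
63.9% men, BMI, waist (regression on BMI plus noise), the binary and
categorical FINDRISC items from Bernoulli/multinomial distributions with
prevalences typical of an older Finnish screening population, and a PRS
that is sample-standardized to mean 0, SD 1 exactly. FINDRISC is then
*computed* from the items with the published 8-item table, so score and
covariates are mutually consistent.

The shipped Weibull coefficient sets are stipulated synthetic values:
plausible effect directions (risk increasing in age, male sex, FINDRISC,
PRS; the PRS log-time weight −0.25 corresponds to a hazard ratio of
about 1.4 per SD) with the intercept calibrated once, against the
default generator, so that ≈ 10.5% of generated adults fall in the
10–20% risk band. The calibration targets only that published figure;
the joint covariate structure of the band (its exact age/sex profile,
the FINDRISC distribution) is *not* matched to the unpublished
registry distribution. Consequently, passing tests demonstrate that the
machinery is correct — selection logic, risk monotonicity, parameter
recovery from simulated follow-up — not that the shipped defaults
reproduce Finnish epidemiology; headline outputs under synthetic inputs
characterise the model, not the population.

## Probabilistic sensitivity analysis

Every uncertain parameter carries a distribution: lognormal for hazard
ratios (natural-scale moment matching, $\sigma^2 = \log(1+(se/m)^2)$,
$\mu = \log m - \sigma^2/2$, which round-trips the stated mean/SD
exactly), gamma for costs (shape $(m/se)^2$, rate $m/se^2$), beta for
utilities and disutilities via method of moments
($\nu = m(1-m)/se^2 - 1$). Where the source publishes explicit beta
shape terms that its own printed mean/SE cannot reproduce (the
complications disutility), the printed shapes are stored and used
directly. Standard errors missing from the sources are recovered from
95% CIs as $(U-L)/(2 \times 1.96)$, or from ±25% bounds when no interval
exists. All draws are independent: no correlation structure is
published, and imposing one would be an invention.

Each PSA replicate samples one parameter set, generates a fresh target
cohort, and simulates *the same individuals through both arms* under
common random numbers — one pre-generated uniform stream per person-year
for death and progression plus per-person streams for uptake and
adherence. Pairing makes the increment estimates far less noisy and
yields exact null equivalence: with a zero PRS coefficient and a free
test the two arms produce bit-identical results, a property the tests
assert. Within a draw, individual-level noise is averaged before any
decision statistic; CEAC counts draws with higher net monetary benefit
for the PRS strategy (exact ties as 0.5, making the null case
symmetric at 50%), and EVPI is the mean per-draw best NMB minus the best
mean NMB.

## Numerical conventions and degenerate inputs

* Risk bands are half-open: 0.20 belongs to very-high; 0.10 to high.
* The target-cohort builder generates in adaptive batches until the
  requested size is reached (erroring after 50 batches if retention is
  pathologically low).
* A zero-hazard incidence model is representable (`intercept = Inf`);
  survival is then exactly 1 at all times.
* `S(t)=0` (degenerate model) raises an error rather than yielding
  `NaN` transition probabilities; all-censored inputs to the fitter are
  an error naming the cause.
* Family selection uses lowest AIC with ties broken by lowest BIC;
  per-family fit failures are reported in the comparison table without
  aborting the others.
* A negative cost-neutral price is clamped to 0 with a warning.
* Sub-seeds for cohorts and arms are derived from the master seed and
  kept below 2³¹.

## Problem sizes

Defaults (`run_config()`) are 1,000 individuals per arm and 100 PSA
draws — sizes chosen so a full base case + PSA + scenario sweep runs in
well under a minute on a single core while leaving Monte-Carlo error
small relative to the effects studied; the full-scale configuration
(10,000 per arm, 1,000 draws) is a matter of two arguments. The test
suite exercises parameter recovery at n = 50,000 with 10-year censoring
and the direction-of-effect property across 20 paired replicates of
2,000 individuals per arm.

## Known limitations

* No competing-risk decomposition of mortality; death is all-cause.
* Intervention effects are independent of PRS (no gene–lifestyle
  interaction), mirroring the evidence gap.
* No adverse effects of the medical therapy, no behaviour change from
  risk disclosure, no travel/direct non-medical costs.
* The synthetic defaults make no claim about FINRISK covariate joint
  distributions (see above); users with access to real coefficient sets
  and life tables should supply them via the YAML/CSV interfaces.
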