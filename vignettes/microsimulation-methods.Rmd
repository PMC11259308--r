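---
title: "Methods: troponin-stratified CVD screening microsimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: troponin-stratified CVD screening microsimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(troposim)
```

## The model

`troposim` is an individual-level discrete-event simulation comparing two
strategies for guiding preventive treatment in an asymptomatic
primary-prevention population:

* **SCORE** — each person's estimated 10-year fatal-CVD risk is binned
  into four classes (Low `< 1%`, Mod `1–<5%`, High `5–<10%`, VeryHigh
  `>= 10%`) and treatment is assigned with class-specific probabilities
  (0 / 0 / 50% / 100%).
* **S-SCORE** — each SCORE class is further split by sex-specific
  high-sensitivity troponin I (hsTnI) cut-offs (women 4 and 10 ng/L, men
  6 and 12 ng/L; the middle band is closed on both sides), giving 11
  stratified classes; treatment probabilities shift down for
  troponin-negative and up for troponin-elevated classes. In the
  VeryHigh class the two elevated bands are merged, since treatment is
  universal there.

Each simulated person carries sex, baseline age, SCORE risk (a
fraction), and hsTnI (ng/L). For every person, latent times to first
CHD event, first stroke, and non-CVD death are drawn from sex-specific
Weibull distributions in the rate form $F(t) = 1 - e^{-\lambda t^k}$.
The earliest latent time within the horizon (default 10 years) is the
person's first event; ties (a measure-zero set) are broken with priority
CHD, stroke, non-CVD death. An event is fatal with a sex- and
event-specific probability; survivors draw a post-event survival time
from a Weibull specific to event type, sex, and **age band at the
event** (baseline age plus event time; bands `<55`, `55–74`, `75+`).
CVD-related death means a fatal event or any post-event death within the
horizon.

The two strategy arms share every random draw (common random numbers):
one uniform per latent event time, one per fatality resolution, one per
post-event survival, and one for treatment assignment. In the S-SCORE
arm, the latent CHD and stroke times of individuals whose management
*changed* are rescaled through the treatment risk ratio $rr$ (default
0.65): newly treated individuals' scales become $\lambda' = rr\lambda$
(equivalently $t' = t\,rr^{-1/k}$ at fixed uniform), withdrawn
individuals get the reciprocal. With $rr = 1$ the two arms are identical
realization by realization, which the test suite asserts bitwise.

$\lambda' = rr\lambda$ is applied literally. Because
$F'(10)/F(10) = (1-(1-p)^{rr})/p \ne rr$ exactly, the realized 10-year
incidence ratio deviates from $rr$ — by under 2% at the male-CHD scale
of event probability. An alternative that solves $\lambda'$ from
$F'(10) = rr\,F(10)$ exactly is available behind
`event_model_params(exact_probability_ratio = TRUE)`, default off.

### Treatment assignment coupling

Nothing in the strategy definitions fixes how the two treatment
Bernoullis are coupled within a person. We use one shared uniform
(comonotonic coupling): a person is treated under a strategy iff
$u < p$. A person's propensity to accept treatment is treated as a
stable trait; independent draws would spuriously inflate the
changed-management fraction above $|p_1 - p_2|$ (a property the tests
verify on both couplings). Independent coupling remains available via
`experiment$coupling = "independent"`.

## Time-to-event calibration

Only 10-year cumulative probabilities are anchored for the three latent
events (CHD female/male 2.4/6.6%, stroke 0.8/1.4%, non-CVD death
3.6/5.9%), so scales are solved from
$\lambda = -\ln(1-p)/T^k$ and the shape defaults to $k = 1$
(exponential). At the 10-year anchor the shape is inert; it is
configurable per sex and event for scenario work. Post-event mortality
is anchored at a 5-year reference horizon (e.g. post-CHD men 75+:
63.2%), again with default shape 1; a second anchor point can be
supplied (`post_event$anchor2`) to fit the shape through two points with
the closed-form two-point solution, which the tests hold to $10^{-9}$
round-trip accuracy. Values for post-event mortality are interpreted as
5-year cumulative probabilities; the underlying source's 1-/5-year pair
is not reprinted in the inputs we anchor to, so the one-point + shape
form is the default.

Every calibration is validated by round trip: simulated latent-time
fractions within 10 years reproduce the configured probabilities at
n = 200,000 within binomial error (`scripts/acceptance.R` recomputes
these), and `km_cumulative_incidence()` (a Kaplan–Meier wrapper around
the survival package, competitors censored) provides an independent
estimator for the same check.

## Economics

Continuous-time discounting uses the annual-equivalent factor
$(1+r)^{-t}$ with $r = 3\%/y$ by default; a constant flow over
$[a, b]$ has the closed form
$x\,\big((1+r)^{-a} - (1+r)^{-b}\big)/\ln(1+r)$, reducing exactly to
$x(b-a)$ at $r = 0$. Discrete cycles and half-cycle corrections are
unnecessary because event times are continuous. The closed forms are
tested against adaptive quadrature to $10^{-8}$.

QALYs: asymptomatic utility 0.96/y until first event or death; a
non-fatal event charges a one-time acute decrement (CHD 0.15, stroke
0.19) discounted to the event time — the decrements are absolute QALY
amounts back-calculated to the event, not rate changes — then the
chronic utility (0.82 / 0.52) runs until death or horizon. Treatment
carries 0.01/y disutility while on treatment. Immediately fatal events
charge no acute decrement (life ends at the event; the decrement
represents the recovery year) — configurable.

Costs (2019 €): screening 44 € at baseline (+25 € for the troponin assay
under S-SCORE); prevention 595 €/y while treated; event costs as
piecewise-constant streams (CHD 15,805 / 2,318 / 600 €/y; stroke
21,724 / 13,528 / 8,571 €/y for the first year, second year, and later
years), truncated at death or horizon. Fatal events charge the full
first-year amount as a lump at the event (acute resource use occurs
regardless of survival) — configurable. Prevention cost and treatment
disutility stop at the first event by default (post-event management is
inside the event cost estimates); `prevention_to_death` continues them.
Person-level cost heterogeneity is a gamma multiplier per event-cost
category with mean 1 and CV 0.10.

## Outcome measures

Per strategy: cumulative first-event incidences, all-cause and
CVD-related death within the horizon, treated fraction, event-free
survival years per 1,000 screened, potential years of working life lost
(years before age 65 lost to CVD-related death) per 1,000, mean
discounted cost and QALYs. Comparisons: ARR, RRR, NNS = 1/ARR,
ICER = incremental cost per QALY gained, and INMB = WTP·ΔQALY − ΔCost at
a default willingness-to-pay of 50,000 €/QALY, with dominance flagged
when the signs disagree.

The base-case design generates one source cohort, then runs 100
independent runs of 20,000 bootstrapped individuals; point estimates are
means across runs and intervals the 2.5th/97.5th percentiles of the run
distribution. The horizon is configurable (15 years reproduces the
extended-horizon scenario); alternative policy tables express
derived-management scenarios.

## The synthetic cohort generator

No individual-level cohort is shipped; the generator emulates the
published marginals of a large European primary-prevention population:

* sex: 48.7% male;
* age: truncated normal, location 50.6 y, spread 13.3 y on [20, 85].
  The spread reproduces the published interquartile range
  (41.3–59.2 y); the printed quartiles are nearly symmetric around the
  median, so no skewed family is needed;
* SCORE risk: hierarchical — class from configurable proportions
  (defaults Low 35.0%, Mod 51.6%, High 8.0%, VeryHigh 5.4%), then
  uniform within the class interval (capped at 25%). Only class
  membership drives management, so within-class placement is inert. The
  default proportions satisfy $0.5\,p_{High} + p_{VeryHigh} = 0.094$,
  reproducing a 9.4% treated fraction under the standard policy in
  expectation;
* hsTnI: lognormal per sex (medians 2.2 / 3.2 ng/L, log-sd 0.6),
  giving an elevated fraction of roughly 15% and sex-specific medians
  below the low cut-offs, as in a mostly low-risk healthy population;
* dependence: a Gaussian copula couples the SCORE-risk percentile to
  the hsTnI percentile with configurable Spearman correlation (default
  0.3, via the exact relation $\rho = 2\sin(\pi\rho_S/6)$). This is the
  policy-relevant free parameter of the generator: it controls how
  troponin elevation concentrates in higher SCORE classes.

### What the generator does not emulate — and what that implies

The event engine draws latent times from sex-stratified *average*
distributions: event risk does not depend on an individual's SCORE risk
or hsTnI. This follows the model design of an age- and risk-independent
average time-to-event per sex, and it is the right surface for testing
calibration, coupling, and accounting identities. It has one important
consequence for the strategy contrast: individuals whose management
changes carry population-average event risk (about 5% over 10 years),
so the QALY gain from their prevented events (≈ 0.05 × 0.35 × ≈2
QALYs ≈ 0.04 per newly treated person) is smaller than ten years of
treatment disutility (≈ 0.087 discounted). With any net treatment
expansion the simulated QALY difference is therefore negative and the
stratified strategy is dominated, even though it does reduce events and
event-free survival improves. A positive QALY gain of the size reported
for the real cohort requires the changed-management group to carry
several times the average event risk — the risk concentration that
biomarker-based reclassification achieves in real data, where outcomes
were bootstrapped jointly with characteristics. Passing simulation tests
here therefore validate the machinery (calibration, coupling,
accounting, uncertainty propagation), not the real-world effectiveness
conclusion; event reduction, cost increase, event-free survival gain and
working-life-years saved do reproduce directionally.

## Uncertainty analysis

Second-order parameter uncertainty uses one distribution per parameter
(beta, normal, uniform, gamma, lognormal, or fixed), sampled
independently. Stated ranges are interpreted as central 95% intervals:
normal sd is $(hi-lo)/3.92$; beta and gamma concentrations are matched
numerically so the mean equals the base value and the central 95%
interval approximates the range; ±10%/±25% ranges expand
multiplicatively. Time-to-event uncertainty enters as a uniform
0.9–1.1 multiplier on each calibrated scale (interval estimates of the
underlying fits are not reprinted in the anchored inputs), applied as
$p' = 1-(1-p)^m$ so that calibration round trips stay exact.
Probabilities are clamped to [0, 1] after sampling.

The PSA runs 500 iterations of 20,000 individuals; each iteration draws
one parameter set and generates a fresh cohort directly at that size
(the male fraction is itself a second-order parameter, so regenerating
is cleaner than bootstrapping a fixed mega-cohort and is
distributionally equivalent for a synthetic population). The CEAC
reports, on a 0–100,000 € grid with 1,000 € steps, the fraction of
iterations with positive net benefit. Univariate (tornado) analysis
runs each ranged parameter at its bounds with all others at base,
100,000 individuals per run, under common random numbers, and sorts by
the largest absolute INMB deviation from base.

## Numerical and degenerate-input conventions

* SCORE class intervals are lower-inclusive (`1 to <5%`); the troponin
  middle band is closed (`4–10`), so exactly 10 ng/L in a woman is
  "plus". hsTnI is ng/L throughout.
* QALY totals are floored at zero (an acute decrement can exceed the
  tiny utility stream of a person who has an event and dies almost
  immediately).
* Empty cohorts, empty assignment sets, and empty PSA results raise
  errors rather than returning NaN; `n = 0` cohort generation returns an
  empty, well-typed table.
* `NNS` is flagged `NA` when ARR ≤ 0; ICER is `NA` under dominance.
* All randomness derives from one root seed through named substreams
  (cohort, management, events, costs, second-order draws, per-run
  seeds), so adding draws in one module never perturbs another and
  every result is exactly reproducible from the config and seed.
* The monotonicity property "a stronger treatment effect never adds
  events" holds for expansion-only policies and is tested on one;
  with withdrawals it cannot hold person-wise, because withdrawn
  individuals carry the reciprocal risk ratio, which grows as the
  treatment effect strengthens.

## Problem sizes used in the shipped tests

Calibration round trips use 200,000 latent times per sex–event cell
(500,000 per arm for the incidence-ratio check); distributional checks
on the generator use 100,000 individuals; the directional base-case
check uses 30 runs of 5,000; coupled-simulation properties use cohorts
of 3,000–10,000; PSA/tornado smoke checks use a few hundred to a few
thousand individuals per run. These sizes keep every stochastic
assertion several standard errors away from its threshold. A full
100 × 20,000 base case and a 500 × 20,000 PSA run in minutes on one
CPU core.

## Limitations

Single first event per person (no recurrence), one-time screening at
baseline, no adherence or lifestyle-advice modelling, treatment effect
from a single drug-class risk ratio applied to both CHD and stroke,
indirect costs summarized only as working-life years lost, and the
synthetic-cohort caveat above. The risk equation itself is out of
scope: estimated risk enters as an attribute.
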