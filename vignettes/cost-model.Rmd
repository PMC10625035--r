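---
title: "Modelling the 20-year cost of pediatric pacing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the 20-year cost of pediatric pacing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedipace)
```

`pedipace` models the economic burden of permanent pacemaker (PPM)
dependence acquired in childhood, when congenital heart surgery (CHS)
injures the conduction system and the patient needs pacing for life.
This vignette is the package's account of its science: the model and
its assumptions, the parameters that matter, what the synthetic-data
generator does and does not emulate, the numerical choices, and the
design decisions taken where more than one defensible option existed.

## The cost model

A patient enters at implantation (cycle 0) and is followed over annual
cycles $t = 1, \dots, H$. The package deliberately uses the *minimal*
state structure consistent with the clinical description: one alive
"with PPM" state with independent per-cycle event draws, plus an
optional absorbing exit state entered with annual probability $q$
(`attrition`, default 0). There is no half-cycle correction; costs
accrue at cycle end, and the implantation cost accrues at $t = 0$
undiscounted.

Events split into two families:

* **Major complications** carry an annual *probability* and are drawn
  as at-most-once-per-year Bernoulli trials: device malfunction
  requiring lead-and-generator replacement ($p = 0.020$), generator
  replacement at battery depletion ($p = 0.112$), and device infection
  ($p = 0.006$).
* **Minor monitoring events** carry an annual *frequency* and are drawn
  as Poisson counts: clinic visits (1.5/y), device checks (0.9/y),
  ECGs (1.8/y), Holter studies (0.1/y), and electrophysiology
  catheterizations (0.1/y). Cardiac rehabilitation is carried in the
  taxonomy with rate 0, since no reference rate or cost is available
  for it.

The Bernoulli/Poisson split is itself a design decision: the reference
inputs distinguish "annual %" from "annual frequency" without naming a
distributional family, and this is the minimal-assumption reading
(probabilities cannot exceed one occurrence per cycle; frequencies
can).

Each occurrence of event $e$ accrues its mean unit cost, discounted at
annual rate $r$ (default 3%), giving the closed-form expectation

$$
\mathrm{E}[C] \;=\; c_{\text{implant}}
  + \sum_{t=1}^{H} (1-q)^t (1+r)^{-t} \sum_e \mathrm{rate}_e \, c_e .
$$

`expected_costs_closed_form()` evaluates this exactly;
`simulate_cohort()` is the patient-level Monte-Carlo version, and the
test suite holds the two to agreement within Monte-Carlo error at every
parameter bundle it tries. Because unit costs enter the simulation as
constants multiplying the event draws, multiplying all unit costs by
$k$ scales the simulated mean and SD by exactly $k$ under a fixed
seed — a property the tests assert, and a useful smoke alarm against
accidental nonlinearity.

**Why expose attrition at all?** Back-calculating from the reference
point estimates under $q = 0$ gives a 20-year expectation materially
above externally reported means for this population, implying an exit
mechanism (death, transfer of care, device explantation) that the
minimal structure omits. Rather than invent states we cannot
parameterize, we expose a single transparent dial:
`calibrate_attrition()` inverts the closed form by root finding
(`stats::uniroot` on $q \in [0, 1)$, matched to within \$1). The
calibrated $q$ should be read as "the exit rate the reported mean
implies under this structure", not as an estimate of mortality.

**Dispersion.** The implantation cost is deterministic (its mean) by
default, because the across-patient spread of a simulated cohort is
otherwise dominated by the implantation SD, which is larger than its
mean; `sample_implant_cost = TRUE` draws it from a zero-truncated
normal instead (inverse-CDF truncation, not clipping, so the
distribution is a genuine truncated Gaussian). Summaries report both
the across-patient SD and the SE of the mean, since "mean (SD)" in
published summaries is ambiguous between the two.

**Random numbers.** Each generator and the simulator take an integer
seed and use one seeded stream with a fixed, documented draw order
(survival first, then each event type in canonical order as a
patients-by-cycles block). This is reproducible byte-for-byte,
invariant to patient labelling, and fully vectorised; we chose it over
per-patient substreams because the single stream is an order of
magnitude faster at the $10^5$-patient scale the oracle-equivalence
check runs at, with no loss of reproducibility.

## Parameters that matter

| Parameter | Units | Default | Notes |
|---|---|---|---|
| `horizon` | years | 20 | follow-up horizon, annual cycles |
| `discount_rate` | fraction/yr | 0.03 | applied to cycles 1..H |
| `attrition` | probability/yr | 0 | exit dial, see above |
| `n_patients` | count | 10 000 | modelled population |
| major `annual_rate` | probability/yr | 0.020 / 0.112 / 0.006 | Bernoulli |
| minor `annual_rate` | events/patient-yr | 1.5 / 0.9 / 1.8 / 0.1 / 0.1 | Poisson mean |
| unit costs | 2018 USD | see `ppm_cost_parameters()` | means; SDs drive PSA and billing noise |

## The synthetic-data generator

The generator (`generator_config()`, `generate_events()`) emulates an
institutional event database: every patient has an index surgery, an
implantation 0–30 days later (uniform integer delay), an implantation
age uniform on [0, 4) years, and per-year event draws identical in law
to the cost model's. Within-year event times are uniform — the
reference material is silent on within-year timing, and nothing
downstream depends on it except the year binning. Lengths of stay are
moment-matched gamma draws (exact mean and SD, non-negative, right
skew), degenerate for the fixed clinic-type LOS of 0.125 day.

**Billing.** Direct charges follow
$\text{charge} = b_e \cdot \text{LOS} + \varepsilon_e$ per event type,
with $b_e$ and the noise SD solved so that the expected charge equals
the event's mean cost, the charge SD equals its cost SD, and the
population $R^2$ of charge on LOS equals a configured target (defaults
0.838 for implantation, 0.23 for malfunction, 0.007 for generator
change, 0.864 for infection). The noise is a moment-matched gamma with
mean equal to the regression intercept rather than a clipped Gaussian:
at these magnitudes (implantation mean \$108,052, SD \$109,053,
residual SD ≈ \$44,000) a Gaussian would fall below zero for a large
share of short stays, and clipping would bias the mean by thousands of
dollars and spoil both the $R^2$ calibration and parameter recovery.
The gamma construction is non-negative by design, hits all three
moments exactly, and is right-skewed like real hospital charges. The
clipped-Gaussian family remains available (`noise_family =
"gaussian"`), with clip counting and a warning above 5%.

**Indirect costs** (the accompanying adult's out-of-pocket burden) are
deterministic per event: a per-day rate (default \$505.14/day,
interpolated from the two fixed-LOS monitoring rows) anchored at each
event type's mean, so the expected indirect cost per event matches the
bundle exactly. A single global per-visit/per-day line cannot do this:
the reference rows are not collinear, which is also why
`fit_indirect_model()` — the plain least-squares fit over those rows —
predicts about \$146 for a 0.125-day clinic visit rather than the
tabulated \$136. The package reports the fitted value honestly rather
than forcing agreement.

**What the generator does not emulate:** lesion complexity and its
correlation with complication risk, time-varying event probabilities
(device technology improved over the decades), correlated events within
a patient (an infection raising subsequent malfunction risk), surgeon
identity, and demographic covariates. Passing tests therefore
demonstrate internal consistency — estimation recovers what the
generator put in, the simulation agrees with its analytic
expectation — not that real costs follow these laws.

## Estimation choices

Cohort selection mirrors the clinical inclusion rules: implantation
within 30 days of surgery (inclusive — "within" is read as ≤), age
strictly under 4 years at implantation, at least 6 months of follow-up,
and exclusion of any patient with a cardioverter-defibrillator.

Annual rates are events per person-year. Follow-up is observable only
up to each patient's last recorded event, and with annual-cycle data
the raw last-event time systematically undercounts exposure (the gap
between the last event and the end of the last at-risk year), which at
monitoring-event frequencies of several per year biases every rate up
by about 1% — more than the Monte-Carlo error at the scales we test.
The default exposure convention is therefore whole at-risk cycles,
`ceiling(last event time in years)`; `exposure = "exact"` gives the raw
convention. Major-event rates are interpreted as annual probabilities
(a good approximation at these magnitudes) with Wilson intervals on
person-year trials; minor-event rates get exact Poisson intervals.
Sample SDs use the $n-1$ denominator throughout; a single event reports
SD 0 with a message rather than `NA`.

## Probabilistic sensitivity analysis

Families follow health-economics convention, since the reference
analysis names none: beta for probabilities, gamma for positive costs,
point masses for parameters with no uncertainty information (the
monitoring frequencies and their deterministic charges). Probabilities
have no reported SD, so beta concentration comes from an effective
sample size (default 255, the size of the follow-up cohort behind the
default rates). The inner evaluation is the closed form, so the
reported spread is parameter uncertainty only; an inner-simulation
option exists and is tested for agreement. Lengths of stay are not
varied because they do not enter the cost expectation — they matter
only through the unit costs, which are varied directly.

## Cumulative cost curves and extrapolation

`build_cost_curves()` bins events by whole years since implantation
(`floor(days/365.25)`), classifies each patient's course as
"complication" (≥ 1 malfunction-replacement or infection; generator
change alone does not qualify), and averages cumulative costs at each
year over the patients still under follow-up at that year — the
varying-$n$ convention, not last-observation-carried-forward.
`extrapolate_20y()` fits ordinary least squares to the mean curve over
years 10–19 and evaluates at year 20; on an exactly linear curve this
is the identity, which the tests assert. Extrapolation defaults to the
no-complication group, whose curve is near-linear after the first year;
the complication group's curve is dominated by rare expensive events
and is extrapolated only on request.

## Numerical notes and problem sizes

Degenerate inputs are handled explicitly: all rates zero collapses the
model to the implantation cost exactly; zero person-years, all-zero
counts, constant LOS designs, and sub-3-point extrapolation windows are
errors, not NaNs; a constant extrapolation curve returns the constant
with an undefined $R^2$ rather than a spurious 1. Attrition calibration
uses `uniroot` at tolerance $10^{-12}$ and validates the attainable
range (implant cost up to the zero-attrition expectation). The test
suite runs the oracle-equivalence check at $10^5$ patients, parameter
recovery at $10^4$ patients over 20 years (≈ $2 \times 10^5$
person-years), and the PSA consistency check at $10^4$ draws; these
sizes make the 3-standard-error acceptance bands decisive while keeping
the default suite to a few minutes.

## Known limitations

The single-state structure with a constant attrition dial is a
transparent stand-in, not a claim about the clinical process; event
probabilities are time-constant; no utilities or QALYs are modelled (no
cost-effectiveness claims are possible); costs are all in 2018 USD with
no inflation structure; and the indirect-cost perspective is
deliberately conservative (one accompanying adult, on-the-ground costs
only). Synthetic volume-series defaults are chosen to match the scale
and growth pattern of a large single-center surgical program
(1960–2018, total-volume growth 2.2%/yr, pacemaker-implantation growth
7.2%/yr from 1963, a surgeon roster growing from 1 to 10); the roster's
printed endpoints and its log-linear slope are mildly inconsistent with
a pure geometric series, and the generator keeps the endpoints.
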