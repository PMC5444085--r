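---
title: "Modelling and measuring adult mosquito behaviour for vector control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring adult mosquito behaviour for vector control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vectorcycle)
```

## The problem

Residual malaria transmission persists under high coverage of long-lasting
insecticidal nets (LLINs) and indoor residual spraying (IRS) because many
vector mosquitoes evade these tools behaviourally: they feed on animals,
feed or rest outdoors, or exit houses quickly. The same behaviours that
protect a vector population from nets and sprays, however, expose it to
other interventions — veterinary insecticides, treated clothing and vapour
emanators, window screening and eave devices, toxic sugar baits, swarm
sprays. `vectorcycle` provides the quantitative machinery for reasoning
about this: a feeding-cycle model of how layered interventions cover and
kill mosquitoes attacking different host/location compartments, estimators
for the behavioural indicators a control programme can survey, and the
threshold rules that map those indicators to applicable technologies.

## The feeding-cycle model

One gonotrophic cycle is modelled as an absorbing process over repeated
attack attempts. A behaviour profile decomposes attempts over five
compartments — humans indoors in bed, humans indoors out of bed, humans
outdoors, treatable livestock, other animals — with baseline weights

\[
a = \left(q\pi_i\pi_b,\; q\pi_i(1-\pi_b),\; q(1-\pi_i),\;
(1-q)f_\ell,\; (1-q)(1-f_\ell)\right),
\]

where \(q\) is the human blood index, \(\pi_i\) the indoor fraction of
human exposure absent protection, \(\pi_b\) the in-bed fraction of indoor
exposure and \(f_\ell\) the livestock share of animal meals.

Each attempt picks a compartment with weight \(a_j\) and then meets the
attack-phase interventions protecting that compartment in their configured
order. An intervention with coverage \(c\), pre-bite kill probability
\(p\) and non-lethal block probability \(b\) kills the attempt with
probability \(cp\), diverts it to a fresh attempt with probability
\(cb\), and otherwise lets it continue; uncovered attacks always feed.
With per-attempt totals \(K\) (kill), \(B\) (block) and \(F_j\) (feed in
\(j\)), the absorbing-chain solution is

\[
p_\text{pre-death} = \frac{K}{1-B}, \qquad
p_\text{fed}[j] = \frac{F_j}{1-B}, \qquad
E[\text{attempts}] = \frac{1}{1-B},
\]

so that \(p_\text{pre-death} + \sum_j p_\text{fed}[j] = 1\) identically.
Post-feed mortality then compounds independent hazards on the fed
mosquitoes: wall sprays reached by resting indoors after an indoor feed
(`r_indoor_rest * coverage * post_kill`), insecticide-treated livestock,
sugar baits scaled by the per-cycle sugar-feeding rate, and swarm sprays.
Every closed-form fate probability is validated in the test suite against
a direct stochastic simulation of these attempt rules (at least \(10^5\)
replicates, fixed seeds, agreement within Monte-Carlo standard errors).

Multiple interventions protecting the same compartment compound as
independent per-attempt hazards in their listed order. Independence is the
minimal assumption for layering technologies whose interactions have not
been characterised; synergy or antagonism between products on the same
host is deliberately out of scope.

### Encounter multiplication and population coverage

Blocking is not only protective — it multiplies the encounters a mosquito
must make. With usage \(u\) of a blocking technology and per-encounter
block probability \(b\), relative blood availability is \(z = 1 - ub\) and
a meal requires on average \(1/z\) encounters. The default block
probability `LLIN_BLOCK_DEFAULT = 0.625` is calibrated so that 80% net
usage exactly doubles the encounters (equivalently, houses entered) per
meal, the empirically observed magnitude for *Anopheles arabiensis* under
high net coverage; it is a named, overridable constant.

Repeated house entry is an opportunity for house-delivered insecticides.
The per-cycle mosquito population coverage of such a product at house
coverage \(C_h\) is modelled as the probability of at least one covered,
indoor encounter over \(e\) independent house entries, scaled by the
human-fed fraction:

\[
C_M = q\left(1 - (1 - \pi_i C_h)^e\right).
\]

At \(e = 1\) this collapses to the simple product \(q \pi_i C_h\); at the
net-driven \(e = 2\) it strictly exceeds the single-entry value at every
intermediate \(C_h\). This functional form is a reconstruction from the
stated limits (simple product at single entry; amplification under
repeated entry) rather than a transcription of any particular published
equation; both limits are enforced by tests.

## Layering and the transmission proxy

`apply_stack()` applies an intervention stack one cumulative prefix at a
time and traces how residual blood meals redistribute. A purely blocking
layer on one compartment strictly shrinks that compartment's share of
residual meals and grows every other share — the plastic ("behavioural
resilience") redistribution that makes second-line interventions
increasingly effective. `remeasure()` inverts a cycle outcome into the
behaviour profile a post-intervention survey would observe; the
indoor-resting and sugar-feeding rates are not identifiable from a meal
distribution and are carried over from the baseline profile.

Each layer's impact is summarised by a relative transmission proxy: with
\(h_k\) the probability of feeding on a human in the cycle and \(S_k\) the
per-cycle survival, the expected lifetime human feeds under geometric
survival are \(h_k/(1-S_k)\), and

\[
T_k = \frac{h_k/(1-S_k)}{h_0/(1-S_0)}.
\]

A background per-cycle survival (default 0.7, corresponding to daily
survival near 0.89 over a three-day cycle) multiplies the
intervention-driven survival. Without it the intervention-free baseline
would have \(S_0 = 1\) and an infinite expected lifetime, making the ratio
degenerate; with it, \(T_0 = 1\) and every effective layer strictly
reduces \(T\). The proxy deliberately omits the sporogonic delay: it
ranks intervention stacks by per-cycle feeding and survival alone, and
should not be read as a vectorial-capacity estimate. Survival-prolonging
interactions (e.g. a shorter cycle under blocking) are not modelled.

## Behavioural indicators from field surveys

Three estimator families cover the field-surveyable indicators:

* **Human blood index** (`human_blood_index()`): proportion of
  host-identified blood meals that are human, with a Wilson score
  interval. Score intervals are used for every proportion in the package
  because they behave sensibly at the 0 and 1 boundaries that small
  entomological samples often hit. Mixed human+animal meals, when
  recorded as `"human+cattle"`-style classes, are split 0.5/0.5 by
  default (configurable) — the convention is documented in the output
  rather than hidden.
* **Exposure distribution** (`exposure_distribution()`): hourly biting
  rates weighted by the human time budget,
  \(w_\text{in}(t) = B_\text{in}(t) H_\text{in}(t)\),
  \(w_\text{out}(t) = B_\text{out}(t)(1 - H_\text{in}(t))\), on 24
  half-open hour bins \([h, h+1)\). Returns the indoor exposure fraction,
  the in-bed fraction of indoor exposure, and the hourly profile. A flag
  excludes in-bed exposure to describe the residual exposure of fully
  protected net users. `residual_outdoor_fraction()` discounts indoor
  exposure by a screening efficacy (0.9 for well-screened housing) to
  give the outdoor share of residual exposure.
* **Indoor-resting fraction** (`indoor_resting_fraction()`): the
  proportion of fed mosquitoes collected resting indoors. The primary
  literature estimates a per-cycle resting-site *usage rate* by
  mark-and-model methods; the simple collection proportion implemented
  here approximates it and says so in an explicit note field, since
  collection biases (indoor collections are easier) are not corrected.

## Decision rules

`recommend()` encodes the opportunity-indicator thresholds for seven
technology rows: housing proofing (residential and migrant-shelter
variants), entry traps/screens/eave devices, treated clothing and
emanators, livestock insecticides, sugar baits and swarm sprays. The
"at least one-third" thresholds are compared exactly as \(3x \ge 1\) —
boundary inclusive, no floating tolerance — because they are advisory
cut-offs, not estimated quantities. Indoor-exposure rules accept the
maximum of historical and current values when both are supplied (past
endophagy justifies house-based tools), while the outdoor rule uses the
current value only. Sugar-bait and swarm-spray rows trigger on positive
dye-labelling surveys; no numeric threshold is established for them, so
they remain boolean. The engine is verified against an independently
written truth table over every flag combination and the boundary values
\(\{0, 1/3-\varepsilon, 1/3, 1\}\).

## The synthetic survey generator

Because the behavioural datasets behind the indicator estimators exist
only as published figures, the package ships a generator that emulates
their statistical structure:

* **Biting curves**: a mixture of two circular-normal (von Mises) peaks
  discretised to hours — a late-evening peak (21:00) and a pre-dawn peak
  (04:00) by default — with total exposure of 10 bites per person-night.
  The indoor/outdoor split is solved so that the exposure-weighted indoor
  fraction equals the configured true \(\pi_i\) exactly; Poisson counting
  noise is added at the configured person-nights of effort (500 by
  default, a realistic multi-week survey), or omitted in the noiseless
  limit used by round-trip tests.
* **Human schedules**: binary indoor (20:00–06:00) and in-bed
  (22:00–05:00) windows wrapping midnight; invalid windows are rejected.
* **Blood meals**: multinomial draws over human/cattle/other with
  probabilities \((q, (1-q)f_\ell, (1-q)(1-f_\ell))\), 200 meals per
  survey by default.
* **Site ensembles**: behavioural fractions drawn from Beta distributions
  centred on the truth with concentration 0.3 by default — spanning
  nearly the whole unit interval, as observed for the human blood index
  across locations within single villages — and an indoor-resting
  parameter drawn log-normally (median 0.05, log-SD 1) so that ensembles
  of several hundred sites span several-hundred-fold ranges, as observed
  across African villages. A concentration of `Inf` (and log-SD 0) gives
  identical sites; non-positive spreads are rejected.

All randomness is routed through explicit seeds; every generator is
byte-identical under a fixed seed and restores the caller's random
stream. What the generator does *not* emulate: trap-specific sampling
biases, within-night weather, moonlight or seasonal effects, spatial
autocorrelation between sites, and human behavioural heterogeneity beyond
the schedule. Passing parameter-recovery tests on these data therefore
demonstrates the estimators' correctness under idealised sampling, not
robustness to real-world collection bias.

## Numerical choices

Probabilities are validated at API boundaries with a tolerance of
\(10^{-9}\); values outside \([0,1]\) by more than that are rejected, not
clamped. Probability conservation (\(p_\text{pre-death} + \sum p_\text{fed} = 1\))
holds to \(10^{-12}\) across randomised sweeps. A stack that blocks every
feeding route (\(B \ge 1\)) raises a total-blockade error rather than
returning a degenerate distribution, and a cycle with no residual feeding
cannot be remeasured. Problem sizes used by the validation suites —
\(10^5\) simulation replicates for oracle equivalence, 200 replicate
surveys at 500 person-nights and 200 blood meals for estimator recovery,
500 replicates for interval coverage, 1000 sites for heterogeneity
ranges — were chosen as the smallest ensembles at which the Monte-Carlo
error of each check is comfortably below the effect being verified.

## Known limitations

The model is a single-cycle, closed-form description: no age structure,
no time-stepped population dynamics, no seasonality, no movement between
villages, and no evolution of innate host preference (behavioural
*resistance* as opposed to plastic *resilience*). The per-intervention
population coverage reported for post-feed technologies is an exposure
probability, not a killing probability. The equivalence of this
formulation to other published layering calculators is not claimed.
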