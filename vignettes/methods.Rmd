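---
title: "Model and methods: a colorectal-cancer screening microsimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: a colorectal-cancer screening microsimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`crcscreen` implements a cost-effectiveness analysis of colorectal cancer
(CRC) screening built around a Markov microsimulation of the
adenoma-carcinoma sequence, in the style used to evaluate national screening
policy in settings — such as middle-income countries of the Caribbean —
where no organised screening exists and stage at diagnosis is late. This
vignette is the package's own account of the model, its assumptions, the
numerical choices, and what the synthetic fixtures do and do not establish.

## The natural-history model

Individuals enter the model at age 20 free of adenomas and are followed in
monthly cycles to age 100 or death. The state space is

```
Healthy -> AdenomaLR -> AdenomaHR -> PreclinLocal -> PreclinRegional -> PreclinDistant
                                        |                |                 |
                                        v                v                 v
                                    ClinLocal       ClinRegional       ClinDistant
```

with death from other causes reachable from every living state and CRC
death reachable only from the diagnosed (clinical) states. Low-risk
adenomas are the small (<10 mm) lesions; high-risk the larger ones.
Preclinical cancer progresses local → regional → distant and may surface
through symptoms, with a symptomatic-detection probability that rises with
stage. One most-advanced lesion is tracked per person (state-based, not
lesion-count-based); serrated pathways, sex stratification and birth-cohort
effects are out of scope.

Assumptions worth making explicit:

* **Undetected cancer carries no excess mortality.** Stage-specific cancer
  mortality applies only after diagnosis, for at most 120 months; beyond
  ten years survivors face all-cause mortality only.
* **Single multinomial draw per person-cycle.** All exits from the current
  state (disease transition, symptomatic detection, all-cause death,
  cancer death where applicable) compete in one draw, with the remainder a
  self-loop. This avoids any within-cycle event ordering.
* **No half-cycle correction.** At a one-month cycle length the correction
  is far below every other source of uncertainty.
* **Ages are completed months**; cycles are half-open intervals
  `[t, t+1)`; a person who dies during a month is counted as having lived
  it (full-cycle accrual).
* **Monthly probabilities** are obtained from annual ones by the
  constant-hazard rule `1 - (1-p)^(1/12)`.

Transition probabilities are age-banded and piecewise constant; the eight
calibrated quantities are adenoma onset (five bands by default), the two
adenoma-progression rates, two preclinical stage-progression rates, and
three stage-specific symptomatic-detection rates.

### Random numbers

Every draw in the compiled simulation core is a pure function of
`(master seed, person, cycle, channel)` through a 64-bit mixing function —
a counter-based generator. Two consequences matter scientifically:

* identical seeds reproduce identical traces, byte for byte;
* strategy arms share **common random numbers**: the disease-transition
  draw of a person-cycle is the same in every arm regardless of how many
  screening draws the arm consumes. A policy that never changes anyone's
  state (for example, adherence 0) therefore reproduces the no-screening
  trace exactly, and incremental comparisons between arms are free of
  between-arm Monte-Carlo noise.

### The deterministic oracle

`cohort_matrix_oracle()` computes the exact expected state occupancy by
forward recursion, tracking diagnosed persons by months since diagnosis so
the ten-year mortality window is applied exactly as in the
microsimulation. The tests require microsimulation occupancy to agree with
the oracle within binomial Monte-Carlo error. Because tens of thousands of
(state, cycle) cells are compared, a literal "every cell within 3 standard
errors" is expected to fail by chance for a perfect engine (about 0.27% of
cells fall outside by construction); the check therefore combines a
family-wise 4.5-SE band, a cap of 1% on the share of cells outside 3 SE,
and — for cells whose expected count is below 5, where the normal
approximation is meaningless — the exact binomial 99.7% acceptance region.

A reduced recursion over the six pre-diagnosis states
(`forward_targets()`) accumulates exactly the quantities calibration
targets refer to (incidence per 100,000 alive-and-undiagnosed
person-years, adenoma prevalence by age, stage distribution at diagnosis,
lifetime incidence). Diagnosed persons leave the risk pool, so
post-diagnosis survival does not enter, which makes this operator cheap
enough to sit inside an optimisation loop (sub-millisecond per
evaluation in compiled code).

## Calibration

`anneal()` fits the natural-history parameters to incidence,
adenoma-prevalence and stage-distribution targets by stepwise simulated
annealing with classic Metropolis acceptance and geometric cooling,
driving the deterministic forward operator rather than the noisy
microsimulation — annealing on a stochastic objective conflates noise with
landscape. The objective is a weighted sum of squared relative deviations,
with a guard of 1 per 100,000 on the incidence scale against near-zero
targets.

### What the targets can and cannot identify

The design of the default stages follows an explicit identifiability
analysis (a singular-value decomposition of the target Jacobian at
representative parameter values), which shaped three decisions:

1. **Stage 1 fits adenoma onset alone against prevalence.** Any-adenoma
   prevalence is nearly blind to the internal low-risk/high-risk split, so
   the progression rates only become identifiable once incidence targets
   join the score in stage 2. (An earlier staging that fitted the
   low-to-high-risk rate against prevalence alone froze an essentially
   arbitrary value.)
2. **A series of two first-order transitions is observationally symmetric
   in its two rates**: prevalence of the pooled adenoma states and the
   flow out of them depend only on the unordered pair. No target set of
   this kind can distinguish `lr_to_hr` from `hr_to_preclin`. The
   synthetic truth therefore sets them equal, the one point where the
   identified unordered pair determines both values.
3. **Sojourn scales must be commensurate with the observable
   timescales.** When preclinical dwell times are a few months, targets
   pin only the ratios of the detection and progression rates — rescaling
   them jointly moves every model output by less than measurement
   resolution. The synthetic truth uses multi-year dwell times, at which
   every rate competes visibly with all-cause mortality (undetected
   persons leak into other-cause death at a rate the stage mix and
   incidence level can see), and the fixture emits single-year incidence
   targets, which resolve the one-to-two-year timing signatures that
   five-year bands average away. Real calibrations face exactly this
   degeneracy and resolve it with external dwell-time constraints; the
   fixtures instead choose an identifiable regime so that
   parameter-recovery tests are meaningful.

The annealing stages perturb only their masked parameters (Gaussian steps
on the logit scale, so proposals stay strictly inside the unit interval);
stage 4 is a small-step joint pass. Because the remaining valley that
couples the sojourn parameters is shallow and curved — a regime where
fixed-step Metropolis mixes slowly — the returned fit is refined by
alternating quasi-Newton (BFGS) and Nelder-Mead rounds on the logit scale,
and the whole procedure is run as several independent chains (default 4)
with the budget split between them: rival local basins exist whose floors
are low but distinctly above the truth basin's, so every chain is lightly
refined before the winner is chosen and polished to convergence.
Infeasible proposals (total exit probability above 1 for any state and
age) are repelled by a penalty proportional to the violation.

Defaults: initial temperature equal to the stage's starting objective,
cooling factor 0.95 every 50 iterations, a 10,000-iteration cap split
across stages and chains, logit step 0.1. All are configurable;
reproducibility is guaranteed by the schedule seed.

## Screening strategies

Four base-case policies are bundled: colonoscopy every 10 years,
sigmoidoscopy every 5, and biennial FIT and FOBT, offered from age 45
through 75 with 60.6% first-line adherence, 100% follow-up-colonoscopy
adherence and 100% surveillance adherence. Adherence is an independent
Bernoulli draw per offer; a declined or negative test reschedules the next
offer one modality interval later. Design choices:

* A **negative colonoscopy** — screening, follow-up or surveillance —
  imposes a 120-month lockout on all screening offers, regardless of the
  person's true lesion status. A colonoscopy that removes a low-risk
  adenoma behaves the same way (the colon has just been cleared).
* **Positive stool or sigmoidoscopy results trigger a follow-up
  colonoscopy** (with its own adherence), which re-attempts detection with
  colonoscopy sensitivity and may therefore miss what the first-line test
  flagged.
* **Detected adenomas are removed completely**; a removed high-risk
  adenoma enrolls the person in colonoscopy surveillance at 36 months,
  then every 60 months (36 again whenever a new high-risk adenoma is
  found), to age 85. Surveillance replaces first-line screening for the
  rest of the person's life.
* **Sigmoidoscopy reach** is modelled as a distal-lesion fraction (fixture
  value 0.6) multiplying sensitivity.
* **Complications** occur per endoscopy with a test-specific probability;
  they cost money and carry a transient disability weight and are never
  fatal (procedural mortality is not modelled).
* A **symptomatic diagnosis** triggers one diagnostic colonoscopy, which
  is how the no-screening arm accrues colonoscopies.
* Colonoscopy **false positives are inert**: a colonoscopy of a
  lesion-free colon is treated as negative (the fixture gives colonoscopy
  specificity 1); stool-test and sigmoidoscopy false positives send the
  person to a follow-up colonoscopy, which is where their cost and
  disability burden arises.
* Colonoscopies of all reasons count into the colonoscopies-per-1,000
  output; sigmoidoscopies are tallied separately.
* The **FIT-to-colonoscopy switch** scenario is a two-phase strategy: FIT
  offers at 45-49, colonoscopy offers from 50 at the decennial interval,
  with any active lockout carried across the phase boundary.
* Screen-detected and symptomatically detected cancers of the same stage
  face identical stage-specific survival.

## Economics

Costs are accrued from a healthcare payer perspective: unit costs per
test, per colonoscopy reason, per complication episode, and one
stage-specific treatment bundle (surgery, hospitalization, imaging,
consultations, chemotherapy) charged at diagnosis, with no
continuing/terminal phase structure. Costs recorded in Dominican pesos
convert at a fixed DOP-to-USD rate (0.017) with a health-CPI inflation
factor.

Effectiveness is disability-adjusted life years (DALYs) averted versus no
screening, computed from discounted life-years (DLY) and years lived with
disability (YLD): `averted = (DLY_S - DLY_NH) + (YLD_NH - YLD_S)`. For a
common cohort this equals the YLL+YLD difference for any fixed reference
and avoids choosing an external life-expectancy standard. Disability
weights cover the endoscopy procedure, complications, a stage-specific
treatment period, and living with cancer (one minus the stage utility) for
up to 120 months after diagnosis, truncated at death. No age-weighting is
applied.

Both costs and DALYs are discounted at 3% per annum evaluated at monthly
resolution, `(1.03)^(-t/12)`; the published phrase "a monthly rate of 3%"
is interpreted as annual-rate-at-monthly-resolution, since 3% per month
(≈43% per year) is economically implausible; the rate is a configuration
knob. The discounting clock starts at model entry (age 20) for every
strategy alike — only between-strategy differences matter, and a common
epoch cancels in increments.

## Decision analysis

`find_frontier()` sorts strategies by cost, removes strictly dominated
ones (at least as costly and at most as effective as another, one relation
strict), then iteratively removes extended dominance (an ICER above the
next frontier ICER), leaving strictly increasing ICERs; ties in cost break
toward the more effective strategy, and exact duplicates are flagged, not
dropped. `decide()` selects the most effective frontier strategy whose
ICER does not exceed the willingness-to-pay threshold (base
US$11,692/DALY averted, a GDP-per-capita threshold), falling back to the
least costly. A zero incremental effect makes the ICER undefined (`NA`),
never infinite.

## Sensitivity analyses

* **One-way (tornado)**: each parameter in turn to its low and high value,
  both comparison arms re-run under common random numbers, bars sorted by
  ICER width.
* **Probabilistic**: costs draw from Gamma and probabilities/disability
  weights from Beta distributions, parameterised by method of moments from
  a mean (the base value) and a standard error (default 20% of the mean
  when no range is given). Natural-history transition probabilities stay
  fixed at their calibrated values. Each iteration re-simulates every
  strategy with the same cohort streams, isolating parameter uncertainty;
  optimality on the willingness-to-pay grid is decided by net monetary
  benefit, giving the cost-effectiveness acceptability curve.
* **Scenarios**: alternative start ages, surveillance stop ages, adherence
  pairs, an alternative (earlier) stage-distribution target that re-runs
  the detection-calibration stage, halved/doubled incidence implemented by
  re-solving a common multiplier on the adenoma-onset probabilities by
  bisection until no-screening lifetime incidence hits the target multiple
  within 1%, and the FIT-to-colonoscopy switch.

## Synthetic fixtures

Everything needed to run the pipeline — lifetable, stage survival, truth
parameters, calibration targets, costs, test characteristics, disability
weights, strategies — is generated by `make_fixture_bundle()`. The
fixtures emulate the statistical *structure* of the real inputs: a
Gompertz-Makeham lifetable at a middle-income mortality level (life
expectancy at age 20 between 50 and 65 years), age-specific incidence
rising to hundreds per 100,000 person-years at old age, adenoma prevalence
rising to 25-45% by age 70, a late-stage-skewed mix at diagnosis in the
`DR-like` variant (majority regional+distant, distant at least 30%) and an
earlier mix in the `SEER8-like` variant (majority local+regional), ordered
placeholder costs (stool test < sigmoidoscopy < colonoscopy < stage
treatments) and test characteristics (colonoscopy ≥ sigmoidoscopy ≥ FIT ≥
FOBT sensitivity per lesion class, FIT specificity ≥ FOBT). Every numeric
value is a *labelled placeholder* with the field's ordinal structure —
never an estimate of any real price list, registry rate or utility — and
fixture values are rounded to seven significant digits so the files
round-trip through the CSV layer byte-identically.

Calibration targets are computed from the truth parameters through the
deterministic oracle, so the calibration objective at the truth is zero to
rounding and parameter-recovery experiments have a known answer.

What passing tests on these fixtures shows: that the simulation engine,
calibration machinery, accounting identities and decision logic are
correct, and that the pipeline's qualitative behaviour (screening reduces
incidence and mortality monotonically in adherence and sensitivity; FIT-
versus-colonoscopy trade-offs move the expected way) is sound. What it
does not show: quantitative agreement with any real population. Absolute
costs, DALYs and ICERs produced on fixtures depend on placeholder values;
reproducing published numbers requires the corresponding real inputs
(national lifetable, registry incidence targets, referral-hospital stage
distribution, payer price lists).

## Problem sizes and tolerances

The packaged tests run cohorts of 1,000-50,000 persons and a probabilistic
sensitivity analysis of 200 iterations at 5,000 persons; the bundled
acceptance script uses 50,000-person cohorts. These sizes put binomial
Monte-Carlo error well below the effects being tested while keeping a
complete run in minutes on a single core; the engine itself simulates
about 130,000 person-lifetimes per second, so scaling to the
100,000-person, 10,000-iteration design of a full analysis is a matter of
configuration. Closed-form identities (discounting streams, life-year
accounting) are checked to 1e-9; envelope and ordering properties of the
generators are checked on multiple seeds; calibration recovery is judged
at ±25% per parameter with the majority rule over three seeds, reflecting
the stochastic nature of annealing.

## Known limitations

* Lesion multiplicity, serrated pathways, and operator-dependent miss
  rates are not modelled; sensitivity is per-test, not per-lesion.
* Colonoscopy capacity is reported (colonoscopies per 1,000) but not
  constrained; no queueing.
* The payer perspective excludes out-of-pocket, productivity and
  transport costs; public/private price differences are not modelled.
* Natural-history parameter uncertainty is not propagated into the
  probabilistic sensitivity analysis (test characteristics, costs and
  weights are), matching common practice for calibrated models.
* The adenoma-progression split is structurally unidentifiable from the
  supported target classes (see above); its fixture truth is the
  symmetric point, and real applications should constrain it externally.
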