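---
title: "A Markov cohort model of edoxaban versus warfarin for VTE: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtecea)
```

## The decision problem

Patients with an acute venous thromboembolism (VTE) — a deep vein thrombosis
(DVT), a pulmonary embolism (PE), or both — receive anticoagulation to
prevent recurrence. The vitamin-K antagonist warfarin is cheap but requires
regular INR monitoring and carries bleeding risk; the factor-Xa inhibitor
edoxaban needs no monitoring and showed fewer bleeds in the Hokusai-VTE
randomised trial, at a higher drug price. `vtecea` implements a
cost-effectiveness model of this trade-off from a UK NHS perspective:
monthly-cycle Markov cohort dynamics over a lifetime (50-year) horizon,
discounted QALYs and costs, and the full apparatus of scenario, subgroup,
deterministic (tornado) and probabilistic sensitivity analysis. The primary
comparative statistic is the net monetary benefit
$\mathrm{NMB} = \Delta E\,\lambda - \Delta C$ at a willingness-to-pay
$\lambda$ of £20,000 per QALY.

## Model structure

Eight mutually exclusive health states describe a patient's month: on
treatment after the index VTE, off treatment, recurrent VTE (rVTE), on
treatment after a recurrence, clinically relevant non-major bleed (CRNMB),
non-intracranial major bleed (non-ICH MB), intracranial haemorrhage (ICH),
and death. Three long-term conditions are *concomitant* states tracked as
prevalences alongside the exclusive occupancy: severe post-thrombotic
syndrome (PTS, after DVT), chronic thromboembolic pulmonary hypertension
(CTEPH, after PE, with a pulmonary-endarterectomy branch), and disability
following ICH.

The four acute event states are one-cycle tunnels: the acute cost and
utility decrement apply for a single month, after which survivors are
routed onward — rVTE survivors start a new treatment episode, CRNMB
survivors resume exactly the treatment month they left, non-ICH MB and ICH
survivors discontinue anticoagulation until the next recurrence. Tunnel
slots are stratified by destination so this bookkeeping is exact.

Event risks while on treatment are time-stratified as in the trial
analysis: one set of baseline monthly probabilities and odds ratios (ORs)
for the first six months after initiation of anticoagulation, another for
later months. Baseline probabilities are warfarin-arm rates; the edoxaban
arm applies the OR on the odds scale,
$p' = \mathrm{OR}\,p / (1 - p + \mathrm{OR}\,p)$, which reduces to
rate-ratio behaviour for small $p$. Off treatment, only the off-treatment
recurrence risk (0.42%/month) and background mortality apply.

### Treatment pathway conventions

Several pathway details are deliberate design choices of this package;
they are set out here because alternative readings are possible.

* **Initial episode.** Everyone starts in month 1 of a 6-month episode on
  the randomised agent, with the first-six-months risk stratum, the
  arm-specific cycle costs (including the heparin lead-in: 6.5 days with
  warfarin, 5 days with edoxaban) and — in the warfarin arm — INR
  monitoring and the warfarin utility decrement.
* **Base-case recurrence efficacy is equal across arms.** The trial was a
  non-inferiority study for efficacy and neither recurrence OR (0.83 and
  0.82, both with confidence intervals spanning 1) reached significance.
  The base case therefore treats recurrence prevention as equivalent and
  reserves the recurrence ORs for the `or_nonsig_to_one` scenario and the
  sensitivity registry. The bleeding contrasts (CRNMB, non-ICH MB, ICH)
  are applied in full. This can be overridden with the
  `rvte_or_in_base = TRUE` setting.
* **Six-month re-treatment** after a recurrence stays on the randomised
  agent with the later-months risk stratum (re-initiated patients are
  anticoagulation-experienced, so the early-treatment excess of the first
  episode is not re-applied) and keeps the warfarin utility decrement in
  the warfarin arm.
* **Lifelong tertiary prevention** — for the fraction of recurrence
  survivors with both an index and a recurrent PE, derived as
  `prop_index_pe * prop_recurrence_pe` (0.227 at base, 0 in the DVT-only
  subgroup) — is modelled as a *new anticoagulant strategy* common to both
  arms: baseline event risks, NOAC-era costs (5-day lead-in, £44.50 first
  month, £53.27 per month), no INR monitoring and no warfarin decrement.
  Setting `lifelong_common = FALSE` keeps these patients on their
  randomised agent instead. Lifelong treatment ends only at a major bleed
  (non-ICH MB or ICH), after which the patient is off treatment until the
  next recurrence.

### Mortality

Background mortality comes from the life table by the cohort's current
age (deterministic ageing, `start_age + cycle/12`, truncated to integer
ages) mixed across sexes by `prop_male`, converted to a monthly
probability via $1-(1-q)^{1/12}$. Event case fatality (PE recurrence,
non-ICH MB, ICH, perioperative endarterectomy) applies at the event;
carriers of CTEPH and post-ICH disability face additional monthly
mortality (0.7% and 3.3%). Within a cycle, competing event probabilities
are used directly as a categorical draw — the engine raises an error if
they ever sum beyond 1 rather than silently renormalising — and
background and disease-specific mortality compete additively.

## Utilities

The index-VTE state utility is the PE/DVT mix of the published state
utilities, $0.401 \times 0.67 + 0.599 \times 0.71 \approx 0.694$ in the
pooled population. Off-treatment survivors take the age-specific general
population EQ-5D norm (0.85 at 45–54 down to 0.73 at 75+), which also acts
as a ceiling on the state utilities (`use_age_utility = FALSE` disables
both). Relative decrements apply multiplicatively: 1.37% with warfarin
while on the randomised agent (`du_warfarin_scope` controls whether
re-treatment episodes are included; the default `"all"` includes them),
14% for the month of an rVTE, 5% / 31.58% / 65.26% for the CRNMB / non-ICH
MB / ICH tunnel month, and 13.68% / 30% / 65.26% for every month carrying
PTS / CTEPH / post-ICH disability. Joint carriers multiply, e.g.
$u \times (1-0.1368) \times (1-0.30)$ for PTS plus CTEPH. Death
contributes zero.

## Costs

Costs are 2015/16 NHS reference costs in pounds sterling. The four
per-cycle treatment costs are primitives — £273.81 / £26.73 per warfarin
cycle (first / subsequent, including INR monitoring and the heparin
lead-in) and £108.62 / £53.27 per edoxaban cycle — because the printed
components do not reconcile exactly; the component fields (heparin
£12.82/day, INR visits £87 first / £26 subsequent, 4 titration visits, 1
monthly visit) are retained, and a sensitivity run that perturbs a
component rebuilds the cycle cost as primitive plus component delta. For
ledger reporting the warfarin first cycle splits into an INR block
(£87 + 4 × £26 = £191) and treatment proper; the lifetime warfarin INR
total then reproduces the published ≈ £323. Event costs: £1,647 per PE and
£551 per DVT (recurrence mix 56.5% PE → £1,170 per recurrence), £384 per
CRNMB, £2,940 per non-ICH MB, £3,012 per ICH plus £524/month while
disabled. Complications: PTS £168 first month then £23/month; CTEPH onset
50.3% × £7,824 endarterectomy plus £1,348/month drugs thereafter
(≈ £5,283 in the onset month). Costs and QALYs accrue at the start of the
cycle in which they arise and are discounted at 3.5% per year,
$(1.035)^{-t/12}$; no half-cycle correction is applied
(`half_cycle_correction` is reserved for exploration).

## Synthetic life table

No UK life-table file ships with the package; `make_life_table()` builds a
deterministic Gompertz–Makeham stand-in,
$q(x) = 1 - \exp\{-(\lambda + a e^{bx})\}$, with sex-specific coefficients
calibrated to contemporary UK all-cause mortality (male
$\lambda = 5\times10^{-4}$, $a = 2\times10^{-5}$, $b = 0.100$; female
$\lambda = 3\times10^{-4}$, $a = 1.1\times10^{-5}$, $b = 0.103$), giving a
mixed-sex life expectancy of 26.9 years at the default entry age of 56
(57% male, the profile of a contemporary VTE trial population; both are
explicit settings because trial demographics are a modelling choice here,
not a data input). `read_life_table()` accepts an official `age,sex,qx`
CSV for users who want exact national rates. Incremental results are
insensitive to modest background-mortality error; absolute life-year and
QALY totals are approximate by construction, which is why the package's
own checks focus on incremental quantities.

## Sensitivity analysis

Every input with a published uncertainty interval sits in
`parameter_registry()`: 46 parameters with base, bounds and sampling
family. `one_way_dsa()` reruns both arms at each bound and reports the NMB
span (tornado). `run_psa()` samples all registry parameters jointly and
independently per draw — beta for probabilities, proportions and
utilities (moment-matched: mean at base, SD a quarter of the interval
width), log-normal for odds ratios (median at base, interval read as a
95% CI), gamma for costs and resource counts — runs both arms per draw,
and classifies each draw by cost-effectiveness-plane quadrant. The CEAC
reports the fraction of draws with positive NMB across a willingness-to-pay
grid. All randomness flows through one seed. The default of 2,000 draws at
the lifetime horizon runs in a few minutes on one core; the cohort engine
itself is deterministic, so the base case takes well under a second.

```{r example}
params <- vte_parameters(horizon_months = 120)  # 10-year horizon for speed
res <- run_ce_analysis(params)
glance(res)
```

## What the checks do and do not show

The packaged base case reproduces the published incremental cost saving,
the INR-monitoring and heparin worked examples, the 1-year and 5-year
horizon scenarios, the DVT-only subgroup and the PSA cost-effectiveness
fraction. Incremental QALYs and life-years land lower than the published
headline (≈ 0.021 and ≈ 0.017 against 0.033 and 0.029): with equal
base-case recurrence efficacy the remaining arm contrast runs through the
bleeding channels, and the published input set bounds their joint QALY
yield below the headline value — while re-activating the recurrence ORs
(`rvte_or_in_base = TRUE`) raises the QALY gain but pushes the cost saving
and recurrence-stream divergence well beyond the published values. The
package ships the first convention as its base case and exposes the
second as a setting; the tension between the two is a property of the
input set, not of either implementation, and users should treat the
incremental QALY magnitude as the least certain headline quantity.
Results on synthetic life tables also say nothing about calendar-time
mortality improvement, which the generator deliberately omits, and the
pooled ORs are reused unchanged in the subgroup analyses because no
subgroup-specific event rates are published.

## Known limitations

* DVT and PE share one health state; their mix enters through weighted
  utilities, costs and sequela probabilities only.
* No distinction between provoked and unprovoked VTE, and no
  microsimulation-level heterogeneity (single cohort age/sex profile).
* Parameters are sampled independently in the PSA; no correlation
  structure is published.
* Patients discontinuing after a major bleed remain off treatment until
  the next recurrence; early re-initiation is not modelled.
* PTS and CTEPH are permanent once acquired.
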