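---
title: "An annual-cycle microsimulation of MASLD natural history"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An annual-cycle microsimulation of MASLD natural history}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(masldsim)
```

## The model

`masldsim` is an agent-based state-transition model of metabolic
dysfunction-associated steatotic liver disease (MASLD) in a dynamic,
US-like population, simulated on an annual cycle from 2000 to 2050. Each
agent occupies exactly one health state per cycle:

* **No steatosis** — susceptible; adults (18+) acquire MASLD with an
  age-group- and calendar-year-specific annual probability.
* **MASL F0–F4 and MASH F0–F4** — two parallel fibrosis tracks (simple
  steatosis vs steatohepatitis), staged F0 (no fibrosis) to F4
  (cirrhosis). Stage progression and regression follow the bundled
  annual transition probabilities (`masld_parameters()`); switching
  between the tracks (MASH onset, 0.0060/yr; MASH resolution, 0.0130/yr)
  is possible only at stages F0–F2, and regression from MASL F0 back to
  no steatosis occurs at half the acquisition probability.
* **Decompensated cirrhosis (DC)** — entered from F4 (0.0268/yr,
  independent of MASH status).
* **Hepatocellular carcinoma (HCC)** — entered from F3 (0.0011/yr), F4
  (0.0022/yr) or DC (0.0011/yr, half the F4 rate).
* **Liver transplant (LT)** — entered from DC or HCC at a shared
  calibrated rate (0.0062/yr); absorbing apart from mortality.
* **Liver death / other death** — absorbing.

Mortality is applied before movement. Everyone faces age- and
sex-specific background mortality from a parametric life table; agents
in any disease state carry an all-cause hazard ratio of 1.15. DC, HCC
and LT add liver-specific annual death probabilities — constant for DC
(0.0734), declining with years since diagnosis for HCC, and depending on
age band at transplant and years since transplant for LT — composed with
background mortality as independent competing causes,
$1-(1-q_x\,\mathrm{HR})(1-p_\text{liver})$, so probabilities never leave
$[0,1]$. A death is attributed to the liver whenever the liver cause
fires.

### Cycle ordering

Within one model year the engine applies, in order: (1) mortality;
(2) one categorical transition draw per survivor (transitions are
mutually exclusive within a cycle — no chained moves); (3) age and
duration increments; (4) the year's entrant batch (births and
migrants). This ordering is a modelling choice, not an empirical fact;
it makes the accounting identity
`alive(t+1) = alive(t) − deaths(t) + entrants(t)` exact, which the test
suite asserts for every cycle. The single-draw rule forbids, e.g.,
DC→HCC→LT within one year; the alternative orderings would differ at
$O(p^2)$ per year for the small $p$ involved.

## Demography

The population component emulates US demography from coarse bundled
fixtures (CSV under `inst/extdata/`, swappable for registry extracts):

* a year-2000 age pyramid (single year of age; mean age 35.8, 49.1%
  male);
* a Gompertz–Makeham life table, $q_x = A + B e^{cx}$ plus an infant
  increment, calibrated to period life expectancy ≈ 75.7 y (male) /
  79.8 y (female); $q_{100}=1$ is the terminal age;
* annual births and net migration 2000–2050 close to the observed US
  series, with migrant ages drawn from a five-band distribution and
  migrants entering disease-free;
* duration-dependent annual death probabilities for HCC (0.55 in the
  first year after diagnosis declining to 0.05 by year 10+; the implied
  5-year survival is ≈ 16%) and for LT (elevated first-year mortality,
  then a low plateau, higher at older transplant ages), in 11 duration
  bins — durations beyond 10 years reuse the 10+ value.

One agent represents ≈ `r round(282162400 / 250000)` persons at the
default 250 000-agent size (100 persons at the full 2 821 624-agent
size); all reported counts are agent tallies times the person weight,
and entrant batches are scaled by its inverse with stochastic rounding
so expected counts are unbiased at any agent count.

The `target_population` column of the demography series is generated by
the package's own deterministic disease-free projection of the
births/migration/life-table fixtures, so the series is internally
consistent; it tracks the observed US totals 2000–2020 to about 1%. The
demographic validation test asserts that the stochastic engine
reproduces this series within 0.5% in every year 2001–2020. Because the
life table is static (no secular mortality improvement), the projected
2050 population (~344M) is below official projections (~375M); this
mainly scales absolute counts, not prevalences.

## Incidence and initialization

Adult MASLD incidence is linear in calendar year within three age groups
(18–39, 40–59, 60+; group multipliers 0.8/1.2/1.1 around the overall
level), with a scenario-specific plateau: the base case rises until 2030
and is constant thereafter; the best case is constant after 2014; the
worst case keeps rising through 2050.

The year-2000 disease state assigns each adult MASLD with probability
`p0` times an age-group shape (0.8/1.15/1.1), and gives prevalent cases
a joint (track, stage) distribution. For that stage mix we deliberately
do **not** use the quasi-stationary distribution of the fibrosis
sub-chain (available as `quasi_stationary_stage_distribution()`): the
chain's long-run mix (≈ 21/29/25/16/10% across F0–F4 for the MASL rates)
is far more advanced than any surveyed MASLD population, because real
prevalent pools are dominated by recent-onset disease. Instead the
default is a *duration-weighted transient*: prevalent cases are modelled
as a mixture over disease durations $d$ with geometric weights
$(1-\rho)^d$ and occupancy $e_{F0} P^d$ of the joint MASL/MASH
sub-chain. The removal rate $\rho = 0.045$/yr is an a-priori choice
composed of pool mortality (~0.02) and pre-2000 relative incidence
growth (~0.025); it yields a 2000 stage mix of roughly 55/27/12/4/2%
(F0–F4). DC, HCC and LT start unoccupied in 2000 and build up
endogenously.

## Calibration

Free baseline scalars — the 2000 incidence level, the annual incidence
slope, the overall 2000 adult prevalence `p0`, and the 2000 MASH share —
are calibrated with `calibrate_baseline()` against the bundled anchor
file: adult MASLD prevalence 28.0% in 2001, 33.7% in 2020 and 36.8% in
2030, and a MASH share of 17.2% in 2018. The 2001 value is a stand-in
anchoring the rising early-period prevalence trend at its
survey-era level; without it the two later anchors alone also admit a
high-initial-prevalence decaying trajectory that contradicts the
surveyed trend. The solve is coordinate-wise bisection on the
deterministic expectation projector (`project_expectation()`), which
shares the engine's kernel code path and is its exact expectation, so
the calibrated point transfers to the microsimulation up to Monte Carlo
error. The rounded result is frozen as `masld_defaults()`.

Free *transition* parameters are calibrated with `calibrate_model()`:
a weighted sum of squared relative deviations between simulated and
target statistics, minimized by Brent's method (one parameter) or a
Nelder–Mead simplex with random restarts (several), with common random
numbers — every loss evaluation reuses the same seeds, making the loss
deterministic in the parameters. Calibration runs use a reduced agent
count (default 200 000) for desk-scale runtime.

`back_calculate_initial_state()` exposes the initialization solve on its
own: bisection on `p0` against a late-period prevalence anchor, then on
the 2000 MASH share against a share anchor, iterated twice.

## Validation machinery

The cohort oracle (`build_transition_matrix()`, `run_expectation()`)
builds the exact one-cycle matrix over the duration-expanded state space
(HCC and LT in 11 duration bins each, keeping the only non-Markov
feature Markov) and iterates expectations. The test suite drives a
closed 100 000-agent cohort through 15 cycles under three seeds and
requires every state occupancy to stay within $4/\sqrt{n}$ of the oracle
expectation; it also checks row-stochasticity to $10^{-12}$, mass
conservation to $10^{-10}$ over 50 cycles, absorbing death states, and
recovery of the calibrated MASH onset and transplant rates (within
±20%) from targets the model itself generated.

## Problem sizes and numerical choices

Default runs use 250 000 agents (the published configuration used
2 821 624; results agree up to Monte Carlo error — the binomial
standard error on an adult prevalence near 40% is about 0.12
percentage points at 250 000 agents and 0.04 at full size). The
acceptance analysis averages three seeds. Bisection
tolerances are $10^{-5}$ on probabilities ($10^{-7}$ on the incidence
slope); the simplex uses a relative loss tolerance of $10^{-3}$. Ages
are capped by the terminal life-table age (100, where $q_x=1$);
durations beyond the 10th year reuse the 10+ survival bin; fractional
entrant counts are rounded stochastically.

## What the model does and does not reproduce

With the bundled fixtures and the published transition table, the
calibrated base case reproduces (run the acceptance script to
recompute): the anchored 2020/2030 adult prevalences; the out-of-sample
2050 prevalence; the 2020 MASH prevalence; the 2020 fibrosis-stage
mix; and plausible late-period F4 shares and HCC/LT incidence. Scenario
ordering (best < base < worst in 2050 prevalence) is preserved.

Two published quantities are *not* reproduced, for structural reasons
worth understanding before using those outputs:

* **Late-period MASH prevalence.** The incidence needed to reproduce
  the prevalence anchors turns the prevalent pool over at roughly 4%/yr,
  and newly incident cases enter MASH-free. With the published onset
  (0.0060/yr) and resolution (0.0130/yr) held fixed, inflow dilution
  outweighs onset and the MASH share declines after its 2018 anchor,
  where the published projection has it roughly constant-to-rising. The
  published analysis used a survey-based MASH-proportion trend from
  supplementary material that is not part of the main-text parameter
  set.
* **Decompensated-cirrhosis growth.** A several-fold rise in DC
  requires the F4 pool to keep growing strongly after 2020; under this
  model's calibrated turnover, the fibrosis mix reaches its
  quasi-equilibrium around 2020 and the F4 pool afterwards grows only
  in proportion to prevalence.

Other limitations are inherited from scope: no treatment or screening
effects, no comorbidity states, no intra-year event timing, no MASLD
recurrence after transplant, a static life table, and migrants assumed
disease-free on entry. The synthetic demographic fixtures emulate
published shapes, not microdata: tests passing against them validate
the model mechanics and calibration machinery, not US vital statistics.
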