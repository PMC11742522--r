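# masldsim

An agent-based, annual-cycle microsimulation of the natural history and
population burden of **metabolic dysfunction-associated steatotic liver
disease (MASLD)** in a dynamic US-like population, 2000–2050. It is
aimed at modellers and hepatology/public-health analysts who need
person-level projections of MASLD, MASH, cirrhosis complications,
liver cancer and transplant demand under explicit, inspectable
assumptions.

## The model in brief

Each simulated agent occupies one health state per year:

```
no steatosis → MASL F0…F4  ⇄  MASH F0…F4 → DC → HCC → LT → death
```

* Parallel **MASL/MASH fibrosis tracks** staged F0–F4, with published
  annual stage progression/regression probabilities; switching between
  tracks (MASH onset 0.0060/yr, resolution 0.0130/yr) only at F0–F2.
* **Cirrhosis complications**: F4 → decompensated cirrhosis (0.0268/yr,
  MASH-independent); F3/F4/DC → hepatocellular carcinoma
  (0.0011/0.0022/0.0011 per yr); DC or HCC → liver transplant at a
  shared calibrated rate (0.0062/yr).
* **Mortality**: life-table background mortality times an all-cause
  hazard ratio of 1.15 in disease states, composed as independent
  competing causes with liver-specific mortality — constant for DC
  (0.0734/yr), declining with years since diagnosis for HCC, and
  age-at-transplant- and duration-dependent for LT:
  `p = 1 − (1 − qx·HR)(1 − p_liver)`.
* **Demography**: a US-2000-like age pyramid (2 821 624 persons per 100
  represented at full scale; mean age 35.8, 49.1% male), annual births
  and migrants, and a Gompertz–Makeham life table.
* **Incidence**: linear-in-year per age group (18–39/40–59/60+), rising
  until 2030 in the base case (until 2014/through 2050 in the
  best/worst cases), calibrated together with the 2000 initial disease
  state against published prevalence anchors (28.0% in 2001, 33.7% in
  2020, 36.8% in 2030, MASH share 17.2% in 2018).

A deterministic expectation projector sharing the engine's kernel is
used both as the calibration workhorse and as a brute-force oracle the
stochastic engine is validated against. See the methods vignette
(`vignettes/masld-microsimulation.Rmd`) for assumptions, parameter
meanings, numerical choices and known limitations.

## Worked example

```r
library(masldsim)
sim <- masld_simulate(masld_scenario(n_agents = 250000, seeds = 1))
sim
#> MASLD microsimulation: scenario 'base', 250000 agents, 1 seed(s), 2000-2050
#>   2020: MASLD 33.8% of adults (86.0M), MASH 5.6%, DC 501 100, HCC 11 300/y, LT 2 900/y
#>   2030: MASLD 36.8% of adults (99.3M), MASH 5.0%, DC 627 500, HCC 14 200/y, LT 2 300/y
#>   2050: MASLD 40.7% of adults (111.8M), MASH 4.3%, DC 656 900, HCC 13 500/y, LT 2 900/y

summarize_period(sim, 2020, 2025)
#>     period mean_annual_hcc mean_annual_lt cumulative_hcc cumulative_lt
#>  2020-2025           10722           3950          64333         23702
```

Reading: in 2020 the base case puts adult MASLD prevalence at 33.8%
(86M people, of whom 5.6 percentage points have MASH), with about half a
million prevalent decompensated-cirrhosis cases and roughly 11 000
incident MASLD-related liver cancers per year (counts are agent tallies
scaled to persons; HCC/LT rates in the header are 5-year means).
`summary(sim)` returns the full per-year table, `plot(sim)` draws
burden-over-time curves, and `run_scenarios()` compares incidence
scenarios or one-way parameter sweeps (`ci_sweep_specs()`).

A thin command-line front end is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/masldsim", package="masldsim"))')" \
  simulate --scenario base --n-agents 100000 --seed 1,2,3 --out runs/base
```

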