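# anaemiaCEA

Country-level health-economic modelling for setting anaemia reduction
targets in women of reproductive age (WRA, 15–49 years).

Global goals call for halving anaemia prevalence in WRA, but what a
country can actually achieve depends on the interventions available to
it, their costs, and what the country is willing to pay per unit of
health gain. `anaemiaCEA` answers the question "how much reduction is
achievable *and* cost-effective here?" for analysts in global health
economics and nutrition policy, and aggregates the answers into regional
and global targets with uncertainty.

## The model

Four interventions are modelled — staple-food iron fortification, oral
iron supplementation in pregnant and in non-pregnant women, and IPTp-SP
antenatal antimalarials — each with a relative risk RR of remaining
anaemic after treatment (so 1 − RR is the fraction of treated cases
resolved). For an intervention scaling from coverage *c* to *c*max, at
the current anaemic population *P* of its benefitting segment:

- cases averted = *P* · Δ*c* · (1 − RR_eff), with Δ*c* = max(0, *c*max − *c*)
- DALYs averted = cases averted · severity-weighted disability weight
  (DALYs = YLDs: no anaemia-attributable mortality, 1-year horizon, no
  discounting)
- ICER = (receiving population · Δ*c* · unit cost) / DALYs averted

Per country, interventions are placed in a league table ordered by
ascending ICER; the cheapest is applied at full scale-up if its ICER is
strictly below the country's cost-effectiveness threshold (CET), the
remaining ICERs are recomputed on the lower prevalence, and the loop
repeats until nothing cost-effective remains. Trial efficacy of oral iron
is discounted for real-world delivery on the risk-reduction scale:
RR_eff = 1 − (1 − RR)(1 − *r*), *r* ~ 38% (21–69). Parameter uncertainty
(RRs, the reduction *r*, coverages, costs, severity splits) is propagated
by Monte Carlo simulation; each country's target is the median relative
reduction with a 95% uncertainty interval, and the global target averages
countries within each iteration.

Scenarios: `cet_gdp1` (1 × GDP per capita per DALY averted, base case),
`cet_opportunity` (supplied opportunity-cost thresholds),
`no_constraint` (thresholds removed — the maximum achievable reduction),
`zero_baseline` (maximum coverage applied as if current coverage were
nil).

A synthetic-world generator (`generate_world()`) emulates the structure
of the required inputs across low/middle/high-income archetypes so the
full pipeline runs without external data.

## Worked example

```r
library(anaemiaCEA)

world   <- generate_world(30, seed = 42)      # 30 synthetic countries
config  <- cea_config(n_sims = 200, seed = 42)
targets <- anaemia_targets(world, config)     # base case: 1 x GDP CET
print(targets)
#> Anaemia reduction targets (women aged 15-49)
#>   scenario: cet_gdp1 | 30 countries | 200 Monte Carlo simulations
#>   global target: 16.0% reduction (95% UI 6.6-26.0)
#>   national targets range 0.0-26.2%
```

The global target is the median, across simulations, of the mean national
reduction: with these synthetic countries, scaling up every intervention
that stays under 1 × GDP per capita per DALY averted cuts the anaemic
population of WRA by 16%, with 95% of simulations between 6.6% and 26%.
National targets spread widely (0–26%): countries whose cheap options are
already at scale, or whose thresholds are low, can achieve little
cost-effectively. Per-country detail:

```r
p    <- world$countries[[1]]
spec <- world$interventions[[p$country_id]]
greedy_apply(p, spec, point_params(spec, config, p$severity_split),
             cet_for_scenario(p, "cet_gdp1"), config)
#> <country_run>
#>   applied: fortification -> iron_pregnant
#>   anaemic: 4906532 -> 4517202  (7.9% relative reduction)
```

For this country only fortification and iron in pregnancy are
cost-effective; applying them resolves 389,330 of 4.9 million anaemic
cases. `summary(targets)` tabulates all levels, `plot(targets)` draws the
national dot-and-interval chart, and `run_simulation()` writes
`targets.csv`, `league.csv` and a run manifest. A thin command-line
wrapper lives at `inst/cli/anaemia-cea` (subcommands `generate`,
`simulate`, `league`).

See `vignette("target-setting")` for the model's assumptions, parameter
defaults, and design choices.

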