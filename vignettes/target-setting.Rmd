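---
title: "Setting cost-effective anaemia reduction targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Setting cost-effective anaemia reduction targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anaemiaCEA)
```

## The problem

Anaemia in women of reproductive age (WRA, 15–49 years) is one of the
largest contributors to years lived with disability worldwide, and
international development goals have committed countries to halving its
prevalence. A useful target, however, has to respect what each country can
actually achieve with the interventions available to it and what it is
willing to pay for health gains. `anaemiaCEA` implements a country-level
health-economic model that derives such targets: the percentage reduction
in anaemia prevalence among WRA that is achievable by scaling up
recommended interventions whose incremental cost-effectiveness ratio
(ICER) stays below the country's cost-effectiveness threshold (CET).

## The model

Four interventions are modelled, each characterised by a relative risk
(RR) of *remaining anaemic* after treatment, so `1 - RR` is the fraction
of treated anaemic cases resolved:

| intervention | receives | benefits | RR (95% CI) |
|---|---|---|---|
| staple-food iron fortification | total population | all anaemic WRA | 0.73 (0.55–0.97) |
| oral iron, non-pregnant women | non-pregnant WRA | non-pregnant anaemic | 0.65 (0.49–0.87) |
| oral iron, pregnant women | pregnant women | pregnant anaemic | 0.30 (0.20–0.47) |
| IPTp-SP antimalarials | pregnant women | pregnant anaemic with malaria | 0.90 (0.87–0.93) |

Trial efficacy of oral iron is discounted for real-world delivery: the
risk reduction `1 - RR` is shrunk by a reduction factor (median 0.38, 95%
CI 0.21–0.69), i.e. `RR_eff = 1 - (1 - RR)(1 - r)`. Composing on the
risk-reduction scale (rather than multiplying the RR itself) keeps the
adjusted RR at or below 1 whenever the trial RR is, which is what
"reduced effectiveness" should mean. Fortification and presumptive
malaria treatment are not compliance-limited in the same way and are left
unadjusted.

Each intervention can scale from its current coverage `c` to a maximum
`c_max`; only the increment `Δc = max(0, c_max − c)` acts on the observed
burden, because current prevalence is already observed *under* current
coverage (no counterfactual re-inflation is attempted). For one
intervention at the current state:

* cases averted = benefitting pool × Δc × (1 − RR_eff)
* DALYs averted = cases averted × severity-weighted mean disability weight
* incremental cost = receiving pool × Δc × unit cost
* ICER = incremental cost / DALYs averted (set to +∞ when nothing is averted)

DALYs equal YLDs here: the model assumes no anaemia-attributable
mortality, a 1-year horizon and no discounting. Malaria-attributable YLDs
are not counted — IPTp is credited only with the anaemia cases it
resolves. Fortification's cost accrues over the *total* population because
fortified staples reach everyone, which is what makes it cheap per DALY in
high-burden settings despite a modest RR.

### The league-table loop

Per country the model iterates a greedy loop: build a league table
(interventions ordered by ascending ICER; ties broken by more DALYs
averted, then alphabetically); if the lowest ICER is *strictly* below the
CET, apply that intervention at its full coverage increment, remove it
from the candidate set, and recompute the remaining ICERs on the shrunken
anaemic population. The loop stops when every intervention is applied or
none of the rest is cost-effective. Because costs are fixed while
benefitting pools only shrink, ICERs of unapplied interventions are
non-decreasing across iterations (asserted inside the loop), so the loop
terminates after at most four applications.

State updates are multiplicative on segment pools — applying an
intervention multiplies its benefitting segment by
`1 − Δc (1 − RR_eff)` — which both handles overlap between interventions
and prevents double-counting of averted cases. Nested segments stay
consistent: shrinking pregnant anaemia shrinks its malaria subset
proportionally, while IPTp removes cases from the malaria subset and
decrements the pregnant anaemic count by the same absolute amount. A
useful consequence is that with the threshold removed the final state is
order-independent and equals a closed-form product of residual factors;
the test suite exploits this as an oracle.

The severity split (mild/moderate/severe) is held fixed as prevalence
falls: interventions are assumed to resolve cases proportionally across
severities. Disability weights default to the GBD anaemia weights (mild
0.004, moderate 0.052, severe 0.149) and are configurable, since severity
handling is the one place where reasonable weight sets differ.

### Thresholds and scenarios

* `cet_gdp1` (base case): willingness to pay of 1 × GDP per capita per
  DALY averted.
* `cet_opportunity`: a country-specific opportunity-cost threshold
  (derived from health expenditure and life expectancy) supplied as an
  input column. These thresholds are estimated per QALY; the model applies
  them to DALYs averted without conversion, a deliberate simplification.
* `no_constraint`: thresholds removed; every intervention with coverage
  headroom is applied — the maximum achievable reduction.
* `zero_baseline`: current coverage treated as nil, so the full maximum
  coverage acts on the baseline burden; the CET stays at 1 × GDP. This
  probes the coverage assumptions, not the economics.

An ICER exactly equal to the CET is *not* applied (strict inequality), and
a CET of zero therefore applies nothing.

## Uncertainty propagation

Each Monte Carlo iteration draws every input parameter from a probability
distribution (1000 iterations by default; the examples below use fewer):

* RRs: lognormal with median at the point estimate and log-sd fitted so
  the 2.5/97.5 quantiles match the published CI, clamped to (0, 1.5].
* Real-world reduction: same construction from its CI, truncated below 1;
  one draw per iteration shared by both oral-iron interventions.
* Coverages: beta with mean at the point estimate and concentration 50
  (a typical survey-sized effective sample; concentration → ∞ recovers the
  point estimate).
* Unit costs: gamma with mean at the point estimate and CV 0.25.
* Severity split: Dirichlet centred on the input split, concentration 100.

Draws are seeded per (run seed, country, iteration), so results are
bit-reproducible and scenarios share common random numbers — scenario
contrasts are paired, never noise-dominated. Effectiveness draws are
*evidence-level*: the same trials inform every country, so within one
iteration a single RR draw (and one reduction draw) applies to all
countries, while coverage, cost and severity draws are country-specific.
This correlation matters for the global target: averaging countries within
an iteration cancels independent noise but not shared effectiveness
uncertainty, so the global uncertainty interval is driven by the latter.
Without shared draws the global interval would collapse to a few tenths of
a percentage point, which understates what is actually unknown.

Per country the model reports the median reduction and the 2.5–97.5
percentile uncertainty interval (linear-interpolation percentiles,
`quantile` type 7). Group and global targets average the member countries'
reductions *within* each iteration (each country counting once, mirroring
how a global target is communicated; population-weighted averaging is
available via `weighted = TRUE`) and summarise those per-iteration means.
The alternative — averaging the countries' medians and interval bounds —
is available as `aggregate_targets(..., interval = "country_summaries")`.

## The synthetic world

`generate_world()` produces country profiles and intervention tables with
the statistical structure the analysis needs, so the pipeline runs without
any external data. Three archetypes span the burden gradient — low-income
high-burden (prevalence U(0.25, 0.60), malaria share up to 50%, GDP
500–2500), middle-income (U(0.15, 0.40)), high-income low-burden
(U(0.05, 0.20), negligible malaria) — with current-coverage bands sitting
below maximum-coverage bands so scale-up headroom is the norm. Unit costs
are uniform within plausible magnitudes (fortification 0.10–1.00 USD per
capita, oral iron 2–15 USD per woman-year, IPTp 1–5 USD per pregnancy);
GDP is log-uniform within the archetype range; the opportunity-cost
threshold is drawn as 0.2–0.6 × GDP per capita, reflecting that
opportunity-cost thresholds sit well below 1 × GDP. Non-pregnant iron
coverage is derived as 0.41 × pregnant-iron coverage, and its ceiling is
antenatal-care coverage.

Each country is generated from its own seed derived from the world seed
and the country id, so enlarging a world never perturbs existing
countries. The generator emulates *structure* (nesting, ranges, headroom),
not any real country's values: synthetic worlds reproduce the model's
qualitative behaviour — scenario orderings, the spread of national targets,
the shape of uncertainty — but no number derived from them is an estimate
for any actual country, and they omit real-data features such as
within-country subnational heterogeneity, correlated coverage across
interventions, and secular trends.

## A worked run

```{r run}
world <- generate_world(30, seed = 42)
config <- cea_config(n_sims = 200, seed = 42)
targets <- anaemia_targets(world, config)
print(targets)
```

The first-iteration league table for one country, at point estimates:

```{r league}
p <- world$countries[[1]]
specs <- world$interventions[[p$country_id]]
run <- greedy_apply(p, specs, point_params(specs, config, p$severity_split),
                    cet_for_scenario(p, "cet_gdp1"), config)
run
```

```{r plot, fig.width = 6, fig.height = 5}
plot(targets, max_countries = 30)
```

## Numerical choices and degenerate inputs

* Zero initial burden is defined as a 0% reduction.
* A zero-DALY intervention has ICER +∞; under a finite CET it is never
  applied, and under `no_constraint` applying it is a no-op (the loop
  applies anything with positive headroom, so the applied set — not the
  final state — can differ from the finite-CET limit).
* Degenerate CIs (low = high) are treated as point masses throughout, and
  infinite concentrations collapse beta/Dirichlet draws to their means, so
  the Monte Carlo median provably converges to the deterministic
  point-estimate run.
* Population counts are non-negative reals; state updates assert
  non-negativity and nested-segment consistency at every step.
* Ties in the league table are broken by DALYs averted, then id, making
  runs reproducible even on engineered ties.

## Problem sizes

The test suite exercises the full pipeline at 191 synthetic countries ×
200 iterations for the scenario-ordering checks and smaller worlds
elsewhere; the bundled `scripts/acceptance.R` runs 191 countries × 200
iterations × 4 scenarios. The defaults (`n_sims = 1000`) are what an
analysis run would use.

## Limitations

* Allocative efficiency only: no budget or affordability constraint, and
  no diminishing returns within an intervention's scale-up.
* A 1-year horizon with immediately effective, continuously administered
  interventions; no projection to a target year.
* No between-country parameter correlation beyond the shared effectiveness
  draws; no uncertainty in the population denominators.
* The QALY-based opportunity-cost thresholds are applied per DALY averted
  without conversion.
* Whether fortification's benefit should differ for women already covered
  by supplementation at baseline is unresolved in the underlying evidence;
  segments are treated uniformly here.
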