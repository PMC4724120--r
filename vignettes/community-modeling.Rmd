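---
title: "Predicting community composition with balanced-growth FBA and hierarchical yield optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting community composition with balanced-growth FBA and hierarchical yield optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commfba)
```

## The modeling problem

Syntrophic microbial communities — the acetogen/methanogen partnerships of
anaerobic digestion are the motivating case — trade metabolites through a
shared medium: a fermenting species oxidizes the primary carbon source and
hands electrons on as hydrogen or formate, which methanogens must consume to
keep the exchange thermodynamically viable. Which *composition* such a
community settles into is not obvious: maximizing the community growth rate
alone typically admits a whole range of compositions, most of which require
some member to "altruistically" waste substrate so the others can keep up.

`commfba` implements a constraint-based answer in three layers:

1. **Single-species flux balance analysis (FBA).** Each organism is a
   stoichiometric model: metabolites, reactions with bounds
   `lb <= r <= ub`, and the steady-state balance `N r = 0` over internal
   metabolites. FBA maximizes a linear objective (usually biomass
   synthesis) over this polytope.

2. **Balanced-growth community assembly.** Species models become
   namespaced compartments joined by an exchange pool. Each species'
   biomass reaction produces one unit of a species biomass compound
   `BM_i`; a community biomass reaction consumes `F_i` units of each
   `BM_i` per unit of total biomass `BM_C`, where
   `F = (F_1, ..., F_n)` on the simplex is the community composition
   (gDW of species *i* per gDW of community). The `BM_i` balance then
   *forces* `r_BMi = F_i * mu_C`: every member grows at the common
   community rate `mu_C`, which is exactly the balanced-growth condition
   for a stable composition in a continuous process. Because all fluxes
   are per gDW of *community* biomass, species-specific capacities
   (uptake caps, maintenance demands, per gDW of that species) must be
   multiplied by `F_i` — `instantiate_community()` does this
   bookkeeping.

3. **Hierarchical optimization.** At a given `F`, first maximize `mu_C`
   (`max_community_growth()`). Then, at that rate, minimize the
   yield-weighted total substrate consumption

   `z = sum over (species i, substrate S_i) of r_Si * Ymax_i(mu_C)`,

   where `Ymax_i(mu_C)` is species *i*'s maximum biomass yield on `S_i`
   at growth rate `mu_C`, computed in the *single-species* model with the
   species' other substrates blocked and its maintenance demand active
   (`species_yield_at()`). `z` is the smallest total biomass synthesis
   rate the consumed substrate could have supported. The **optimality
   degree**

   `OptDeg = mu_C / z_opt`

   is 1 exactly when every member converts its substrate to biomass at
   maximum yield; below 1, someone is wasting substrate to balance the
   community. We take the composition with `OptDeg = 1` as the predicted
   operating point: any member growing below its maximum yield could gain
   by using substrate more efficiently, which would shift the composition.
   `OptDeg` can exceed 1 only when a species co-consumes several
   substrates whose combination outperforms the per-substrate maxima —
   those points are still optimal operating points.

## What counts as a substrate in `z`

Only the metabolites declared in `species_spec(substrates = ...)`
contribute summands: they are the catabolic electron/carbon sources whose
conversion efficiency the secondary objective scores. Co-substrates that
merely close elemental balances (CO2 in hydrogenotrophic methanogenesis,
for instance) should *not* be declared — their uptake is stoichiometrically
tied to the true substrate and double-counting them would distort the
weights. When a species has several declared substrates, each gets its own
summand with its own yield weight; a substrate that cannot support growth
at the current rate is dropped from the objective (and flagged `NA` in
`yield_table()`).

## Tunable parameters

| Parameter | Unit | Default | Meaning |
|---|---|---|---|
| `rate_caps` | mmol/gDW_i/h | none | capacity caps on named reactions (uptake or production); F-scaled in the community |
| `atp_maintenance` | mmol ATP/gDW_i/h | 0 | lower bound on the ATP-hydrolysis reaction; F-scaled |
| `step` | – | 0.01 | composition lattice spacing of `scan_compositions()` |
| `mu_c` | 1/h | `"max"` | fixed community growth rate(s), for chemostat-style predictions |
| exchange policy | – | — | per pool metabolite: `closed` (must be consumed in-community), `accumulating` (export allowed), `medium` (uptake allowed) |

The exchange policy encodes the biology of the cross-feeding: hydrogen and
formate are `closed` in a syntrophic community (their accumulation would
stall the acetogen), fermentation end products and the gaseous product are
`accumulating`, and the primary carbon source is `medium`. Default bounds
where a model specifies none follow the COBRA convention, (-1000, 1000)
for reversible and (0, 1000) for irreversible reactions, and the SBML
loader warns about every reaction it defaults.

Maintenance matters most at low growth rates: the apparent yield
`Y(mu) = mu Y0 / (mu + m Y0)` collapses as `mu -> 0`, so a
high-maintenance member catabolizes more substrate per unit of its own
biomass, produces more cross-fed intermediates, and is therefore needed at
a *lower* fraction — the optimal composition becomes growth-rate dependent
as soon as maintenance coefficients differ between members.

## The toy cross-feeding generator

`make_toy_pair()` builds a minimal producer/consumer pair with explicit
ATP accounting: the producer ferments substrate S to one ATP plus `x`
units of the cross-fed metabolite X per mmol; the consumer oxidizes X to
one ATP plus a product P. Biomass costs `1/Y0` ATP per gram, and
maintenance is an F-scaled bound on ATP hydrolysis. This gives closed
forms (`oracle_balanced_optimum()`) that the LP pipeline must reproduce:

```{r toy}
pair <- make_toy_pair()   # Y0 = 0.05 / 0.02 gDW/mmol, caps 10 / 15, x = 1
oracle_balanced_optimum(toy_pair_spec())[c("mu_max", "f_star")]
glance(optimality_degree(pair$template, c(A = 5 / 7, B = 2 / 7)))
```

With waste pathways off, the ATP-hydrolysis bound is pinned to the
maintenance value and only the balanced composition can grow at all;
switching waste on lets a species burn surplus ATP, which widens the
feasible composition range and produces the `OptDeg < 1` flanks that the
scanner maps:

```{r scanplot, fig.width = 5, fig.height = 3, eval = requireNamespace("ggplot2", quietly = TRUE)}
pw <- make_toy_pair(toy_pair_spec(waste_a = TRUE, waste_b = TRUE))
sc <- scan_compositions(pw$template, step = 0.02)
autoplot(sc)
```

What the toys deliberately do *not* emulate: genome-scale redundancy
(alternative pathways with different ATP stoichiometries), elemental
balancing of C/N/S, thermodynamic feasibility, and co-substrate coupling.
Tests passing on toys therefore certify the *optimization machinery* —
balanced-growth coupling, F-scaling, yield weighting, the fractional
programs — not the biological fidelity of any particular reconstruction,
which enters through the SBML models the user supplies.

## Numerical choices

- **LP solver.** All problems are solved by a two-phase dense tableau
  simplex with Bland's anti-cycling rule, written for this package
  (`R/simplex.R`). Problem sizes here are tens of variables, where a dense
  exact-pivot method is both fast enough (milliseconds per solve) and far
  more robust on the highly degenerate `N r = 0` systems than available
  alternatives; its optima are property-tested against brute-force
  basic-solution enumeration on random fixtures.
- **Tolerances.** Feasibility 1e-9; phase-1 infeasibility declared above
  1e-7; `OptDeg = 1` reported within 1e-4 by `locate_optima()` (lattice
  and LP noise are far below the two decimals at which compositions are
  reported).
- **Degenerate optima.** `fba()` returns one optimal vertex, unspecified
  which. Every downstream quantity that matters (minimum product rates,
  yields, `z_opt`) is recomputed by its own dedicated LP rather than read
  off a single FBA solution.
- **Product yields** are linear-fractional programs (export divided by
  reference uptake at fixed `F`, `mu_C`). They are solved exactly by the
  Charnes-Cooper transformation — variables `y = t r`, `t >= 0`,
  denominator normalized to 1, bounds tied to `t` — with a bisection
  solver (`method = "bisection"`) kept as an independent cross-check. A
  composition/rate point where the reference uptake is zero over the whole
  feasible set has no defined yield and is flagged `undefined`.
- **Minimum product rates** are computed subject to feasibility at
  `(F, mu_C)` only, matching the observed anti-correlation with OptDeg; an
  `at_z_opt = TRUE` switch additionally restricts to the yield-optimal
  face for the stricter variant.
- **Zero growth.** At `mu_C = 0` with maintenance active, yields vanish
  and `OptDeg` is 0/0; such rows are flagged infeasible-for-OptDeg rather
  than given an arbitrary value.
- **Exchange direction.** Every pool and environment transport is split
  into irreversible uptake/export halves at assembly, so substrate uptake
  fluxes are nonnegative and the yield-weighted objective is sign-safe.
- **Ties.** When several lattice points share the maximal OptDeg within
  tolerance, all are reported — competition scenarios genuinely have line
  segments of optima, and collapsing them to an argmax would hide that.

## Scan sizes

The test suite and the reproduction script use two-species scans at steps
0.01–0.05 (101–21 points) and three-species scans at step 0.1
(66 points); a full 0.01 three-species lattice (5151 points) runs in a few
minutes with this solver and is practical interactively but unnecessary
for the properties being checked.

## Known limitations

- No thermodynamic or loopless constraints; energy-spilling futile cycles
  are represented explicitly (waste pathways), not detected.
- The SBML subset covers constraint-based models (fbc bounds/objectives,
  L2 kinetic-law bounds, boundary conditions); kinetics, rules and events
  are ignored.
- Yield weights are recomputed per growth rate (cached to 1e-9 in
  `mu_C`); for species whose yield is limited by something other than the
  declared substrate the single-species LP still reports the uptake-based
  yield, which is the intended definition but worth keeping in mind when
  declaring substrates.
- The dense simplex is not meant for genome-scale community models with
  thousands of reactions; it is sized for core-metabolism models of the
  kind this workflow targets.
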