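# commfba

Constraint-based modeling of microbial communities under **balanced
growth**, with composition prediction by **hierarchical optimization**.

Syntrophic communities — the acetogen–methanogen partnerships of anaerobic
digestion are the canonical case — trade metabolites through a shared
medium: a fermenter oxidizes the carbon source and passes electrons on as
hydrogen or formate, which methanogens must consume for the exchange to
remain thermodynamically viable. `commfba` answers the question *which
community composition such a system settles into*, using only the
stoichiometry of the member species.

## The model

Each species is a stoichiometric metabolic model (metabolites, reactions,
flux bounds). Flux balance analysis (FBA) optimizes a linear objective
over the steady-state flux polytope

```
maximize c'r    s.t.    N r = 0,    lb <= r <= ub .
```

Community assembly (`assemble_community()`) joins the species as
namespaced compartments around an exchange pool and adds

- per species *i*, a biomass reaction producing 1 unit of `BM_i`, and
- a community biomass reaction `F_1 BM_1 + ... + F_n BM_n -> 1 BM_C`
  running at the community growth rate `mu_C`,

where `F` (the biomass-fraction vector on the simplex) is the community
composition. The `BM_i` mass balance forces `r_BMi = F_i * mu_C` — every
member grows at the common rate, the balanced-growth condition for a
stable composition. Species-specific capacities (uptake caps, ATP
maintenance, per gDW of that species) are multiplied by `F_i` so that all
community fluxes are per gDW of total biomass.

Composition is predicted hierarchically (`optimality_degree()`):

1. maximize `mu_C` at the given `F`;
2. minimize the yield-weighted substrate consumption
   `z = sum_i r_Si * Ymax_i(mu_C)`, where `Ymax_i` is species *i*'s
   maximum biomass yield on its substrate at that growth rate;
3. report the **optimality degree** `OptDeg = mu_C / z_opt`.

`OptDeg = 1` means every member converts substrate to biomass at maximum
yield — the predicted operating point; `OptDeg < 1` means some member must
waste substrate to keep the community balanced. `scan_compositions()`
maps `OptDeg`, feasibility, and minimum product rates/yields (solved as
exact linear-fractional programs) over the composition simplex and the
growth-rate axis.

Supporting estimators implement the standard parameter derivations:
`pirt_fit()` (chemostat data → true yield + maintenance uptake),
`atp_maintenance()` (zero-growth uptake × maximum ATP yield),
`cell_volume()`/`dry_weight()`/`counts_to_fractions()` (cell counts →
biomass fractions).

## Worked example

A producer/consumer toy community with explicit ATP accounting: the
producer ferments S (biomass yield 0.05 gDW/mmol, uptake cap
10 mmol/gDW/h) to the cross-fed metabolite X, which the consumer oxidizes
to P (yield 0.02 gDW/mmol, cap 15). The X pool is closed — everything
produced must be consumed:

```r
library(commfba)

pair <- make_toy_pair()
res <- optimality_degree(pair$template, c(A = 5 / 7, B = 2 / 7))
res
#> <optdeg_result> F = (A=0.714, B=0.286)
#>   mu_C = 0.3 1/h   z = 0.3   OptDeg = 1
tidy(res)
#> # A tibble: 2 × 4
#>   species substrate uptake yield
#>   <chr>   <chr>      <dbl> <dbl>
#> 1 A       S           4.29  0.05
#> 2 B       X           4.29  0.02
```

The community's maximum growth rate is 0.30 1/h, reached exactly at the
composition where the producer:consumer biomass ratio equals the ratio of
their yields (F_A = 5/7 ≈ 0.71); both species then take up 4.29
mmol/gDW/h of their substrates and `OptDeg = 1` confirms both run at
maximum yield. Scanning a variant in which both species may spill energy
shows the optimum as the peak of the OptDeg landscape:

```r
pw <- make_toy_pair(toy_pair_spec(waste_a = TRUE, waste_b = TRUE))
sc <- scan_compositions(pw$template, step = 0.05)
locate_optima(sc, tol = 0.05)
#> # A tibble: 2 × 7
#>     F_A   F_B  mu_c mu_c_max z_opt optdeg feasible
#>   <dbl> <dbl> <dbl>    <dbl> <dbl>  <dbl> <lgl>
#> 1  0.7   0.3   0.3      0.3  0.315  0.952 TRUE
#> 2  0.75  0.25  0.25     0.25 0.262  0.952 TRUE
autoplot(sc)   # OptDeg against the producer fraction
```

Maintenance estimation from (synthetic) chemostat data, converting the
zero-growth substrate uptake into an ATP-maintenance coefficient with a
published ATP yield of 1.25 mol/mol:

```r
csv <- system.file("extdata", "synthetic_chemostat.csv", package = "commfba")
cmd_estimate(csv, atp_yield = 1.25)
#> # A tibble: 1 × 3
#>   true_yield maintenance_uptake atp_maintenance
#>        <dbl>              <dbl>           <dbl>
#> 1     0.0118               2.84            3.56
```

Real studies supply their species as SBML files (`load_sbml()`, fbc or
kinetic-law bounds) and drive everything from a YAML configuration — see
`read_run_config()`, `cmd_scan()`, `cmd_predict()` and the shell wrapper
in `inst/cli/commfba`.

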