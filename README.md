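# crperturb

Consumer–resource communities under species-specific antibiotic
perturbations.

## What this package is for

Antibiotic treatment reshapes multispecies microbial communities (gut,
soil, wastewater) through more than its direct killing: species compete for
nutrients, so weakening one member reshuffles everyone's niche.  `crperturb`
implements a chemostat consumer–resource (CR) model with species-specific
death rates and the geometric coexistence theory that goes with it, for
theorists and computational microbiologists who want to ask: when does an
antibiotic's community-level effect depend on *context* — on dose, on the
order of sequential drugs, or on combination with another drug — even when
nothing but resource competition is in play?

The model for `m` species on `p` substitutable resources in a chemostat
with dilution rate `d` is

    dn_i/dt = n_i ( Σ_μ R_iμ s_μ / Σ_k n_k R_kμ − (d + d_i) ),

with consumption rates `R_iμ`, supply rates `s_μ`, and a bactericidal death
rate `d_i` (equivalently, a bacteriostatic susceptibility `b_i = (d+d_i)/d`
dividing the consumption rates — the two are identical at steady state up
to the rescaling `n_static = b · n_cidal`).  A subset of species coexists
exactly when its rescaled consumption rates `R̂_iμ = R_iμ c*_μ` lie on a
common hyperplane with positive, finite `c*`, no outsider can invade, and
the normalized supply point falls inside the convex hull of the
loss-normalized rescaled rows.  The package provides:

* `cr_community()` — the model object, with JSON/CSV serialization,
  nondimensionalization, enzyme budgets, bactericidal↔bacteriostatic
  conversion, and evenness (exponential Shannon index);
* `steady_state()` / `cr_integrate()` — adaptive Runge–Kutta integration
  (deSolve) with the extinction threshold `1e-7` and curvature-based
  convergence criteria, plus `steady_state_with_reservoir()` for outcomes
  under a re-seeding species pool;
* `coexisting_set()`, `candidate_hyperplanes()`, `direct_steady_state()`,
  `rescaled_frame()`, `coexistence_region_size()` — the analytic route
  (compiled subset enumeration with a tested pure-R reference);
* `dose_scan()`, `sequential_treatment()`, `classify_mechanism()`,
  `combination_treatment()`, `ensemble_scan()` — the treatment pipelines:
  non-monotonic richness under increasing dose, non-transitivity
  (promotion / neutralization) under order swaps, non-additivity
  (antagonism / synergism) under combinations, and their cross-occurrence
  statistics over random ensembles;
* `sample_random_community()`, `build_structured_community()` — the
  simplex-uniform and distance-parametrized community generators;
* `integrate_with_leakage()`, `reduce_to_effective_supply()`,
  `aggregate_symmetric_species()` — metabolic cross-feeding via leakage and
  the exact reductions that connect it (and larger symmetric communities)
  back to the three-species analysis;
* `run_config()` — YAML/JSON-configured pipeline runs with deterministic
  CSV/JSON artifacts.

## A worked example

A symmetric three-species community: two targeted species at distance 0.25
from the supplied-resource point on their own simplex axes, a specialized
non-target at 0.55, each antibiotic killing its target at rate 0.5.

```r
library(crperturb)

comm <- build_structured_community(structured_family_spec(0.25, 0.25, 0.55))
ab   <- structured_antibiotics(structured_family_spec(0.25, 0.25, 0.55, 0.5, 0.5))

steady_state_with_reservoir(comm)
#> Steady state (geometry): richness 3, survivors {1, 2, 3}
#>   abundances: 0.40741, 0.40741, 0.18519

combination_treatment(comm, ab$A, ab$B)
#> Combination treatment: antagonistic (combined richness 3 vs additive 1)

sequential_treatment(comm, ab$A, ab$B)
#> Sequential treatment: rho(A->B) = 2, rho(B->A) = 2, delta_rho = 0
#>   mechanism: transitive
```

All three species coexist untreated.  Either antibiotic alone kills its
target (the additive expectation is richness 1), but applied together the
two targets shield each other — the full community survives: antagonism at
the level of community richness, from resource competition alone.  The
treatment order doesn't matter here (the community is symmetric under
swapping the targets), so the sequence is transitive.

Ensemble statistics over random communities (consumption rows uniform on
the simplex, two U(0,1)-rate antibiotics, communities drawn until all three
species coexist pre-treatment):

```r
ensemble_scan(sampler_random3(), 2000, seed = 1)
#> Ensemble of 2000 communities (0 failures, 6419 draws rejected)
#>                 additivity
#> mechanism        additive antagonistic synergistic
#>   transitive         1238          520          11
#>   promotion             0          216           0
#>   neutralization        0            0           9
#>   unclassified          2            4           0
```

Order-dependent outcomes (`promotion` + `neutralization`) occur in about
11% of communities; every promotion case is simultaneously antagonistic
and essentially every neutralization case synergistic — the mechanisms
behind non-transitivity and non-additivity overlap almost completely.

## Layout

```
R/                  model, dynamics, geometry, treatments, samplers,
                    cross-feeding, config runner
src/                compiled steady-state subset solver (RcppArmadillo)
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette (model, assumptions, numerics)
inst/extdata/       small plain-text fixture communities
scripts/            acceptance script
```
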