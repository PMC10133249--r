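---
title: "Antibiotic perturbations of consumer-resource communities: model and methods"
author: "crperturb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Antibiotic perturbations of consumer-resource communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crperturb)
```

## The model

`crperturb` studies how narrow-spectrum antibiotics (or any species-specific
growth-inhibiting perturbation: phage, temperature, pH) reshape coexistence
in a microbial community competing for substitutable nutrients in a
chemostat.  With `m` species and `p` resources, species abundances follow

$$\frac{dn_i}{dt} = n_i\left(\sum_{\mu=1}^{p}
  \frac{R_{i\mu}\, s_\mu}{\sum_k n_k R_{k\mu}} - (d + d_i)\right),$$

where $R_{i\mu}$ is the rate at which species $i$ consumes resource $\mu$,
$s_\mu$ the supply rate, $d$ the dilution rate, and $d_i \ge 0$ a
species-specific death rate representing bactericidal antibiotic action.
Resource availabilities equilibrate instantaneously:
$c_\mu = s_\mu / \sum_k n_k R_{k\mu}$.  Bacteriostatic action is modelled
instead by dividing a species' consumption rates by a susceptibility
$b_i \ge 1$.  When $b_i = (d + d_i)/d$ the two forms have identical survivor
sets and abundances related by $n^{static}_i = b_i\, n^{cidal}_i$; the
package stores whichever representation was supplied, converts to the
bactericidal form internally, and reports abundances in the community's own
representation.  The equivalence is exercised directly in the test suite
(geometric fixed points and integrated Eq-2 dynamics against integrated
Eq-3 dynamics).

All computations are carried out in dimensionless units ($t' = td$,
$n' = n\,d/S$, $R' = R\,S/d^2$, $s' = s/S$), so $d = S = 1$ internally;
`normalize_community()`/`denormalize_community()` expose the rescaling.

### Assumptions worth keeping in mind

* Substitutable resources, a single shared pool, no species-specific yields.
* Death rates are constant while a treatment is "on" (no pharmacokinetics).
* Deterministic dynamics; no demographic noise, no multistability analysis.
* The uninvadable steady state is assumed unique for the communities the
  samplers produce; the solver asserts this and warns when numerical
  degeneracy makes several subsets look feasible (measure-zero inputs such
  as duplicated consumption rows).

## Steady states two ways

The package deliberately maintains two independent routes to the same
object, and the test suite holds them against each other on hundreds of
random communities:

1. **Geometry (`coexisting_set()`)**: a survivor subset $A$ is feasible
   when the availabilities $c^*_\mu$ solving
   $\sum_\mu R_{i\mu} c^*_\mu = d + d_i$ (for $i \in A$) are positive and
   finite, no outsider satisfies
   $\sum_\mu R_{j\mu} c^*_\mu > d + d_j$, and the normalized supply point
   lies inside the convex hull of the loss-normalized rescaled rows
   $\hat R_i = R_i c^* / (d + d_i)$ — equivalently, all subset abundances
   solving $\sum_k n_k R_{k\mu} = s_\mu / c^*_\mu$ are positive.  Subsets
   with fewer members than resources have no unique hyperplane; their
   abundances are instead the interior minimum of the strictly convex
   potential $G(n) = \sum_i n_i (d + d_i) - \sum_\mu s_\mu \log T_\mu(n)$,
   found by damped Newton iteration (the gradient of $G$ is exactly the
   steady-state residual, and its positive-definite Hessian is available in
   closed form).  Subset enumeration is implemented in compiled code
   (RcppArmadillo) with a pure-R reference implementation tested against it.
2. **Integration (`steady_state(method = "ode")`)**: explicit adaptive
   Runge–Kutta (deSolve's `ode45`, rtol $10^{-8}$, atol $10^{-10}$) in
   chunks, clamping abundances below $10^{-7}$ to zero (extinction is
   absorbing).  A run is converged when every remaining species has
   $|d^2 \ln n_i / dt^2| < 10^{-6}$, estimated by finite differences over
   the last three samples of a sliding window, and a residual per-capita
   rate below $10^{-4}$ (the extra slope guard stops the curvature test
   from firing during slow relaxations).  Richness counts species with
   $n_i > 10^{-7}$ and $d\ln n_i/dt > -10^{-3}$.  The endpoint is then
   refined by Newton iteration on the fixed-point equations of the
   integration's own survivor set; since the interior fixed point of a
   given support is unique this refinement cannot change the outcome, only
   sharpen it.  Runs that exhaust the time budget ($10^4$ dimensionless
   units with up to 3 restarts) are flagged `converged = FALSE` — in random
   ensembles this affects well under 1% of communities, invariably
   marginal ones with a species declining slower than the richness
   threshold.

Hull-boundary supplies are counted as contained with tolerance $10^{-9}$ so
that results are deterministic at region boundaries.

## Coexistence region size

`coexistence_region_size()` reports the fraction of the supply simplex for
which the whole community coexists.  For $m = p \in \{2, 3\}$ this is exact:
with $c^*$ fixed by the full-subset hyperplane, the coexistence region is
the convex hull of the loss-normalized rows, so the fraction is an interval
length ($p=2$) or a triangle-area ratio ($p=3$).  Otherwise seeded
Monte-Carlo over the supply simplex is used (default 20,000 samples,
reported with a binomial standard error).  The two-resource archetypes
behave as expected: a specialist pair coexists everywhere regardless of
death rates; targeting one of two symmetric generalists only shrinks the
region; weakening a generalist competing with a specialist enlarges it; and
targeting the more generalist member of an asymmetric pair traces an
interior maximum — antibiotic action can promote coexistence.

## Treatment protocols

All protocol stages use the geometry solver, with a systematic fraction of
ensemble members spot-checked against the integrator.

**Dose scans** (`dose_scan()`) scale a death-rate direction by a
concentration multiplier $c$ and follow richness with re-seeding-reservoir
semantics (steady state from the full pool at every dose).  Change points
are located on a grid (default 401 points) and refined by bisection to
$10^{-4}$ in $c$; `n_changes` counts richness transitions up to and
including the extinction of the targeted species.  Two changes below one
grid step apart would be merged — the default grid was chosen an order of
magnitude finer than any change-point spacing we observed in the scanned
families.  A caveat the package documents deliberately: when a strongly
specialized target is *replaced* at its extinction dose (another species
enters exactly as the target leaves, because the post-extinction pool
supports the same richness), the richness path records no change there.
The "emergence before extinction" reading therefore describes the typical
dose scan of a coexisting target, not a theorem; the bundled fixture family
(a targeted near-generalist against two non-targets sharing a preferred
resource) exhibits the full 1→2→3→2→3→2 five-change path, verified against
a brute-force fine-grid rescan.

**Sequential treatment** (`sequential_treatment()`): equilibrate the full
pool without antibiotic; apply antibiotic A to the survivors (no reservoir —
extinctions are permanent); swap A for B directly; compare the final
richness with the reverse order, $\Delta\rho = |\rho_{AB} - \rho_{BA}|$.
Across the structured family and the random ensemble $\Delta\rho \in
\{0, 1\}$ throughout.

**Mechanism classification** (`classify_mechanism()`): for each antibiotic,
its target's fate is evaluated on the full pre-antibiotic community and on
the community with the other antibiotic's target removed.  Competition
*promotes* an antibiotic whose target dies only in the full community, and
*neutralizes* one whose target dies only once the other target is absent.
An order-dependent outcome is labelled `promotion` when at least one
antibiotic is promoted and none neutralized (both-promoted cases are
common — roughly a quarter of order-dependent random communities — and are
genuine promotion), `neutralization` symmetrically, and `unclassified`
otherwise (about 0.25% of order-dependent cases, mostly cascades in which
a non-target goes extinct during a single-antibiotic stage).

**Combination treatment** (`combination_treatment()`): from the
pre-antibiotic survivors, extinction sets are computed under A alone, B
alone, and A+B.  The additive baseline removes the union of the
single-antibiotic extinction sets; fewer combined survivors than the
baseline is *synergism*, more is *antagonism*.  Zero doses are additive by
construction.

**Ensembles** (`ensemble_scan()`): by default draws are conditioned on full
pre-antibiotic coexistence — rejection sampling until all species coexist
at zero dose.  This is the regime in which sequential and combination
protocols can interact with the full community, and it is the convention
under which the package's headline rates (roughly 10.5% promotion, 0.6%
neutralization, 37.8% antagonism, 1.1% synergism; every promotion case
antagonistic and essentially every neutralization case synergistic) are
reproduced by `scripts/acceptance.R`.  Unconditioned sampling is available
via `condition_full_coexistence = FALSE` and yields far lower rates, since
partially coexisting communities have little room for order dependence.

## Synthetic communities

`sample_random_community()` draws consumption rows uniformly on the unit
simplex via normalized exponentials (exact uniformity; normalizing uniform
deviates is not uniform), giving every species an enzyme budget
$E_i = \sum_\mu R_{i\mu} = 1$; resources are supplied equally with $S = 1$
and $d = 1$.  Death-rate schemes: a simplex-uniform vector across species,
or independent $U(0,1)$ rates on two designated targets.
`build_structured_community()` places three species on the three
centroid-to-vertex axes of the resource simplex at prescribed distances
$D_{T1}, D_{T2}, D_N \in (0, \sqrt{2/3})$ from the supplied-resource point
(the upper limit is the centroid-to-vertex distance, which pins this
construction as the one consistent with the stated domain); the derived
target-target distance is $D_T = \sqrt{D_{T1}^2 + D_{T2}^2 + D_{T1}D_{T2}}$.
In this family all three species coexist before treatment for every
interior parameter choice (the centroid is always a positive combination of
the three placed rows), so the structured scans need no conditioning.

What the generator does *not* emulate: unequal supplies, correlated or
heavy-tailed consumption profiles, more species than resources, measured
microbiome rate parameters.  Passing tests demonstrate internal consistency
of the model and faithful reproduction of its ensemble statistics — not
that any particular real community behaves this way.

## Cross-feeding

`leakage_model()` attaches per-resource leakage fractions $l_\mu \in [0,1)$
(species-independent) and a row-stochastic byproduct matrix $B$: a fraction
$l_\mu$ of consumed resource-$\mu$ mass is excreted and redistributed as
$B_{\mu\nu}$ rather than grown on.  Consumption fluxes then solve
$F = s + B^\top(l \circ F)$, a linear system that is always invertible for
$l < 1$, and growth draws on $(1 - l_\mu) F_\mu$.  With uniform byproducts
the model is *exactly* the leakage-free chemostat with shifted supplies
$\tilde s_\mu = (1 - l_\mu) F_\mu$ (`reduce_to_effective_supply()`), which
conserves total supply.  The package integrates the leakage dynamics
natively and requires, as its correctness criterion, that survivors and
abundances match the reduced model to $10^{-5}$, and that additivity
classifications computed under the two routes coincide; leakage fractions
for the bundled experiments are drawn $U(0, 0.5)$.

## Aggregating symmetric species

Non-targeted species whose consumption rows are permutations of each other
on their private resources (equal elsewhere, equal death rates, equal
private supplies, other species symmetric across the private columns) act
as one effective species: `aggregate_symmetric_species()` merges the group
and its private resources, summing supplies and consumption.  Under exact
symmetry the reduction is exact (the merged community's trajectories map
onto symmetric trajectories of the full one); under mild perturbations
(1% noise) classifications still agree on ≥95% of random draws, which the
test suite checks by symmetrizing within a stated tolerance and refusing
larger violations.

## Problem sizes and numerical defaults

Chosen once, as the package's own desk-scale conventions: random-ensemble
statistics use 50,000 conditioned communities (tests use 20,000) with 1-in-
500 ODE spot-checks; structured-family scans use 50,000 uniform parameter
draws; the geometry-vs-integration equivalence is asserted on 500 random
communities; Monte-Carlo region sizes use 20,000 supply samples.  Newton
iterations stop at residual $10^{-11}$ (relative to the largest loss rate)
with backtracking line search confined to the positive orthant; rank-
deficient subsets are skipped and reported.  All randomness flows from
explicit seeds; identical seeds give byte-identical CSV artifacts through
`run_config()`.

## Known limitations

* Exact hull computations stop at $p = 3$; larger communities fall back to
  Monte-Carlo region sizes, and subset enumeration is practical only for
  small $m$ (the intended regime, $m, p \le 8$).
* The Methods-style stopping criteria admit a sliver of ambiguity for
  species declining slower than the richness slope threshold; such runs are
  flagged rather than silently resolved.
* Multistability, dynamic nutrient supply, toxin-mediated interactions,
  species-specific leakage and non-uniform byproduct stoichiometries are
  out of scope.
* The mechanism labels describe resource-competition context dependence
  only; they are not claims about pharmacological interaction between the
  drugs themselves.
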