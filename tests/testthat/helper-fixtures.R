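# Shared fixtures.  All instances below were located by numerical search
# (fine-grid scans confirmed by the ODE integrator) and frozen; each test
# re-derives the asserted behaviour from the instance at run time.

# Three specialists on three equally supplied resources.
specialists3 <- function() cr_community(diag(3), rep(1 / 3, 3), 1)

# Equal-budget symmetric generalists with supply at the simplex centroid.
symmetric3 <- function()
  cr_community(rbind(c(0.6, 0.2, 0.2), c(0.2, 0.6, 0.2), c(0.2, 0.2, 0.6)),
               rep(1 / 3, 3), 1)

# Three species on two resources for which exactly two of the three pairwise
# coexistence hyperplanes satisfy the feasibility conditions.
two_hyperplane_community <- function()
  cr_community(rbind(c(0.9, 0.1), c(0.55, 0.45), c(0.15, 0.85)),
               c(0.5, 0.5), 1)

# Dose-scan community: a targeted near-generalist (species 1) against two
# non-targets competing for the same preferred resource.  The richness path
# under increasing antibiotic concentration is 1 > 2 > 3 > 2 > 3 > 2 (five
# changes up to extinction of the target at c ~ 1.05).
dose_scan_community <- function()
  cr_community(rbind(c(0.12, 0.40, 0.48),
                     c(0.054, 0.892, 0.054),
                     c(0.034, 0.738, 0.228)), rep(1 / 3, 3), 1)

# Additional targeted-species placements for the same non-targets, all with
# the target coexisting pre-antibiotic and at least two richness changes.
dose_scan_targets <- function()
  list(c(0.12, 0.40, 0.48), c(0.08, 0.44, 0.48),
       c(0.10, 0.30, 0.60), c(0.16, 0.36, 0.48))

# Structured-family parameter sets with known treatment behaviour
# (D_T1, D_T2, D_N, d_1, d_2).
promotion_pars <- function() c(0.05, 0.51, 0.40, 0.97, 0.36)
neutralization_pars <- function() c(0.55, 0.22, 0.15, 0.19, 0.38)
antagonism_pars <- function() c(0.25, 0.25, 0.55, 0.50, 0.50)
synergism_pars <- function() c(0.40, 0.40, 0.18, 0.20, 0.20)

structured_from <- function(p)
  structured_family_spec(p[1], p[2], p[3], p[4], p[5])

# Four-species community whose two non-targets (3, 4) have consumption
# niches related by swapping their private resources (3, 4).
mirror4_community <- function()
  cr_community(rbind(c(0.50, 0.20, 0.15, 0.15),
                     c(0.10, 0.60, 0.15, 0.15),
                     c(0.20, 0.15, 0.40, 0.25),
                     c(0.20, 0.15, 0.25, 0.40)), rep(1 / 4, 4), 1)

# Largest abundance discrepancy between two steady states (full-length
# vectors; zero abundances compare exactly).
max_abund_diff <- function(a, b) max(abs(a$abundances - b$abundances))
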