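test_that("dose scans trace richness with reservoir semantics", {
  comm <- dose_scan_community()
  ds <- dose_scan(comm, c(1, 0, 0), c_max = 80, n_grid = 401)
  expect_equal(ds$richness_path, c(1, 2, 3, 2, 3, 2))
  expect_equal(ds$n_changes, 5L)
  expect_false(ds$capped)
  expect_true(is.finite(ds$extinction_dose))
  expect_true(all(ds$richness_grid %in% 0:3))
  # change points agree with a fine-grid brute-force rescan
  fine <- seq(0, 1.2 * ds$extinction_dose, length.out = 3000)
  rho_fine <- vapply(fine, function(cc)
    steady_state_with_reservoir(
      cr_community(comm$R, comm$s, 1, death_rates = cc * c(1, 0, 0))
    )$richness, integer(1))
  jumps <- fine[which(diff(rho_fine) != 0)]
  expect_equal(length(jumps), length(ds$change_points) +
                 sum(ds$change_points > max(fine)))
  expect_equal(sort(ds$change_points), sort(jumps),
               tolerance = diff(fine[1:2]) * 2 + 1e-4)
})

test_that("a target that coexists before treatment sees at least two richness changes", {
  o <- c(0.054, 0.892, 0.054); g <- c(0.034, 0.738, 0.228)
  for (blue in dose_scan_targets()) {
    comm <- cr_community(rbind(blue, o, g), rep(1 / 3, 3), 1)
    expect_true(1 %in% coexisting_set(comm)$survivors)
    ds <- dose_scan(comm, c(1, 0, 0), c_max = 80, n_grid = 401)
    expect_gte(ds$n_changes, 2)
  }
})

test_that("a target that is extinct at zero dose stays out and contributes no changes", {
  # species 1 dominated by the non-targets' overlapping niches
  comm <- cr_community(rbind(c(0.04, 0.80, 0.16),
                             c(0.054, 0.892, 0.054),
                             c(0.034, 0.738, 0.228)), rep(1 / 3, 3), 1)
  expect_false(1 %in% coexisting_set(comm)$survivors)
  ds <- dose_scan(comm, c(1, 0, 0), c_max = 10, n_grid = 101)
  expect_equal(ds$extinction_dose, 0)
  expect_equal(ds$n_changes, 0L)
})

test_that("sequential order dependence and its mechanism classify as frozen instances prescribe", {
  # symmetric community and symmetric antibiotics: order cannot matter
  spsym <- structured_family_spec(0.3, 0.3, 0.45, 0.6, 0.6)
  csym <- build_structured_community(spsym)
  absym <- structured_antibiotics(spsym)
  sqsym <- sequential_treatment(csym, absym$A, absym$B)
  expect_equal(sqsym$delta_rho, 0L)
  expect_identical(sqsym$mechanism, "transitive")

  # promotion: the first-order kill of the target needs its competitor
  spp <- structured_from(promotion_pars())
  cp <- build_structured_community(spp); abp <- structured_antibiotics(spp)
  sqp <- sequential_treatment(cp, abp$A, abp$B)
  expect_equal(sqp$delta_rho, 1L)
  expect_identical(sqp$mechanism, "promotion")
  expect_setequal(sort(c(sqp$rho_AB, sqp$rho_BA)), c(1, 2))
  # ODE confirmation of the context-dependence that defines promotion: the
  # promoted antibiotic (B, per the context flags) kills its target in the
  # full community but not once the other target is removed
  expect_true(sqp$context_flags$B[["extinct_in_full"]])
  expect_false(sqp$context_flags$B[["extinct_without_other_target"]])
  fullB <- suppressWarnings(steady_state(
    cr_community(cp$R, cp$s, 1, death_rates = abp$B), method = "ode"))
  aloneB <- suppressWarnings(steady_state(
    cr_community(cp$R, cp$s, 1, death_rates = abp$B), present = c(2, 3),
    method = "ode"))
  expect_false(2 %in% fullB$survivors)
  expect_true(2 %in% aloneB$survivors)

  # neutralization: the kill only happens once the other target is gone
  spn <- structured_from(neutralization_pars())
  cn <- build_structured_community(spn); abn <- structured_antibiotics(spn)
  sqn <- sequential_treatment(cn, abn$A, abn$B)
  expect_equal(sqn$delta_rho, 1L)
  expect_identical(sqn$mechanism, "neutralization")
  expect_false(sqn$context_flags$A[["extinct_in_full"]])
  expect_true(sqn$context_flags$A[["extinct_without_other_target"]])
  fulln <- suppressWarnings(steady_state(
    cr_community(cn$R, cn$s, 1, death_rates = abn$A), method = "ode"))
  alonen <- suppressWarnings(steady_state(
    cr_community(cn$R, cn$s, 1, death_rates = abn$A), present = c(1, 3),
    method = "ode"))
  expect_true(1 %in% fulln$survivors)
  expect_false(1 %in% alonen$survivors)
})

test_that("a specialized non-target makes every sequence transitive", {
  set.seed(5)
  dmax <- sqrt(2 / 3)
  for (i in 1:150) {
    sp <- structured_family_spec(runif(1, 0, dmax), runif(1, 0, dmax),
                                 runif(1, 0.55, dmax), runif(1), runif(1))
    comm <- build_structured_community(sp)
    ab <- structured_antibiotics(sp)
    expect_equal(sequential_treatment(comm, ab$A, ab$B)$delta_rho, 0L)
  }
})

test_that("delta_rho stays within {0, 1} across the structured family", {
  sc <- scan_structured_family(400, seed = 2)
  expect_true(all(sc$details$delta_rho %in% c(0L, 1L)))
  expect_true(all(sc$details$mechanism[sc$details$delta_rho == 0] ==
                    "transitive"))
})

test_that("combination treatments classify against the additive baseline", {
  # zero doses: nothing dies, additive by construction
  comm <- symmetric3()
  cb0 <- combination_treatment(comm, rep(0, 3), rep(0, 3))
  expect_identical(cb0$classification, "additive")
  expect_length(cb0$extinct_A, 0)
  expect_length(cb0$extinct_AB, 0)

  # antagonism: each antibiotic alone kills its target, together the
  # targets shield each other and all three coexist
  spa <- structured_from(antagonism_pars())
  ca <- build_structured_community(spa); aba <- structured_antibiotics(spa)
  cba <- combination_treatment(ca, aba$A, aba$B)
  expect_identical(cba$classification, "antagonistic")
  expect_identical(cba$extinct_A, 1L)
  expect_identical(cba$extinct_B, 2L)
  expect_length(cba$extinct_AB, 0)
  expect_equal(cba$d_min, 0.5)
  # ODE confirmation of the combined outcome
  oab <- suppressWarnings(steady_state(
    cr_community(ca$R, ca$s, 1, death_rates = aba$A + aba$B), method = "ode"))
  expect_identical(oab$survivors, 1:3)

  # synergism: singles preserve coexistence, the combination lets the
  # non-target drive both targets extinct
  sps <- structured_from(synergism_pars())
  cs <- build_structured_community(sps); abs_ <- structured_antibiotics(sps)
  cbs <- combination_treatment(cs, abs_$A, abs_$B)
  expect_identical(cbs$classification, "synergistic")
  expect_length(cbs$extinct_A, 0)
  expect_length(cbs$extinct_B, 0)
  expect_identical(cbs$extinct_AB, c(1L, 2L))
  os <- suppressWarnings(steady_state(
    cr_community(cs$R, cs$s, 1, death_rates = abs_$A + abs_$B), method = "ode"))
  expect_identical(os$survivors, 3L)
})

test_that("ensemble scans are deterministic and structured as a cross table", {
  e0 <- ensemble_scan(sampler_random3(), 0, seed = 1)
  expect_equal(sum(e0$counts), 0)
  e1 <- ensemble_scan(sampler_random3(), 150, seed = 42,
                      ode_check_fraction = 0)
  e2 <- ensemble_scan(sampler_random3(), 150, seed = 42,
                      ode_check_fraction = 0.05)
  expect_identical(e1$counts, e2$counts)   # spot-checks do not shift draws
  expect_equal(sum(e1$counts), 150)
  expect_equal(nrow(e1$details), 150)
  expect_true(all(e1$details$rho_pre == 3))   # conditioned by default
  expect_equal(e2$ode_mismatch, 0)
  # without conditioning, partially coexisting communities appear
  eu <- ensemble_scan(sampler_random3(), 150, seed = 42,
                      condition_full_coexistence = FALSE,
                      ode_check_fraction = 0)
  expect_true(any(eu$details$rho_pre < 3))
})

test_that("aggregating mirror-symmetric non-targets preserves treatment outcomes", {
  comm4 <- mirror4_community()
  red <- aggregate_symmetric_species(comm4, c(3, 4))
  expect_equal(red$m, 3)
  expect_equal(red$p, 3)
  expect_equal(red$s, c(0.25, 0.25, 0.5))
  A4 <- c(0.6, 0, 0, 0); B4 <- c(0, 0.5, 0, 0)
  A3 <- c(0.6, 0, 0); B3 <- c(0, 0.5, 0)
  expect_identical(combination_treatment(comm4, A4, B4)$classification,
                   combination_treatment(red, A3, B3)$classification)
  expect_identical(sequential_treatment(comm4, A4, B4)$delta_rho,
                   sequential_treatment(red, A3, B3)$delta_rho)
  # merged abundance equals the summed pair abundance (ODE on the full model)
  o4 <- suppressWarnings(steady_state(comm4, method = "ode"))
  g3 <- coexisting_set(red)
  expect_equal(g3$abundances[3], sum(o4$abundances[3:4]), tolerance = 1e-5)
  # nothing to merge: identity
  same <- aggregate_symmetric_species(comm4, 3)
  expect_equal(same$R, comm4$R)
  # asymmetry beyond tolerance is refused
  bad <- comm4; bad$R[4, 3] <- bad$R[4, 3] + 0.05
  expect_error(aggregate_symmetric_species(bad, c(3, 4)), "tolerance|permutations")
})

test_that("mildly perturbed symmetry still aggregates to matching classifications", {
  set.seed(33)
  agree <- 0; n <- 40
  for (i in 1:n) {
    comm4 <- mirror4_community()
    pert <- matrix(runif(16, -0.01, 0.01), 4)
    Rp <- pmax(comm4$R + pert, 1e-4)
    comm4p <- cr_community(Rp, comm4$s, 1)
    red <- tryCatch(aggregate_symmetric_species(comm4p, c(3, 4), tol = 0.05),
                    error = function(e) NULL)
    if (is.null(red)) next
    d12 <- runif(2)
    full_cls <- combination_treatment(comm4p, c(d12[1], 0, 0, 0),
                                      c(0, d12[2], 0, 0))$classification
    red_cls <- combination_treatment(red, c(d12[1], 0, 0),
                                     c(0, d12[2], 0))$classification
    if (identical(full_cls, red_cls)) agree <- agree + 1
  }
  expect_gte(agree / n, 0.95)
})
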