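test_that("candidate hyperplanes satisfy positivity and no-invasion conditions", {
  # identity consumption: the unique full-subset hyperplane has c* = 1
  ch <- candidate_hyperplanes(specialists3())
  full <- Filter(function(x) length(x$subset) == 3, ch)
  expect_length(full, 1)
  expect_equal(full[[1]]$c_star, rep(1, 3), tolerance = 1e-12)
  # single species on one resource: c* = (d + d_i)/R
  one <- cr_community(matrix(0.4, 1, 1), s = 1, d = 1, death_rates = 0.2)
  ch1 <- candidate_hyperplanes(one)
  expect_equal(ch1[[1]]$c_star, 1.2 / 0.4, tolerance = 1e-12)
  # three species on two resources: exactly two pairwise hyperplanes remain
  ch2 <- candidate_hyperplanes(two_hyperplane_community())
  pairs <- Filter(function(x) length(x$subset) == 2, ch2)
  expect_length(pairs, 2)
  expect_length(ch2, 2)   # no single-species state survives condition 2
})

test_that("direct steady state solves the survivor equations", {
  comm <- specialists3()
  d3 <- direct_steady_state(comm, 1:3)
  expect_true(d3$feasible)
  expect_equal(d3$abundances, rep(1 / 3, 3), tolerance = 1e-12)
  # single generalist with a death rate: flux balance S/(d + d_1)
  single <- cr_community(matrix(c(0.5, 0.5), 1), s = c(0.5, 0.5), d = 1,
                         death_rates = 1)
  d1 <- direct_steady_state(single, 1)
  expect_equal(d1$abundances[1], 0.5, tolerance = 1e-12)
  expect_equal(d1$c_star, c(2, 2), tolerance = 1e-12)
  # random invertible system agrees with the ODE route
  set.seed(31)
  comm <- sample_random_community(3, 3, death_scheme = "simplex")
  st <- coexisting_set(comm)
  ds <- direct_steady_state(comm, st$survivors)
  expect_true(ds$feasible && ds$uninvadable)
  o <- steady_state(comm, method = "ode")
  expect_equal(ds$abundances, o$abundances, tolerance = 1e-6)
})

test_that("compiled and reference solvers agree", {
  set.seed(55)
  for (i in 1:60) {
    comm <- sample_random_community(3, 3, death_scheme = "simplex")
    a <- coexisting_set(comm, engine = "cpp")
    b <- coexisting_set(comm, engine = "r")
    expect_identical(a$survivors, b$survivors)
    expect_equal(a$abundances, b$abundances, tolerance = 1e-9)
  }
})

test_that("the supply point lies in the survivor hull, on the survivor hyperplane", {
  comm <- symmetric3()
  st <- coexisting_set(comm)
  expect_identical(st$survivors, 1:3)   # centroid inside the hull
  fr <- rescaled_frame(comm, st)
  expect_true(fr$hull_contains_supply)
  expect_equal(rowSums(fr$R_hat[fr$member_subset, ]), rep(1, 3),
               tolerance = 1e-10)
  expect_equal(sum(fr$s_hat), 1, tolerance = 1e-12)
  # a targeted community whose survivor hyperplane excludes one species
  set.seed(8)
  rc <- sample_random_community(3, 3, death_scheme = "simplex")
  stc <- coexisting_set(rc)
  frc <- rescaled_frame(rc, stc)
  expect_true(frc$hull_contains_supply)
  expect_equal(rowSums(frc$R_hat[stc$survivors, , drop = FALSE]),
               (1 + rc$death_rates)[stc$survivors], tolerance = 1e-8)
})

test_that("coexistence region sizes: specialists, generalists, and exact/MC agreement", {
  # two specialists coexist for every interior supply, any death rates
  for (d1 in c(0, 0.7, 4))
    expect_equal(coexistence_region_size(
      cr_community(diag(2), death_rates = c(d1, 0)))$fraction, 1)
  # symmetric generalists: coexist iff supply share lies between the niches
  sym <- cr_community(rbind(c(0.8, 0.2), c(0.2, 0.8)))
  expect_equal(coexistence_region_size(sym)$fraction, 0.6, tolerance = 1e-12)
  # single species: everything coexists
  expect_equal(coexistence_region_size(
    cr_community(matrix(c(0.3, 0.7), 1)))$fraction, 1)
  # Monte-Carlo agrees with the exact hull area within a few stderr
  set.seed(14)
  rc <- sample_random_community(3, 3, death_scheme = "simplex")
  ex <- coexistence_region_size(rc, method = "exact")
  mc <- coexistence_region_size(rc, method = "mc", n_samples = 4000, seed = 2)
  expect_lt(abs(mc$fraction - ex$fraction), 4 * mc$stderr + 1e-3)
  # invariant under a simultaneous permutation of resources
  perm <- c(2, 3, 1)
  rp <- cr_community(rc$R[, perm], rc$s[perm], 1, death_rates = rc$death_rates)
  expect_equal(coexistence_region_size(rp)$fraction, ex$fraction,
               tolerance = 1e-10)
})

test_that("region size reduces to the equal-budget hull rule without antibiotics", {
  # with all death rates zero the survivor hyperplane is c* = 1 and the
  # region is the hull of the raw consumption rows
  comm <- symmetric3()
  ex <- coexistence_region_size(comm)$fraction
  # hull of the three rows, area relative to the simplex (exact: the rows
  # form a shrunk copy of the simplex at scale 0.4)
  expect_equal(ex, 0.4^2, tolerance = 1e-10)
})

test_that("region size responds to targeting as the four archetypes prescribe", {
  region <- function(R, d1 = 0, d2 = 0)
    coexistence_region_size(cr_community(R, death_rates = c(d1, d2)))$fraction
  bs <- c(1, 1.3, 1.8, 2.5, 4)
  # symmetric generalists: maximal at equal budgets, non-increasing outward
  sym <- rbind(c(0.8, 0.2), c(0.2, 0.8))
  v <- vapply(bs, function(b) region(sym, d1 = b - 1), numeric(1))
  expect_equal(which.max(v), 1L)
  expect_true(all(diff(v) <= 1e-12))
  # mirrored targeting gives the mirrored curve
  v2 <- vapply(bs, function(b) region(sym, d2 = b - 1), numeric(1))
  expect_equal(v, v2, tolerance = 1e-12)
  # generalist + specialist: weakening the generalist enlarges the region
  gs <- rbind(c(0.6, 0.4), c(0, 1))
  vg <- vapply(bs, function(b) region(gs, d1 = b - 1), numeric(1))
  expect_true(all(diff(vg) > 0))
  # asymmetric generalists: interior maximum when the more generalist
  # consumer is targeted
  asym <- rbind(c(0.9, 0.1), c(0.6, 0.4))
  ba <- seq(1, 3, 0.2)
  va <- vapply(ba, function(b) region(asym, d2 = b - 1), numeric(1))
  expect_gt(which.max(va), 1)
  expect_lt(which.max(va), length(va))
})
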