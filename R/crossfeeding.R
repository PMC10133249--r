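# Metabolic leakage (cross-feeding): during consumption a fraction l_mu of
# the mass of resource mu is excreted as byproducts rather than grown on,
# and the leaked flux re-enters the resource pool according to a
# row-stochastic byproduct distribution.  With species-independent leakage
# fractions the consumption fluxes F solve the linear balance
#   F = s + t(B) %*% (l * F),
# and growth draws on (1 - l_mu) of the consumed flux, so the model is the
# leakage-free chemostat with shifted supply rates (1 - l) * F.

#' Leakage model
#'
#' @param fractions per-resource leakage fractions \code{l_mu} in
#'   \code{[0, 1)}, identical across species.
#' @param byproduct optional row-stochastic matrix distributing leaked mass
#'   of each resource over the resource pool; default uniform (\code{1/p}
#'   everywhere).
#' @return a \code{cr_leakage} object.
#' @export
leakage_model <- function(fractions, byproduct = NULL) {
  l <- as.numeric(fractions)
  if (any(!is.finite(l)) || any(l < 0) || any(l >= 1))
    stop("leakage fractions must lie in [0, 1)")
  p <- length(l)
  if (is.null(byproduct)) byproduct <- matrix(1 / p, p, p)
  byproduct <- as.matrix(byproduct)
  if (!all(dim(byproduct) == p) || any(byproduct < 0) ||
      max(abs(rowSums(byproduct) - 1)) > 1e-10)
    stop("byproduct must be a row-stochastic p x p matrix")
  structure(list(leakage_fractions = l, byproduct_distribution = byproduct),
            class = "cr_leakage")
}

# Steady consumption fluxes F_mu including recycled byproducts.
leakage_fluxes <- function(s, leakage) {
  p <- length(s)
  M <- diag(p) - t(leakage$byproduct_distribution) %*%
    diag(leakage$leakage_fractions, p)
  f <- tryCatch(solve(M, s), error = function(e) NULL)
  if (is.null(f) || any(!is.finite(f)) || any(f < 0))
    stop("divergent byproduct recycling: effective supply is not finite")
  f
}

#' Integrate community dynamics with metabolic leakage
#'
#' Species growth from resource \code{mu} carries the factor
#' \code{1 - l_mu}; the leaked share of every consumption flux re-enters the
#' pool through the byproduct distribution.  Steady-state and extinction
#' criteria are those of \code{\link{cr_integrate}}.
#'
#' @param community a \code{\link{cr_community}}.
#' @param leakage a \code{\link{leakage_model}}.
#' @param init initial abundances (default equal).
#' @param t_max integration horizon.
#' @return a \code{cr_trajectory}.
#' @export
integrate_with_leakage <- function(community, leakage, init = NULL,
                                   t_max = 100) {
  stopifnot(is_cr_community(community), inherits(leakage, "cr_leakage"))
  comm <- normalize_community(static_if_needed(community))
  stopifnot(length(leakage$leakage_fractions) == comm$p)
  f <- leakage_fluxes(comm$s, leakage)
  snum <- (1 - leakage$leakage_fractions) * f
  eng <- ode_engine(comm, snum = snum)
  if (is.null(init)) init <- rep(1 / comm$m, comm$m)
  res <- eng$run(as.numeric(init), 0, t_max, 200L)
  structure(list(times = res$times, abundances = res$states,
                 all_extinct = all(res$final <= 0)),
            class = "cr_trajectory")
}

#' @rdname integrate_with_leakage
#' @return \code{steady_state_with_leakage} integrates to steady state and
#'   returns a \code{cr_steady_state}.
#' @export
steady_state_with_leakage <- function(community, leakage, t_max = 1e4) {
  stopifnot(is_cr_community(community), inherits(leakage, "cr_leakage"))
  comm <- normalize_community(static_if_needed(community))
  f <- leakage_fluxes(comm$s, leakage)
  snum <- (1 - leakage$leakage_fractions) * f
  eng <- ode_engine(comm, snum = snum)
  res <- run_to_steady(eng, rep(1 / comm$m, comm$m), t_max = t_max)
  make_steady_state(comm, res$state, res$slope, res$converged, "ode")
}

#' Reduce a leakage model to shifted supply rates
#'
#' When byproducts are distributed uniformly and leakage fractions are
#' species-independent, the leakage model is equivalent to the leakage-free
#' chemostat with supply rates \code{(1 - l) * F}, where \code{F} are the
#' recycled consumption fluxes.  The shifted supply conserves the total
#' supply.
#'
#' @inheritParams integrate_with_leakage
#' @return a leakage-free \code{\link{cr_community}} with shifted supply.
#' @export
reduce_to_effective_supply <- function(community, leakage) {
  stopifnot(is_cr_community(community), inherits(leakage, "cr_leakage"))
  B <- leakage$byproduct_distribution
  if (max(abs(B - 1 / nrow(B))) > 1e-10)
    stop("the supply-shift reduction requires a uniform byproduct distribution")
  comm <- static_if_needed(community)
  f <- leakage_fluxes(comm$s, leakage)
  s_eff <- (1 - leakage$leakage_fractions) * f
  cr_community(comm$R, s_eff, comm$d,
               death_rates = comm$death_rates)
}
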