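#' @useDynLib crperturb, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Thresholds of the steady-state and richness criteria (dimensionless
# abundances).  A species whose abundance falls below EXTINCT_THR is clamped
# to zero and removed from subsequent competition; a run is at steady state
# once every remaining species has |d^2 ln n / dt^2| < SS_D2_TOL; richness
# counts species with n > EXTINCT_THR and d ln n / dt > -RICH_SLOPE_TOL.
EXTINCT_THR   <- 1e-7
SS_D2_TOL     <- 1e-6
RICH_SLOPE_TOL <- 1e-3

# Per-capita growth rates at abundances n (zeros allowed; extinct species get
# growth 0).  `snum` is the vector multiplying R in the numerator (the supply
# rates, or leakage-adjusted effective supply rates).
cr_growth <- function(R, snum, n) {
  alive <- n > 0
  g <- numeric(length(n))
  if (!any(alive)) return(g)
  Tmu <- colSums(R[alive, , drop = FALSE] * n[alive])
  ratio <- ifelse(Tmu > 0, snum / Tmu, 0)
  g[alive] <- as.vector(R[alive, , drop = FALSE] %*% ratio)
  g
}

#' Integrate the community dynamics
#'
#' Integrates the bactericidal-form dynamics with an explicit adaptive
#' Runge-Kutta method (via \pkg{deSolve}), in dimensionless time
#' \code{t' = t d}.  Extinction is absorbing: a species whose abundance drops
#' below \code{1e-7} is clamped to zero and no longer competes.
#'
#' @param community a \code{\link{cr_community}}.
#' @param init initial abundances (dimensionless); default equal abundances
#'   \code{1/m} for all species.
#' @param t_max integration horizon in dimensionless time units.
#' @param n_record approximate number of recorded time points.
#' @return a \code{cr_trajectory}: list with \code{times} and the
#'   time-by-species \code{abundances} matrix; \code{all_extinct} flags runs
#'   that lost every species.
#' @export
cr_integrate <- function(community, init = NULL, t_max = 100,
                         n_record = 200) {
  stopifnot(is_cr_community(community))
  comm <- normalize_community(community)
  eng <- ode_engine(comm)
  if (is.null(init)) init <- rep(1 / comm$m, comm$m)
  init <- as.numeric(init)
  stopifnot(length(init) == comm$m, all(init >= 0))
  res <- eng$run(init, 0, t_max, max(n_record, 2L))
  structure(list(times = res$times, abundances = res$states,
                 all_extinct = all(res$states[nrow(res$states), ] <= 0)),
            class = "cr_trajectory")
}

# Chunked ODE engine with absorbing extinction.  `snum` defaults to the
# supply rates; cross-feeding passes leakage-adjusted effective supplies.
# Susceptibility (bacteriostatic) communities are integrated in their own
# form: consumption rates divided by b_i, plain dilution loss.
ode_engine <- function(comm, snum = NULL, delta = NULL) {
  R <- comm$R
  if (!is.null(comm$susceptibilities)) {
    R <- R / comm$susceptibilities
    if (is.null(delta)) delta <- rep(comm$d, comm$m)
  }
  if (is.null(snum)) snum <- comm$s
  if (is.null(delta)) delta <- loss_rates(comm)
  derivs <- function(t, n, parms) {
    n <- pmax(n, 0)
    list(n * (cr_growth(R, snum, n) - delta))
  }
  run <- function(init, t0, t1, npts) {
    times <- seq(t0, t1, length.out = npts)
    # integrate in chunks so that extinction clamping is applied promptly
    chunk <- max(5, (t1 - t0) / 20)
    bounds <- unique(c(seq(t0, t1, by = chunk), t1))
    state <- init
    all_t <- t0
    all_s <- matrix(state, nrow = 1)
    for (b in seq_len(length(bounds) - 1L)) {
      tt <- times[times > bounds[b] & times <= bounds[b + 1L]]
      tt <- unique(c(bounds[b], tt, bounds[b + 1L]))
      sol <- deSolve::ode(y = state, times = tt, func = derivs, parms = NULL,
                          method = "ode45", rtol = 1e-8, atol = 1e-10)
      st <- unname(sol[-1, -1, drop = FALSE])
      st[st < EXTINCT_THR] <- 0
      state <- st[nrow(st), ]
      all_t <- c(all_t, sol[-1, 1])
      all_s <- rbind(all_s, st)
    }
    list(times = all_t, states = all_s, final = state)
  }
  polish <- function(state, alive) {
    RA <- R[alive, , drop = FALSE]
    cons <- which(colSums(RA) > 0 & snum > 0)
    if (length(cons) < length(alive)) return(NULL)
    newton_subset_r(RA[, cons, drop = FALSE], snum[cons], delta[alive],
                    n_init = state[alive])
  }
  list(run = run, delta = delta, growth = function(n) cr_growth(R, snum, n),
       polish = polish)
}

# Integrate to steady state per the convergence criteria; returns final
# state, diagnostics and convergence flag.  The second derivative of
# log-abundance is estimated by central finite differences over the last
# three samples of a sliding window.
run_to_steady <- function(eng, init, t_max = 1e4, restarts = 3) {
  dt <- 5
  state <- init
  t_now <- 0
  budget <- t_max * (restarts + 1)
  ts <- numeric(0)   # sample times of the sliding window
  lns <- list()      # log-abundance samples
  converged <- FALSE
  while (t_now < budget) {
    res <- eng$run(state, t_now, t_now + dt, 2L)
    state <- res$final
    t_now <- t_now + dt
    dt <- min(dt * 1.3, 100)
    alive <- state > 0
    ln <- ifelse(alive, log(pmax(state, 1e-300)), NA_real_)
    ts <- c(ts, t_now); lns <- c(lns, list(ln))
    if (length(lns) > 3) { ts <- ts[-1]; lns <- lns[-1] }
    if (!any(alive)) { converged <- TRUE; break }
    if (length(lns) == 3) {
      # unequal-spacing finite-difference estimate of d^2 ln n / dt^2
      d1a <- (lns[[2]] - lns[[1]]) / (ts[2] - ts[1])
      d1b <- (lns[[3]] - lns[[2]]) / (ts[3] - ts[2])
      d2 <- 2 * (d1b - d1a) / (ts[3] - ts[1])
      slope <- eng$growth(state) - eng$delta
      # settled species have flat log-abundance curvature AND a residual
      # per-capita rate an order of magnitude below the richness threshold;
      # the slope guard keeps slow relaxations and slow extinctions (both of
      # which flatten d2 early) integrating until they resolve
      settled <- !alive | (!is.na(d2) & abs(d2) < SS_D2_TOL &
                             abs(slope) < 1e-4)
      if (all(settled, na.rm = TRUE)) {
        converged <- TRUE; break
      }
    }
  }
  # polish: the stopping criteria leave the state close to, but not exactly
  # on, the fixed point; refine the surviving abundances by Newton iteration
  # on the fixed-point equations, starting from the trajectory endpoint (the
  # survivor set itself remains the integration's verdict)
  if (converged && any(state > EXTINCT_THR)) {
    alive <- which(state > EXTINCT_THR)
    # the interior fixed point for a given survivor set is unique, so any
    # converged refinement is the steady state of that support; the guard
    # only rejects runaway corrections
    pol <- eng$polish(state, alive)
    if (!is.null(pol) && max(abs(pol - state[alive])) < 0.5) {
      state[alive] <- pol
      state[-alive] <- 0
    }
  }
  slope <- eng$growth(state) - eng$delta
  list(state = state, slope = slope, converged = converged, t_end = t_now)
}

# Assemble a cr_steady_state object from a final state.
make_steady_state <- function(comm, state, slope, converged, method) {
  surv <- which(state > EXTINCT_THR & slope > -RICH_SLOPE_TOL)
  Reff <- if (!is.null(comm$susceptibilities))
    comm$R / comm$susceptibilities else comm$R
  Tmu <- colSums(Reff * state)
  cst <- ifelse(Tmu > 0, comm$s / Tmu, ifelse(comm$s > 0, Inf, 0))
  ev <- if (length(surv)) evenness(state[surv]) else NA_real_
  structure(list(abundances = state, survivors = surv,
                 richness = length(surv), resource_availabilities = cst,
                 converged = converged, evenness = ev, method = method),
            class = "cr_steady_state")
}

#' @export
print.cr_steady_state <- function(x, ...) {
  cat(sprintf("Steady state (%s): richness %d, survivors {%s}\n",
              x$method, x$richness, paste(x$survivors, collapse = ", ")))
  cat("  abundances:", paste(signif(x$abundances, 5), collapse = ", "), "\n")
  if (!x$converged) cat("  WARNING: not converged\n")
  invisible(x)
}

#' Steady state of a community
#'
#' Runs the community to steady state from equal abundances of the present
#' species.  With \code{method = "ode"} the dynamics are integrated until
#' every species either falls below the extinction threshold \code{1e-7} or
#' satisfies \code{|d^2 ln n / dt^2| < 1e-6}; richness then counts species
#' with \code{n > 1e-7} and \code{d ln n / dt > -1e-3}.  With
#' \code{method = "geometry"} the steady state is obtained from the analytic
#' coexistence conditions (see \code{\link{coexisting_set}}); the two routes
#' agree for this model class.
#'
#' @param community a \code{\link{cr_community}}.
#' @param present indices of initially present species (default all).
#' @param method \code{"ode"} or \code{"geometry"}.
#' @param t_max ODE time budget (dimensionless), with up to 3 restarts.
#' @return a \code{cr_steady_state}: abundances (dimensionless; zero for
#'   extinct species), survivor indices, richness, steady-state resource
#'   availabilities \code{c*}, evenness and a convergence flag.
#' @export
steady_state <- function(community, present = NULL,
                         method = c("ode", "geometry"), t_max = 1e4) {
  method <- match.arg(method)
  stopifnot(is_cr_community(community))
  comm <- normalize_community(community)
  if (is.null(present)) present <- seq_len(comm$m)
  present <- sort(unique(as.integer(present)))
  if (!length(present)) stop("present_species must be non-empty")
  if (method == "geometry") return(coexisting_set(community, present))
  init <- numeric(comm$m)
  init[present] <- 1 / comm$m
  eng <- ode_engine(comm)
  res <- run_to_steady(eng, init, t_max = t_max)
  if (!res$converged)
    warning("steady state not reached within the time budget")
  make_steady_state(comm, res$state, res$slope, res$converged, "ode")
}

#' Steady state in the presence of a re-seeding reservoir
#'
#' Evaluates the community outcome with all species transiently repopulated
#' from an external pool, i.e. the steady state from the full species set
#' regardless of which species survived any earlier condition.
#'
#' @inheritParams steady_state
#' @export
steady_state_with_reservoir <- function(community,
                                        method = c("geometry", "ode")) {
  method <- match.arg(method)
  steady_state(community, present = seq_len(community$m), method = method)
}

#' @export
#' @rdname cr_integrate
#' @param object,nsim,seed standard \code{\link[stats]{simulate}} arguments;
#'   \code{nsim} trajectories are returned as a list when \code{nsim > 1}.
#' @param ... passed on to \code{cr_integrate}.
simulate.cr_community <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nsim), function(k) cr_integrate(object, ...))
  if (nsim == 1) out[[1]] else out
}

#' @export
print.cr_trajectory <- function(x, ...) {
  cat(sprintf("Community trajectory: %d time points, %d species, t in [%g, %g]\n",
              length(x$times), ncol(x$abundances), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
plot.cr_trajectory <- function(x, log = "", ...) {
  graphics::matplot(x$times, x$abundances, type = "l", lty = 1,
                    xlab = "time (dimensionless)", ylab = "abundance",
                    log = log, ...)
  invisible(x)
}

#' Export a trajectory as tidy CSV
#'
#' One row per (time, species) pair with columns \code{time},
#' \code{species_id}, \code{abundance}.
#'
#' @param trajectory a \code{cr_trajectory}.
#' @param path output file.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  m <- ncol(trajectory$abundances)
  df <- data.frame(
    time = rep(trajectory$times, each = m),
    species_id = rep(seq_len(m), times = length(trajectory$times)),
    abundance = as.vector(t(trajectory$abundances)))
  utils::write.csv(format_sig(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# 12-significant-digit formatting for diffable CSV outputs.
format_sig <- function(df, digits = 12) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = digits,
                                                 format = "g"))
  df
}
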