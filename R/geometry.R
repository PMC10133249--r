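# Analytic coexistence machinery on the resource simplex.
#
# At a steady state with survivor set A, the availabilities
# c*_mu = s_mu / sum_{k in A} n_k R_kmu satisfy, for every survivor i,
#   sum_mu R_imu c*_mu = d + d_i                     (the survivor hyperplane)
# and every non-survivor j must obey
#   sum_mu R_jmu c*_mu <= d + d_j                    (uninvadability).
# Writing R^_imu = R_imu c*_mu and s^_mu = s_mu d/S, the survivor rows lie on
# a common hyperplane and coexistence requires s^ to lie in the convex hull
# of the (loss-rate-normalized) rescaled rows.

HULL_TOL <- 1e-9

# Internal fast solve on raw matrices (dimensionless inputs).
solve_state <- function(R, s, delta, present) {
  .cr_solve_cpp(R, s, delta, as.integer(present))
}

# Reference R implementation of the same enumeration (used as a cross-check
# of the compiled solver in the test suite).
solve_state_r <- function(R, s, delta, present) {
  best <- NULL; n_feasible <- 0L
  peff <- sum(s > 0)
  for (k in seq(min(length(present), peff), 1)) {
    subsets <- utils::combn(present, k, simplify = FALSE)
    for (A in subsets) {
      cand <- subset_state(R, s, delta, A, setdiff(present, A))
      if (is.null(cand)) next
      n_feasible <- n_feasible + 1L
      if (is.null(best)) best <- c(cand, list(subset = A))
    }
  }
  if (is.null(best))
    return(list(found = FALSE, survivors = integer(0),
                abundances = numeric(nrow(R)), c_star = rep(NA_real_, ncol(R)),
                n_feasible = 0L))
  nf <- numeric(nrow(R)); nf[best$subset] <- best$abundances
  list(found = TRUE, survivors = best$subset, abundances = nf,
       c_star = best$c_star, n_feasible = n_feasible)
}

# Steady state restricted to subset A, or NULL if infeasible/invadable.
subset_state <- function(R, s, delta, A, others = integer(0)) {
  p <- ncol(R)
  RA <- R[A, , drop = FALSE]
  cons <- which(colSums(RA) > 0 & s > 0)
  k <- length(A)
  if (length(cons) < k) return(NULL)
  if (k == length(cons)) {
    RAc <- RA[, cons, drop = FALSE]
    cc <- tryCatch(solve(RAc, delta[A]), error = function(e) NULL)
    if (is.null(cc) || any(!is.finite(cc)) || any(cc <= 0)) return(NULL)
    n <- tryCatch(solve(t(RAc), s[cons] / cc), error = function(e) NULL)
    if (is.null(n) || any(n <= 0)) return(NULL)
  } else {
    n <- newton_subset_r(RA[, cons, drop = FALSE], s[cons], delta[A])
    if (is.null(n)) return(NULL)
    cc <- s[cons] / as.vector(t(RA[, cons, drop = FALSE]) %*% n)
  }
  cst <- ifelse(s > 0, Inf, 0)
  cst[cons] <- cc
  for (j in others) {
    act <- R[j, ] > 0
    if (any(act & !is.finite(cst))) return(NULL)
    if (sum(R[j, act] * cst[act]) > delta[j] + HULL_TOL) return(NULL)
  }
  list(abundances = as.numeric(n), c_star = cst)
}

# Damped Newton minimisation of G(n) = sum n_i delta_i - sum s_mu log T_mu
# for survivor subsets smaller than the number of supplied resources.
newton_subset_r <- function(RA, sc, deltaA, n_init = NULL) {
  k <- nrow(RA)
  n <- if (is.null(n_init)) rep(sum(sc) / sum(deltaA), k) else n_init
  for (iter in 1:100) {
    Tmu <- as.vector(t(RA) %*% n)
    if (min(Tmu) <= 0) return(NULL)
    g <- deltaA - as.vector(RA %*% (sc / Tmu))
    if (max(abs(g)) < 1e-11 * max(1, max(deltaA))) return(n)
    H <- RA %*% (t(RA) * (sc / Tmu^2))
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    t_ <- 1
    pos <- step > 0
    if (any(pos)) t_ <- min(1, 0.95 * min(n[pos] / step[pos]))
    G0 <- sum(n * deltaA) - sum(sc * log(Tmu))
    ok <- FALSE
    for (ls in 1:40) {
      ntry <- n - t_ * step
      Ttry <- as.vector(t(RA) %*% ntry)
      if (min(ntry) > 0 && min(Ttry) > 0) {
        if (sum(ntry * deltaA) - sum(sc * log(Ttry)) <=
            G0 + 1e-12 * abs(G0)) { n <- ntry; ok <- TRUE; break }
      }
      t_ <- t_ / 2
    }
    if (!ok || min(n) < 1e-12 * sum(sc)) return(NULL)
  }
  NULL
}

#' Candidate coexistence hyperplanes
#'
#' Enumerates species subsets of size at most \code{p} whose steady-state
#' availabilities \code{c*} (i) are positive and finite and (ii) leave no
#' other species able to invade (\code{sum_mu R_jmu c*_mu <= d + d_j}).  For
#' subsets smaller than \code{p} the availabilities are pinned by the direct
#' steady state of the subset (\code{c*_mu = s_mu / T_mu}) rather than by an
#' underdetermined hyperplane.  Rank-deficient subsets are skipped and listed
#' in the \code{skipped} attribute.
#'
#' @param community a \code{\link{cr_community}}.
#' @param present indices of species to consider (default all).
#' @return list of candidates, each with \code{subset} and \code{c_star}.
#' @export
candidate_hyperplanes <- function(community, present = NULL) {
  stopifnot(is_cr_community(community))
  comm <- normalize_community(static_if_needed(community))
  if (is.null(present)) present <- seq_len(comm$m)
  delta <- loss_rates(comm)
  peff <- sum(comm$s > 0)
  out <- list(); skipped <- list()
  for (k in seq(min(length(present), peff), 1)) {
    for (A in utils::combn(present, k, simplify = FALSE)) {
      RA <- comm$R[A, , drop = FALSE]
      cons <- which(colSums(RA) > 0 & comm$s > 0)
      if (length(cons) == k &&
          qr(RA[, cons, drop = FALSE])$rank < k) {
        skipped <- c(skipped, list(A)); next
      }
      cand <- subset_state(comm$R, comm$s, delta, A, setdiff(present, A))
      if (!is.null(cand))
        out <- c(out, list(list(subset = A, c_star = cand$c_star)))
    }
  }
  attr(out, "skipped") <- skipped
  out
}

static_if_needed <- function(community) {
  if (!is.null(community$susceptibilities)) static_to_cidal(community)
  else community
}

#' Direct steady state for a prescribed survivor subset
#'
#' Solves the survivor equations \code{sum_mu R_imu c*_mu = d + d_i} for the
#' availabilities, then the linear system \code{sum_k n_k R_kmu = s_mu/c*_mu}
#' for abundances.  A subset is feasible when all abundances and
#' availabilities are positive; \code{uninvadable} additionally screens all
#' remaining species against condition (2).
#'
#' @param community a \code{\link{cr_community}}.
#' @param subset survivor species indices (at most \code{p}).
#' @return list with \code{feasible}, \code{abundances} (full length, zeros
#'   off the subset), \code{c_star} and \code{uninvadable}.
#' @export
direct_steady_state <- function(community, subset) {
  stopifnot(is_cr_community(community))
  comm <- normalize_community(static_if_needed(community))
  subset <- sort(unique(as.integer(subset)))
  stopifnot(length(subset) >= 1, all(subset >= 1), all(subset <= comm$m))
  delta <- loss_rates(comm)
  others <- setdiff(seq_len(comm$m), subset)
  cand <- subset_state(comm$R, comm$s, delta, subset, integer(0))
  if (is.null(cand))
    return(list(feasible = FALSE, abundances = numeric(comm$m),
                c_star = rep(NA_real_, comm$p), uninvadable = NA))
  uninv <- !is.null(subset_state(comm$R, comm$s, delta, subset, others))
  n <- numeric(comm$m); n[subset] <- cand$abundances
  list(feasible = TRUE, abundances = n, c_star = cand$c_star,
       uninvadable = uninv)
}

#' Coexisting set from the geometric conditions
#'
#' Returns the unique feasible, uninvadable steady state over the given
#' species pool: the survivor subset whose rescaled consumption rates lie on
#' a common hyperplane whose convex hull contains the normalized supply
#' rates.  Agrees with \code{\link{steady_state_with_reservoir}}.
#'
#' @param community a \code{\link{cr_community}}.
#' @param present species pool (default all species).
#' @param engine \code{"cpp"} (compiled, default) or \code{"r"} (reference).
#' @return a \code{cr_steady_state}.
#' @export
coexisting_set <- function(community, present = NULL,
                           engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(is_cr_community(community))
  comm <- normalize_community(static_if_needed(community))
  if (is.null(present)) present <- seq_len(comm$m)
  present <- sort(unique(as.integer(present)))
  delta <- loss_rates(comm)
  sol <- if (engine == "cpp") solve_state(comm$R, comm$s, delta, present)
         else solve_state_r(comm$R, comm$s, delta, present)
  if (!sol$found && length(present))
    stop("no feasible coexistence hyperplane found (degenerate community?)")
  if (sol$n_feasible > 1)
    warning(sprintf("%d feasible uninvadable states found; using the largest",
                    sol$n_feasible))
  n <- as.numeric(sol$abundances)
  # report abundances in the community's own representation: the
  # bacteriostatic fixed point is the bactericidal one rescaled by b_i
  if (!is.null(community$susceptibilities))
    n <- n * community$susceptibilities
  st <- make_steady_state(comm, n, slope = rep(0, comm$m), converged = TRUE,
                          method = "geometry")
  # survivors straight from the solver (no slope thresholding needed)
  st$survivors <- sort(as.integer(sol$survivors))
  st$richness <- length(st$survivors)
  st$resource_availabilities <- as.numeric(sol$c_star)
  st
}

#' Rescaled simplex-geometry view of a steady state
#'
#' @param community a \code{\link{cr_community}}.
#' @param state optional \code{cr_steady_state}; computed via
#'   \code{\link{coexisting_set}} when missing.
#' @return a \code{cr_rescaled_frame}: normalized supply \code{s_hat},
#'   rescaled rates \code{R_hat = R c*} (rows of members summing to
#'   \code{d + d_i}), the member subset and whether the (loss-normalized)
#'   member hull contains the supply point.
#' @export
rescaled_frame <- function(community, state = NULL) {
  stopifnot(is_cr_community(community))
  comm <- normalize_community(static_if_needed(community))
  if (is.null(state)) state <- coexisting_set(community)
  cst <- state$resource_availabilities
  R_hat <- sweep(comm$R, 2, ifelse(is.finite(cst), cst, 0), "*")
  s_hat <- comm$s * comm$d / comm$S
  members <- state$survivors
  delta <- loss_rates(comm)
  H <- R_hat[members, , drop = FALSE] / delta[members]
  contains <- hull_contains(H, s_hat)
  structure(list(c_star = cst, s_hat = s_hat, R_hat = R_hat,
                 member_subset = members, hull_contains_supply = contains),
            class = "cr_rescaled_frame")
}

# Does the convex hull of the rows of H (points on the simplex) contain x?
# Solved as a small non-negative least-squares feasibility problem; boundary
# cases within HULL_TOL count as contained.
hull_contains <- function(H, x) {
  k <- nrow(H)
  if (k == 0) return(FALSE)
  A <- rbind(t(H), rep(1, k))
  b <- c(x, 1)
  w <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (!is.null(w) && max(abs(A %*% w - b)) < 1e-8 && min(w) >= -HULL_TOL)
    return(TRUE)
  if (k <= 2 || is.null(w)) return(FALSE)
  # rank-deficient or over-complete: try all sub-simplices
  for (kk in seq(min(k - 1, length(x)), 1))
    for (idx in utils::combn(k, kk, simplify = FALSE))
      if (hull_contains(H[idx, , drop = FALSE], x)) return(TRUE)
  FALSE
}

#' Coexistence region size
#'
#' Fraction of the supply simplex (supply vectors with the community's total
#' supply) for which all species coexist at steady state.  For \code{m == p}
#' with two or three resources the fraction is computed exactly as the
#' relative length/area of the convex hull of the loss-normalized rescaled
#' consumption rows; otherwise seeded Monte-Carlo sampling over the supply
#' simplex is used, reported with its binomial standard error.
#'
#' @param community a \code{\link{cr_community}} (its \code{s} is ignored:
#'   the supply point is what is being swept).
#' @param method \code{"auto"}, \code{"exact"} or \code{"mc"}.
#' @param n_samples Monte-Carlo sample count.
#' @param seed Monte-Carlo seed.
#' @return list with \code{fraction}, \code{stderr} (0 for exact results) and
#'   \code{method}.
#' @export
coexistence_region_size <- function(community, method = c("auto", "exact", "mc"),
                                    n_samples = 20000, seed = 1) {
  method <- match.arg(method)
  stopifnot(is_cr_community(community))
  comm <- normalize_community(static_if_needed(community))
  delta <- loss_rates(comm)
  m <- comm$m; p <- comm$p
  exact_ok <- (m == p && p %in% c(2, 3)) || m == 1
  if (method == "auto") method <- if (exact_ok) "exact" else "mc"
  if (method == "exact" && !exact_ok)
    stop("exact computation requires m == p with p in {2, 3}, or m == 1")
  if (method == "exact") {
    if (m == 1) return(list(fraction = 1, stderr = 0, method = "exact"))
    cc <- tryCatch(solve(comm$R, delta), error = function(e) NULL)
    if (is.null(cc) || any(!is.finite(cc)) || any(cc <= 0))
      return(list(fraction = 0, stderr = 0, method = "exact"))
    H <- sweep(comm$R, 2, cc, "*") / delta   # rows on the unit simplex
    frac <- if (p == 2) abs(H[1, 1] - H[2, 1])
            else abs((H[2, 1] - H[1, 1]) * (H[3, 2] - H[1, 2]) -
                     (H[3, 1] - H[1, 1]) * (H[2, 2] - H[1, 2]))
    return(list(fraction = frac, stderr = 0, method = "exact"))
  }
  set.seed(seed)
  ss <- runif_simplex(n_samples, p)
  hits <- 0L
  for (i in seq_len(n_samples)) {
    sol <- solve_state(comm$R, ss[i, ], delta, seq_len(m))
    if (sol$found && length(sol$survivors) == m) hits <- hits + 1L
  }
  fr <- hits / n_samples
  list(fraction = fr, stderr = sqrt(fr * (1 - fr) / n_samples), method = "mc")
}

#' Write coexistence-region results as CSV
#'
#' Tidy export with columns \code{community_id}, \code{fraction},
#' \code{stderr}, \code{method}.
#'
#' @param results list of \code{\link{coexistence_region_size}} results.
#' @param path output file.
#' @export
write_region_sizes_csv <- function(results, path) {
  df <- data.frame(
    community_id = seq_along(results),
    fraction = vapply(results, `[[`, numeric(1), "fraction"),
    stderr = vapply(results, `[[`, numeric(1), "stderr"),
    method = vapply(results, `[[`, character(1), "method"))
  utils::write.csv(format_sig(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
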