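# Treatment protocols: antibiotic dose scans, sequential antibiotics
# (non-transitivity and its mechanism) and antibiotic combinations
# (non-additivity), plus ensemble statistics over random communities.

# Internal: geometry-backed survivors of `community` with death-rate vector
# `extra` added, restricted to the present pool.  Works on pre-extracted
# matrices for speed inside ensembles.
surv_with <- function(R, s, d, base_death, extra, present) {
  if (!length(present)) return(integer(0))
  sol <- solve_state(R, s, d + base_death + extra, present)
  if (!sol$found) stop("no feasible steady state found")
  sort(as.integer(sol$survivors))
}

#' Antibiotic dose scan
#'
#' Scales a death-rate direction by a concentration multiplier \code{c}
#' (\code{d_i -> c d_i}) and follows community richness, evaluated with
#' re-seeding-reservoir semantics (steady state from the full species pool at
#' every dose).  Change points of the piecewise-constant richness path are
#' located on a grid and refined by bisection to a resolution of \code{1e-4}
#' in \code{c}.  \code{n_changes} counts the richness transitions from
#' \code{c = 0} up to and including the dose at which the targeted species
#' (the positive entries of \code{target_profile}) goes extinct.
#'
#' @param community a \code{\link{cr_community}} (its own death rates, if
#'   any, act as a constant background).
#' @param target_profile non-negative death-rate direction; defaults to the
#'   community's death rates.
#' @param c_max largest multiplier scanned.
#' @param n_grid initial grid resolution.
#' @return a \code{cr_dose_scan}: \code{concentration_grid},
#'   \code{richness_path} (values on the segments between change points),
#'   \code{change_points}, \code{n_changes}, \code{extinction_dose}
#'   (\code{Inf} with \code{capped = TRUE} if the target survives up to
#'   \code{c_max}) and the evaluated grid richness.
#' @export
dose_scan <- function(community, target_profile = NULL, c_max = 20,
                      n_grid = 401) {
  stopifnot(is_cr_community(community))
  comm <- normalize_community(static_if_needed(community))
  if (is.null(target_profile)) target_profile <- cidal_death_rates(comm)
  profile <- as.numeric(target_profile)
  stopifnot(length(profile) == comm$m, all(profile >= 0))
  if (all(profile == 0)) stop("target_profile must have a positive entry")
  targets <- which(profile > 0)
  pool <- seq_len(comm$m)
  rho_at <- function(cc)
    surv_with(comm$R, comm$s, comm$d, numeric(comm$m), cc * profile, pool)
  grid <- seq(0, c_max, length.out = n_grid)
  surv_grid <- lapply(grid, rho_at)
  rho_grid <- lengths(surv_grid)
  target_alive <- vapply(surv_grid, function(sv) any(targets %in% sv),
                         logical(1))

  bisect <- function(lo, hi, flo) {
    while (hi - lo > 1e-4) {
      mid <- (lo + hi) / 2
      if (length(rho_at(mid)) == flo) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  change_points <- numeric(0)
  rho_path <- rho_grid[1]
  for (i in seq_len(n_grid - 1)) {
    if (rho_grid[i + 1] != rho_grid[i]) {
      change_points <- c(change_points, bisect(grid[i], grid[i + 1],
                                               rho_grid[i]))
      rho_path <- c(rho_path, rho_grid[i + 1])
    }
  }
  capped <- target_alive[n_grid]
  extinction_dose <- Inf
  if (!capped) {
    i <- which(!target_alive)[1]
    extinction_dose <- if (i == 1) 0 else {
      lo <- grid[i - 1]; hi <- grid[i]
      while (hi - lo > 1e-4) {
        mid <- (lo + hi) / 2
        if (any(targets %in% rho_at(mid))) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    }
  }
  n_changes <- sum(change_points <= min(extinction_dose, c_max) + 1e-4)
  structure(list(concentration_grid = grid, base_death_rates = profile,
                 richness_grid = rho_grid, richness_path = rho_path,
                 change_points = change_points, n_changes = n_changes,
                 extinction_dose = extinction_dose, capped = capped),
            class = "cr_dose_scan")
}

#' @export
print.cr_dose_scan <- function(x, ...) {
  cat(sprintf("Dose scan: %d richness change(s) up to extinction dose %s\n",
              x$n_changes,
              if (is.finite(x$extinction_dose))
                signif(x$extinction_dose, 5) else "Inf (capped)"))
  cat("  richness path:", paste(x$richness_path, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
plot.cr_dose_scan <- function(x, ...) {
  graphics::plot(x$concentration_grid, x$richness_grid, type = "s",
                 xlab = "antibiotic concentration multiplier c",
                 ylab = "richness (with reservoir)", ...)
  graphics::abline(v = x$change_points, lty = 3, col = "grey")
  invisible(x)
}

# Shared protocol engine.  Returns every quantity the sequential and
# combination analyses need, computing each steady state at most once.
treatment_outcomes <- function(comm, dA, dB, need_mechanism = TRUE) {
  base <- cidal_death_rates(comm)
  R <- comm$R; s <- comm$s; d <- comm$d
  pool <- seq_len(comm$m)
  zero <- numeric(comm$m)
  tA <- which(dA > 0); tB <- which(dB > 0)
  S0 <- surv_with(R, s, d, base, zero, pool)
  SA <- surv_with(R, s, d, base, dA, S0)          # A applied to S0
  SB <- surv_with(R, s, d, base, dB, S0)
  S_AB <- surv_with(R, s, d, base, dB, SA)        # then B, no interlude
  S_BA <- surv_with(R, s, d, base, dA, SB)
  rho_AB <- length(S_AB); rho_BA <- length(S_BA)
  delta_rho <- abs(rho_AB - rho_BA)

  extinct_A <- setdiff(S0, SA)
  extinct_B <- setdiff(S0, SB)
  S_both <- surv_with(R, s, d, base, dA + dB, S0)
  extinct_AB <- setdiff(S0, S_both)
  rho_additive <- length(S0) - length(union(extinct_A, extinct_B))
  rho_combined <- length(S_both)
  additivity <- if (rho_combined < rho_additive) "synergistic"
                else if (rho_combined > rho_additive) "antagonistic"
                else "additive"

  mechanism <- NA_character_
  flags <- NULL
  if (need_mechanism) {
    if (delta_rho == 0) mechanism <- "transitive"
    else if (length(tA) != 1 || length(tB) != 1) mechanism <- "unclassified"
    else {
      e_full_A <- !(tA %in% SA)
      e_full_B <- !(tB %in% SB)
      e_alone_A <- !(tA %in% surv_with(R, s, d, base, dA, setdiff(S0, tB)))
      e_alone_B <- !(tB %in% surv_with(R, s, d, base, dB, setdiff(S0, tA)))
      type_of <- function(e_full, e_alone) {
        if (e_full && !e_alone) "promotion"
        else if (!e_full && e_alone) "neutralization"
        else "context-independent"
      }
      ty <- c(type_of(e_full_A, e_alone_A), type_of(e_full_B, e_alone_B))
      # competition promoting (or neutralizing) the action of at least one
      # antibiotic, and not doing the opposite to the other
      mechanism <- if (any(ty == "promotion") && !any(ty == "neutralization"))
        "promotion"
      else if (any(ty == "neutralization") && !any(ty == "promotion"))
        "neutralization"
      else "unclassified"
      flags <- list(A = c(extinct_in_full = e_full_A,
                          extinct_without_other_target = e_alone_A),
                    B = c(extinct_in_full = e_full_B,
                          extinct_without_other_target = e_alone_B))
    }
  }
  applied <- c(dA[dA > 0], dB[dB > 0])
  list(S0 = S0, order_AB_survivors = S_AB, order_BA_survivors = S_BA,
       rho_AB = rho_AB, rho_BA = rho_BA, delta_rho = delta_rho,
       mechanism = mechanism, context_flags = flags,
       extinct_A = extinct_A, extinct_B = extinct_B,
       extinct_AB = extinct_AB, rho_additive = rho_additive,
       rho_combined = rho_combined, classification = additivity,
       d_min = if (length(applied)) min(applied) else 0)
}

#' Sequential application of two antibiotics
#'
#' Protocol: (i) steady state with no antibiotic from the full pool gives the
#' pre-antibiotic survivors; (ii) antibiotic A is applied to those survivors
#' (no reservoir: extinct species stay extinct); (iii) A is swapped directly
#' for B with no antibiotic-free interlude.  The reverse order is run the
#' same way, and non-transitivity is the absolute richness difference
#' \code{delta_rho} between the two final states.  Nonzero \code{delta_rho}
#' is attributed to resource competition either promoting or neutralizing one
#' antibiotic's action (see \code{\link{classify_mechanism}}).
#'
#' @param community a \code{\link{cr_community}}.
#' @param antibiotic_A,antibiotic_B death-rate vectors (typically a single
#'   positive entry each).
#' @return a \code{cr_sequence} with the two final survivor sets,
#'   \code{delta_rho}, the \code{mechanism} (\code{transitive},
#'   \code{promotion}, \code{neutralization} or \code{unclassified}) and
#'   per-antibiotic context flags.
#' @export
sequential_treatment <- function(community, antibiotic_A, antibiotic_B) {
  stopifnot(is_cr_community(community))
  comm <- normalize_community(static_if_needed(community))
  out <- treatment_outcomes(comm, as.numeric(antibiotic_A),
                            as.numeric(antibiotic_B))
  structure(out[c("order_AB_survivors", "order_BA_survivors", "rho_AB",
                  "rho_BA", "delta_rho", "mechanism", "context_flags", "S0")],
            class = "cr_sequence")
}

#' @export
print.cr_sequence <- function(x, ...) {
  cat(sprintf("Sequential treatment: rho(A->B) = %d, rho(B->A) = %d, delta_rho = %d\n",
              x$rho_AB, x$rho_BA, x$delta_rho))
  cat("  mechanism:", x$mechanism, "\n")
  invisible(x)
}

#' Mechanism of non-transitivity
#'
#' For each antibiotic targeting species \code{x}, compares extinction of
#' \code{x} when the antibiotic acts on the full pre-antibiotic community
#' versus on the community with the other antibiotic's target removed.  An
#' antibiotic is \emph{promoted} by competition when its target dies only in
#' the full community, and \emph{neutralized} when its target dies only once
#' the other target is absent.  With nonzero \code{delta_rho} and exactly one
#' context-dependent antibiotic, that antibiotic's type is returned;
#' otherwise \code{"unclassified"} (or \code{"transitive"} when
#' \code{delta_rho = 0}).
#'
#' @inheritParams sequential_treatment
#' @return character mechanism label.
#' @export
classify_mechanism <- function(community, antibiotic_A, antibiotic_B) {
  sequential_treatment(community, antibiotic_A, antibiotic_B)$mechanism
}

#' Simultaneous application of two antibiotics
#'
#' From the pre-antibiotic steady state, computes the extinction sets under
#' antibiotic A alone, B alone, and both applied together.  The additive
#' expectation removes the union of the single-antibiotic extinction sets;
#' the combination is \emph{synergistic} if it leaves fewer survivors than
#' that baseline, \emph{antagonistic} if more, and \emph{additive} otherwise.
#'
#' @inheritParams sequential_treatment
#' @return a \code{cr_combination} with the three extinction sets,
#'   \code{rho_additive}, \code{rho_combined}, the \code{classification} and
#'   \code{d_min} (smallest applied nonzero death rate).
#' @export
combination_treatment <- function(community, antibiotic_A, antibiotic_B) {
  stopifnot(is_cr_community(community))
  comm <- normalize_community(static_if_needed(community))
  out <- treatment_outcomes(comm, as.numeric(antibiotic_A),
                            as.numeric(antibiotic_B), need_mechanism = FALSE)
  structure(out[c("extinct_A", "extinct_B", "extinct_AB", "rho_additive",
                  "rho_combined", "classification", "d_min", "S0")],
            class = "cr_combination")
}

#' @export
print.cr_combination <- function(x, ...) {
  cat(sprintf("Combination treatment: %s (combined richness %d vs additive %d)\n",
              x$classification, x$rho_combined, x$rho_additive))
  invisible(x)
}

#' Ensemble scan over random communities
#'
#' Draws \code{n} communities with an antibiotic pair from \code{sampler},
#' runs the sequential and combination protocols on each, and tabulates the
#' cross-occurrence of non-transitivity mechanism (transitive / promotion /
#' neutralization) against additivity class (additive / antagonistic /
#' synergistic).  A fixed fraction of members is spot-checked against the ODE
#' integrator.
#'
#' @param sampler function of no arguments returning
#'   \code{list(community, antibiotic_A, antibiotic_B)}; see
#'   \code{\link{sampler_random3}}.  Called under the seeded RNG stream.
#' @param n_communities ensemble size (number of communities analysed).
#' @param seed RNG seed (all randomness flows from it).
#' @param condition_full_coexistence if \code{TRUE} (default), draws are
#'   rejected until all species coexist before antibiotic perturbation, so
#'   the ensemble consists of initially fully coexisting communities.
#' @param ode_check_fraction fraction of members whose pre-antibiotic steady
#'   state is re-derived by ODE integration as a guard on the geometry
#'   solver.
#' @return a \code{cr_ensemble}: the 4x3 \code{counts} table (mechanism,
#'   including an unclassified row, by additivity class), \code{fractions}
#'   (of all analysed communities), a per-community \code{details} data
#'   frame, the number of rejected draws and \code{failures} excluded, and
#'   ODE spot-check mismatches.
#' @export
ensemble_scan <- function(sampler, n_communities, seed = 1,
                          condition_full_coexistence = TRUE,
                          ode_check_fraction = 0.01) {
  stopifnot(n_communities >= 0)
  set.seed(seed)
  mechs <- c("transitive", "promotion", "neutralization", "unclassified")
  adds <- c("additive", "antagonistic", "synergistic")
  counts <- matrix(0L, 4, 3, dimnames = list(mechanism = mechs,
                                             additivity = adds))
  det_drho <- integer(n_communities)
  det_mech <- character(n_communities)
  det_add <- character(n_communities)
  det_rho0 <- integer(n_communities)
  det_dmin <- numeric(n_communities)
  failures <- 0L
  rejected <- 0L
  ode_checked <- 0L
  ode_mismatch <- 0L
  max_draws <- max(100, n_communities * 1000)
  i <- 0L
  draws <- 0L
  while (i < n_communities && draws < max_draws) {
    draws <- draws + 1L
    smp <- sampler()
    comm <- normalize_community(static_if_needed(smp$community))
    out <- tryCatch(
      treatment_outcomes(comm, as.numeric(smp$antibiotic_A),
                         as.numeric(smp$antibiotic_B)),
      error = function(e) NULL)
    if (is.null(out)) { failures <- failures + 1L; next }
    if (condition_full_coexistence && length(out$S0) < comm$m) {
      rejected <- rejected + 1L
      next
    }
    i <- i + 1L
    mech <- out$mechanism
    counts[mech, out$classification] <- counts[mech, out$classification] + 1L
    # systematic spot-check (no RNG draw: keeps the sample stream identical
    # across ode_check_fraction settings)
    if (ode_check_fraction > 0 && i %% ceiling(1 / ode_check_fraction) == 0) {
      ode <- suppressWarnings(steady_state(smp$community, method = "ode"))
      if (ode$converged) {
        ode_checked <- ode_checked + 1L
        if (!identical(sort(ode$survivors), out$S0))
          ode_mismatch <- ode_mismatch + 1L
      }
    }
    det_drho[i] <- out$delta_rho
    det_mech[i] <- mech
    det_add[i] <- out$classification
    det_rho0[i] <- length(out$S0)
    det_dmin[i] <- out$d_min
  }
  details <- data.frame(id = seq_len(i), delta_rho = det_drho[seq_len(i)],
                        mechanism = det_mech[seq_len(i)],
                        additivity = det_add[seq_len(i)],
                        rho_pre = det_rho0[seq_len(i)],
                        d_min = det_dmin[seq_len(i)])
  total <- sum(counts)
  structure(list(counts = counts,
                 fractions = if (total > 0) counts / total else counts,
                 details = details, failures = failures,
                 rejected = rejected, n = i, seed = seed,
                 ode_checked = ode_checked,
                 ode_mismatch = ode_mismatch),
            class = "cr_ensemble")
}

#' @export
print.cr_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d communities (%d failures, %d draws rejected)\n",
              x$n, x$failures, x$rejected))
  print(x$counts)
  if (x$ode_checked)
    cat(sprintf("  ODE spot-checks: %d/%d mismatched\n",
                x$ode_mismatch, x$ode_checked))
  invisible(x)
}

#' Random three-species ensemble sampler
#'
#' The random two-antibiotic scheme: three consumption vectors uniform on the
#' unit simplex, equal supply, unit dilution, and two antibiotics with
#' independent U(0,1) death rates targeting species 1 and 2.
#'
#' @return a sampler closure for \code{\link{ensemble_scan}}.
#' @export
sampler_random3 <- function() {
  function() {
    R <- runif_simplex(3, 3)
    d12 <- stats::runif(2)
    list(community = cr_community(R, rep(1 / 3, 3), 1),
         antibiotic_A = c(d12[1], 0, 0),
         antibiotic_B = c(0, d12[2], 0))
  }
}

#' Scan the structured three-species family
#'
#' Samples (or grids) the five structured-family parameters — the simplex
#' distances \code{D_T1}, \code{D_T2}, \code{D_N} over \code{(0, sqrt(2/3))}
#' and the death rates \code{d_1}, \code{d_2} over \code{(0, 1)} — and runs
#' the sequential protocol on each member, recording \code{delta_rho} and the
#' mechanism.
#'
#' @param n number of parameter combinations (random mode), or per-distance
#'   grid resolution (grid mode: \code{n^3 * n_death^2} members).
#' @param seed RNG seed (random mode).
#' @param mode \code{"random"} or \code{"grid"}.
#' @param n_death grid resolution per death rate (grid mode).
#' @return list with per-member \code{details} and the promotion /
#'   neutralization shares among nonzero-\code{delta_rho} members.
#' @export
scan_structured_family <- function(n, seed = 1, mode = c("random", "grid"),
                                   n_death = 10) {
  mode <- match.arg(mode)
  dmax <- sqrt(2 / 3)
  if (mode == "random") {
    set.seed(seed)
    pars <- data.frame(D_T1 = stats::runif(n, 0, dmax),
                       D_T2 = stats::runif(n, 0, dmax),
                       D_N = stats::runif(n, 0, dmax),
                       d_1 = stats::runif(n), d_2 = stats::runif(n))
  } else {
    gD <- seq(0, dmax, length.out = n + 2)[-c(1, n + 2)]
    gd <- seq(0, 1, length.out = n_death + 2)[-c(1, n_death + 2)]
    pars <- expand.grid(D_T1 = gD, D_T2 = gD, D_N = gD, d_1 = gd, d_2 = gd)
  }
  res <- structured_family_outcomes(pars)
  nz <- res$delta_rho > 0
  shares <- c(promotion = mean(res$mechanism[nz] == "promotion"),
              neutralization = mean(res$mechanism[nz] == "neutralization"))
  list(details = cbind(pars, res), shares = shares,
       n_nonzero = sum(nz), n = nrow(pars))
}

# Vectorized-ish evaluation of the sequential protocol over structured-family
# parameter rows.
structured_family_outcomes <- function(pars) {
  n <- nrow(pars)
  delta_rho <- integer(n)
  mech <- character(n)
  for (i in seq_len(n)) {
    spec <- structured_family_spec(pars$D_T1[i], pars$D_T2[i], pars$D_N[i],
                                   pars$d_1[i], pars$d_2[i])
    comm <- build_structured_community(spec)
    ab <- structured_antibiotics(spec)
    out <- treatment_outcomes(comm, ab$A, ab$B)
    delta_rho[i] <- out$delta_rho
    mech[i] <- out$mechanism
  }
  data.frame(delta_rho = delta_rho, mechanism = mech)
}

#' Aggregate symmetric non-targeted species
#'
#' Non-targeted species whose consumption vectors are related by a
#' permutation of their private resources (and that share a death rate) act
#' collectively as a single effective species: the group is merged into one
#' species, its private resources into one resource with the summed supply,
#' and every other species' consumption of the private resources is summed.
#' Treatment classifications of the reduced community match the original
#' (exactly under exact symmetry).
#'
#' @param community a \code{\link{cr_community}}.
#' @param group indices of the symmetric non-targeted species.
#' @param private_resources resources permuted among the group; inferred as
#'   the columns on which the group rows differ when missing.
#' @param tol symmetry tolerance; violations beyond it are an error, smaller
#'   deviations are symmetrized away.
#' @return the reduced \code{cr_community}, with attributes
#'   \code{species_map} and \code{resource_map} giving, for every original
#'   index, its index in the reduced community.
#' @export
aggregate_symmetric_species <- function(community, group,
                                        private_resources = NULL,
                                        tol = 1e-6) {
  stopifnot(is_cr_community(community))
  comm <- static_if_needed(community)
  group <- sort(unique(as.integer(group)))
  if (length(group) <= 1) return(comm)
  R <- comm$R
  if (is.null(private_resources)) {
    spread <- apply(R[group, , drop = FALSE], 2, function(x) diff(range(x)))
    private_resources <- which(spread > tol)
  }
  priv <- sort(unique(as.integer(private_resources)))
  shared <- setdiff(seq_len(comm$p), priv)
  others <- setdiff(seq_len(comm$m), group)
  # symmetry checks
  dr <- cidal_death_rates(comm)
  if (diff(range(dr[group])) > tol)
    stop("group death rates differ beyond tolerance")
  if (length(shared) &&
      max(apply(R[group, shared, drop = FALSE], 2,
                function(x) diff(range(x)))) > tol)
    stop("group rows differ on shared resources beyond tolerance")
  sorted <- apply(R[group, priv, drop = FALSE], 1, sort)
  if (length(priv) && max(apply(sorted, 1, function(x) diff(range(x)))) > tol)
    stop("group rows are not permutations of each other on private resources")
  if (length(priv) && diff(range(comm$s[priv])) > tol)
    stop("private-resource supply rates differ beyond tolerance")
  for (j in others)
    if (length(priv) && diff(range(R[j, priv])) > tol)
      stop("non-group species consume private resources asymmetrically")

  # build reduced community (symmetrizing within tolerance)
  new_species <- c(others, group[1])
  Rn <- matrix(0, length(others) + 1, length(shared) + 1)
  sn <- c(comm$s[shared], sum(comm$s[priv]))
  for (oi in seq_along(others)) {
    j <- others[oi]
    Rn[oi, ] <- c(R[j, shared], sum(R[j, priv]))
  }
  Rn[length(others) + 1, ] <- c(colMeans(R[group, shared, drop = FALSE]),
                                sum(R[group[1], priv]))
  drn <- c(dr[others], mean(dr[group]))
  out <- cr_community(Rn, sn, comm$d,
                      death_rates = if (any(drn > 0)) drn)
  smap <- integer(comm$m)
  smap[others] <- seq_along(others)
  smap[group] <- length(others) + 1L
  rmap <- integer(comm$p)
  rmap[shared] <- seq_along(shared)
  rmap[priv] <- length(shared) + 1L
  attr(out, "species_map") <- smap
  attr(out, "resource_map") <- rmap
  out
}
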