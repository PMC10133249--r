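# Samplers generating the synthetic community ensembles that stand in for
# study data: consumption vectors uniform on the unit simplex (so every
# species has enzyme budget 1), equal supply rates, unit dilution, and the
# structured three-species family parametrized by simplex distances.

#' Uniform samples from the unit simplex
#'
#' Draws via normalized i.i.d. exponentials, which is exactly uniform on the
#' simplex (naively normalizing uniforms is not).
#'
#' @param n number of samples.
#' @param k simplex dimension (vector length).
#' @return an \code{n x k} matrix with non-negative rows summing to 1.
#' @export
runif_simplex <- function(n, k) {
  x <- matrix(stats::rexp(n * k), n, k)
  x / rowSums(x)
}

#' Sample a random community
#'
#' Consumption vectors are uniform on the unit simplex (enzyme budgets equal
#' to 1), all resources are supplied at equal rates with total supply 1, and
#' the dilution rate is 1.  Death-rate schemes: \code{"none"} (no antibiotic),
#' \code{"simplex"} (a death-rate vector uniform on the unit simplex across
#' all species) or \code{"targets"} (independent U(0,1) death rates on the
#' species in \code{targets}, the two-antibiotic random ensemble scheme).
#'
#' @param m,p species and resource counts.
#' @param seed optional integer seed (deterministic per seed).
#' @param death_scheme one of \code{"none"}, \code{"simplex"},
#'   \code{"targets"}.
#' @param targets species receiving U(0,1) death rates under
#'   \code{"targets"}.
#' @return a \code{\link{cr_community}}.
#' @export
sample_random_community <- function(m, p, seed = NULL,
                                    death_scheme = c("none", "simplex",
                                                     "targets"),
                                    targets = c(1, 2)) {
  death_scheme <- match.arg(death_scheme)
  if (!is.null(seed)) set.seed(seed)
  R <- runif_simplex(m, p)
  dr <- switch(death_scheme,
               none = NULL,
               simplex = as.vector(runif_simplex(1, m)),
               targets = {
                 v <- numeric(m)
                 v[targets] <- stats::runif(length(targets))
                 v
               })
  cr_community(R, s = rep(1 / p, p), d = 1, death_rates = dr)
}

#' Structured three-species family
#'
#' Parametrizes a three-species, three-resource community by the Euclidean
#' distances of each species' consumption vector from the supplied-resource
#' point (the simplex centroid under equal supply): the two targeted species
#' at distances \code{D_T1}, \code{D_T2} and the non-targeted species at
#' \code{D_N}, each placed on the segment from the centroid toward its own
#' vertex (species \code{i} toward vertex \code{i}; the non-targeted species
#' is species 3).  The admissible range \code{(0, sqrt(2/3))} is the
#' centroid-to-vertex distance of the unit simplex.  \code{d_1}, \code{d_2}
#' are the death rates applied to the targeted species during treatment.
#'
#' @param D_T1,D_T2,D_N distances in \code{(0, sqrt(2/3))} (the endpoints are
#'   admitted as limits).
#' @param d_1,d_2 death rates of the targeted species in \code{(0, 1)}.
#' @return a \code{cr_structured_spec} list, including the derived distance
#'   \code{D_T} between the two targeted species' consumption vectors.
#' @export
structured_family_spec <- function(D_T1, D_T2, D_N, d_1 = 0, d_2 = 0) {
  dmax <- sqrt(2 / 3)
  for (D in c(D_T1, D_T2, D_N))
    if (D < 0 || D > dmax + 1e-12)
      stop("distances must lie in [0, sqrt(2/3)]")
  # u_i . u_j = -1/2 for the three centroid-to-vertex unit vectors
  D_T <- sqrt(D_T1^2 + D_T2^2 + D_T1 * D_T2)
  structure(list(D_T1 = D_T1, D_T2 = D_T2, D_N = D_N, D_T = D_T,
                 d_1 = d_1, d_2 = d_2),
            class = "cr_structured_spec")
}

#' @rdname structured_family_spec
#' @param spec a \code{cr_structured_spec}.
#' @return \code{build_structured_community} returns the corresponding
#'   \code{\link{cr_community}} (equal supply, unit dilution, no active death
#'   rates: treatments supply the death rates).
#' @export
build_structured_community <- function(spec) {
  stopifnot(inherits(spec, "cr_structured_spec"))
  centroid <- rep(1 / 3, 3)
  R <- t(vapply(1:3, function(i) {
    u <- -centroid; u[i] <- u[i] + 1
    u <- u / sqrt(sum(u^2))
    D <- c(spec$D_T1, spec$D_T2, spec$D_N)[i]
    centroid + D * u
  }, numeric(3)))
  R[R < 0 & R > -1e-12] <- 0
  cr_community(R, s = rep(1 / 3, 3), d = 1)
}

#' @rdname structured_family_spec
#' @return \code{structured_antibiotics} returns the pair of death-rate
#'   vectors (one per antibiotic) encoded in the parameter object.
#' @export
structured_antibiotics <- function(spec) {
  stopifnot(inherits(spec, "cr_structured_spec"))
  list(A = c(spec$d_1, 0, 0), B = c(0, spec$d_2, 0))
}

#' Sample leakage fractions
#'
#' Leakage fractions i.i.d. uniform on (0, 0.5), one per resource.
#'
#' @param p number of resources.
#' @param seed optional integer seed.
#' @export
sample_leakage_fractions <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stats::runif(p, 0, 0.5)
}
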