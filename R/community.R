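#' Construct a chemostat consumer-resource community
#'
#' A community is defined by its consumption-rate matrix, the resource supply
#' rates, the chemostat dilution rate, and the action of an antibiotic (or any
#' other species-specific growth-inhibiting perturbation), represented either
#' as bactericidal death rates \code{d_i} or as bacteriostatic susceptibilities
#' \code{b_i} that shrink consumption rates by the factor \code{1/b_i}.  The
#' two representations are equivalent at steady state when
#' \code{b_i = (d + d_i)/d}; see \code{\link{cidal_to_static}}.
#'
#' The per-capita dynamics are
#' \deqn{dn_i/dt = n_i \left( \sum_\mu R_{i\mu} s_\mu / \sum_k n_k R_{k\mu}
#'   - (d + d_i) \right),}
#' i.e. resource availabilities equilibrate instantaneously to
#' \eqn{c_\mu = s_\mu / \sum_k n_k R_{k\mu}}.
#'
#' @param R numeric matrix (species x resources) of consumption rates; every
#'   row must contain at least one positive entry.
#' @param s supply rates (length \code{ncol(R)}); defaults to equal supply
#'   with total supply 1.
#' @param d chemostat dilution rate (positive scalar).
#' @param death_rates optional non-negative species-specific death rates.
#' @param susceptibilities optional susceptibilities \code{b_i >= 1}; mutually
#'   exclusive with \code{death_rates}.
#' @return an object of class \code{cr_community} with fields \code{m},
#'   \code{p}, \code{R}, \code{s}, \code{S}, \code{d} and whichever antibiotic
#'   representation was supplied.
#' @examples
#' comm <- cr_community(diag(2))           # two specialists
#' enzyme_budget(comm)
#' @export
cr_community <- function(R, s = NULL, d = 1, death_rates = NULL,
                         susceptibilities = NULL) {
  R <- as.matrix(R)
  storage.mode(R) <- "double"
  m <- nrow(R); p <- ncol(R)
  if (m < 1L || p < 1L) stop("R must have at least one row and one column")
  if (any(!is.finite(R)) || any(R < 0)) stop("R must be finite and non-negative")
  if (any(rowSums(R) <= 0))
    stop("every species must consume at least one resource")
  if (is.null(s)) s <- rep(1 / p, p)
  s <- as.numeric(s)
  if (length(s) != p) stop("s must have length ncol(R)")
  if (any(!is.finite(s)) || any(s < 0) || sum(s) <= 0)
    stop("s must be non-negative with positive total supply")
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0)
    stop("d must be a positive scalar")
  if (!is.null(death_rates) && !is.null(susceptibilities))
    stop("supply death_rates or susceptibilities, not both")
  if (!is.null(death_rates)) {
    death_rates <- as.numeric(death_rates)
    if (length(death_rates) != m) stop("death_rates must have length nrow(R)")
    if (any(!is.finite(death_rates)) || any(death_rates < 0))
      stop("death_rates must be finite and non-negative")
  }
  if (!is.null(susceptibilities)) {
    susceptibilities <- as.numeric(susceptibilities)
    if (length(susceptibilities) != m)
      stop("susceptibilities must have length nrow(R)")
    if (any(!is.finite(susceptibilities)) || any(susceptibilities < 1))
      stop("susceptibilities must be >= 1")
  }
  structure(list(m = m, p = p, R = R, s = s, S = sum(s), d = d,
                 death_rates = death_rates,
                 susceptibilities = susceptibilities),
            class = "cr_community")
}

is_cr_community <- function(x) inherits(x, "cr_community")

#' @export
print.cr_community <- function(x, ...) {
  rep_str <- if (!is.null(x$susceptibilities)) "bacteriostatic (b_i)"
             else if (!is.null(x$death_rates) && any(x$death_rates > 0))
               "bactericidal (d_i)" else "none"
  cat(sprintf("Consumer-resource community: %d species, %d resources\n",
              x$m, x$p))
  cat(sprintf("  dilution rate d = %g, total supply S = %g\n", x$d, x$S))
  cat(sprintf("  antibiotic representation: %s\n", rep_str))
  invisible(x)
}

#' @export
summary.cr_community <- function(object, ...) {
  print(object)
  cat("  enzyme budgets:",
      paste(signif(enzyme_budget(object), 4), collapse = ", "), "\n")
  cat("  supply rates:", paste(signif(object$s, 4), collapse = ", "), "\n")
  if (!is.null(object$death_rates))
    cat("  death rates:",
        paste(signif(object$death_rates, 4), collapse = ", "), "\n")
  invisible(object)
}

# Internal canonical (bactericidal) view: death rates, zero-filled.
cidal_death_rates <- function(community) {
  if (!is.null(community$susceptibilities))
    community$d * (community$susceptibilities - 1)
  else if (!is.null(community$death_rates)) community$death_rates
  else rep(0, community$m)
}

# Internal: total per-capita loss rates d + d_i in the bactericidal view.
loss_rates <- function(community) community$d + cidal_death_rates(community)

#' Enzyme budgets
#'
#' The enzyme budget of species \code{i} is the row sum of its effective
#' consumption rates, \eqn{E_i = \sum_\mu R_{i\mu}}.  Under bacteriostatic
#' antibiotic action the rates are reduced by the susceptibility factor, so
#' the budget shrinks to \eqn{E_i / b_i}.
#'
#' @param community a \code{\link{cr_community}}.
#' @return numeric vector of length \code{m}.
#' @export
enzyme_budget <- function(community) {
  stopifnot(is_cr_community(community))
  E <- rowSums(community$R)
  if (!is.null(community$susceptibilities)) E / community$susceptibilities
  else E
}

#' Convert between bactericidal and bacteriostatic antibiotic action
#'
#' A death rate \code{d_i} and a susceptibility \code{b_i = (d + d_i)/d} give
#' identical survivor sets, and steady-state abundances that agree after the
#' rescaling \code{n_static = b * n_cidal}.  \code{cidal_to_static} converts a
#' death-rate community to the equivalent susceptibility form;
#' \code{static_to_cidal} is its inverse.
#'
#' @param community a \code{\link{cr_community}}.
#' @return a \code{cr_community} with the other antibiotic representation.
#' @export
cidal_to_static <- function(community) {
  stopifnot(is_cr_community(community))
  if (!is.null(community$susceptibilities))
    stop("community already uses the bacteriostatic representation")
  di <- cidal_death_rates(community)
  cr_community(community$R, community$s, community$d,
               susceptibilities = (community$d + di) / community$d)
}

#' @rdname cidal_to_static
#' @export
static_to_cidal <- function(community) {
  stopifnot(is_cr_community(community))
  if (is.null(community$susceptibilities))
    stop("community does not use the bacteriostatic representation")
  b <- community$susceptibilities
  cr_community(community$R, community$s, community$d,
               death_rates = community$d * (b - 1))
}

#' Nondimensionalize a community
#'
#' Rescales to dimensionless units in which the dilution rate and total
#' supply are both 1: time \code{t' = t d}, abundance \code{n' = n d/S},
#' consumption rates \code{R' = R S/d^2}, supply \code{s' = s/S} and death
#' rates \code{d_i' = d_i/d}.  \code{denormalize_community} restores the
#' original units; the round trip is the identity to machine precision.
#'
#' @param community a \code{\link{cr_community}}.
#' @param d,S the original dilution rate and total supply to restore.
#' @return a \code{cr_community}.
#' @export
normalize_community <- function(community) {
  stopifnot(is_cr_community(community))
  d <- community$d; S <- community$S
  dr <- if (!is.null(community$death_rates)) community$death_rates / d
  cr_community(community$R * (S / d^2), community$s / S, d = 1,
               death_rates = dr,
               susceptibilities = community$susceptibilities)
}

#' @rdname normalize_community
#' @export
denormalize_community <- function(community, d, S) {
  stopifnot(is_cr_community(community))
  dr <- if (!is.null(community$death_rates)) community$death_rates * d
  cr_community(community$R * (d^2 / S), community$s * S, d = d,
               death_rates = dr,
               susceptibilities = community$susceptibilities)
}

#' Evenness as the effective number of species
#'
#' The exponential of the Shannon diversity index of relative abundances,
#' with the convention \code{0 log 0 = 0}.  Ranges from 1 (one species
#' dominates completely) to the number of species (all equally abundant).
#'
#' @param abundances non-negative abundances with positive sum.
#' @return effective species number.
#' @examples
#' evenness(c(1, 1, 1))          # 3
#' evenness(c(0.5, 0.25, 0.25))  # 2 * sqrt(2)
#' @export
evenness <- function(abundances) {
  abundances <- as.numeric(abundances)
  if (any(abundances < 0)) stop("abundances must be non-negative")
  tot <- sum(abundances)
  if (tot <= 0) stop("abundances must not all be zero")
  q <- abundances / tot
  q <- q[q > 0]
  exp(-sum(q * log(q)))
}

#' Read and write community files
#'
#' JSON layout: an object with fields \code{m}, \code{p}, \code{R} (row-major
#' vector of consumption rates), \code{s}, \code{d} and \code{death_rates}.
#' CSV layout: comment header lines \code{"# s: ..."} and \code{"# d: ..."}
#' followed by a table with columns \code{id}, \code{R_1 .. R_p},
#' \code{death_rate}.
#'
#' @param community a \code{\link{cr_community}} (death-rate representation).
#' @param path file path.
#' @return \code{read_*} return a \code{cr_community}; \code{write_*} return
#'   \code{path} invisibly.
#' @export
write_community_json <- function(community, path) {
  stopifnot(is_cr_community(community))
  obj <- list(m = community$m, p = community$p,
              R = as.vector(t(community$R)), s = community$s,
              d = community$d, death_rates = cidal_death_rates(community))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_community_json
#' @export
read_community_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("m", "p", "R", "s", "d"))
    if (is.null(obj[[f]])) stop("community JSON is missing field: ", f)
  R <- matrix(as.numeric(obj$R), nrow = obj$m, ncol = obj$p, byrow = TRUE)
  cr_community(R, obj$s, obj$d, death_rates = obj$death_rates)
}

#' @rdname write_community_json
#' @export
write_community_csv <- function(community, path) {
  stopifnot(is_cr_community(community))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# s:", paste(format(community$s, digits = 17),
                                   collapse = " ")),
               paste("# d:", format(community$d, digits = 17))), con)
  df <- data.frame(id = seq_len(community$m), community$R,
                   death_rate = cidal_death_rates(community))
  names(df) <- c("id", paste0("R_", seq_len(community$p)), "death_rate")
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_community_json
#' @export
read_community_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  sline <- sub("^# s: *", "", grep("^# s:", hdr, value = TRUE))
  dline <- sub("^# d: *", "", grep("^# d:", hdr, value = TRUE))
  if (length(sline) != 1L || length(dline) != 1L)
    stop("community CSV must carry '# s:' and '# d:' header lines")
  s <- as.numeric(strsplit(trimws(sline), " +")[[1]])
  d <- as.numeric(dline)
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  Rcols <- grep("^R_", names(df))
  cr_community(as.matrix(df[Rcols]), s, d, death_rates = df$death_rate)
}
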