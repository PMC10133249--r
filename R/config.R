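#' Run a configured analysis pipeline
#'
#' Executes one of the package's pipelines from a YAML or JSON configuration
#' file and writes its artifacts (tidy CSV outputs, a JSON summary and a run
#' manifest echoing the configuration) into an output directory.  All
#' randomness flows from the single \code{seed} field, so identical
#' configurations produce byte-identical CSV outputs.
#'
#' Config fields: \code{experiment} (one of \code{generate},
#' \code{simulate}, \code{dose_scan}, \code{sequence}, \code{combine},
#' \code{ensemble}, \code{crossfeed}), \code{seed}, \code{out_dir}, plus
#' experiment-specific parameters: \code{n}, \code{m}, \code{p},
#' \code{death_scheme} (generate); \code{community} (path to a community
#' JSON/CSV; simulate, dose_scan, sequence, combine, crossfeed);
#' \code{t_max} (simulate); \code{target_profile}, \code{c_max}
#' (dose_scan); \code{antibiotic_A}, \code{antibiotic_B} (sequence,
#' combine); \code{n} (ensemble); \code{leakage_seed} (crossfeed).
#'
#' @param config_path path to the YAML/JSON configuration.
#' @param out_dir output directory; overrides the config's \code{out_dir}.
#' @return invisibly, the list of files written.
#' @export
run_config <- function(config_path, out_dir = NULL) {
  cfg <- if (grepl("\\.ya?ml$", config_path)) yaml::read_yaml(config_path)
         else jsonlite::read_json(config_path, simplifyVector = TRUE)
  need <- function(field) {
    if (is.null(cfg[[field]]))
      stop("config validation error: missing required field '", field, "'")
    cfg[[field]]
  }
  experiment <- need("experiment")
  seed <- as.integer(need("seed"))
  if (is.null(out_dir)) out_dir <- need("out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  set.seed(seed)

  load_comm <- function() {
    path <- need("community")
    if (grepl("\\.json$", path)) read_community_json(path)
    else read_community_csv(path)
  }
  files <- character(0)
  emit_csv <- function(df, name) {
    f <- file.path(out_dir, name)
    utils::write.csv(format_sig(df), f, row.names = FALSE, quote = FALSE)
    files <<- c(files, f)
  }
  emit_json <- function(obj, name) {
    f <- file.path(out_dir, name)
    jsonlite::write_json(obj, f, digits = NA, auto_unbox = TRUE, pretty = TRUE)
    files <<- c(files, f)
  }

  summary_obj <- switch(
    experiment,
    generate = {
      n <- need("n")
      for (i in seq_len(n)) {
        comm <- sample_random_community(need("m"), need("p"),
                                        death_scheme = cfg$death_scheme %||% "none")
        f <- file.path(out_dir, sprintf("community_%04d.json", i))
        write_community_json(comm, f)
        files <- c(files, f)
      }
      list(n_generated = n)
    },
    simulate = {
      comm <- load_comm()
      traj <- cr_integrate(comm, t_max = cfg$t_max %||% 100)
      f <- file.path(out_dir, "trajectory.csv")
      write_trajectory_csv(traj, f); files <- c(files, f)
      ss <- steady_state(comm)
      list(richness = ss$richness, survivors = ss$survivors,
           evenness = ss$evenness, converged = ss$converged)
    },
    dose_scan = {
      comm <- load_comm()
      scan <- dose_scan(comm, as.numeric(need("target_profile")),
                        c_max = cfg$c_max %||% 20)
      emit_csv(data.frame(concentration = scan$concentration_grid,
                          richness = scan$richness_grid), "dose_scan.csv")
      list(n_changes = scan$n_changes,
           extinction_dose = scan$extinction_dose,
           change_points = scan$change_points, capped = scan$capped)
    },
    sequence = {
      comm <- load_comm()
      sq <- sequential_treatment(comm, as.numeric(need("antibiotic_A")),
                                 as.numeric(need("antibiotic_B")))
      list(rho_AB = sq$rho_AB, rho_BA = sq$rho_BA,
           delta_rho = sq$delta_rho, mechanism = sq$mechanism)
    },
    combine = {
      comm <- load_comm()
      cb <- combination_treatment(comm, as.numeric(need("antibiotic_A")),
                                  as.numeric(need("antibiotic_B")))
      list(classification = cb$classification,
           rho_combined = cb$rho_combined, rho_additive = cb$rho_additive,
           d_min = cb$d_min)
    },
    ensemble = {
      ens <- ensemble_scan(sampler_random3(), need("n"), seed = seed,
                           ode_check_fraction = cfg$ode_check_fraction %||% 0)
      emit_csv(ens$details, "ensemble_details.csv")
      cn <- as.vector(ens$counts); fr <- as.vector(ens$fractions)
      nm <- outer(rownames(ens$counts), colnames(ens$counts), paste, sep = "_")
      stderrs <- sqrt(fr * (1 - fr) / max(1, sum(ens$counts)))
      names(cn) <- names(fr) <- names(stderrs) <- as.vector(nm)
      list(counts = as.list(cn), fractions = as.list(fr),
           stderr = as.list(stderrs), failures = ens$failures)
    },
    crossfeed = {
      comm <- load_comm()
      l <- sample_leakage_fractions(comm$p)
      lm <- leakage_model(l)
      red <- reduce_to_effective_supply(comm, lm)
      ss_full <- steady_state_with_leakage(comm, lm)
      ss_red <- coexisting_set(red)
      list(leakage_fractions = l,
           survivors_leakage = ss_full$survivors,
           survivors_reduced = ss_red$survivors,
           effective_supply = red$s)
    },
    stop("config validation error: unknown experiment '", experiment, "'"))

  emit_json(summary_obj, "summary.json")
  manifest <- list(config = cfg, seed = seed,
                   package_version = as.character(utils::packageVersion("crperturb")),
                   wall_time_s = proc.time()[["elapsed"]] - t0)
  emit_json(manifest, "manifest.json")
  invisible(files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
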