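# Configuration files are plain YAML with three optional sections (`params`,
# `dispersal`, `run`) plus an `experiment` name; omitted fields fall back to
# the reference defaults (R_in = 5, delta = 0.98, D_min = 0.05, D_max = 0.30,
# P_mut = 1e-6, propagule mean 0.25). Unknown keys are rejected so typos
# cannot silently change a run.

config_defaults <- function() {
  list(
    experiment = NA_character_,
    params = list(R_in = 5, delta = 0.98, D_min = 0.05, D_max = 0.30,
                  alpha = 1, P_mut = 1e-6, T_unit = 1),
    dispersal = list(mode = "none", delta_g = 100L,
                     propagule_shape = c(5, 15), viscosity = 1L,
                     max_events = 10L, sm_candidates = 10L),
    run = list(seed = 1L, n_reps = 1e5, n_trials = 100L, n_gens = 2e4,
               p = 0.25, scale_factor = 1, outdir = "results")
  )
}

merge_section <- function(defaults, supplied, section) {
  if (is.null(supplied)) return(defaults)
  unknown <- setdiff(names(supplied), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown key(s) in '%s': %s", section,
                 paste(unknown, collapse = ", ")))
  }
  utils::modifyList(defaults, supplied)
}

#' Read and validate a run configuration
#'
#' @param path Path to a YAML configuration file.
#' @return An object of class `run_config`: a list with `experiment`,
#'   `params` (a validated [model_params()]), `dispersal` (a validated
#'   [dispersal_config()]), and `run` (seed, replicate/trial counts,
#'   generations, propagule fraction `p`, `scale_factor`, `outdir`).
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  def <- config_defaults()
  unknown <- setdiff(names(raw), names(def))
  if (length(unknown)) {
    stop("unknown top-level key(s): ", paste(unknown, collapse = ", "))
  }
  experiment <- if (!is.null(raw$experiment)) raw$experiment else
    def$experiment
  pl <- merge_section(def$params, raw$params, "params")
  dl <- merge_section(def$dispersal, raw$dispersal, "dispersal")
  rl <- merge_section(def$run, raw$run, "run")
  params <- do.call(model_params, pl)
  dispersal <- do.call(dispersal_config, dl)
  if (rl$scale_factor <= 0) stop("run$scale_factor must be positive")
  if (rl$n_reps < 1 || rl$n_trials < 1 || rl$n_gens < 1) {
    stop("run$n_reps, run$n_trials and run$n_gens must be at least 1")
  }
  structure(list(experiment = experiment, params = params,
                 dispersal = dispersal, run = rl),
            class = "run_config")
}

#' Write a run configuration back to YAML
#'
#' Round-trips losslessly through [parse_config()].
#'
#' @param cfg A `run_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  out <- list(
    experiment = cfg$experiment,
    params = unclass(cfg$params),
    dispersal = unclass(cfg$dispersal),
    run = cfg$run
  )
  if (is.na(out$experiment)) out$experiment <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a tidy results table with a metadata record
#'
#' Writes `<name>.csv` (one row per replicate, grid point, or trial) and
#' `<name>_meta.json` (parameters, seed, package version, timestamp) so that
#' any table can be regenerated byte-identically from its metadata.
#'
#' @param table A data frame (may have zero rows: a header-only file is
#'   written).
#' @param metadata A named list; serialized as JSON.
#' @param outdir Output directory (created if needed).
#' @param name File stem.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_results <- function(table, metadata, outdir, name) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(outdir)) stop("cannot create outdir: ", outdir)
  }
  csv <- file.path(outdir, paste0(name, ".csv"))
  meta <- file.path(outdir, paste0(name, "_meta.json"))
  utils::write.csv(table, csv, row.names = FALSE)
  metadata$package_version <- as.character(utils::packageVersion("ecoscaffold"))
  metadata$written_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(metadata, meta, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(table = csv, metadata = meta))
}
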