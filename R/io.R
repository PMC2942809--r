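# Configuration, serialization, and the command-line shell.
#
# Config format: YAML.  Results are written as CSV (tables, trajectories)
# and JSON (reports, summaries) with fixed formatting so outputs diff
# cleanly between runs.

.config_keys <- c("parameters", "autoreceptors", "drivers", "solver",
                  "experiment", "output_dir", "units")

#' Load a run configuration
#'
#' Reads a YAML configuration, validates every key, and resolves it against
#' the calibrated defaults.  An empty file yields the full calibrated
#' baseline configuration.  Unknown top-level keys and unknown parameter
#' names are rejected with the nearest known name suggested.
#'
#' Recognised sections: `parameters` (named overrides of
#' [kinetic_parameters()] entries), `autoreceptors` (`synthesis`,
#' `release`), `solver` (`rtol`, `atol`), `experiment` (`name` plus
#' options), `drivers` (`fire`, `fluox`, `btrp` constants), `output_dir`,
#' `units`.
#'
#' @param path path to a YAML file.
#' @return an object of class `seroterm_config`: list with resolved
#'   `params` (a calibrated `seroterm_params`), `cfg`
#'   (`seroterm_autoconfig`), `solver`, `drivers`, `experiment`,
#'   `output_dir`, and an `echo` of defaults + overrides with provenance.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  bad <- setdiff(names(raw), .config_keys)
  if (length(bad))
    stop("unknown config key '", bad[1], "'",
         .nearest_hint(bad[1], .config_keys), call. = FALSE)
  overrides <- raw$parameters
  if (!is.null(overrides)) {
    badp <- setdiff(names(overrides), .seroterm_param_names)
    if (length(badp))
      stop("unknown parameter '", badp[1], "'",
           .nearest_hint(badp[1], .seroterm_param_names), call. = FALSE)
  }
  params <- do.call(kinetic_parameters, as.list(overrides))
  auto <- raw$autoreceptors
  cfg <- autoreceptor_config(
    synthesis = if (is.null(auto$synthesis)) TRUE else isTRUE(auto$synthesis),
    release = if (is.null(auto$release)) TRUE else isTRUE(auto$release))
  solver <- list(rtol = raw$solver$rtol %||% 1e-8,
                 atol = raw$solver$atol %||% 1e-10)
  drv <- list(fire = raw$drivers$fire %||% 1,
              fluox = raw$drivers$fluox %||% 1,
              btrp = raw$drivers$btrp %||% 96)
  echo <- list(parameters = stats::setNames(
    as.list(unlist(params[.seroterm_param_names])), .seroterm_param_names),
    provenance = as.list(attr(params, "provenance")),
    autoreceptors = unclass(cfg), solver = solver, drivers = drv,
    experiment = raw$experiment, output_dir = raw$output_dir)
  structure(list(params = params, cfg = cfg, solver = solver, drivers = drv,
                 experiment = raw$experiment,
                 output_dir = raw$output_dir %||% ".", echo = echo),
            class = "seroterm_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a configuration echo
#'
#' Serialises the effective configuration (defaults + overrides +
#' provenance) back to YAML; [load_config()] of the written file reproduces
#' an identical effective configuration.
#'
#' @param config a `seroterm_config`.
#' @param path destination YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  out <- list(parameters = config$echo$parameters,
              autoreceptors = config$echo$autoreceptors,
              solver = config$echo$solver,
              drivers = config$echo$drivers)
  if (!is.null(config$experiment)) out$experiment <- config$experiment
  if (!is.null(config$output_dir)) out$output_dir <- config$output_dir
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

.fmt_num <- function(x) formatC(x, digits = 12, format = "g")

.write_table <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write results to a directory
#'
#' Serialises trajectories and tables as CSV (time/units in the header
#' row), steady-state and experiment summaries as JSON with embedded unit
#' strings.  Field ordering and number formatting are fixed, so two runs
#' with the same configuration produce byte-identical files.
#'
#' @param x a `seroterm_trajectory`, `seroterm_steady` or
#'   `seroterm_experiment`.
#' @param dir destination directory (created if missing).
#' @return character vector of the files written, invisibly.
#' @export
write_outputs <- function(x, dir) UseMethod("write_outputs")

#' @export
write_outputs.seroterm_trajectory <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- as.data.frame(x)
  names(df) <- c("time_hr", paste0(.seroterm_state_names, "_uM"))
  f <- file.path(dir, "trajectory.csv")
  .write_table(df, f)
  invisible(f)
}

#' @export
write_outputs.seroterm_steady <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- file.path(dir, "steady_state.json")
  payload <- list(
    units = list(concentration = "uM", e5ht_nM = "nM", velocity = "uM/hr"),
    state = as.list(x$state),
    e5ht_nM = x$state[["e5ht"]] * 1000,
    velocities = x$velocities,
    identity_residuals = as.list(x$identity_residuals),
    residual_norm = x$residual_norm,
    converged = x$converged,
    targets_delta = as.list(x$targets_delta))
  jsonlite::write_json(payload, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(f)
}

#' @export
write_outputs.seroterm_experiment <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (nm in names(x$tables)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    .write_table(x$tables[[nm]], f)
    written <- c(written, f)
  }
  for (nm in names(x$trajectories)) {
    f <- file.path(dir, paste0("trajectory_", nm, ".csv"))
    .write_table(as.data.frame(x$trajectories[[nm]]), f)
    written <- c(written, f)
  }
  f <- file.path(dir, "summary.json")
  jsonlite::write_json(list(name = x$name, summary = x$summary), f,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  written <- c(written, f)
  f <- file.path(dir, "config.yaml")
  yaml::write_yaml(x$config, f, precision = 15)
  invisible(c(written, f))
}

.cli_help <- function() {
  cat("seroterm - serotonergic terminal kinetic model\n\n",
      "usage: seroterm <command> [options]\n\n",
      "commands:\n",
      "  calibrate                      print the calibrated constants and\n",
      "                                 baseline steady state\n",
      "  steady [--fire R] [--fluox F] [--btrp B] [--out DIR]\n",
      "                                 solve a steady state\n",
      "  simulate --config FILE [--out DIR]\n",
      "                                 integrate under a YAML configuration\n",
      "  experiment NAME [--out DIR]    run a scripted experiment; NAME is one\n",
      "                                 of table4, pulse, meals, homeostasis,\n",
      "                                 ssri, agonist\n", sep = "")
  invisible(0)
}

.cli_opt <- function(args, flag, default) {
  i <- which(args == flag)
  if (!length(i)) return(default)
  if (i[1] == length(args)) stop("missing value for ", flag, call. = FALSE)
  args[i[1] + 1]
}

#' Command-line entry point
#'
#' Thin shell over the package functions; see the `inst/cli/seroterm.R`
#' script.  Subcommands: `calibrate`, `steady`, `simulate`, `experiment`.
#' Prints help and returns 0 when called without arguments.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code (0 on success), invisibly.
#' @export
seroterm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    if (!length(args)) return(invisible(.cli_help()))
    cmd <- args[1]
    rest <- args[-1]
    out_dir <- .cli_opt(rest, "--out", ".")
    if (cmd == "calibrate") {
      p <- kinetic_parameters()
      print(p)
      ss <- find_steady_state(p, cross_check = TRUE)
      print(ss)
      write_outputs(ss, out_dir)
    } else if (cmd == "steady") {
      p <- kinetic_parameters()
      ss <- find_steady_state(
        p,
        fire = as.numeric(.cli_opt(rest, "--fire", "1")),
        fluox = as.numeric(.cli_opt(rest, "--fluox", "1")),
        btrp = as.numeric(.cli_opt(rest, "--btrp", "96")))
      print(ss)
      message("written: ", write_outputs(ss, out_dir))
    } else if (cmd == "simulate") {
      cfgf <- .cli_opt(rest, "--config", NA)
      if (is.na(cfgf)) stop("simulate requires --config FILE", call. = FALSE)
      rc <- load_config(cfgf)
      t_max <- as.numeric(.cli_opt(rest, "--t-max", "24"))
      drv <- drivers(fire = rc$drivers$fire, fluox = rc$drivers$fluox,
                     btrp = rc$drivers$btrp)
      traj <- integrate_terminal(rc$params, drv,
                                 times = seq(0, t_max, by = 0.01),
                                 cfg = rc$cfg, rtol = rc$solver$rtol,
                                 atol = rc$solver$atol)
      message("written: ", write_outputs(traj, out_dir))
      write_config(rc, file.path(out_dir, "config.yaml"))
    } else if (cmd == "experiment") {
      if (!length(rest) || startsWith(rest[1], "--"))
        stop("experiment requires a name", call. = FALSE)
      name <- rest[1]
      p <- kinetic_parameters()
      res <- switch(name,
        table4 = table4_sweep(p),
        pulse = pulse_release(p, blocked_fraction =
                                as.numeric(.cli_opt(rest, "--blocked", "0"))),
        meals = meals_experiment(p),
        homeostasis = homeostasis_sweep(
          p, vary = .cli_opt(rest, "--vary", "fire")),
        ssri = ssri_experiment(
          p, f_min = as.numeric(.cli_opt(rest, "--f-min", "0.58")),
          knockout_1b = "--knockout-1b" %in% rest),
        agonist = agonist_experiment(
          p, f_min = as.numeric(.cli_opt(rest, "--f-min", "0.20"))),
        stop("unknown experiment '", name, "'", call. = FALSE))
      print(res)
      message("written: ",
              paste(write_outputs(res, out_dir), collapse = ", "))
    } else {
      .cli_help()
      stop("unknown command '", cmd, "'", call. = FALSE)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}
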