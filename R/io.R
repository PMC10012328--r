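# Reproducibility scaffolding: configuration files, seed derivation,
# tabular writers and the run manifest.

#' Default configuration
#'
#' The fully resolved default configuration as a nested list, mirroring the
#' reference parameter set of [model_params()].  Configuration files only
#' need to state deviations from these values.
#'
#' @return nested list of configuration sections
#' @export
default_config <- function() {
  list(
    neuron = list(E_L = -70, V_th = -55, g_m = 0.03, C_m = 1,
                  refractory_ms = 2, delay_ms = 2, tau_s = 20,
                  A_ADP = 0.2, tau_ADP = 250),
    plasticity = list(A_plus = 0.65, A_minus = 0.65, tau_s = 20,
                      gamma_p = 1.5, gamma_d = 0.75,
                      eps_ltp = 1, eps_ltd = 1, variant = "full",
                      trace_window_ms = 200, theta_only_window_ms = 100,
                      heterosynaptic_enabled = FALSE),
    connectivity = list(nc_intra_p = 0.25, nc_intra_wmax = 0.3,
                        nc_to_hip_wmax = 0.35, hip_to_nc_wmax = 0.08,
                        hip_p = 0.5, hip_wmax = 0.65),
    background = list(nc_rate = 4000, nc_wmax = 0.023,
                      hip_rate = 1500, hip_wmax = 0.015),
    oscillators = list(nc_alpha_hz = 10, nc_alpha_amp = 0.1,
                       hip_theta_hz = 4, hip_theta_amp = 0.25),
    ec = list(w_ec = 0.3),
    synapse = list(gain = 0.08),
    sim = list(dt_ms = 1, seed = 1)
  )
}

#' Load and validate a configuration file
#'
#' Reads a YAML or JSON configuration, fills every unset key from
#' [default_config()], rejects unknown keys with a message naming the key,
#' and runs cross-field checks.  An empty file yields the full default
#' configuration.  A warning is raised if a single historic spike could
#' already cross a plasticity threshold (`A_plus >= eps_ltp` or
#' `A_minus >= eps_ltd`), since that defeats the singlet-nullifying role of
#' the thresholds.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file
#' @return the resolved configuration (nested list)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config(), user)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  # constructors carry the field-level checks
  params_from_config(cfg)
  if (cfg$plasticity$A_plus >= cfg$plasticity$eps_ltp ||
      cfg$plasticity$A_minus >= cfg$plasticity$eps_ltd)
    warning("a single historic spike can cross a plasticity threshold ",
            "(A_plus >= eps_ltp or A_minus >= eps_ltd): singlet spike ",
            "pairings will no longer be nullified")
  invisible(cfg)
}

#' Build model parameters from a resolved configuration
#'
#' @param cfg a configuration list as returned by [load_config()] or
#'   [default_config()]
#' @return a [model_params()] object
#' @export
params_from_config <- function(cfg) {
  model_params(
    neuron = do.call(neuron_params, cfg$neuron),
    plasticity = do.call(plasticity_params, cfg$plasticity),
    connectivity = do.call(connectivity_spec, cfg$connectivity),
    nc_rate = cfg$background$nc_rate, nc_wmax = cfg$background$nc_wmax,
    hip_rate = cfg$background$hip_rate, hip_wmax = cfg$background$hip_wmax,
    nc_alpha_hz = cfg$oscillators$nc_alpha_hz,
    nc_alpha_amp = cfg$oscillators$nc_alpha_amp,
    hip_theta_hz = cfg$oscillators$hip_theta_hz,
    hip_theta_amp = cfg$oscillators$hip_theta_amp,
    w_ec = cfg$ec$w_ec, syn_gain = cfg$synapse$gain, dt_ms = cfg$sim$dt_ms)
}

#' Write a configuration file
#'
#' @param cfg configuration list
#' @param path destination (`.yaml` or `.json` decides the format)
#' @return `path`, invisibly
#' @export
write_config <- function(cfg, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' Derive a per-trial seed from a master seed
#'
#' Deterministic, collision-free expansion of one master seed into the
#' condition-by-trial grid: with integer condition ids below 16384 and trial
#' indices below 131072, `(condition_id, trial_index)` maps injectively into
#' the 31-bit seed space (offset by a scrambled master base), so re-running
#' any single trial in isolation reproduces its in-grid result.  Character
#' condition ids are hashed into the integer id space first (distinct names
#' may then, rarely, share an id; grid runners use integer ids).
#'
#' @param master_seed master integer seed
#' @param condition_id integer condition index (or a string, hashed)
#' @param trial_index trial number within the condition
#' @return an integer seed in `[0, 2^31 - 1)`
#' @export
derive_trial_seed <- function(master_seed, condition_id, trial_index) {
  m <- 2^31
  cond <- if (is.numeric(condition_id)) {
    as.numeric(condition_id)
  } else {
    h <- 7
    for (ch in utf8ToInt(as.character(condition_id))) h <- (h * 31 + ch) %% 16384
    h
  }
  if (cond < 0 || cond >= 16384) stop("condition_id out of range [0, 16384)")
  if (trial_index < 0 || trial_index >= 131072)
    stop("trial_index out of range [0, 131072)")
  base <- ((as.numeric(master_seed) %% m) * 69069 + 12345) %% m
  as.integer((base + cond * 131072 + trial_index) %% m)
}

#' Write simulation outputs with a run manifest
#'
#' Writes the given tables as RFC-4180 CSV files (UTF-8, `.` decimal
#' separator) into `dir`, overwriting existing files, and a
#' `manifest.json` listing every written file with its MD5 checksum, the
#' resolved configuration, the master seed and a timestamp.
#'
#' @param tables named list of data frames; each is written as
#'   `<name>.csv`
#' @param dir output directory (created if needed)
#' @param config resolved configuration list to embed in the manifest
#' @param master_seed master seed to record
#' @return invisible data frame inventory (`file`, `md5`)
#' @export
write_outputs <- function(tables, dir, config = default_config(),
                          master_seed = NA) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  inv <- data.frame(file = basename(files),
                    md5 = unname(tools::md5sum(files)))
  manifest <- list(
    package = "thetaSTDP",
    version = as.character(utils::packageVersion("thetaSTDP")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    master_seed = master_seed,
    seed_scheme = "derive_trial_seed(master, 2*condition_id [+1], trial)",
    config = config,
    files = inv)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(inv)
}
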