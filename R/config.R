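# Run configuration: nested sections mirroring the module types, read from
# JSON or YAML with defaults filled in and unknown keys rejected.

#' Default run configuration
#'
#' Sections: `model` (plant constants), `design` (sampling time, desired
#' pole, limiter gain), `limits` (therapy limits), `reference` (piecewise
#' reference schedule), `cohort` (cohort experiment settings).
#'
#' @export
default_config <- function() {
  list(
    schema_version = 1,
    model = list(kexc = KEXC_NOMINAL, ksec = KSEC_NOMINAL,
                 kreac = 7.25, km = 9.504e3, vmax = 2.19e-4,
                 kreac_scale = "raw"),
    design = list(Td = 672, z0 = -0.01, kr = 0.5, neglect_threshold = 1e-6,
                  kexc_range = c(0.16, 0.36)),
    limits = list(dose_max = 200, dose_quantum = 12.5, max_step = 12.5,
                  range_lo = 9.2, range_hi = 16),
    reference = list(time_h = 0, value = 13),
    # NB: the count key is "n_patients", not "n" — a bare "n" is parsed as a
    # boolean by YAML 1.1 readers
    cohort = list(n_patients = 50, seed = 42, n_visits = 12,
                  half_life_days = c(9, 10), cv = 0.3,
                  bioavailability_range = c(0.64, 0.83),
                  circadian_amplitude = 0.05)
  )
}

merge_config <- function(defaults, user, path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config section '", paste(path, collapse = "$"),
                           "' must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key: ",
         paste(c(path, unknown[1]), collapse = "$"))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], c(path, k))
    } else {
      defaults[[k]] <- if (is.list(user[[k]])) unlist(user[[k]]) else user[[k]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  do.call(thyroid_params, cfg$model)
  design_spec(cfg$design$z0, cfg$design$Td, cfg$design$kr,
              cfg$design$neglect_threshold)
  do.call(therapy_limits, cfg$limits)
  reference_schedule(cfg$reference$time_h, cfg$reference$value)
  if (cfg$limits$dose_max > 200) {
    warning("dose_max = ", cfg$limits$dose_max, " ug/day exceeds the 200 ug ",
            "physician-consultation threshold; daily doses beyond 500 ug in ",
            "adults risk serious toxicity")
  }
  invisible(cfg)
}

#' Load a run configuration from JSON or YAML
#'
#' Missing keys take their defaults ([default_config()]); unknown keys are
#' rejected with a message naming the offending key.  An empty file yields
#' the all-defaults configuration.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file
#' @return a validated config list
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (file.size(path) == 0) NULL else jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- merge_config(default_config(), user)
  validate_config(cfg)
  cfg
}

#' Save a run configuration (JSON or YAML by extension)
#' @param cfg a config list
#' @param path output path
#' @export
save_config <- function(cfg, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path, precision = 15)
  }
  invisible(path)
}

# Helpers assembling module objects from a config
config_params <- function(cfg) do.call(thyroid_params, cfg$model)
config_spec <- function(cfg) design_spec(cfg$design$z0, cfg$design$Td,
                                         cfg$design$kr,
                                         cfg$design$neglect_threshold)
config_limits <- function(cfg) do.call(therapy_limits, cfg$limits)
config_refs <- function(cfg) reference_schedule(cfg$reference$time_h,
                                                cfg$reference$value)
config_cohort <- function(cfg) {
  cohort_config(n = cfg$cohort$n_patients, seed = cfg$cohort$seed,
                n_visits = cfg$cohort$n_visits,
                reference = cfg$reference$value[1],
                kexc_range = cfg$design$kexc_range,
                half_life_days = cfg$cohort$half_life_days,
                cv = cfg$cohort$cv,
                bioavailability_range = cfg$cohort$bioavailability_range,
                circadian_amplitude = cfg$cohort$circadian_amplitude)
}
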