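# Loop configuration: defaults, YAML/JSON loading with validation, saving.

#' Default loop configuration
#'
#' The complete parameter set describing the as-built loop: working fluid,
#' waveform family, branch geometry, pump, calibration protocol, the two
#' Hall-effect sensors (pump outlet and reservoir return), sensor-averaging
#' protocol, thermal model and thermostat, access-path layout and friction
#' fixture. Every value is overridable from a YAML or JSON file via
#' [load_config()].
#'
#' The friction measurements are a synthetic default fixture (bench force
#' data are not published); they reproduce a mean coefficient of 0.12 with
#' SD about 0.05.
#'
#' @return A nested list of class `loop_config`.
#' @export
default_config <- function() {
  structure(
    list(
      seed = 1L,
      fluid = list(dynamic_viscosity_cp = 1.0, density_g_cm3 = 1.0),
      waveform = list(
        heart_rate_bpm = 60,
        mean_total_lpm = 3.10,
        svc_fraction = 1 / 3,
        amp_systolic = 0.8,
        center_systolic = 0.25,
        width_systolic = 0.25,
        amp_diastolic = 0.5,
        center_diastolic = 0.65,
        width_diastolic = 0.25,
        amp_reversal = 0.3,
        center_reversal = 0.95,
        width_reversal = 0.15,
        n_samples = 256L,
        n_steps = 20L
      ),
      geometry = list(d_svc_cm = 1.27, d_ivc_cm = 2.0, d_in_cm = 2.0),
      pump = list(
        deadband_duty = 55,
        gain_lpm_per_count = 0.03,
        correction_slope = 1.0,
        correction_intercept = 0.0,
        max_duty = 255
      ),
      calibration = list(
        setpoints_lpm = c(3, 4, 5, 6),
        trials_per_point = 3L,
        timing_sd_s = 0.1,
        mark_volume_l = 1.0
      ),
      sensors = list(
        pump_outlet = list(pulses_per_liter = 396, window_s = 10, count_jitter_sd = 2),
        reservoir_return = list(pulses_per_liter = 396, window_s = 10, count_jitter_sd = 2)
      ),
      pulsatile = list(n_cycles = 10L, n_trials = 3L, tolerance_lpm = 0.13),
      thermal = list(
        volume_l = 3,
        heater_power_w = 1000,
        loss_coefficient_w_per_c = 5,
        ambient_c = 20,
        specific_heat_j_per_kg_c = 4186,
        density_kg_per_l = 1,
        setpoint_c = 37,
        deadband_c = 1,
        initial_c = 20,
        duration_s = 3600,
        dt_s = 1,
        tail_fraction = 0.5
      ),
      layout = list(
        target_length_cm = 80,
        radial = list(
          list(name = "axillary_line", internal_diameter_cm = 0.95, length_cm = 30),
          list(name = "subclavian_line", internal_diameter_cm = 1.27, length_cm = 25),
          list(name = "svc_line", internal_diameter_cm = 1.27, length_cm = 25)
        ),
        femoral = list(
          list(name = "femoral_port", internal_diameter_cm = 2.0, length_cm = 5),
          list(name = "ivc_line", internal_diameter_cm = 2.0, length_cm = 75)
        )
      ),
      friction = list(
        friction_force_n = c(1.2, 0.6, 1.8, 1.55, 0.85),
        normal_force_n = c(10, 10, 10, 10, 10)
      )
    ),
    class = "loop_config"
  )
}

# recursive merge of user values over defaults, rejecting unknown keys.
# Segment lists (unnamed lists under layout$radial / layout$femoral) replace
# the default wholesale and are validated per-segment.
merge_config <- function(default, user, path = "") {
  if (is.null(user)) {
    return(default)
  }
  if (!is.list(user) || is.null(names(user)) || any(names(user) == "")) {
    stop_config(sprintf("config section `%s` must be a named mapping", path))
  }
  unknown <- setdiff(names(user), names(default))
  if (length(unknown) > 0) {
    stop_config(sprintf(
      "unknown config key%s: %s",
      if (length(unknown) > 1) "s" else "",
      paste0(sub("^\\$", "", paste0(path, "$", unknown)), collapse = ", ")
    ))
  }
  for (key in names(user)) {
    here <- sub("^\\$", "", paste0(path, "$", key))
    d <- default[[key]]
    u <- user[[key]]
    if (is.list(d) && !is.null(names(d)) && all(names(d) != "")) {
      default[[key]] <- merge_config(d, u, path = paste0("$", here))
    } else {
      default[[key]] <- u
    }
  }
  default
}

segment_tibble <- function(segments, path) {
  rows <- purrr::map(segments, function(seg) {
    extra <- setdiff(names(seg), c("name", "internal_diameter_cm", "length_cm"))
    if (length(extra) > 0) {
      stop_config(sprintf(
        "unknown segment key%s in %s: %s",
        if (length(extra) > 1) "s" else "", path, paste(extra, collapse = ", ")
      ))
    }
    if (!all(c("name", "internal_diameter_cm", "length_cm") %in% names(seg))) {
      stop_config(sprintf(
        "%s: each segment needs `name`, `internal_diameter_cm`, `length_cm`", path
      ))
    }
    tibble::tibble(
      name = seg$name,
      internal_diameter_cm = seg$internal_diameter_cm,
      length_cm = seg$length_cm
    )
  })
  dplyr::bind_rows(rows)
}

# construct every component object so that invariant violations surface with
# a path-qualified message; returns the realized components
realize_config <- function(config) {
  with_field <- function(field, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("config `%s`: %s", field, conditionMessage(e)),
        class = "venaloop_config_error"
      )
    })
  }
  list(
    fluid = with_field("fluid", do.call(fluid_properties, config$fluid)),
    params = with_field("waveform", do.call(
      venous_waveform_params,
      config$waveform[setdiff(names(config$waveform), c("n_samples", "n_steps"))]
    )),
    pump = with_field("pump", do.call(pump_model, config$pump)),
    sensors = list(
      pump_outlet = with_field(
        "sensors$pump_outlet",
        do.call(turbine_sensor, config$sensors$pump_outlet)
      ),
      reservoir_return = with_field(
        "sensors$reservoir_return",
        do.call(turbine_sensor, config$sensors$reservoir_return)
      )
    ),
    thermal = with_field("thermal", do.call(
      thermal_model,
      config$thermal[c(
        "volume_l", "heater_power_w", "loss_coefficient_w_per_c",
        "ambient_c", "specific_heat_j_per_kg_c", "density_kg_per_l"
      )]
    )),
    thermostat = with_field(
      "thermal",
      thermostat_controller(config$thermal$setpoint_c, config$thermal$deadband_c)
    ),
    layout = with_field("layout", loop_layout(
      radial = segment_tibble(config$layout$radial, "layout$radial"),
      femoral = segment_tibble(config$layout$femoral, "layout$femoral")
    )),
    geometry = with_field("geometry", {
      cross_section_area(c(
        config$geometry$d_svc_cm, config$geometry$d_ivc_cm, config$geometry$d_in_cm
      ))
      config$geometry
    })
  )
}

#' Load a loop configuration from YAML or JSON
#'
#' Reads the file (YAML by default; `.json` files via jsonlite), fills every
#' missing key with the documented default, rejects unknown keys with a
#' path-qualified message, and validates all component invariants. A `NULL`
#' path or an empty file yields the all-defaults configuration.
#'
#' @param path File path, or `NULL` for defaults.
#' @return A validated `loop_config`.
#' @export
load_config <- function(path = NULL) {
  user <- NULL
  if (!is.null(path)) {
    if (!file.exists(path)) stop_config(sprintf("config file not found: %s", path))
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    } else {
      tryCatch(yaml::read_yaml(path), error = function(e) {
        stop_config(sprintf("could not parse config %s: %s", path, conditionMessage(e)))
      })
    }
  }
  config <- merge_config(unclass(default_config()), user)
  config$seed <- as.integer(config$seed)
  class(config) <- "loop_config"
  realize_config(config) # validate; discard realized components here
  config
}

#' Save a loop configuration as YAML
#'
#' @param config A `loop_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "loop_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @export
print.loop_config <- function(x, ...) {
  cat("<loop_config>\n")
  cat(sprintf(
    "  waveform: %g bpm, mean %g L/min, SVC fraction %.3f\n",
    x$waveform$heart_rate_bpm, x$waveform$mean_total_lpm, x$waveform$svc_fraction
  ))
  cat(sprintf(
    "  pump: deadband %g, gain %g L/min per count, correction %.4g x %+.4g\n",
    x$pump$deadband_duty, x$pump$gain_lpm_per_count,
    x$pump$correction_slope, x$pump$correction_intercept
  ))
  cat(sprintf(
    "  thermal: setpoint %g degC (deadband %g), %g L reservoir\n",
    x$thermal$setpoint_c, x$thermal$deadband_c, x$thermal$volume_l
  ))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
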