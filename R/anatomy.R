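# Anatomical verification: cadaver-literature heart dimensions, vessel
# diameters, access-path lengths and the friction-coefficient check.

#' Literature and as-built heart dimensions
#'
#' Five caliper-verifiable axes of the right heart (right atrial long/short
#' axis; right ventricular long axis, maximal and midway short axes), each
#' with the smaller-heart, larger-heart and average-heart mean +/- SD from
#' cadaver silicone-mold studies, plus the as-built model's measurement.
#' The acceptance rule is the average-heart mean +/- 1 SD
#' ([literature_range()]).
#'
#' The default `our_value` for the midway right-ventricular short axis is
#' 3.81 cm; see [run_report()], which flags a known 3.81 vs 4.81 cm
#' discrepancy between tabulated and narrated source measurements.
#'
#' @param our_values Optional named numeric vector overriding the as-built
#'   measurements; names must be axis identifiers.
#'
#' @return A tibble with columns `axis`, `smaller_mean`, `smaller_sd`,
#'   `larger_mean`, `larger_sd`, `average_mean`, `average_sd`, `our_value`
#'   (all cm).
#' @export
heart_dimension_table <- function(our_values = NULL) {
  tbl <- tibble::tribble(
    ~axis, ~smaller_mean, ~smaller_sd, ~larger_mean, ~larger_sd,
    ~average_mean, ~average_sd, ~our_value,
    "right_atrial_long", 4.43, 0.40, 4.65, 0.33, 4.51, 0.47, 4.45,
    "right_atrial_short", 4.63, 0.31, 4.96, 0.29, 4.79, 0.47, 5.08,
    "rv_long", 7.55, 0.46, 8.58, 0.40, 8.04, 0.94, 7.62,
    "rv_short_max", 4.53, 0.35, 4.73, 0.33, 4.62, 0.44, 5.00,
    "rv_short_mid", 3.56, 0.28, 3.77, 0.39, 3.72, 0.44, 3.81
  )
  if (!is.null(our_values)) {
    unknown <- setdiff(names(our_values), tbl$axis)
    if (length(unknown) > 0) {
      stop_key(sprintf("unknown heart axis: %s", paste(unknown, collapse = ", ")))
    }
    idx <- match(names(our_values), tbl$axis)
    tbl$our_value[idx] <- unname(our_values)
  }
  if (any(tbl$our_value <= 0) || any(tbl$average_sd < 0)) {
    stop_domain("heart dimensions must be positive and SDs non-negative")
  }
  tbl
}

#' Reference chamber areas (no verification rule)
#'
#' Literature right atrial and right ventricular areas, kept for reference
#' only: the as-built model's areas were not measured (they require imaging
#' of silicone casts), so no acceptance rule applies.
#'
#' @return A tibble with columns `measure`, `smaller_mean`, `smaller_sd`,
#'   `larger_mean`, `larger_sd`, `average_mean`, `average_sd` (cm^2).
#' @export
heart_area_reference <- function() {
  tibble::tribble(
    ~measure, ~smaller_mean, ~smaller_sd, ~larger_mean, ~larger_sd,
    ~average_mean, ~average_sd,
    "right_atrial_area", 18.72, 1.60, 19.97, 1.97, 19.53, 2.41,
    "right_ventricular_area", 25.81, 2.85, 30.57, 3.53, 28.53, 5.57
  )
}

#' Literature acceptance range for a heart axis
#'
#' The rule consistent with every published range pair: average-heart mean
#' +/- 1 SD, bounds inclusive (e.g. right atrial long axis 4.51 +/- 0.47
#' gives 4.04-4.98 cm).
#'
#' @param table A [heart_dimension_table()].
#' @param axis Axis identifier.
#' @return Named numeric `c(low = , high = )` in cm.
#' @export
literature_range <- function(table = heart_dimension_table(), axis) {
  row <- table[table$axis == axis, ]
  if (nrow(row) != 1L) {
    stop_key(sprintf(
      "unknown heart axis '%s'; expected one of %s",
      axis, paste(table$axis, collapse = ", ")
    ))
  }
  c(low = row$average_mean - row$average_sd, high = row$average_mean + row$average_sd)
}

#' Verify the as-built heart against literature ranges
#'
#' An axis passes when its measured value lies inside the [literature_range()]
#' for that axis, bounds inclusive.
#'
#' @param table A [heart_dimension_table()].
#' @return A tibble with columns `axis`, `our_value`, `low`, `high`, `pass`.
#' @export
#' @examples
#' verify_heart_dimensions() # the as-built model: all five axes pass
verify_heart_dimensions <- function(table = heart_dimension_table()) {
  out <- dplyr::mutate(
    table,
    low = average_mean - average_sd,
    high = average_mean + average_sd,
    pass = our_value >= low & our_value <= high
  )
  dplyr::select(out, axis, our_value, low, high, pass)
}

#' Anatomical vessel diameters and the as-built tubing
#'
#' Literature internal diameters (mean +/- SD) of the venous access path and
#' pulmonary vessels, with the as-built tubing diameter for each. The
#' femoral port is structurally excluded from verification: it is a short
#' catheter-insertion port whose diameter is inconsequential.
#'
#' @return A tibble with columns `vessel`, `anatomical_mean_cm`,
#'   `anatomical_sd_cm`, `system_diameter_cm`, `excluded`.
#' @export
vessel_table <- function() {
  tibble::tribble(
    ~vessel, ~anatomical_mean_cm, ~anatomical_sd_cm, ~system_diameter_cm, ~excluded,
    "right_femoral_vein", 1.10, 0.10, 2.00, TRUE,
    "inferior_vena_cava", 1.75, 0.25, 2.00, FALSE,
    "superior_vena_cava", 1.45, 0.20, 1.27, FALSE,
    "right_subclavian_vein", 1.33, 0.20, 1.27, FALSE,
    "right_axillary_vein", 1.04, 0.18, 0.95, FALSE,
    "pulmonary_trunk", 2.48, 0.51, 2.54, FALSE,
    "right_pulmonary_artery", 1.28, 0.28, 1.27, FALSE,
    "left_pulmonary_artery", 1.22, 0.42, 1.27, FALSE
  )
}

#' Verify the as-built vessel diameters
#'
#' A vessel passes when its tubing diameter lies within `k_sd` literature
#' SDs of the anatomical mean (inclusive). Excluded vessels (the femoral
#' insertion port) are reported as `"excluded"`, never failed.
#'
#' @param table A [vessel_table()].
#' @param k_sd SD multiplier for the acceptance band (default 1).
#' @return A tibble with columns `vessel`, `system_diameter_cm`, `low`,
#'   `high`, `status` (`"pass"`, `"fail"` or `"excluded"`), `pass` (`NA` for
#'   excluded vessels).
#' @export
verify_vessel_diameters <- function(table = vessel_table(), k_sd = 1) {
  check_scalar_number(k_sd, "k_sd", non_negative = TRUE)
  if (any(table$system_diameter_cm <= 0) || any(table$anatomical_mean_cm <= 0)) {
    stop_domain("vessel diameters must be > 0")
  }
  dplyr::mutate(
    table,
    low = anatomical_mean_cm - k_sd * anatomical_sd_cm,
    high = anatomical_mean_cm + k_sd * anatomical_sd_cm,
    in_band = system_diameter_cm >= low & system_diameter_cm <= high,
    status = dplyr::case_when(
      excluded ~ "excluded",
      in_band ~ "pass",
      TRUE ~ "fail"
    ),
    pass = dplyr::if_else(excluded, NA, in_band)
  )[, c("vessel", "system_diameter_cm", "low", "high", "status", "pass")]
}

#' Access-path layout of the loop
#'
#' Ordered tubing segments from each catheter access port to the heart
#' inlet. Both default paths total 80 cm, the as-built access length; the
#' split into segments (radial: axillary 30 + subclavian 25 + SVC 25 cm;
#' femoral: port 5 + IVC line 75 cm) is the package's default layout.
#'
#' @param radial,femoral Tibbles (or data frames) of ordered segments with
#'   columns `name`, `internal_diameter_cm` (> 0) and `length_cm` (>= 0).
#' @return A list of class `loop_layout` with elements `radial`, `femoral`.
#' @export
loop_layout <- function(radial = NULL, femoral = NULL) {
  default_radial <- tibble::tribble(
    ~name, ~internal_diameter_cm, ~length_cm,
    "axillary_line", 0.95, 30,
    "subclavian_line", 1.27, 25,
    "svc_line", 1.27, 25
  )
  default_femoral <- tibble::tribble(
    ~name, ~internal_diameter_cm, ~length_cm,
    "femoral_port", 2.00, 5,
    "ivc_line", 2.00, 75
  )
  radial <- tibble::as_tibble(radial %||% default_radial)
  femoral <- tibble::as_tibble(femoral %||% default_femoral)
  for (path in list(radial, femoral)) {
    if (nrow(path) == 0L) stop_shape("each access path needs at least one segment")
    if (!all(c("name", "internal_diameter_cm", "length_cm") %in% names(path))) {
      stop_shape("segments need columns `name`, `internal_diameter_cm`, `length_cm`")
    }
    if (any(path$internal_diameter_cm <= 0)) stop_domain("segment diameters must be > 0")
    if (any(path$length_cm < 0)) stop_domain("segment lengths must be >= 0")
  }
  structure(list(radial = radial, femoral = femoral), class = "loop_layout")
}

#' Total access-path length to the heart
#'
#' @param layout A [loop_layout()].
#' @param site `"radial"` or `"femoral"`.
#' @return Length in cm.
#' @export
#' @examples
#' access_path_length(loop_layout(), "femoral") # 80
access_path_length <- function(layout = loop_layout(), site) {
  stopifnot(inherits(layout, "loop_layout"))
  if (!site %in% names(layout)) {
    stop_key(sprintf("unknown access site '%s'; expected radial or femoral", site))
  }
  sum(layout[[site]]$length_cm)
}

#' Friction coefficient from force-pair measurements
#'
#' For each (friction force, normal force) pair, `mu = F_friction / F_normal`;
#' reports the mean and sample SD over measurements. With one measurement
#' the SD is undefined and reported as 0 with `degenerate_sd = TRUE`.
#'
#' @param measurements A tibble with columns `friction_force_n` (>= 0) and
#'   `normal_force_n` (> 0); at least one row.
#' @return A list with `mean_mu`, `sd_mu`, `n`, `degenerate_sd`, and the
#'   per-measurement `mu` vector.
#' @export
friction_coefficient <- function(measurements) {
  if (is.null(measurements) || nrow(measurements) == 0L) {
    stop_shape("need at least one friction measurement")
  }
  if (!all(c("friction_force_n", "normal_force_n") %in% names(measurements))) {
    stop_shape("`measurements` must have columns `friction_force_n` and `normal_force_n`")
  }
  if (any(measurements$normal_force_n <= 0)) {
    stop_domain("normal force must be > 0")
  }
  if (any(measurements$friction_force_n < 0)) {
    stop_domain("friction force must be >= 0")
  }
  mu <- measurements$friction_force_n / measurements$normal_force_n
  n <- length(mu)
  list(
    mean_mu = mean(mu),
    sd_mu = if (n < 2) 0 else sd(mu),
    n = n,
    degenerate_sd = n < 2,
    mu = mu
  )
}

#' Check a friction coefficient against physiological and design ranges
#'
#' The physiological band for vascular surfaces is 0.015-0.13 (inclusive);
#' the loop's design criterion is the strict band 0 < mu < 0.5.
#'
#' @param mean_mu Mean friction coefficient (finite).
#' @return A list with `physiological_pass` and `design_pass`.
#' @export
verify_friction <- function(mean_mu) {
  check_scalar_number(mean_mu, "mean_mu")
  list(
    physiological_pass = mean_mu >= 0.015 && mean_mu <= 0.13,
    design_pass = mean_mu > 0 && mean_mu < 0.5
  )
}
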