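#' Flexural rigidity of a rectangular cantilever beam
#'
#' The bending stiffness EI of a rectangular-section beam, `E * b * h^3 / 12`,
#' with elastic modulus E, width b and thickness h. All computation is done
#' in SI units; inputs use the instrument's mixed units (GPa, mm).
#'
#' @param beams A tibble of beam specifications as returned by
#'   [beam_registry()] (columns `elastic_modulus_gpa`, `width_mm`,
#'   `thickness_mm`).
#' @return The input tibble with a `rigidity_nm2` column (N m^2) appended.
#' @examples
#' flexural_rigidity(beam_registry())
#' @export
flexural_rigidity <- function(beams) {
  check_beam_tbl(beams)
  mutate(beams,
    rigidity_nm2 = .data$elastic_modulus_gpa * 1e9 *
      (.data$width_mm / 1e3) * (.data$thickness_mm / 1e3)^3 / 12
  )
}

#' Ideal-cantilever calibration ratios
#'
#' Closed-form calibration of the sensing beam under an ideal-cantilever
#' assumption: a point load F at the beam tip (where the microwire sits)
#' deflects the beam, and the laser reads the deflection d_c at the laser
#' height. With the clamped base of height `clamp_height_mm` subtracted from
#' both arms -- load arm `a = length - clamp` and laser arm
#' `x = laser height - clamp` -- Euler-Bernoulli theory gives the deflection
#' at the laser point as `F x^2 (3a - x) / (6 EI)`, so
#'
#' * `force_per_laser_deflection  = 6 EI / (x^2 (3a - x))`  (F_i/d_c, mN/mm)
#' * `loadpoint_per_laser_deflection = 2 a^3 / (x^2 (3a - x))` (d_l/d_c)
#'
#' These are the theoretical counterparts of the finite-element calibration
#' coefficients; the difference between them (up to ~20% on the softest
#' beam) is attributed to gravity of the mounted components, which the ideal
#' model deliberately omits.
#'
#' @inheritParams flexural_rigidity
#' @param laser A one-row tibble as returned by [laser_spec()].
#' @return A tibble with columns `beam`, `force_per_laser_deflection`
#'   (mN/mm) and `loadpoint_per_laser_deflection` (dimensionless).
#' @examples
#' ideal_calibration(beam_registry())
#' @export
ideal_calibration <- function(beams, laser = laser_spec()) {
  beams <- flexural_rigidity(beams)
  a <- (beams$length_mm - beams$clamp_height_mm) / 1e3
  x <- (laser$height_mm - beams$clamp_height_mm) / 1e3
  if (any(x <= 0)) abort("Laser height must be above the clamp.")
  if (any(x >= a)) abort("Laser height must be below the load point (beam tip).")
  denom <- x^2 * (3 * a - x)
  tibble(
    beam = beams$beam,
    # N/m and mN/mm are the same number
    force_per_laser_deflection = 6 * beams$rigidity_nm2 / denom,
    loadpoint_per_laser_deflection = 2 * a^3 / denom
  )
}

#' Measurement capacity of a beam/laser pairing
#'
#' The maximum measurable force and the force resolution follow linearly
#' from the calibration coefficient and the laser specification:
#' `max_force = (F_i/d_c) * range` and `resolution = (F_i/d_c) * quantum`.
#'
#' @param calib A calibration tibble with columns `beam` and
#'   `force_per_laser_deflection` (mN/mm), e.g. from
#'   [calibration_registry()].
#' @inheritParams ideal_calibration
#' @return `calib` with `max_force_mn` and `force_resolution_un` (micro-N)
#'   appended.
#' @examples
#' measurement_capacity(calibration_registry("fem"))
#' @export
measurement_capacity <- function(calib, laser = laser_spec()) {
  check_positive(calib$force_per_laser_deflection, "force_per_laser_deflection")
  mutate(calib,
    max_force_mn = .data$force_per_laser_deflection * laser$range_mm,
    # ratio [mN/mm] * resolution [um -> mm] = mN -> uN
    force_resolution_un = .data$force_per_laser_deflection *
      laser$resolution_um * 1e-3 * 1e3
  )
}

#' Measurement error from beam tilt
#'
#' Beam deflection tilts the top plate (and the microwire) by a small angle
#' alpha; the component of motion lost to the tilt gives a relative
#' measurement error of `1 - cos(alpha)`.
#'
#' @param angle_deg Tilt angle(s) in degrees, in `[0, 90)`. May also be a
#'   data frame with a `tilt_angle_deg` column.
#' @return A tibble with columns `tilt_angle_deg`, `relative_error`
#'   (fraction) and `percent_error`; when a data frame is supplied the
#'   columns are appended to it.
#' @examples
#' tilt_error(c(0.92, 1.75))
#' @export
tilt_error <- function(angle_deg) {
  if (is.data.frame(angle_deg)) {
    out <- angle_deg
    ang <- out$tilt_angle_deg
  } else {
    ang <- angle_deg
    out <- tibble(tilt_angle_deg = ang)
  }
  if (!is.numeric(ang) || any(!is.finite(ang)) || any(ang < 0) || any(ang >= 90)) {
    abort("`angle_deg` must lie in [0, 90).")
  }
  mutate(out,
    relative_error = 1 - cos(.data$tilt_angle_deg * pi / 180),
    percent_error = 100 * .data$relative_error
  )
}

#' Euler critical buckling load of a slender microelectrode
#'
#' A wire under axial insertion load buckles instead of penetrating once the
#' force exceeds `P = m pi^2 E I / L_u^2`, with end-condition factor m,
#' elastic modulus E, second moment of area I and unsupported length L_u.
#' Circular wires use `I = pi d^4 / 64`; planar silicon shanks use the
#' rectangular `I = w t^3 / 12` (bending about the thin axis).
#'
#' @param wires A tibble of wire specifications (see [wire_registry()]):
#'   columns `elastic_modulus_gpa`, `unsupported_length_mm`,
#'   `end_condition`, and either `diameter_um` (circular) or `width_um` +
#'   `thickness_um` (rectangular, `cross_section == "rectangular"`).
#' @return `wires` with a `buckling_load_mn` column appended.
#' @examples
#' critical_buckling_load(wire_registry())
#' @export
critical_buckling_load <- function(wires) {
  check_positive(wires$elastic_modulus_gpa, "elastic_modulus_gpa")
  check_positive(wires$unsupported_length_mm, "unsupported_length_mm")
  check_nonneg(wires$end_condition, "end_condition")
  section <- if ("cross_section" %in% names(wires)) wires$cross_section else
    rep("circular", nrow(wires))
  I_m4 <- ifelse(section == "rectangular",
    (wires$width_um * 1e-6) * (wires$thickness_um * 1e-6)^3 / 12,
    pi * (wires$diameter_um * 1e-6)^4 / 64
  )
  check_positive(I_m4, "second moment of area")
  mutate(wires,
    buckling_load_mn = .data$end_condition * pi^2 *
      (.data$elastic_modulus_gpa * 1e9) * I_m4 /
      (.data$unsupported_length_mm / 1e3)^2 * 1e3
  )
}

#' Percent difference against a reference value
#'
#' `|value - reference| / reference * 100`. The calibration report uses the
#' ideal-cantilever value as reference for force ratios and the experimental
#' value as reference for deflection ratios.
#'
#' @param value,reference Numeric vectors; `reference` must be nonzero.
#' @return Percent differences.
#' @examples
#' percent_difference(3.238, 4.058)
#' @export
percent_difference <- function(value, reference) {
  if (any(!is.finite(reference)) || any(reference == 0)) {
    abort("`reference` must be finite and nonzero.")
  }
  abs(value - reference) / abs(reference) * 100
}

#' Calibration comparison report
#'
#' Side-by-side comparison of the finite-element, ideal-cantilever and
#' experimental calibration coefficients for every registered beam, with
#' percent differences computed against the convention of the calibration
#' study: FEM force ratios are compared to the ideal value, FEM deflection
#' ratios to the experimental value.
#'
#' @inheritParams ideal_calibration
#' @param ideal_published Use the published ideal force ratios rather than
#'   recomputing from geometry (see [calibration_registry()]).
#' @return A tibble with one row per beam: `force_fem`, `force_ideal`,
#'   `force_difference_pct`, `loadpoint_fem`, `loadpoint_experiment`,
#'   `loadpoint_discrepancy_pct`.
#' @examples
#' calibration_report()
#' @export
calibration_report <- function(beams = beam_registry(), laser = laser_spec(),
                               ideal_published = TRUE) {
  fem <- calibration_registry("fem")
  expt <- calibration_registry("experiment")
  ideal <- calibration_registry("ideal", published = ideal_published)
  fem |>
    filter(.data$beam %in% beams$beam) |>
    select("beam",
           force_fem = "force_per_laser_deflection",
           loadpoint_fem = "loadpoint_per_laser_deflection") |>
    left_join(select(ideal, "beam", force_ideal = "force_per_laser_deflection"),
              by = "beam") |>
    left_join(select(expt, "beam",
                     loadpoint_experiment = "loadpoint_per_laser_deflection"),
              by = "beam") |>
    mutate(
      force_difference_pct = percent_difference(.data$force_fem, .data$force_ideal),
      loadpoint_discrepancy_pct = percent_difference(.data$loadpoint_fem,
                                                     .data$loadpoint_experiment),
      .after = "force_ideal"
    ) |>
    select("beam", "force_fem", "force_ideal", "force_difference_pct",
           "loadpoint_fem", "loadpoint_experiment", "loadpoint_discrepancy_pct")
}

#' Tilt-error report for the worst-case trials
#'
#' Applies [tilt_error()] to the packaged worst-case tilt scenarios
#' ([tilt_cases()]): the largest-rupture-force trial recorded on each beam.
#'
#' @return The [tilt_cases()] tibble with `relative_error` and
#'   `percent_error` appended.
#' @examples
#' tilt_error_report()
#' @export
tilt_error_report <- function() {
  tilt_error(tilt_cases())
}

check_beam_tbl <- function(beams) {
  need <- c("elastic_modulus_gpa", "width_mm", "thickness_mm")
  missing <- setdiff(need, names(beams))
  if (length(missing) > 0) {
    abort(sprintf("Beam table is missing column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  for (f in need) check_positive(beams[[f]], f)
  invisible(beams)
}
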