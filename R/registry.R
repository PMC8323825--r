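#' Packaged instrument registry
#'
#' The measurement system is built around four interchangeable cantilever
#' sensing beams read by a single laser displacement sensor. Their design
#' parameters, the sensor specification, and the calibration coefficients
#' (finite-element and experimental) ship with the package as a plain-text
#' registry; these accessors load and validate it.
#'
#' @param path Path to a registry file. Defaults to the packaged registry.
#' @return `beam_registry()`: a tibble with one row per sensing beam
#'   (`beam`, `material`, `elastic_modulus_gpa`, `length_mm`, `thickness_mm`,
#'   `width_mm`, `clamp_height_mm`). `laser_spec()`: a one-row tibble
#'   (`height_mm`, `range_mm`, `resolution_um`). `wire_materials()`: a tibble
#'   of microwire materials and elastic moduli.
#' @examples
#' beam_registry()
#' laser_spec()
#' @export
beam_registry <- function(path = system_config_path()) {
  cfg <- load_system_config(path)
  purrr::map_dfr(cfg$beams, function(b) {
    tibble(
      beam = b$name,
      material = b$material,
      elastic_modulus_gpa = b$elastic_modulus_gpa,
      length_mm = b$length_mm,
      thickness_mm = b$thickness_mm,
      width_mm = b$width_mm,
      clamp_height_mm = cfg$clamp_height_mm
    )
  })
}

#' @rdname beam_registry
#' @export
laser_spec <- function(path = system_config_path()) {
  cfg <- load_system_config(path)
  tibble(
    height_mm = cfg$laser$height_mm,
    range_mm = cfg$laser$range_mm,
    resolution_um = cfg$laser$resolution_um
  )
}

#' @rdname beam_registry
#' @export
wire_materials <- function(path = system_config_path()) {
  cfg <- load_system_config(path)
  purrr::imap_dfr(cfg$wire_materials, function(m, nm) {
    tibble(material = nm, elastic_modulus_gpa = m$elastic_modulus_gpa)
  })
}

#' Calibration coefficients linking laser reading to force and deflection
#'
#' Each beam has two linear calibration coefficients: the force produced per
#' unit laser-point deflection (F_i/d_c, mN/mm) and the load-point deflection
#' per unit laser-point deflection (d_l/d_c, dimensionless). Three sources
#' are available: `"fem"` (finite-element calibration including component
#' gravity -- the coefficients used for measurement), `"ideal"` (closed-form
#' ideal-cantilever theory, computed by [ideal_calibration()] or taken from
#' the published table via `published = TRUE`), and `"experiment"` (stage
#' push-calibration of d_l/d_c).
#'
#' @param source One of `"fem"`, `"ideal"`, `"experiment"`.
#' @param published For `source = "ideal"`, return the published table values
#'   rather than recomputing from beam geometry. The published ideal force
#'   ratio for `beam2` is inconsistent with beam theory for its geometry
#'   (see the package vignette); recomputation is the default.
#' @param path Path to a registry file.
#' @return A tibble with columns `beam`, `source`,
#'   `force_per_laser_deflection` (mN/mm) and/or
#'   `loadpoint_per_laser_deflection` (dimensionless).
#' @examples
#' calibration_registry("fem")
#' @export
calibration_registry <- function(source = c("fem", "ideal", "experiment"),
                                 published = FALSE,
                                 path = system_config_path()) {
  source <- match.arg(source)
  cfg <- load_system_config(path)
  if (source == "ideal" && !published) {
    out <- ideal_calibration(beam_registry(path), laser_spec(path))
    return(mutate(out, source = "ideal", .after = "beam"))
  }
  purrr::imap_dfr(cfg$calibration[[source]], function(co, nm) {
    tibble(
      beam = nm,
      source = source,
      force_per_laser_deflection = co$force_per_laser_deflection %||% NA_real_,
      loadpoint_per_laser_deflection = co$loadpoint_per_laser_deflection %||% NA_real_
    )
  })
}

#' @rdname calibration_registry
#' @param beam Beam identifier, e.g. `"beam1"`.
#' @export
calibration_for <- function(beam, source = c("fem", "ideal", "experiment"),
                            path = system_config_path()) {
  source <- match.arg(source)
  reg <- calibration_registry(source, path = path)
  row <- filter(reg, .data$beam == !!beam)
  if (nrow(row) == 0) {
    abort(sprintf("Unknown beam `%s`; registry has: %s.",
                  beam, paste(reg$beam, collapse = ", ")))
  }
  if (source == "experiment") {
    # the experiment calibrates only d_l/d_c; pair it with the FEM force ratio
    fem <- filter(calibration_registry("fem", path = path), .data$beam == !!beam)
    row$force_per_laser_deflection <- fem$force_per_laser_deflection
  }
  row
}

#' Study microwire stock
#'
#' The eleven microwire types used in the insertion study: tungsten wires
#' with sharp (25/50/100 um) or blunt (12/25/50/100 um) tips and blunt
#' stainless-steel wires (12/25/50/100 um). Unsupported length out of the
#' capillary tube follows the diameter (1.5 mm for 12/25 um, 3.0 mm for
#' 50/100 um) and the end-condition factor defaults to 1.
#'
#' @inheritParams beam_registry
#' @return A tibble with columns `material`, `tip`, `diameter_um`,
#'   `elastic_modulus_gpa`, `unsupported_length_mm`, `end_condition`.
#' @examples
#' wire_registry()
#' @export
wire_registry <- function(path = system_config_path()) {
  cfg <- load_system_config(path)
  grid <- bind_rows(
    tidyr::expand_grid(material = "tungsten", tip = c("sharp", "blunt"),
                       diameter_um = c(12, 25, 50, 100)),
    tidyr::expand_grid(material = "stainless_steel", tip = "blunt",
                       diameter_um = c(12, 25, 50, 100))
  )
  grid <- filter(grid, !(.data$tip == "sharp" & .data$diameter_um == 12))
  overhang <- purrr::map_dbl(cfg$wire_overhang_mm, identity)
  grid |>
    left_join(wire_materials(path), by = "material") |>
    mutate(
      unsupported_length_mm = unname(overhang[as.character(.data$diameter_um)]),
      end_condition = 1
    )
}

#' Published penetration/buckling counts
#'
#' Per-condition counts of penetrated vs total insertion trials for each
#' microwire type under pia-only and dura-pia penetration, as recorded in
#' the study (115 pia-only and 123 dura-pia effective trials).
#'
#' @return A tibble with columns `membrane`, `material`, `tip`,
#'   `diameter_um`, `penetrated`, `total`.
#' @examples
#' penetration_counts()
#' @export
penetration_counts <- function() {
  path <- system.file("extdata", "penetration_counts.csv",
                      package = "microforce", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' Worst-case beam-tilt scenarios
#'
#' For each sensing beam, the trial with the largest recorded rupture force
#' and the maximum top-plate tilt angle extracted from the corresponding
#' finite-element deformation (consumed here as inputs; no FEM is run).
#'
#' @return A tibble with columns `beam`, `wire`, `membrane`,
#'   `rupture_force_mn`, `tilt_angle_deg`.
#' @seealso [tilt_error_report()] which appends the resulting measurement
#'   error.
#' @export
tilt_cases <- function() {
  path <- system.file("extdata", "tilt_cases.csv",
                      package = "microforce", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

system_config_path <- function() {
  system.file("extdata", "system_config.yaml",
              package = "microforce", mustWork = TRUE)
}

# cached, schema-validated load of the registry file
load_system_config <- local({
  cache <- new.env(parent = emptyenv())
  function(path) {
    key <- normalizePath(path, mustWork = TRUE)
    if (!is.null(cache[[key]])) return(cache[[key]])
    cfg <- yaml::read_yaml(key)
    validate_system_config(cfg)
    cache[[key]] <- cfg
    cfg
  }
})

validate_system_config <- function(cfg) {
  required <- c("laser", "clamp_height_mm", "beams", "calibration",
                "wire_materials", "wire_overhang_mm")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0) {
    abort(sprintf("Registry is missing key(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  check_positive(cfg$laser$height_mm, "laser.height_mm")
  check_positive(cfg$laser$range_mm, "laser.range_mm")
  check_positive(cfg$laser$resolution_um, "laser.resolution_um")
  if (cfg$laser$range_mm * 1e3 <= cfg$laser$resolution_um) {
    abort("Laser range must exceed its resolution.")
  }
  check_positive(cfg$clamp_height_mm, "clamp_height_mm")
  for (b in cfg$beams) {
    for (f in c("elastic_modulus_gpa", "length_mm", "thickness_mm", "width_mm")) {
      check_positive(b[[f]], paste0("beams.", b$name, ".", f))
    }
    if (cfg$clamp_height_mm >= b$length_mm) {
      abort(sprintf("Clamp height must be below the length of `%s`.", b$name))
    }
    if (cfg$laser$height_mm <= cfg$clamp_height_mm ||
        cfg$laser$height_mm >= b$length_mm) {
      abort(sprintf("Laser height must lie between clamp and tip of `%s`.", b$name))
    }
  }
  for (src in names(cfg$calibration)) {
    for (nm in names(cfg$calibration[[src]])) {
      co <- cfg$calibration[[src]][[nm]]
      for (f in names(co)) check_positive(co[[f]], paste0("calibration.", src, ".", nm, ".", f))
    }
  }
  invisible(cfg)
}
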