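test_that("flexural rigidity reproduces the published beam constants", {
  ei <- flexural_rigidity(beam_registry())$rigidity_nm2
  expect_equal(round(ei, 4), c(0.0152, 0.0297, 0.1248, 0.3876))
  # degenerate thickness: rigidity vanishes with h^3
  thin <- dplyr::mutate(beam_registry()[1, ], thickness_mm = 1e-9)
  expect_lt(flexural_rigidity(thin)$rigidity_nm2, 1e-20)
  bad <- dplyr::mutate(beam_registry()[1, ], width_mm = 0)
  expect_error(flexural_rigidity(bad), "positive")
})

test_that("ideal cantilever ratios match the published calibration table", {
  ideal <- ideal_calibration(beam_registry())
  published_force <- c(beam1 = 4.058, beam3 = 32.712, beam4 = 101.76)
  for (b in names(published_force)) {
    got <- ideal$force_per_laser_deflection[ideal$beam == b]
    expect_lt(abs(got - published_force[[b]]) / published_force[[b]], 0.005)
  }
  # the d_l/d_c ratio agrees with the FEM calibration within 2% on all beams
  fem <- calibration_registry("fem")
  expect_true(all(
    abs(ideal$loadpoint_per_laser_deflection - fem$loadpoint_per_laser_deflection) /
      fem$loadpoint_per_laser_deflection < 0.02
  ))
})

test_that("laser placed at the load point recovers the textbook tip-load forms", {
  beams <- flexural_rigidity(beam_registry())
  a_mm <- beams$length_mm - beams$clamp_height_mm
  at_tip <- laser_spec()
  for (i in seq_len(nrow(beams))) {
    at_tip$height_mm <- beams$length_mm[i] - 1e-9
    one <- ideal_calibration(beams[i, ], at_tip)
    expect_equal(one$force_per_laser_deflection,
                 3 * beams$rigidity_nm2[i] / (a_mm[i] / 1e3)^3,
                 tolerance = 1e-6)
    expect_equal(one$loadpoint_per_laser_deflection, 1, tolerance = 1e-6)
  }
  below_clamp <- laser_spec()
  below_clamp$height_mm <- 10
  expect_error(ideal_calibration(beams[1, ], below_clamp), "clamp")
})

test_that("closed forms agree with independent beam integration to 6 figures", {
  skip_if_not_installed("pracma")
  beams <- flexural_rigidity(beam_registry())
  ideal <- ideal_calibration(beams)
  for (i in seq_len(nrow(beams))) {
    a <- (beams$length_mm[i] - beams$clamp_height_mm[i]) / 1e3
    x <- (laser_spec()$height_mm - beams$clamp_height_mm[i]) / 1e3
    w <- eb_deflection_per_force(beams$rigidity_nm2[i], a, c(x, a))
    expect_equal(ideal$force_per_laser_deflection[i], 1 / w[1], tolerance = 1e-6)
    expect_equal(ideal$loadpoint_per_laser_deflection[i], w[2] / w[1],
                 tolerance = 1e-6)
  }
})

test_that("measurement capacity follows linearly from ratio and laser spec", {
  cap <- measurement_capacity(calibration_registry("fem"))
  expect_equal(round(cap$max_force_mn[cap$beam == "beam1"], 1), 6.5)
  expect_equal(round(cap$force_resolution_un[cap$beam == "beam1"], 3), 0.032)
  expect_equal(round(cap$force_resolution_un[cap$beam == "beam4"], 2), 1.09)
  # linear in each laser parameter
  l2 <- laser_spec()
  l2$range_mm <- 2 * l2$range_mm
  l2$resolution_um <- 3 * l2$resolution_um
  cap2 <- measurement_capacity(calibration_registry("fem"), l2)
  expect_equal(cap2$max_force_mn, 2 * cap$max_force_mn)
  expect_equal(cap2$force_resolution_un, 3 * cap$force_resolution_un)
})

test_that("tilt error is 1 - cos(alpha), increasing, and quadratic when small", {
  expect_equal(tilt_error(0)$relative_error, 0)
  expect_equal(round(tilt_error(1.75)$percent_error, 3), 0.047)
  expect_equal(round(tilt_error(0.92)$percent_error, 3), 0.013)
  angles <- seq(0, 89.9, by = 0.5)
  expect_true(all(diff(tilt_error(angles)$relative_error) > 0))
  small <- seq(0.1, 4.9, by = 0.2)
  approx <- (small * pi / 180)^2 / 2
  expect_true(all(abs(tilt_error(small)$relative_error - approx) / approx < 0.01))
  expect_error(tilt_error(90), "90")
  expect_error(tilt_error(-1), "90")
})

test_that("critical buckling load matches direct evaluation and scales sanely", {
  w25 <- tibble::tibble(material = "tungsten", elastic_modulus_gpa = 410,
                        diameter_um = 25, unsupported_length_mm = 1.5,
                        end_condition = 1)
  p <- critical_buckling_load(w25)$buckling_load_mn
  # oracle: P = m pi^2 E (pi d^4/64) / L^2, evaluated independently in SI
  expect_equal(p, pi^2 * 410e9 * (pi * (25e-6)^4 / 64) / 0.0015^2 * 1e3,
               tolerance = 1e-12)
  expect_equal(round(p, 1), 34.5)
  ss <- dplyr::mutate(w25, elastic_modulus_gpa = 200)
  expect_equal(critical_buckling_load(ss)$buckling_load_mn, p * 200 / 410)
  # monotone in diameter, inversely in unsupported length
  grid <- tidyr::expand_grid(w25[, -3], diameter_um = c(12, 25, 50, 100))
  expect_true(all(diff(critical_buckling_load(grid)$buckling_load_mn) > 0))
  long <- dplyr::mutate(w25, unsupported_length_mm = 3)
  expect_lt(critical_buckling_load(long)$buckling_load_mn, p)
  # free end (m -> 0) kills the load
  free <- dplyr::mutate(w25, end_condition = 0)
  expect_equal(critical_buckling_load(free)$buckling_load_mn, 0)
  # rectangular silicon shank section
  shank <- tibble::tibble(material = "silicon", elastic_modulus_gpa = 165,
                          width_um = 50, thickness_um = 15,
                          unsupported_length_mm = 3, end_condition = 1,
                          cross_section = "rectangular")
  expect_equal(critical_buckling_load(shank)$buckling_load_mn,
               pi^2 * 165e9 * (50e-6 * (15e-6)^3 / 12) / 0.003^2 * 1e3)
})

test_that("calibration report recomputes the published comparison rows", {
  rep <- calibration_report()
  expect_equal(round(rep$force_difference_pct, 2), c(20.21, 5.85, 4.54, 7.47))
  expect_equal(round(rep$loadpoint_discrepancy_pct, 2), c(2.40, 1.86, 1.99, 2.20))
  expect_equal(percent_difference(3.238, 4.058), 20.21, tolerance = 1e-3)
  expect_equal(percent_difference(5, 5), 0)
  expect_error(percent_difference(1, 0), "nonzero")
})
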