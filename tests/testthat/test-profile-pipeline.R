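test_that("trace conversion applies the calibration map channel-wise", {
  calib <- beam1_calib()
  trace <- tibble::tibble(time_s = seq(0, 1.998, by = 0.002),
                          d_c_mm = 1)
  prof <- convert_trace(trace, calib, start_index = 1)
  expect_equal(unique(prof$force_mn), 3.238)
  expect_equal(unique(prof$loadpoint_mm), 4.1789)
  # stage advances at the feed rate from contact
  expect_equal(prof$stage_mm[501], 500 * 0.002 * 100 * 1e-3)
  # all-zero trace: all derived channels zero, dimpling equals stage
  zero <- convert_trace(dplyr::mutate(trace, d_c_mm = 0), calib, start_index = 1)
  expect_true(all(zero$force_mn == 0) && all(zero$loadpoint_mm == 0))
  expect_equal(zero$dimpling_mm, zero$stage_mm)
  expect_error(convert_trace(trace[0, ], calib), "empty")
})

test_that("conversion is linear and preserves the dimpling identity", {
  sim <- simulate_insertion(membrane = quiet_pia(), seed = 11)
  calib <- beam1_calib()
  prof <- convert_trace(sim$trace, calib)
  # d_i = d_t - d_l holds exactly at every sample
  expect_equal(prof$dimpling_mm, prof$stage_mm - prof$loadpoint_mm)
  # scaling the raw reading scales force and deflection by the same factor
  scaled <- dplyr::mutate(sim$trace, d_c_mm = 2 * d_c_mm)
  for (a in c("start_index", "retraction_index", "insertion_rate_um_s")) {
    attr(scaled, a) <- attr(sim$trace, a)
  }
  prof2 <- convert_trace(scaled, calib)
  expect_equal(prof2$force_mn, 2 * prof$force_mn)
  expect_equal(prof2$loadpoint_mm, 2 * prof$loadpoint_mm)
  # stage is non-decreasing up to retraction
  ret <- attr(prof, "retraction_index")
  expect_true(all(diff(prof$stage_mm[1:ret]) >= 0))
})

test_that("round trip through the simulator recovers ground-truth force", {
  calib <- beam1_calib()
  # noiseless: recovery exact to the quantization bound
  sim <- simulate_insertion(
    membrane = quiet_pia(),
    noise = physio_noise(breathing_amplitude_mn = 0, sensor_noise_sd_um = 0),
    seed = 2)
  ev <- detect_rupture(convert_trace(sim$trace, calib))
  q_force <- 0.01 * 1e-3 * calib$force_per_laser_deflection
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$rupture_force_mn - sim$truth$rupture_force_mn),
            q_force + 0.0616 * 0.002 + 1e-12)  # quantum + one feed step
  expect_lt(abs(ev$dimpling_mm - sim$truth$dimpling_at_rupture_mm), 0.005)
  # with physiologic noise, within 3x the breathing amplitude
  sim2 <- simulate_insertion(membrane = quiet_pia(), seed = 4)
  ev2 <- detect_rupture(convert_trace(sim2$trace, calib))
  expect_lt(abs(ev2$rupture_force_mn - 3),
            3 * sim2$truth$breathing_amplitude_mn)
})

test_that("rupture detection rejects ramps, breathing and constants", {
  calib <- beam1_calib()
  # strictly increasing ramp: no event
  t <- seq(0, 60, by = 0.002)
  ramp <- tibble::tibble(time_s = t, d_c_mm = t / 60)
  expect_equal(nrow(detect_rupture(convert_trace(ramp, calib, start_index = 1))), 0)
  # breathing-only oscillation below threshold: no false positive
  free <- simulate_insertion(membrane = membrane_model("pia_only",
                                                       rupture_force_mn = Inf),
                             seed = 9)
  prof <- suppressWarnings(convert_trace(free$trace, calib))
  expect_equal(nrow(detect_rupture(prof)), 0)
  # constant profile: absent with a diagnostic
  const <- convert_trace(tibble::tibble(time_s = t, d_c_mm = 0.5), calib,
                         start_index = 1)
  out <- detect_rupture(const)
  expect_equal(nrow(out), 0)
  expect_match(attr(out, "diagnostic"), "constant")
})

test_that("outcomes classify as penetrated, buckled or invalid", {
  calib <- beam1_calib()
  pen <- simulate_insertion(membrane = quiet_pia(), seed = 21)
  expect_equal(
    classify_outcome(convert_trace(pen$trace, calib), buckling_load_mn = 34.5)$outcome,
    "penetrated")
  # rupture force above the Euler load: plateau at the critical load
  buck <- simulate_insertion(membrane = membrane_model("pia_only", rupture_force_mn = 5),
                             buckling_load_mn = 2.5, seed = 22)
  res <- classify_outcome(convert_trace(buck$trace, calib), buckling_load_mn = 2.5)
  expect_equal(res$outcome, "buckled")
  expect_lt(abs(res$plateau_force_mn - 2.5) / 2.5, 0.25)
  # flat zero-force trace: invalid
  t <- seq(0, 20, by = 0.002)
  flat <- convert_trace(tibble::tibble(time_s = t, d_c_mm = 0), calib,
                        start_index = 1)
  out <- classify_outcome(flat, buckling_load_mn = 2.5)
  expect_equal(out$outcome, "invalid")
  expect_match(out$diagnostic, "no rupture")
})

test_that("breathing oscillation is recovered from the pre-rupture segment", {
  calib <- beam1_calib()
  sim <- simulate_insertion(
    membrane = quiet_pia(),
    noise = physio_noise(breathing_period_s = 1.5, breathing_amplitude_mn = 0.1),
    seed = 31)
  br <- extract_breathing(convert_trace(sim$trace, calib))
  expect_lt(abs(br$period_s - 1.5), 0.1)
  sim2 <- simulate_insertion(
    membrane = quiet_pia(),
    noise = physio_noise(breathing_period_s = 2, breathing_amplitude_mn = 0.2),
    seed = 32)
  br2 <- extract_breathing(convert_trace(sim2$trace, calib))
  expect_lt(abs(br2$period_s - 2) / 2, 0.1)
  expect_lt(abs(br2$amplitude_mn - 0.2) / 0.2, 0.1)
  # no breathing: estimated amplitude sits at the sensor noise floor
  sim3 <- simulate_insertion(membrane = quiet_pia(),
                             noise = physio_noise(breathing_amplitude_mn = 0),
                             seed = 33)
  br3 <- extract_breathing(convert_trace(sim3$trace, calib))
  expect_lt(br3$amplitude_mn, 0.01)
  # too-short segment: empty result
  short <- convert_trace(sim$trace[1:2000, ], calib, start_index = 1001,
                         retraction_index = 2000)
  expect_equal(nrow(extract_breathing(short)), 0)
})

test_that("traces round-trip through the delimited-text format", {
  sim <- simulate_insertion(membrane = quiet_pia(), seed = 41)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(sim$trace, path)
  back <- read_trace(path)
  expect_equal(back$d_c_mm, sim$trace$d_c_mm)
  expect_equal(attr(back, "start_index"), attr(sim$trace, "start_index"))
  expect_equal(attr(back, "retraction_index"), attr(sim$trace, "retraction_index"))
  expect_equal(attr(back, "insertion_rate_um_s"), 100)
})
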