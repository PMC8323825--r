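# Independent numerical Euler-Bernoulli oracle: integrate the curvature
# M(x)/EI of a clamped cantilever under a unit tip load twice (trapezoid on
# a 10 um grid; curvature is linear in x so the first pass is exact and the
# second has O(h^2) error, far below 1e-6 relative).
eb_deflection_per_force <- function(EI, a, x_eval, h = 1e-5) {
  xs <- seq(0, a, by = h)
  curv <- (a - xs) / EI
  slope <- pracma::cumtrapz(xs, curv)
  w <- pracma::cumtrapz(xs, as.numeric(slope))
  w[match(round(x_eval / h), round(xs / h))]
}

# quiet simulator presets for deterministic tests
noiseless <- function(period = 1.5) {
  physio_noise(breathing_period_s = period, breathing_amplitude_mn = 0,
               sensor_noise_sd_um = 0, quantization_um = 0)
}

quiet_pia <- function(rupture = 3) {
  membrane_model("pia_only", rupture_force_mn = rupture)
}

beam1_calib <- function() calibration_for("beam1", "fem")

# tiny study design for fast statistical tests
small_design <- function(...) study_design(animals = 2, ...)
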