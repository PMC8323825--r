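#' Membrane and physiologic-noise models for trace simulation
#'
#' `membrane_model()` parameterizes the brain-surface membrane as a linear
#' spring of stiffness k_m resisting dimpling up to a ground-truth rupture
#' force, with a shallow friction slope governing the post-rupture force and
#' an adhesion force producing the negative dip on retraction. The linear
#' spring matches the linear force rise observed during dimpling; no
#' hyperelastic behaviour is modeled. Defaults are synthetic: the study
#' deposited no membrane constants, so stiffness values are chosen to place
#' dimpling depths in the observed qualitative range (pia ~3 mN/mm, dura
#' ~10 mN/mm).
#'
#' `physio_noise()` parameterizes what the sensor sees on top of the
#' mechanics: a breathing force oscillation with period drawn uniformly
#' from 1-2 s (anesthetized-animal respiration), Gaussian sensor noise on
#' the laser reading, and quantization at the laser resolution (0.01 um).
#'
#' @param membrane `"pia_only"` or `"dura_pia"` (selects the default
#'   stiffness and rupture scale).
#' @param stiffness_mn_mm Membrane spring stiffness k_m (mN per mm of
#'   dimpling).
#' @param rupture_force_mn Ground-truth rupture force (mN); `Inf` disables
#'   rupture (the trace saturates and is flagged).
#' @param friction_slope_mn_mm Post-rupture force per mm of insertion
#'   depth.
#' @param adhesion_force_mn Magnitude of the negative retraction dip.
#' @return A one-row tibble of model parameters.
#' @export
membrane_model <- function(membrane = c("pia_only", "dura_pia"),
                           stiffness_mn_mm = NULL,
                           rupture_force_mn = NULL,
                           friction_slope_mn_mm = 0.2,
                           adhesion_force_mn = 0.1) {
  membrane <- match.arg(membrane)
  defaults <- list(
    pia_only = list(k = 3, f = 1.5),
    dura_pia = list(k = 10, f = 15)
  )[[membrane]]
  k <- stiffness_mn_mm %||% defaults$k
  f <- rupture_force_mn %||% defaults$f
  check_positive(k, "stiffness_mn_mm")
  if (!is.infinite(f)) check_positive(f, "rupture_force_mn")
  check_nonneg(friction_slope_mn_mm, "friction_slope_mn_mm")
  check_nonneg(adhesion_force_mn, "adhesion_force_mn")
  tibble(membrane = membrane, stiffness_mn_mm = k, rupture_force_mn = f,
         friction_slope_mn_mm = friction_slope_mn_mm,
         adhesion_force_mn = adhesion_force_mn)
}

#' @rdname membrane_model
#' @param breathing_period_s Breathing period in seconds; `NULL` draws one
#'   uniformly from `[1, 2]` at simulation time.
#' @param breathing_amplitude_mn Breathing force amplitude (mN).
#' @param sensor_noise_sd_um Gaussian sensor noise standard deviation (um).
#' @param quantization_um Laser quantization step (um).
#' @export
physio_noise <- function(breathing_period_s = NULL,
                         breathing_amplitude_mn = 0.1,
                         sensor_noise_sd_um = 0.05,
                         quantization_um = 0.01) {
  if (!is.null(breathing_period_s)) check_positive(breathing_period_s, "breathing_period_s")
  check_nonneg(breathing_amplitude_mn, "breathing_amplitude_mn")
  check_nonneg(sensor_noise_sd_um, "sensor_noise_sd_um")
  check_nonneg(quantization_um, "quantization_um")
  tibble(breathing_period_s = breathing_period_s %||% NA_real_,
         breathing_amplitude_mn = breathing_amplitude_mn,
         sensor_noise_sd_um = sensor_noise_sd_um,
         quantization_um = quantization_um)
}

#' Simulate one insertion trace
#'
#' Generates the laser reading d_c(t) for one quasi-static insertion at the
#' 500 Hz sampling rate. The beam (stiffness at the load point
#' `k_b = (F_i/d_c)/(d_l/d_c)`) and the membrane spring k_m act in series
#' while the stage advances at the feed rate, so the force rises linearly
#' with stage travel at `k_eff = 1/(1/k_b + 1/k_m)` until it reaches the
#' rupture force. Rupture is instantaneous: the membrane spring vanishes,
#' the beam re-equilibrates against the shallow friction line (the stored
#' beam deflection is released into insertion depth -- the "beam rebound"),
#' and the force follows the friction slope until retraction, which ramps
#' the force down through the adhesion dip back to zero. Breathing
#' oscillation and Gaussian sensor noise are added to d_c during contact
#' and the reading is quantized to the laser resolution.
#'
#' If a `buckling_load_mn` below the rupture force is supplied, the wire
#' buckles instead: the force plateaus at the critical load (no rupture
#' drop) until retraction.
#'
#' @param beam Beam identifier (e.g. `"beam1"`) or a calibration row.
#' @param membrane A [membrane_model()] row.
#' @param noise A [physio_noise()] row.
#' @param feed_um_s Stage feed rate (um/s), 100 by default.
#' @param buckling_load_mn Optional Euler critical load of the mounted wire.
#' @param lead_in_s Pre-contact recording time (s).
#' @param plateau_s Time between rupture (or buckling-load onset) and
#'   retraction (s).
#' @param retract_after_s Optional cap on contact time: the stage reverses
#'   this many seconds after contact even if no rupture has occurred
#'   (an abandoned insertion), producing a rupture-free trace.
#' @param calibration_source Calibration used to map force to d_c.
#' @param seed Integer seed; the trace is reproducible given the seed.
#' @param laser Laser specification.
#' @return A list with elements `trace` (tibble `time_s`, `d_c_mm`, with
#'   metadata attributes) and `truth` (one-row tibble of ground-truth
#'   values: programmed rupture force, dimpling at rupture, rupture index,
#'   outcome, breathing parameters, stiffnesses, saturation flag).
#' @examples
#' sim <- simulate_insertion(seed = 1)
#' head(sim$trace)
#' sim$truth
#' @export
simulate_insertion <- function(beam = "beam1",
                               membrane = membrane_model("pia_only"),
                               noise = physio_noise(),
                               feed_um_s = 100,
                               buckling_load_mn = NULL,
                               lead_in_s = 2,
                               plateau_s = 5,
                               retract_after_s = NULL,
                               calibration_source = "fem",
                               seed = NULL,
                               laser = laser_spec()) {
  calib <- if (is.character(beam)) calibration_for(beam, calibration_source) else beam
  check_positive(feed_um_s, "feed_um_s")
  with_seed(seed, {
    dt <- 0.002
    feed <- feed_um_s * 1e-3                      # mm/s
    k_b <- calib$force_per_laser_deflection / calib$loadpoint_per_laser_deflection
    k_m <- membrane$stiffness_mn_mm
    k_eff <- 1 / (1 / k_b + 1 / k_m)
    s <- membrane$friction_slope_mn_mm
    s_eff <- if (s > 0) s * k_b / (s + k_b) else 0

    f_rupture <- membrane$rupture_force_mn
    p_crit <- buckling_load_mn %||% Inf
    buckles <- p_crit < f_rupture
    f_stop <- min(f_rupture, p_crit)

    # force reachable before the laser saturates
    f_max_laser <- calib$force_per_laser_deflection * laser$range_mm
    truncated <- is.finite(f_stop) && f_stop > f_max_laser
    if (truncated || is.infinite(f_stop)) f_stop <- f_max_laser

    t_contact <- lead_in_s
    t_stop <- t_contact + f_stop / (k_eff * feed)
    t_retract <- t_stop + plateau_s
    if (!is.null(retract_after_s)) {
      t_retract <- min(t_retract, t_contact + retract_after_s)
    }
    reached <- t_stop < t_retract
    stage_at_retract <- (t_retract - t_contact) * feed
    t_end <- t_retract + stage_at_retract / feed
    time <- seq(0, t_end, by = dt)
    n <- length(time)

    stage <- pmax(time - t_contact, 0) * feed
    # contact sample: stage is exactly zero here and grows from the next one
    idx_start <- which(time >= t_contact - dt / 2)[1]
    idx_retract <- which(time >= t_retract)[1]
    stage[idx_retract:n] <- pmax(stage_at_retract -
      (time[idx_retract:n] - t_retract) * feed, 0)

    force <- k_eff * stage
    ruptured <- reached && !buckles && !truncated && is.finite(f_rupture)
    idx_rupture <- NA_integer_
    pre <- seq_len(n) < idx_retract
    if (ruptured) {
      idx_rupture <- which(pre & force >= f_rupture)[1]
      post <- seq_len(n) >= idx_rupture & pre
      force[post] <- s_eff * stage[post]
    } else if (reached && (buckles || truncated)) {
      force[pre] <- pmin(force[pre], f_stop)
    }
    # retraction: quick unload to the adhesion dip, then linear to zero exit
    ret <- seq_len(n) >= idx_retract
    f_at_ret <- force[idx_retract - 1]
    dip <- -membrane$adhesion_force_mn
    t_rel <- time[ret] - t_retract
    unload_t <- max((f_at_ret - dip) / (k_b * feed), dt)
    force[ret] <- ifelse(
      t_rel <= unload_t,
      f_at_ret - (f_at_ret - dip) * t_rel / unload_t,
      dip * pmax(1 - (t_rel - unload_t) / pmax(t_end - t_retract - unload_t, dt), 0)
    )

    # map mechanics to the laser reading and add what the sensor sees
    d_c <- force / calib$force_per_laser_deflection
    period <- noise$breathing_period_s
    if (is.na(period)) period <- stats::runif(1, 1, 2)
    phase <- stats::runif(1, 0, 2 * pi)
    contact <- time >= t_contact & stage > 0
    breathing_mm <- noise$breathing_amplitude_mn / calib$force_per_laser_deflection
    d_c <- d_c + contact * breathing_mm * sin(2 * pi * (time - t_contact) / period + phase)
    if (noise$sensor_noise_sd_um > 0) {
      d_c <- d_c + stats::rnorm(n, 0, noise$sensor_noise_sd_um * 1e-3)
    }
    q <- noise$quantization_um * 1e-3
    if (q > 0) d_c <- round(d_c / q) * q
    saturated <- any(d_c >= laser$range_mm)
    d_c <- pmin(pmax(d_c, 0), laser$range_mm)

    trace <- structure(
      tibble(time_s = time, d_c_mm = d_c),
      beam = calib$beam %||% NA_character_,
      insertion_rate_um_s = feed_um_s,
      start_index = idx_start,
      retraction_index = as.integer(idx_retract),
      sample_period = dt,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    )
    truth <- tibble(
      beam = calib$beam %||% NA_character_,
      outcome = if (ruptured) "penetrated" else if (!reached) "no_rupture"
        else if (buckles) "buckled" else "truncated",
      rupture_force_mn = if (ruptured) f_rupture else NA_real_,
      dimpling_at_rupture_mm = if (ruptured) f_rupture / k_m else NA_real_,
      rupture_index = idx_rupture,
      start_index = idx_start,
      retraction_index = as.integer(idx_retract),
      breathing_period_s = period,
      breathing_amplitude_mn = noise$breathing_amplitude_mn,
      quantization_um = noise$quantization_um,
      k_beam_mn_mm = k_b,
      k_membrane_mn_mm = k_m,
      k_effective_mn_mm = k_eff,
      buckling_load_mn = if (is.finite(p_crit)) p_crit else NA_real_,
      saturated = saturated,
      truncated = truncated,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    )
    list(trace = trace, truth = truth)
  })
}
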