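#' Convert a laser displacement trace to a force/dimpling profile
#'
#' Converts the raw laser reading d_c (mm, sampled at 500 Hz) into the four
#' derived channels used by the insertion analysis:
#'
#' * `force_mn`      -- insertion force, `(F_i/d_c) * d_c`;
#' * `loadpoint_mm`  -- beam deflection at the microwire, `(d_l/d_c) * d_c`;
#' * `stage_mm`      -- stage travel, feed rate times elapsed time since
#'                      first membrane contact (zero before contact,
#'                      decreasing after retraction onset);
#' * `dimpling_mm`   -- tissue dimpling / insertion depth,
#'                      `stage_mm - loadpoint_mm`.
#'
#' Readings at or beyond the laser range are flagged (attribute
#' `saturated`), never silently clipped.
#'
#' @param trace A displacement trace: tibble with columns `time_s` and
#'   `d_c_mm`, e.g. from [simulate_insertion()] or [read_trace()].
#' @param calib One calibration row (see [calibration_for()]).
#' @param insertion_rate_um_s Stage feed rate; defaults to the trace
#'   attribute, else 100 um/s.
#' @param start_index Sample at which the wire first touches the membrane.
#'   Defaults to the trace attribute; if absent, the first sample whose
#'   force exceeds 3x the pre-contact noise level (see Details).
#' @param retraction_index Sample at which the stage reverses (optional;
#'   trace attribute by default).
#' @param laser Laser specification, for the saturation check.
#' @details When `start_index` must be inferred, the noise level is taken
#'   as the standard deviation of the first 0.5 s of readings and contact
#'   is the first sample exceeding 3x that level (falling back to the first
#'   sample if the trace starts already in contact).
#' @return A `force_profile` tibble: `time_s`, `d_c_mm`, `force_mn`,
#'   `loadpoint_mm`, `stage_mm`, `dimpling_mm`, with attributes
#'   `sample_period`, `start_index`, `retraction_index`, `saturated`.
#' @export
convert_trace <- function(trace, calib,
                          insertion_rate_um_s = NULL,
                          start_index = NULL,
                          retraction_index = NULL,
                          laser = laser_spec()) {
  if (!all(c("time_s", "d_c_mm") %in% names(trace))) {
    abort("`trace` needs columns `time_s` and `d_c_mm`.")
  }
  if (nrow(trace) == 0) abort("`trace` is empty.")
  check_positive(calib$force_per_laser_deflection, "force_per_laser_deflection")
  check_positive(calib$loadpoint_per_laser_deflection, "loadpoint_per_laser_deflection")

  rate <- insertion_rate_um_s %||% attr(trace, "insertion_rate_um_s") %||% 100
  start <- start_index %||% attr(trace, "start_index")
  retract <- retraction_index %||% attr(trace, "retraction_index")
  dt <- if (nrow(trace) > 1) stats::median(diff(trace$time_s)) else 0.002

  force <- calib$force_per_laser_deflection * trace$d_c_mm
  if (is.null(start)) start <- infer_start_index(force, dt)
  if (!is.null(retract) && start >= retract) {
    abort("`start_index` must precede `retraction_index`.")
  }

  n <- nrow(trace)
  elapsed <- (seq_len(n) - start) * dt
  stage <- pmax(elapsed, 0) * rate * 1e-3  # um/s * s -> mm
  if (!is.null(retract)) {
    past <- seq_len(n) > retract
    stage_at <- stage[retract]
    stage[past] <- pmax(stage_at - (seq_len(n)[past] - retract) * dt * rate * 1e-3, 0)
  }

  saturated <- any(trace$d_c_mm >= laser$range_mm)
  if (saturated) {
    warn("Trace contains readings at the laser range limit; profile flagged as saturated.")
  }

  out <- tibble(
    time_s = trace$time_s,
    d_c_mm = trace$d_c_mm,
    force_mn = force,
    loadpoint_mm = calib$loadpoint_per_laser_deflection * trace$d_c_mm,
    stage_mm = stage
  )
  out$dimpling_mm <- out$stage_mm - out$loadpoint_mm
  structure(out,
    class = c("force_profile", class(out)),
    sample_period = dt,
    start_index = as.integer(start),
    retraction_index = if (!is.null(retract)) as.integer(retract),
    saturated = saturated
  )
}

infer_start_index <- function(force, dt) {
  n_pre <- max(5L, min(length(force), round(0.5 / dt)))
  noise <- stats::sd(force[seq_len(n_pre)])
  thr <- 3 * max(noise, .Machine$double.eps)
  idx <- which(force > thr)
  if (length(idx) == 0) 1L else idx[1]
}

#' Detect the membrane rupture event in a force profile
#'
#' Membrane rupture appears as a sudden force drop: within at most
#' `drop_window` seconds the force falls by at least
#' `drop_fraction * running maximum` (and by at least `min_drop` mN, an
#' absolute floor that keeps slow physiologic breathing oscillation from
#' triggering). Only the segment before retraction onset is searched. The
#' rupture force is the running maximum immediately preceding the drop and
#' the dimpling at rupture is the dimpling channel at that maximum.
#'
#' @param profile A `force_profile` from [convert_trace()].
#' @param drop_fraction Minimum relative drop (default 0.05).
#' @param drop_window Maximum drop duration in seconds (default 0.1).
#' @param min_drop Minimum absolute drop in mN (default 0.2).
#' @return A one-row tibble (`index`, `time_s`, `rupture_force_mn`,
#'   `dimpling_mm`, `drop_mn`) or a zero-row tibble when no qualifying
#'   drop exists (with a `diagnostic` attribute saying why).
#' @export
detect_rupture <- function(profile, drop_fraction = 0.05, drop_window = 0.1,
                           min_drop = 0.2) {
  check_positive(drop_fraction, "drop_fraction")
  check_positive(drop_window, "drop_window")
  check_nonneg(min_drop, "min_drop")
  dt <- attr(profile, "sample_period") %||% 0.002
  last <- attr(profile, "retraction_index") %||% nrow(profile)
  f <- profile$force_mn[seq_len(last)]

  empty <- function(reason) {
    structure(
      tibble(index = integer(), time_s = double(), rupture_force_mn = double(),
             dimpling_mm = double(), drop_mn = double()),
      diagnostic = reason
    )
  }
  if (length(f) < 2) return(empty("profile too short"))
  if (diff(range(f)) < .Machine$double.eps^0.5) {
    return(empty("constant force profile"))
  }

  w <- max(2L, as.integer(round(drop_window / dt)) + 1L)
  runmax <- cummax(f)
  fwd_min <- roll_min_forward(f, w)
  # the fall must occur within the window (f[i] -> forward min), while the
  # relative threshold references the running maximum so far
  drop <- f - fwd_min
  needed <- pmax(drop_fraction * runmax, min_drop)
  hit <- which(drop >= needed)
  if (length(hit) == 0) return(empty("no qualifying force drop"))

  i <- hit[1]
  # top of the cliff inside the triggering window, then the running max
  # immediately preceding the drop
  win <- i:min(i + w - 1L, length(f))
  top <- win[which.max(f[win])]
  peak <- which.max(f[seq_len(top)])
  tibble(
    index = as.integer(peak),
    time_s = profile$time_s[peak],
    rupture_force_mn = f[peak],
    dimpling_mm = profile$dimpling_mm[peak],
    drop_mn = runmax[i] - fwd_min[i]
  )
}

#' Classify an insertion as penetrated, buckled or invalid
#'
#' An insertion is `penetrated` when a rupture event is detected. Without a
#' rupture it is `buckled` when the pre-retraction force plateaus (mean
#' absolute slope below `plateau_slope` over the final `plateau_window`
#' seconds) at a level within `tolerance_factor` (relative) of the wire's
#' Euler critical buckling load -- a buckled slender wire sustains roughly
#' its critical load. Anything else is `invalid`. The buckling criterion is
#' this package's construction: the source study identified buckled trials
#' from the recordings without stating a formal signature.
#'
#' @inheritParams detect_rupture
#' @param wire One wire-specification row (see [wire_registry()]); used to
#'   compute the critical load unless `buckling_load_mn` is given.
#' @param buckling_load_mn Critical load in mN, overriding `wire`.
#' @param plateau_window Seconds of trailing profile tested for flatness
#'   (default 4, at least two breathing periods).
#' @param plateau_slope Maximum fitted slope magnitude in mN/s (default 0.1).
#' @param tolerance_factor Relative band around the critical load
#'   (default 0.25).
#' @param ... Passed to [detect_rupture()].
#' @return A one-row tibble: `outcome` ("penetrated"/"buckled"/"invalid"),
#'   `rupture_force_mn`, `dimpling_mm`, `drop_mn`, `plateau_force_mn`,
#'   `diagnostic`.
#' @export
classify_outcome <- function(profile, wire = NULL, buckling_load_mn = NULL,
                             plateau_window = 4, plateau_slope = 0.1,
                             tolerance_factor = 0.25, ...) {
  event <- detect_rupture(profile, ...)
  if (nrow(event) == 1) {
    return(tibble(outcome = "penetrated",
                  rupture_force_mn = event$rupture_force_mn,
                  dimpling_mm = event$dimpling_mm,
                  drop_mn = event$drop_mn,
                  plateau_force_mn = NA_real_,
                  diagnostic = NA_character_))
  }
  p_crit <- buckling_load_mn %||% (
    if (!is.null(wire)) critical_buckling_load(wire)$buckling_load_mn
  )
  if (is.null(p_crit)) {
    abort("Provide `wire` or `buckling_load_mn` to test for buckling.")
  }
  dt <- attr(profile, "sample_period") %||% 0.002
  last <- attr(profile, "retraction_index") %||% nrow(profile)
  n_win <- min(last, max(3L, round(plateau_window / dt)))
  seg <- profile[(last - n_win + 1):last, ]
  slope <- stats::coef(stats::lm(force_mn ~ time_s, data = seg))[2]
  level <- mean(seg$force_mn)
  flat <- abs(slope) <= plateau_slope
  near_crit <- level > 0 && abs(level - p_crit) <= tolerance_factor * p_crit
  if (flat && near_crit) {
    tibble(outcome = "buckled", rupture_force_mn = NA_real_,
           dimpling_mm = NA_real_, drop_mn = NA_real_,
           plateau_force_mn = level, diagnostic = NA_character_)
  } else {
    tibble(outcome = "invalid", rupture_force_mn = NA_real_,
           dimpling_mm = NA_real_, drop_mn = NA_real_,
           plateau_force_mn = level,
           diagnostic = sprintf(
             "no rupture; plateau %s (slope %.3f mN/s), level %.3f mN vs critical %.3f mN",
             if (flat) "flat" else "not flat", slope, level, p_crit))
  }
}

#' Estimate the breathing oscillation in a force profile
#'
#' Anesthetized-animal recordings carry a 1-2 s periodic force oscillation
#' from breathing. The pre-rupture (or pre-retraction) force is linearly
#' detrended and the dominant spectral peak in the 0.2-5 Hz band is located
#' by FFT, then refined by harmonic regression on a fine frequency grid
#' around the peak bin; the amplitude is the fitted sinusoid amplitude.
#'
#' @inheritParams detect_rupture
#' @param min_duration Minimum usable segment length in seconds (default 4).
#' @param band Frequency band searched, Hz.
#' @param ... Passed to [detect_rupture()] to delimit the pre-rupture
#'   segment.
#' @return A one-row tibble (`period_s`, `amplitude_mn`), or zero rows if
#'   the segment is shorter than `min_duration`.
#' @export
extract_breathing <- function(profile, min_duration = 4, band = c(0.2, 5), ...) {
  dt <- attr(profile, "sample_period") %||% 0.002
  start <- attr(profile, "start_index") %||% 1L
  last <- attr(profile, "retraction_index") %||% nrow(profile)
  event <- detect_rupture(profile, ...)
  if (nrow(event) == 1) last <- min(last, event$index)
  if ((last - start) * dt < min_duration) {
    return(structure(tibble(period_s = double(), amplitude_mn = double()),
                     diagnostic = "pre-rupture segment shorter than `min_duration`"))
  }
  seg <- profile[start:last, ]
  detr <- stats::resid(stats::lm(force_mn ~ time_s, data = seg))
  n <- length(detr)
  spec <- Mod(stats::fft(detr))[seq_len(floor(n / 2))]
  freq <- (seq_len(floor(n / 2)) - 1) / (n * dt)
  in_band <- freq >= band[1] & freq <= band[2]
  if (!any(in_band)) {
    return(structure(tibble(period_s = double(), amplitude_mn = double()),
                     diagnostic = "no spectral support in band"))
  }
  f0 <- freq[in_band][which.max(spec[in_band])]
  df <- 1 / (n * dt)
  # refine frequency and fit amplitude by least squares around the peak bin
  grid <- seq(max(band[1], f0 - df), min(band[2], f0 + df), length.out = 41)
  t <- seg$time_s
  best <- purrr::map(grid, function(fg) {
    fit <- stats::lm(detr ~ sin(2 * pi * fg * t) + cos(2 * pi * fg * t))
    list(f = fg, rss = sum(stats::resid(fit)^2), co = stats::coef(fit))
  })
  pick <- best[[which.min(purrr::map_dbl(best, "rss"))]]
  tibble(
    period_s = 1 / pick$f,
    amplitude_mn = sqrt(pick$co[2]^2 + pick$co[3]^2)
  )
}
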