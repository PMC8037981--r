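# Synthetic two-channel chair-BCG generator.
#
# The simulator reproduces the statistical structure the estimation method
# relies on, not cardiovascular physiology: a train of Gaussian-windowed
# oscillations (one per heartbeat) recorded on a back channel, repeated on a
# seat channel after a per-beat transit delay that depends linearly (and
# negatively) on the instantaneous systolic pressure. Respiration enters as a
# low-frequency baseline plus a small amplitude modulation of the beats;
# motion artifacts as Poisson-timed high-amplitude bursts.

#' Simulation configuration for a synthetic BCG session
#'
#' Builds and validates the parameter set for [simulate_session()]. Defaults
#' describe a healthy adult at rest or recovering from treadmill exercise
#' stopped at a fraction of the age-predicted maximum heart rate (220 - age).
#'
#' @param subject_age Age in years (used only through the 220 - age rule).
#' @param resting_hr Resting heart rate, beats/min.
#' @param resting_sbp,resting_dbp Resting systolic/diastolic pressure, mmHg.
#' @param session `"rest"` or `"recovery"`.
#' @param duration_s Recording length in seconds. Defaults to 50 s (5 epochs)
#'   at rest and 100 s (10 epochs) in recovery.
#' @param fs Sampling rate, Hz.
#' @param recovery_hr_peak_frac Fraction of maximum heart rate reached at the
#'   end of exercise; the recovery session starts there.
#' @param recovery_tau_s Exponential time constant (seconds) with which heart
#'   rate and blood pressure decay back to rest.
#' @param delta_sbp,delta_dbp Pressure elevation (mmHg) at recovery start;
#'   `delta_dbp` defaults to `delta_sbp / 3`.
#' @param transit_base_ms Inter-channel beat transit delay at resting SBP, ms.
#' @param transit_slope_ms_per_mmhg Delay change per mmHg of SBP; negative,
#'   because higher pressure stiffens the arterial path and shortens transit.
#' @param resp_freq_hz Respiration frequency, Hz.
#' @param resp_baseline_amp Amplitude of the additive respiratory baseline,
#'   in units of the unit-peak beat waveform.
#' @param resp_am_frac Fractional amplitude modulation of beats by respiration.
#' @param noise_sd Additive white-noise standard deviation per channel.
#' @param motion_burst_rate Motion-artifact bursts per minute (0.5 s each).
#'   Defaults to 0 at rest and 2/min in recovery.
#' @param beat_jitter_sd Gaussian jitter of beat onsets, seconds.
#' @param wavelet_freq_hz,wavelet_width_s Centre frequency and Gaussian width
#'   of the per-beat waveform; see [bcg_wavelet()].
#' @param epoch_s Reference-epoch length, seconds.
#' @param seed Integer seed; the same configuration reproduces the same
#'   recording bit for bit.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(subject_age = 35,
                       resting_hr = 65,
                       resting_sbp = 115,
                       resting_dbp = 75,
                       session = c("rest", "recovery"),
                       duration_s = NULL,
                       fs = 100,
                       recovery_hr_peak_frac = 0.8,
                       recovery_tau_s = 120,
                       delta_sbp = 40,
                       delta_dbp = delta_sbp / 3,
                       transit_base_ms = 30,
                       transit_slope_ms_per_mmhg = -0.5,
                       resp_freq_hz = 0.25,
                       resp_baseline_amp = 0.3,
                       resp_am_frac = 0.03,
                       noise_sd = 0.05,
                       motion_burst_rate = NULL,
                       beat_jitter_sd = 0.005,
                       wavelet_freq_hz = 3,
                       wavelet_width_s = 0.15,
                       epoch_s = 10,
                       seed = 1L) {
  session <- match.arg(session)
  if (is.null(duration_s)) duration_s <- if (session == "rest") 50 else 100
  if (is.null(motion_burst_rate)) {
    motion_burst_rate <- if (session == "rest") 0 else 2
  }
  cfg <- list(
    subject_age = subject_age, resting_hr = resting_hr,
    resting_sbp = resting_sbp, resting_dbp = resting_dbp,
    session = session, duration_s = duration_s, fs = fs,
    recovery_hr_peak_frac = recovery_hr_peak_frac,
    recovery_tau_s = recovery_tau_s,
    delta_sbp = delta_sbp, delta_dbp = delta_dbp,
    transit_base_ms = transit_base_ms,
    transit_slope_ms_per_mmhg = transit_slope_ms_per_mmhg,
    resp_freq_hz = resp_freq_hz, resp_baseline_amp = resp_baseline_amp,
    resp_am_frac = resp_am_frac, noise_sd = noise_sd,
    motion_burst_rate = motion_burst_rate,
    beat_jitter_sd = beat_jitter_sd,
    wavelet_freq_hz = wavelet_freq_hz, wavelet_width_s = wavelet_width_s,
    epoch_s = epoch_s, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$fs > 0, cfg$duration_s > 0,
    cfg$recovery_hr_peak_frac > 0, cfg$recovery_hr_peak_frac <= 1,
    cfg$resting_sbp > cfg$resting_dbp, cfg$resting_dbp > 0,
    cfg$transit_base_ms > 0, cfg$noise_sd >= 0,
    cfg$motion_burst_rate >= 0, cfg$epoch_s > 0
  )
  if (cfg$duration_s < cfg$epoch_s) {
    stop("duration_s (", cfg$duration_s, " s) is shorter than one epoch (",
         cfg$epoch_s, " s)", call. = FALSE)
  }
  # transit delay must stay positive over the BP range this config can reach
  sbp_max <- cfg$resting_sbp + max(0, cfg$delta_sbp) *
    (cfg$session == "recovery")
  d_min <- cfg$transit_base_ms +
    cfg$transit_slope_ms_per_mmhg * (sbp_max - cfg$resting_sbp)
  if (d_min <= 0) {
    stop("transit delay becomes non-positive at peak SBP (", d_min,
         " ms); adjust transit_base_ms or the slope", call. = FALSE)
  }
  invisible(cfg)
}

# Deterministic sub-stream seed derivation: one top-level seed fans out to
# independent component seeds (beats, noise, artifacts, ...).
derive_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 7919 + 104729 * idx) %% 2147483629)
}

#' Beat onset times from a heart-rate trajectory
#'
#' Places beat onsets by integrating the instantaneous rate: the k-th beat
#' falls where the cumulative number of beats `integral hr(t)/60 dt` crosses k
#' (k = 0, 1, ...), with optional Gaussian timing jitter.
#'
#' @param hr_trajectory Function mapping time (s) to heart rate (beats/min);
#'   must be positive over the whole recording.
#' @param duration_s Length of the recording, seconds.
#' @param seed Integer seed for the jitter stream.
#' @param jitter_sd Standard deviation of beat-time jitter, seconds.
#' @return Numeric vector of beat onset times in `[0, duration_s)`.
#' @export
beat_times <- function(hr_trajectory, duration_s, seed = 1L, jitter_sd = 0) {
  dt <- 1e-3
  tg <- seq(0, duration_s, by = dt)
  hr <- hr_trajectory(tg)
  if (any(!is.finite(hr)) || any(hr <= 0)) {
    stop("heart-rate trajectory must be positive and finite over [0, duration_s]",
         call. = FALSE)
  }
  # cumulative beat count by trapezoidal integration of hr/60
  cum <- c(0, cumsum((hr[-1] + hr[-length(hr)]) / 2 * dt / 60))
  n_beats <- floor(cum[length(cum)] - 1e-12) + 1  # crossings of 0,1,...
  k <- seq_len(n_beats) - 1
  # invert the monotone cumulative count by linear interpolation
  times <- stats::approx(cum, tg, xout = k, ties = "ordered")$y
  if (jitter_sd > 0) {
    times <- with_seed(derive_seed(seed, 1L), {
      times + stats::rnorm(length(times), 0, jitter_sd)
    })
    times <- sort(pmin(pmax(times, 0), duration_s - 1e-9))
  }
  times[times < duration_s]
}

#' Gaussian-windowed beat waveform template
#'
#' A unit-peak, Gaussian-enveloped cosine that stands in for the I-J-K
#' complex of a ballistocardiogram heartbeat. Its spectrum is a Gaussian
#' centred on `center_freq_hz`, so with the default centre it sits inside the
#' 0.5-6 Hz cardiac analysis band.
#'
#' @param fs Sampling rate, Hz.
#' @param center_freq_hz Centre frequency, Hz; must lie in `[0.5, 6]`.
#' @param width_s Gaussian envelope standard deviation, seconds.
#' @return Numeric vector sampling the template on `[-4, 4]` envelope widths.
#' @export
bcg_wavelet <- function(fs, center_freq_hz = 3, width_s = 0.15) {
  if (center_freq_hz < 0.5 || center_freq_hz > 6) {
    stop("center_freq_hz must lie inside the 0.5-6 Hz analysis band",
         call. = FALSE)
  }
  stopifnot(width_s > 0, fs > 0)
  half <- ceiling(4 * width_s * fs)
  t <- (-half:half) / fs
  wavelet_eval(t, center_freq_hz, width_s)
}

# continuous-time evaluation so beats can be placed at sub-sample delays
wavelet_eval <- function(t, f, sigma) {
  exp(-t^2 / (2 * sigma^2)) * cos(2 * pi * f * t)
}

# run expr with a temporary RNG state, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Two-channel raw BCG recording
#'
#' @param ch_back,ch_seat Equal-length numeric sample vectors.
#' @param fs Sampling rate, Hz.
#' @param session `"rest"` or `"recovery"`.
#' @param t0 Start time, seconds.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(ch_back, ch_seat, fs, session = "rest", t0 = 0) {
  stopifnot(length(ch_back) == length(ch_seat), fs > 0)
  structure(list(ch_back = as.numeric(ch_back),
                 ch_seat = as.numeric(ch_seat),
                 fs = fs, session = session, t0 = t0),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %s session, %d samples/channel at %g Hz (%.1f s)\n",
              x$session, length(x$ch_back), x$fs, length(x$ch_back) / x$fs))
  invisible(x)
}

# Session trajectories. Rest: constants. Recovery: exponential decay from the
# exercise endpoint (heart rate from the 220-age rule) back to rest.
session_trajectories <- function(cfg) {
  if (cfg$session == "rest") {
    list(
      hr  = function(t) rep(cfg$resting_hr, length(t)),
      sbp = function(t) rep(cfg$resting_sbp, length(t)),
      dbp = function(t) rep(cfg$resting_dbp, length(t))
    )
  } else {
    hr_peak <- cfg$recovery_hr_peak_frac * (220 - cfg$subject_age)
    tau <- cfg$recovery_tau_s
    list(
      hr  = function(t) cfg$resting_hr + (hr_peak - cfg$resting_hr) * exp(-t / tau),
      sbp = function(t) cfg$resting_sbp + cfg$delta_sbp * exp(-t / tau),
      dbp = function(t) cfg$resting_dbp + cfg$delta_dbp * exp(-t / tau)
    )
  }
}

# closed-form window mean of resting + delta * exp(-t/tau) over [a, b]
decay_window_mean <- function(resting, delta, tau, a, b) {
  if (delta == 0) return(resting)
  resting + delta * tau * (exp(-a / tau) - exp(-b / tau)) / (b - a)
}

#' Simulate one two-channel BCG session with ground-truth blood pressure
#'
#' Generates a back-channel beat train and a seat channel in which every beat
#' is re-emitted after a transit delay of
#' `transit_base_ms + transit_slope_ms_per_mmhg * (SBP(t_beat) - resting_sbp)`
#' milliseconds, so the inter-channel phase relation carries the pressure
#' signal. One reference pressure pair is attached per epoch, equal to the
#' window mean of the underlying pressure trajectory.
#'
#' @param cfg A [sim_config()] object.
#' @return A list with elements `recording` (a [raw_recording()]) and `refs`
#'   (data frame with columns `epoch_start_s`, `sbp`, `dbp`).
#' @export
simulate_session <- function(cfg) {
  validate_sim_config(cfg)
  traj <- session_trajectories(cfg)
  n <- round(cfg$duration_s * cfg$fs)
  tt <- (seq_len(n) - 1) / cfg$fs

  beats <- beat_times(traj$hr, cfg$duration_s,
                      seed = derive_seed(cfg$seed, 11L),
                      jitter_sd = cfg$beat_jitter_sd)
  delays_s <- (cfg$transit_base_ms + cfg$transit_slope_ms_per_mmhg *
                 (traj$sbp(beats) - cfg$resting_sbp)) / 1000
  amps <- 1 + cfg$resp_am_frac * sin(2 * pi * cfg$resp_freq_hz * beats)

  sigma <- cfg$wavelet_width_s
  f0 <- cfg$wavelet_freq_hz
  half_w <- 4 * sigma
  place_beats <- function(onsets, amp) {
    y <- numeric(n)
    for (i in seq_along(onsets)) {
      i0 <- max(1L, ceiling((onsets[i] - half_w) * cfg$fs) + 1L)
      i1 <- min(n, floor((onsets[i] + half_w) * cfg$fs) + 1L)
      if (i1 < i0) next
      idx <- i0:i1
      y[idx] <- y[idx] + amp[i] * wavelet_eval(tt[idx] - onsets[i], f0, sigma)
    }
    y
  }
  ch_back <- place_beats(beats, amps)
  ch_seat <- place_beats(beats + delays_s, amps)

  baseline <- cfg$resp_baseline_amp * sin(2 * pi * cfg$resp_freq_hz * tt)
  ch_back <- ch_back + baseline
  ch_seat <- ch_seat + baseline

  if (cfg$noise_sd > 0) {
    ch_back <- ch_back + with_seed(derive_seed(cfg$seed, 21L),
                                   stats::rnorm(n, 0, cfg$noise_sd))
    ch_seat <- ch_seat + with_seed(derive_seed(cfg$seed, 22L),
                                   stats::rnorm(n, 0, cfg$noise_sd))
  }
  if (cfg$motion_burst_rate > 0) {
    bursts <- with_seed(derive_seed(cfg$seed, 31L), {
      n_b <- stats::rpois(1, cfg$motion_burst_rate * cfg$duration_s / 60)
      sort(stats::runif(n_b, 0, max(0, cfg$duration_s - 0.5)))
    })
    for (b in bursts) {
      idx <- which(tt >= b & tt < b + 0.5)
      ch_back[idx] <- ch_back[idx] +
        with_seed(derive_seed(cfg$seed, 41L + round(b * 1000)),
                  stats::rnorm(length(idx), 0, 5))
      ch_seat[idx] <- ch_seat[idx] +
        with_seed(derive_seed(cfg$seed, 42L + round(b * 1000)),
                  stats::rnorm(length(idx), 0, 5))
    }
  }

  n_epochs <- floor(cfg$duration_s / cfg$epoch_s)
  starts <- (seq_len(n_epochs) - 1) * cfg$epoch_s
  if (cfg$session == "rest") {
    sbp_ref <- rep(cfg$resting_sbp, n_epochs)
    dbp_ref <- rep(cfg$resting_dbp, n_epochs)
  } else {
    sbp_ref <- vapply(starts, function(a)
      decay_window_mean(cfg$resting_sbp, cfg$delta_sbp, cfg$recovery_tau_s,
                        a, a + cfg$epoch_s), numeric(1))
    dbp_ref <- vapply(starts, function(a)
      decay_window_mean(cfg$resting_dbp, cfg$delta_dbp, cfg$recovery_tau_s,
                        a, a + cfg$epoch_s), numeric(1))
  }

  list(
    recording = raw_recording(ch_back, ch_seat, cfg$fs, cfg$session),
    refs = data.frame(epoch_start_s = starts, sbp = sbp_ref, dbp = dbp_ref)
  )
}

#' Write / read a recording as CSV
#'
#' Plain CSV with header `t,ch_back,ch_seat` (time in seconds).
#' @param rec A [raw_recording()].
#' @param path Output file.
#' @export
write_recording_csv <- function(rec, path) {
  n <- length(rec$ch_back)
  df <- data.frame(t = rec$t0 + (seq_len(n) - 1) / rec$fs,
                   ch_back = rec$ch_back, ch_seat = rec$ch_seat)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param session,fs Session label and sampling rate to attach on read; `fs`
#'   defaults to the median time step in the file.
#' @export
read_recording_csv <- function(path, session = "rest", fs = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("t", "ch_back", "ch_seat") %in% names(df)))
  if (is.null(fs)) fs <- 1 / stats::median(diff(df$t))
  raw_recording(df$ch_back, df$ch_seat, fs, session, t0 = df$t[1])
}

#' Write / read blood-pressure references as CSV
#'
#' Columns `epoch_start_s,sbp,dbp`.
#' @param refs Data frame of per-epoch references.
#' @param path File path.
#' @export
write_refs_csv <- function(refs, path) {
  utils::write.csv(refs[, c("epoch_start_s", "sbp", "dbp")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_refs_csv
#' @export
read_refs_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("epoch_start_s", "sbp", "dbp") %in% names(df)))
  df
}
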