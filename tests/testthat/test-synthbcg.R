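# Synthetic two-channel BCG generator

test_that("beat placement follows the integrated heart rate", {
  # constant rates: beats on a regular grid
  bt <- beat_times(function(t) rep(60, length(t)), 10, jitter_sd = 0)
  expect_equal(bt, 0:9, tolerance = 1e-9)
  bt2 <- beat_times(function(t) rep(120, length(t)), 10, jitter_sd = 0)
  expect_length(bt2, 20)
  expect_equal(diff(bt2), rep(0.5, 19), tolerance = 1e-9)

  # decaying rate: beat count matches quadrature of the rate function
  hr <- function(t) 60 + 90 * exp(-t / 30)
  bt3 <- beat_times(hr, 60, jitter_sd = 0)
  expected <- stats::integrate(function(t) hr(t) / 60, 0, 60)$value
  expect_lte(abs(length(bt3) - round(expected)), 1)
  # inter-beat intervals approximate 60/hr at the beat time
  ibi <- diff(bt3)
  expect_lt(max(abs(ibi - 60 / hr(bt3[-length(bt3)]))), 0.02)
})

test_that("beat placement rejects non-positive heart rates", {
  expect_error(beat_times(function(t) 60 - 2 * t, 60), "positive")
})

test_that("beat waveform has unit peak and the configured spectral center", {
  fs <- 100
  w <- bcg_wavelet(fs, 2, 0.25)
  expect_equal(max(w), 1)
  # dominant FFT bin at 2 Hz
  n <- length(w)
  sp <- Mod(stats::fft(w))^2
  freqs <- (seq_len(n) - 1) * fs / n
  pk <- freqs[which.max(sp[freqs <= fs / 2])]
  expect_lt(abs(pk - 2), fs / n + 1e-9)
  # energy-weighted mean frequency within 10% of the centre
  expect_lt(abs(bcgbp:::mean_frequency(w, fs) - 2) / 2, 0.1)
})

test_that("waveform -3 dB bandwidth matches the Gaussian closed form", {
  fs <- 1000  # fine grid so the interpolated bandwidth is accurate
  f0 <- 4; width <- 0.25
  w <- bcg_wavelet(fs, f0, width)
  n <- 2^15
  sp <- Mod(stats::fft(c(w, numeric(n - length(w)))))
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2
  sp <- sp[half]; freqs <- freqs[half]
  pk <- max(sp)
  above <- which(sp >= pk / sqrt(2))
  bw <- freqs[max(above)] - freqs[min(above)]
  # Gaussian envelope sigma_t = width -> sigma_f = 1/(2 pi width);
  # |W(f)| = exp(-(f-f0)^2 / (2 sigma_f^2)) -> -3 dB full width
  sigma_f <- 1 / (2 * pi * width)
  bw_expected <- 2 * sigma_f * sqrt(log(2))
  expect_lt(abs(bw - bw_expected) / bw_expected, 0.05)
})

test_that("waveform centre frequency is confined to the analysis band", {
  expect_error(bcg_wavelet(100, 0.2), "band")
  expect_error(bcg_wavelet(100, 7), "band")
})

test_that("rest session with a flat trajectory yields constant references", {
  cfg <- sim_config(session = "rest", noise_sd = 0, beat_jitter_sd = 0,
                    seed = 2)
  sim <- simulate_session(cfg)
  expect_equal(sim$refs$sbp, rep(cfg$resting_sbp, 5))
  expect_equal(sim$refs$dbp, rep(cfg$resting_dbp, 5))
  expect_length(sim$recording$ch_back, round(cfg$duration_s * cfg$fs))
})

test_that("identical config and seed reproduce the recording exactly", {
  cfg <- sim_config(session = "recovery", seed = 77)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(a$recording$ch_back, b$recording$ch_back)
  expect_identical(a$recording$ch_seat, b$recording$ch_seat)
  expect_identical(a$refs, b$refs)
})

test_that("recovery epoch means equal the quadrature of the decay curve", {
  cfg <- sim_config(session = "recovery", duration_s = 600, delta_sbp = 40,
                    recovery_tau_s = 120, noise_sd = 0, seed = 4)
  sim <- simulate_session(cfg)
  for (i in seq_len(nrow(sim$refs))) {
    a <- sim$refs$epoch_start_s[i]
    expected <- cfg$resting_sbp + 40 *
      stats::integrate(function(t) exp(-t / 120), a, a + 10)$value / 10
    expect_equal(sim$refs$sbp[i], expected, tolerance = 1e-6)
  }
})

test_that("recovery heart rate starts at the configured max-HR fraction", {
  cfg <- sim_config(subject_age = 35, session = "recovery",
                    recovery_hr_peak_frac = 0.8)
  traj <- bcgbp:::session_trajectories(cfg)
  expect_equal(traj$hr(0), 0.8 * (220 - 35))
})

test_that("epoch-mean SBP decreases strictly through a noise-free recovery", {
  cfg <- sim_config(session = "recovery", noise_sd = 0,
                    motion_burst_rate = 0, seed = 5)
  sim <- simulate_session(cfg)
  expect_true(all(diff(sim$refs$sbp) < 0))
})

test_that("the seat channel lags the back channel by the configured transit delay", {
  # noise-free: per-beat cross-correlation lag equals the delay at that
  # beat's SBP, within one sample
  cfg <- sim_config(session = "recovery", duration_s = 100, noise_sd = 0,
                    beat_jitter_sd = 0, motion_burst_rate = 0,
                    resp_baseline_amp = 0, delta_sbp = 40,
                    transit_base_ms = 40, seed = 6)
  sim <- simulate_session(cfg)
  traj <- bcgbp:::session_trajectories(cfg)
  beats <- beat_times(traj$hr, cfg$duration_s,
                      seed = bcgbp:::derive_seed(cfg$seed, 11L), jitter_sd = 0)
  fs <- cfg$fs
  n <- length(sim$recording$ch_back)
  for (tb in beats[c(5, 30, 60, 90)]) {
    idx <- round(tb * fs) + (-150:150)
    idx <- idx[idx >= 1 & idx <= n]
    xb <- sim$recording$ch_back[idx]
    xs <- sim$recording$ch_seat[idx]
    lags <- -10:10
    xc <- vapply(lags, function(L) {
      m <- length(xb)
      i <- max(1, 1 - L):min(m, m - L)
      sum(xs[i + L] * xb[i])
    }, numeric(1))
    lag_hat <- lags[which.max(xc)]
    d_true <- (cfg$transit_base_ms + cfg$transit_slope_ms_per_mmhg *
                 (traj$sbp(tb) - cfg$resting_sbp)) / 1000
    expect_lte(abs(lag_hat - d_true * fs), 1)
  }
})

test_that("at least 90% of clean beat-train energy lies in the 0.5-6 Hz band", {
  cfg <- sim_config(session = "rest", noise_sd = 0, resp_baseline_amp = 0,
                    motion_burst_rate = 0, seed = 7)
  sim <- simulate_session(cfg)
  x <- sim$recording$ch_back
  n <- length(x)
  sp <- Mod(stats::fft(x))^2
  freqs <- (seq_len(n) - 1) * cfg$fs / n
  half <- freqs <= cfg$fs / 2
  in_band <- half & freqs >= 0.5 & freqs <= 6
  expect_gte(sum(sp[in_band]) / sum(sp[half]), 0.9)
})

test_that("simulation rejects invalid configurations", {
  expect_error(sim_config(duration_s = 5), "epoch")
  expect_error(sim_config(resting_sbp = 70, resting_dbp = 80))
  expect_error(sim_config(session = "recovery", transit_base_ms = 10,
                          delta_sbp = 40, transit_slope_ms_per_mmhg = -0.5),
               "non-positive")
})

test_that("recording and reference CSVs round-trip", {
  cfg <- sim_config(session = "rest", seed = 8)
  sim <- simulate_session(cfg)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_recording_csv(sim$recording, f1)
  write_refs_csv(sim$refs, f2)
  rec <- read_recording_csv(f1, session = "rest", fs = 100)
  expect_equal(rec$ch_back, sim$recording$ch_back, tolerance = 1e-9)
  expect_equal(read_refs_csv(f2), sim$refs, tolerance = 1e-9)
})
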