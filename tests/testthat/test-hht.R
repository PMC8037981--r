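# Empirical mode decomposition and Hilbert instantaneous phase

test_that("interior extrema are located exactly, with plateau midpoints", {
  ex <- find_extrema(c(0, 1, 0))
  expect_equal(ex$maxima, 2L)
  expect_length(ex$minima, 0)

  ex <- find_extrema(seq_len(50))
  expect_length(ex$maxima, 0)
  expect_length(ex$minima, 0)

  # 2 Hz sine over 1 s: analytic extrema at 0.125/0.375/0.625/0.875 s
  fs <- 100
  t <- (0:99) / fs
  ex <- find_extrema(sin(2 * pi * 2 * t))
  expect_length(ex$maxima, 2)
  expect_length(ex$minima, 2)
  expect_lte(max(abs(ex$maxima - (c(0.125, 0.625) * fs + 1))), 1)
  expect_lte(max(abs(ex$minima - (c(0.375, 0.875) * fs + 1))), 1)

  # plateau: a flat top counts once, at its midpoint
  ex <- find_extrema(c(0, 1, 2, 2, 2, 1, 0))
  expect_equal(ex$maxima, 4L)
})

test_that("maxima and minima interleave", {
  for (seed in 1:10) {
    x <- make_bandlimited(seed, n = 500)
    ex <- find_extrema(x)
    all_ex <- sort(c(ex$maxima, ex$minima))
    kinds <- ifelse(all_ex %in% ex$maxima, "M", "m")
    expect_true(all(kinds[-1] != kinds[-length(kinds)]))
  }
})

test_that("the envelope mean is near zero for a sinusoid and shifts with it", {
  t <- (0:999) / 100
  x <- sin(2 * pi * 2 * t)
  inner <- 101:900
  m <- envelope_mean(x)
  expect_lt(max(abs(m[inner])), 0.05)
  m2 <- envelope_mean(x + 3)
  expect_lt(max(abs(m2[inner] - 3)), 0.05)
})

test_that("the envelope mean tracks the slow component of a two-tone signal", {
  t <- (0:999) / 100
  slow <- sin(2 * pi * 1 * t)
  x <- slow + 0.8 * sin(2 * pi * 5 * t)
  inner <- 101:900
  m <- envelope_mean(x)
  expect_gt(stats::cor(m[inner], slow[inner]), 0.95)
})

test_that("signals without oscillation cannot be sifted", {
  expect_error(envelope_mean(seq(0, 1, length.out = 100)), "cannot sift")
})

test_that("sifting leaves a clean sinusoid essentially unchanged", {
  t <- (0:999) / 100
  x <- sin(2 * pi * 3 * t)
  h <- sift(x)
  expect_lt(sqrt(mean((h - x)^2)) / sqrt(mean(x^2)), 0.01)
})

test_that("sifting isolates the fast tone of a two-tone signal", {
  tw <- make_two_tone(3)
  h <- sift(tw$signal)
  inner <- interior(length(h))
  expect_gt(stats::cor(h[inner], tw$tone_fast[inner]), 0.95)
  # an IMF has zero-crossing and extrema counts within one of each other
  ex <- find_extrema(h)
  zc <- sum(diff(sign(h)) != 0)
  expect_lte(abs(zc - (length(ex$maxima) + length(ex$minima))), 1)
})

test_that("decomposition stops immediately on monotone input", {
  x <- seq(0, 5, length.out = 200)
  dec <- emd_decompose(x)
  expect_equal(dec$n, 0)
  expect_identical(dec$residue, x)
})

test_that("IMFs plus residue reconstruct the input to round-off", {
  for (seed in 1:10) {
    x <- make_bandlimited(seed)
    dec <- emd_decompose(x)
    err <- max(abs(imf_reconstruct(dec) - x)) / max(abs(x))
    expect_lt(err, 1e-8)
    # decomposition ends at the cap or with a monotone-like residue
    # (monotone up to float-level ripple: oscillation amplitude beyond the
    # endpoint trend is negligible relative to the input scale)
    r <- dec$residue
    ex <- find_extrema(r)
    ripple <- diff(range(r)) - abs(r[length(r)] - r[1])
    expect_true(dec$n == sift_settings()$max_imfs ||
                  length(ex$maxima) + length(ex$minima) < 2 ||
                  ripple < 1e-9 * max(abs(x)))
  }
})

test_that("IMFs are ordered from high to low frequency on two-tone input", {
  tw <- make_two_tone(9)
  dec <- emd_decompose(tw$signal)
  expect_gte(dec$n, 2)
  f1 <- bcgbp:::mean_frequency(dec$imfs[[1]], 100)
  f2 <- bcgbp:::mean_frequency(dec$imfs[[2]], 100)
  expect_gt(f1, f2)
})

test_that("IMF(1) of clean filtered BCG sits in the cardiac band", {
  cfg <- sim_config(session = "rest", noise_sd = 0, motion_burst_rate = 0,
                    seed = 10)
  sim <- simulate_session(cfg)
  filt <- bandpass_filter(sim$recording, filter_spec(fs = 100))
  dec <- emd_decompose(filt$ch_back)
  f1 <- bcgbp:::mean_frequency(dec$imfs[[1]], 100)
  expect_gte(f1, 0.5)
  expect_lte(f1, 6)
})

test_that("IMF(1) agrees with the independent reference implementation", {
  sigs <- sapply(1:5, function(s) make_two_tone(s)$signal)
  ref <- reference_imf1(sigs)
  inner <- interior(nrow(sigs))
  for (j in seq_len(ncol(sigs))) {
    mine <- emd_decompose(sigs[, j])$imfs[[1]]
    expect_gt(stats::cor(mine[inner], ref[inner, j]), 0.99)
  }
})

test_that("instantaneous phase of a cosine advances at its angular frequency", {
  fs <- 100
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  ph <- hilbert_phase(cos(2 * pi * 2 * t), fs)
  expect_true(all(ph$phase > -pi & ph$phase <= pi))
  inner <- interior(length(t))
  u <- unwrap_phase(ph$phase)
  slope <- stats::coef(stats::lm(u[inner] ~ t[inner]))[[2]]
  expect_lt(abs(slope - 4 * pi) / (4 * pi), 0.01)
})

test_that("a quadrature pair is offset by -pi/2", {
  fs <- 100
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  pc <- hilbert_phase(cos(2 * pi * 2 * t), fs)$phase
  ps <- hilbert_phase(sin(2 * pi * 2 * t), fs)$phase
  off <- wrap_phase(ps - pc)
  inner <- interior(length(t))
  expect_lt(max(abs(off[inner] + pi / 2)), 0.05)
})

test_that("instantaneous frequency tracks a linear chirp", {
  fs <- 100
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  f0 <- 1; f1 <- 5; Tt <- 10
  x <- cos(2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * Tt)))
  fi <- instantaneous_frequency(hilbert_phase(x, fs))
  law <- f0 + (f1 - f0) * t / Tt
  inner <- interior(length(fi))
  expect_lt(max(abs(fi[inner] - law[inner]) / law[inner]), 0.05)
})

test_that("instantaneous frequency handles simple phase sequences", {
  fs <- 100
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  fi <- instantaneous_frequency(hilbert_phase(cos(2 * pi * 2 * t), fs))
  expect_length(fi, length(t) - 1)
  expect_lt(abs(stats::median(fi) - 2) / 2, 0.01)
  expect_equal(instantaneous_frequency(rep(0.3, 50), fs = 100), rep(0, 49))
})

test_that("phase wrapping is exact and round-trips through unwrap", {
  set.seed(20)
  p <- cumsum(stats::rnorm(500, 0.3, 0.2))
  w <- wrap_phase(p)
  expect_true(all(w > -pi & w <= pi))
  expect_equal(wrap_phase(unwrap_phase(w)), w, tolerance = 1e-9)
  expect_equal(wrap_phase(pi), pi)
  expect_equal(wrap_phase(-pi), pi)
})

test_that("constant input is rejected by the phase extractor", {
  expect_error(hilbert_phase(rep(1, 100), 100), "constant")
})
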