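# shared fixtures, built in code

# seeded random two-tone mixture (well-separated 1 Hz + 5 Hz) and its fast tone
make_two_tone <- function(seed, fs = 100, dur = 10) {
  set.seed(seed)
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  a <- stats::runif(1, 0.5, 1.5)
  b <- stats::runif(1, 0.5, 1.5)
  p1 <- stats::runif(1, 0, 2 * pi)
  p2 <- stats::runif(1, 0, 2 * pi)
  tone_fast <- a * sin(2 * pi * 5 * t + p1)
  list(t = t, signal = tone_fast + b * sin(2 * pi * 1 * t + p2),
       tone_fast = tone_fast)
}

# seeded band-limited random signal: sum of sinusoids inside 0.3-10 Hz
make_bandlimited <- function(seed, n = 1000, fs = 100) {
  set.seed(seed)
  t <- (seq_len(n) - 1) / fs
  f <- stats::runif(8, 0.3, 10)
  a <- stats::runif(8, 0.2, 1)
  p <- stats::runif(8, 0, 2 * pi)
  rowSums(vapply(1:8, function(i) a[i] * sin(2 * pi * f[i] * t + p[i]),
                 numeric(n)))
}

# interior 80% index window
interior <- function(n, frac = 0.8) {
  drop <- floor(n * (1 - frac) / 2)
  (drop + 1):(n - drop)
}

# steady-state amplitude of a sinusoid at freq f in a filtered record,
# by least-squares fit on an interior window
fitted_amplitude <- function(y, f, fs, window) {
  t <- (seq_along(y) - 1) / fs
  X <- cbind(sin(2 * pi * f * t[window]), cos(2 * pi * f * t[window]))
  cf <- stats::coef(stats::lm.fit(X, y[window]))
  sqrt(sum(cf^2))
}

# run the shipped independent Python EMD on a matrix of signals (columns),
# returning the matrix of first IMFs
reference_imf1 <- function(sigs) {
  script <- system.file("oracle", "emd_reference.py", package = "bcgbp")
  fin <- tempfile(fileext = ".csv")
  fout <- tempfile(fileext = ".csv")
  utils::write.table(sigs, fin, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  status <- system2("python", c(script, fin, fout))
  stopifnot(status == 0)
  as.matrix(utils::read.csv(fout, header = FALSE))
}

# tiny architecture for fast CNN unit tests
small_arch <- function() {
  architecture_spec(input_len = 16, in_channels = 2,
                    conv_filters = c(4, 6, 8), conv_kernels = c(5, 3, 3))
}

# epoch set whose SBP is an exact linear function of the seat-channel phase
# shift: both channels carry a wrapped 2.5 Hz phase ramp, the seat channel
# delayed per epoch
make_linear_phase_epochs <- function(n_epochs, seed = 1, fs = 100,
                                     len = 1000) {
  set.seed(seed)
  t <- (seq_len(len) - 1) / fs
  f0 <- 2.5
  delays <- stats::runif(n_epochs, 0, 0.04)  # 0-40 ms
  sbp <- 100 + 600 * delays                  # 100-124 mmHg, exactly linear
  pb <- t(vapply(seq_len(n_epochs), function(i)
    wrap_phase(2 * pi * f0 * t), numeric(len)))
  ps <- t(vapply(seq_len(n_epochs), function(i)
    wrap_phase(2 * pi * f0 * (t - delays[i])), numeric(len)))
  epoch_set(pb, ps, sbp, sbp - 40, session = "rest",
            subject_id = sprintf("s%02d", seq_len(n_epochs)), fs = fs)
}
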