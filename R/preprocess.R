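# Cardiac-band isolation: third-order Butterworth band-pass, 0.5-6 Hz.

#' Band-pass filter specification
#'
#' @param order Butterworth prototype order (a band-pass of order `order` has
#'   `2 * order` poles).
#' @param f_lo,f_hi Pass-band edges, Hz.
#' @param fs Sampling rate, Hz.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(order = 3, f_lo = 0.5, f_hi = 6, fs = 100) {
  stopifnot(order >= 1, f_lo > 0, f_hi > f_lo)
  if (f_hi >= fs / 2) {
    stop("f_hi (", f_hi, " Hz) must be below the Nyquist frequency ",
         fs / 2, " Hz", call. = FALSE)
  }
  structure(list(order = order, f_lo = f_lo, f_hi = f_hi, fs = fs),
            class = "filter_spec")
}

# settling length: samples spanned by the slowest pass-band time constant
settle_samples <- function(spec) ceiling(spec$fs / spec$f_lo)

# zero-phase (or single-pass) Butterworth band-pass of one channel, with
# reflect-padding of 3 settling lengths to suppress edge transients
butter_apply <- function(x, spec, zero_phase = TRUE) {
  bf <- signal::butter(spec$order,
                       c(spec$f_lo, spec$f_hi) / (spec$fs / 2),
                       type = "pass")
  # remove the mean first: DC is outside the pass-band anyway, and feeding it
  # to the filter would excite the slow low-corner transient
  x <- x - mean(x)
  n <- length(x)
  pad <- min(n - 1L, 3L * settle_samples(spec))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filter(bf, xp)
  if (zero_phase) {
    y <- rev(as.numeric(signal::filter(bf, rev(y))))
  }
  as.numeric(y)[(pad + 1):(pad + n)]
}

#' Band-pass filter a two-channel BCG recording
#'
#' Isolates the cardiac band of both channels with the same Butterworth
#' band-pass. By default the filter is applied forward and backward
#' (zero-phase), so the inter-channel phase relation that carries the
#' blood-pressure information is not skewed by filter group delay; note that
#' the two-pass application squares the magnitude response.
#'
#' @param record A [raw_recording()].
#' @param spec A [filter_spec()]; its `fs` must match the recording.
#' @param zero_phase Apply forward-backward (`TRUE`, default) or single-pass.
#' @return A filtered [raw_recording()] of the same length and rate.
#' @export
bandpass_filter <- function(record, spec = filter_spec(fs = record$fs),
                            zero_phase = TRUE) {
  stopifnot(inherits(record, "raw_recording"), inherits(spec, "filter_spec"))
  if (abs(spec$fs - record$fs) > 1e-9) {
    stop("filter_spec fs (", spec$fs, ") does not match recording fs (",
         record$fs, ")", call. = FALSE)
  }
  n <- length(record$ch_back)
  if (n <= 3 * settle_samples(spec)) {
    stop("recording too short to filter: ", n, " samples <= 3 settling ",
         "lengths (", 3 * settle_samples(spec), ")", call. = FALSE)
  }
  raw_recording(butter_apply(record$ch_back, spec, zero_phase),
                butter_apply(record$ch_seat, spec, zero_phase),
                record$fs, record$session, record$t0)
}

#' Closed-form Butterworth band-pass magnitude response
#'
#' Analytic steady-state gain of the digital Butterworth band-pass designed
#' by bilinear transform with pre-warped band edges: with
#' `w = tan(pi f / fs)` and warped edges `w_lo`, `w_hi`,
#' `|H|^2 = 1 / (1 + ((w^2 - w0^2) / (B w))^(2 order))`
#' where `w0^2 = w_lo * w_hi` and `B = w_hi - w_lo`. When `zero_phase` the
#' gain is squared (forward-backward application).
#'
#' @param f Frequencies, Hz.
#' @param spec A [filter_spec()].
#' @param zero_phase Square the magnitude (two-pass application).
#' @return Gain at each frequency.
#' @export
butter_bandpass_gain <- function(f, spec, zero_phase = TRUE) {
  w <- tan(pi * f / spec$fs)
  wlo <- tan(pi * spec$f_lo / spec$fs)
  whi <- tan(pi * spec$f_hi / spec$fs)
  w0sq <- wlo * whi
  B <- whi - wlo
  h2 <- 1 / (1 + ((w^2 - w0sq) / (B * w))^(2 * spec$order))
  h <- sqrt(h2)
  if (zero_phase) h^2 else h
}
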