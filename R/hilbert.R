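# Instantaneous phase via the analytic signal.

# analytic signal by the frequency-domain construction: zero the negative
# frequencies, double the positive ones, keep DC (and Nyquist if present)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Wrapped instantaneous phase of an intrinsic mode function
#'
#' Computes the analytic signal of the input on the full record (no
#' windowing, so no per-epoch edge artifacts) and returns its four-quadrant
#' angle, wrapped to `(-pi, pi]`. Applied to IMF(1) of a band-passed BCG
#' channel this is the cardiac instantaneous phase that the regression model
#' consumes.
#'
#' @param imf Numeric vector; must not be constant.
#' @param fs Sampling rate, Hz.
#' @return An object of class `phase_series`: list with `phase` (wrapped
#'   radians) and `fs`.
#' @export
hilbert_phase <- function(imf, fs) {
  if (stats::sd(imf) == 0 || !all(is.finite(imf))) {
    stop("cannot compute instantaneous phase of a constant or non-finite signal",
         call. = FALSE)
  }
  p <- Arg(analytic_signal(imf))
  p[p <= -pi] <- pi
  structure(list(phase = p, fs = fs), class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series> %d samples at %g Hz\n", length(x$phase), x$fs))
  invisible(x)
}

#' Wrap phase values to (-pi, pi]
#'
#' @param p Numeric vector of phases, radians.
#' @return Wrapped phases.
#' @export
wrap_phase <- function(p) {
  w <- p %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

#' Unwrap a wrapped phase sequence
#'
#' Diagnostic utility: removes the 2*pi jumps so the phase becomes a smooth
#' (for a narrow-band signal, near-linear) function of time.
#'
#' @param p Wrapped phases, radians.
#' @return Unwrapped phases.
#' @export
unwrap_phase <- function(p) {
  signal::unwrap(p)
}

#' Instantaneous frequency from a phase series
#'
#' Finite-difference derivative of the unwrapped phase divided by `2 pi`.
#'
#' @param ps A `phase_series` (or a numeric phase vector with `fs` supplied).
#' @param fs Sampling rate, Hz; taken from `ps` when it is a `phase_series`.
#' @return Numeric vector of per-sample frequencies (Hz), length one less
#'   than the input.
#' @export
instantaneous_frequency <- function(ps, fs = NULL) {
  if (inherits(ps, "phase_series")) {
    p <- ps$phase
    fs <- ps$fs
  } else {
    p <- ps
    if (is.null(fs)) stop("fs required for a bare phase vector", call. = FALSE)
  }
  stopifnot(length(p) >= 2)
  diff(unwrap_phase(p)) * fs / (2 * pi)
}

#' Instantaneous phase of both channels of a filtered recording
#'
#' Convenience wrapper: decomposes each channel with [emd_decompose()], takes
#' IMF(1), and returns its Hilbert phase. This is the per-recording feature
#' extraction step of the pipeline.
#'
#' @param record A band-passed [raw_recording()].
#' @param settings A [sift_settings()].
#' @return List with `phase_back` and `phase_seat` (`phase_series` objects).
#' @export
recording_phase <- function(record, settings = sift_settings()) {
  stopifnot(inherits(record, "raw_recording"))
  ph_one <- function(x) {
    dec <- emd_decompose(x, settings)
    if (dec$n < 1) {
      stop("no IMF extracted from channel; signal has no oscillatory content",
           call. = FALSE)
    }
    hilbert_phase(dec$imfs[[1]], record$fs)
  }
  list(phase_back = ph_one(record$ch_back),
       phase_seat = ph_one(record$ch_seat))
}
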