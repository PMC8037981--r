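# Empirical mode decomposition by envelope-mean sifting.
#
# The decomposition repeatedly subtracts the mean of the cubic-spline upper
# and lower envelopes from the running signal until the remainder behaves as
# an intrinsic mode function (IMF), peels that IMF off, and continues on the
# residue until the residue is monotone-like (fewer than two interior
# extrema). IMF(1) is the highest-frequency component and is the carrier of
# the cardiac phase used downstream.

#' Sifting settings
#'
#' @param sd_threshold Cauchy stopping threshold for one sift: stop when
#'   `sum((h_prev - h)^2) / sum(h_prev^2)` drops below it. 0.2 is the classic
#'   choice.
#' @param max_sift_iters Hard cap on sift iterations per IMF.
#' @param max_imfs Maximum number of IMFs to extract.
#' @return An object of class `sift_settings`.
#' @export
sift_settings <- function(sd_threshold = 0.2, max_sift_iters = 100,
                          max_imfs = 10) {
  stopifnot(sd_threshold > 0, max_sift_iters >= 1, max_imfs >= 1)
  structure(list(sd_threshold = sd_threshold,
                 max_sift_iters = as.integer(max_sift_iters),
                 max_imfs = as.integer(max_imfs)),
            class = "sift_settings")
}

#' Locate interior extrema of a sampled signal
#'
#' Strict interior maxima and minima. A plateau (run of equal samples) that
#' forms an extremum contributes the midpoint index of the run as a single
#' extremum.
#'
#' @param x Numeric vector, length >= 3.
#' @return List with integer vectors `maxima` and `minima`.
#' @export
find_extrema <- function(x) {
  n <- length(x)
  stopifnot(n >= 3)
  # compress runs of equal consecutive samples to their midpoints
  keep <- c(TRUE, diff(x) != 0)
  starts <- which(keep)
  ends <- c(starts[-1] - 1L, n)
  mids <- as.integer(floor((starts + ends) / 2))
  y <- x[starts]
  m <- length(y)
  if (m < 3) return(list(maxima = integer(0), minima = integer(0)))
  s <- sign(diff(y))
  i <- 2:(m - 1)
  maxima <- mids[i][s[i - 1] > 0 & s[i] < 0]
  minima <- mids[i][s[i - 1] < 0 & s[i] > 0]
  list(maxima = maxima, minima = minima)
}

# a signal can be sifted iff it still oscillates: at least one interior
# maximum and one interior minimum (>= 2 interior extrema in total)
can_sift <- function(x) {
  if (length(x) < 3) return(FALSE)
  ex <- find_extrema(x)
  length(ex$maxima) >= 1 && length(ex$minima) >= 1
}

# mirror the two extrema nearest each end about the end samples, so the
# envelope spline has support beyond the record and does not swing at edges
mirror_knots <- function(idx, vals, n) {
  k <- length(idx)
  take <- seq_len(min(2L, k))
  left_i <- 2 - idx[take]
  right_i <- 2 * n - idx[k + 1 - take]
  ord <- order(c(left_i, idx, right_i))
  xi <- c(left_i, idx, right_i)[ord]
  yi <- c(vals[take], vals, vals[k + 1 - take])[ord]
  dup <- duplicated(xi)
  list(x = xi[!dup], y = yi[!dup])
}

#' Mean of the spline envelopes of a signal
#'
#' Upper and lower envelopes are natural cubic splines through the interior
#' maxima and minima (extended by mirroring at the record edges); the result
#' is their pointwise mean, the quantity subtracted at each sift step.
#'
#' @param x Numeric vector.
#' @param settings A [sift_settings()] (reserved for envelope options).
#' @return Numeric vector `m(t)` of the same length as `x`.
#' @export
envelope_mean <- function(x, settings = sift_settings()) {
  n <- length(x)
  ex <- find_extrema(x)
  if (length(ex$maxima) < 1 || length(ex$minima) < 1) {
    stop("cannot sift: fewer than one interior maximum and minimum",
         call. = FALSE)
  }
  up <- mirror_knots(ex$maxima, x[ex$maxima], n)
  lo <- mirror_knots(ex$minima, x[ex$minima], n)
  upper <- stats::splinefun(up$x, up$y, method = "natural")(seq_len(n))
  lower <- stats::splinefun(lo$x, lo$y, method = "natural")(seq_len(n))
  (upper + lower) / 2
}

#' Extract one intrinsic mode function by sifting
#'
#' Repeatedly subtracts the envelope mean from the running signal until the
#' Cauchy criterion `sum(m^2) / sum(h^2) < sd_threshold` is met, the iteration
#' cap is reached, or the remainder stops oscillating.
#'
#' @param x Numeric vector that can be sifted (see [envelope_mean()]).
#' @param settings A [sift_settings()].
#' @return One IMF, same length as `x`.
#' @export
sift <- function(x, settings = sift_settings()) {
  h <- x
  for (it in seq_len(settings$max_sift_iters)) {
    if (!can_sift(h)) break
    m <- envelope_mean(h, settings)
    sd_k <- sum(m^2) / sum(h^2)
    h <- h - m
    if (is.na(sd_k) || sd_k < settings$sd_threshold) break
  }
  h
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions plus a monotone-like
#' residue. Extraction stops when the running residue has fewer than two
#' interior extrema (it is monotone up to a single bend) or `max_imfs` is
#' reached. The components sum back to the input exactly up to floating
#' round-off, because each IMF is literally subtracted from the running
#' residue.
#'
#' @param x Numeric vector, length >= 10.
#' @param settings A [sift_settings()].
#' @return An object of class `imf_set`: list with `imfs` (list of numeric
#'   vectors, highest frequency first), `residue`, and `n` (IMF count).
#' @export
emd_decompose <- function(x, settings = sift_settings()) {
  stopifnot(length(x) >= 10)
  residue <- as.numeric(x)
  imfs <- list()
  while (length(imfs) < settings$max_imfs && can_sift(residue)) {
    imf <- sift(residue, settings)
    if (sum(imf^2) <= 1e-24 * max(1, sum(x^2))) break
    imfs[[length(imfs) + 1]] <- imf
    residue <- residue - imf
  }
  structure(list(imfs = imfs, residue = residue, n = length(imfs)),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs + residue, %d samples\n",
              x$n, length(x$residue)))
  invisible(x)
}

#' Reconstruct the source signal from an IMF set
#'
#' @param decomp An `imf_set`.
#' @return Numeric vector: elementwise sum of all IMFs and the residue.
#' @export
imf_reconstruct <- function(decomp) {
  Reduce(`+`, decomp$imfs, decomp$residue)
}

# energy-weighted mean frequency of a signal (diagnostic used in tests and
# simulator validation)
mean_frequency <- function(x, fs) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))^2
  half <- 2:(floor(n / 2) + 1)
  fr <- (half - 1) * fs / n
  sum(fr * sp[half]) / sum(sp[half])
}
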