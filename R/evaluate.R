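# Agreement statistics between estimated and reference blood pressure.
#
# Error direction is estimated - reference throughout. The AAMI verdict
# follows the ANSI/AAMI/ISO 2013 device-agreement bounds: mean error below
# 5 mmHg in magnitude and error standard deviation below 8 mmHg.

#' Error summary for a set of blood-pressure estimates
#'
#' Mean error (ME), sample standard deviation of the errors (SD, n-1
#' denominator — the convention for agreement studies), Bland-Altman bias
#' and 95% limits of agreement (bias +/- 1.96 SD), and the AAMI verdict.
#'
#' @param estimates,references Equal-length numeric vectors, mmHg.
#' @param target,session Labels carried into the summary (e.g. `"sbp"`,
#'   `"rest"`).
#' @return An object of class `error_summary`.
#' @export
error_summary <- function(estimates, references, target = NA_character_,
                          session = NA_character_) {
  if (length(estimates) != length(references)) {
    stop("estimates and references differ in length", call. = FALSE)
  }
  n <- length(estimates)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- estimates - references
  me <- mean(d)
  sd_d <- stats::sd(d)
  verdict <- aami_check(me, sd_d)
  structure(list(n = n, me = me, sd = sd_d,
                 ba_bias = me,
                 ba_loa_low = me - 1.96 * sd_d,
                 ba_loa_high = me + 1.96 * sd_d,
                 aami_pass = verdict$pass,
                 aami_detail = verdict,
                 target = target, session = session),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("<error_summary> %s / %s: n = %d, ME = %.2f mmHg, SD = %.2f mmHg\n",
              toupper(x$target), x$session, x$n, x$me, x$sd))
  cat(sprintf("  Bland-Altman bias %.2f, LoA [%.2f, %.2f] mmHg\n",
              x$ba_bias, x$ba_loa_low, x$ba_loa_high))
  cat(sprintf("  AAMI (|ME| < 5, SD < 8): %s%s\n",
              if (x$aami_pass) "PASS" else "FAIL",
              if (x$aami_pass) "" else
                paste0(" (", paste(x$aami_detail$failed, collapse = ", "), ")")))
  invisible(x)
}

#' AAMI pass/fail verdict
#'
#' Pass requires `|me| < 5` mmHg and `sd < 8` mmHg. The magnitude of the
#' mean error is used, matching the protocol's intent for signed biases.
#'
#' @param me Mean error, mmHg.
#' @param sd Error standard deviation, mmHg.
#' @return List with `pass` (logical) and `failed` (character vector naming
#'   any violated criterion: `"ME"`, `"SD"`).
#' @export
aami_check <- function(me, sd) {
  stopifnot(is.finite(me), is.finite(sd))
  failed <- character(0)
  if (abs(me) >= 5) failed <- c(failed, "ME")
  if (sd >= 8) failed <- c(failed, "SD")
  list(pass = length(failed) == 0, failed = failed)
}

#' Bland-Altman pairs and summary
#'
#' @param estimates,references Equal-length numeric vectors, mmHg.
#' @return List with `rows` (data frame: per-pair `mean` and `difference`)
#'   and `summary` (bias and limits of agreement, consistent with
#'   [error_summary()]).
#' @export
bland_altman_table <- function(estimates, references) {
  es <- error_summary(estimates, references)
  list(rows = data.frame(mean = (estimates + references) / 2,
                         difference = estimates - references),
       summary = list(bias = es$ba_bias, loa_low = es$ba_loa_low,
                      loa_high = es$ba_loa_high, n = es$n))
}

#' Bland-Altman plot
#'
#' Per-pair difference against per-pair mean with the bias and 95% limits of
#' agreement drawn as horizontal lines.
#'
#' @param estimates,references Equal-length numeric vectors, mmHg.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(estimates, references, title = "Bland-Altman") {
  ba <- bland_altman_table(estimates, references)
  ggplot2::ggplot(ba$rows, ggplot2::aes(x = mean, y = difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = ba$summary$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(ba$summary$loa_low,
                                       ba$summary$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(title = title, x = "Mean of estimate and reference (mmHg)",
                  y = "Estimate - reference (mmHg)") +
    ggplot2::theme_minimal()
}

#' Write an error summary as a one-row CSV
#'
#' @param es An `error_summary`.
#' @param path File path.
#' @export
write_error_summary <- function(es, path) {
  utils::write.csv(data.frame(
    target = es$target, session = es$session, n = es$n,
    me = es$me, sd = es$sd, ba_bias = es$ba_bias,
    ba_loa_low = es$ba_loa_low, ba_loa_high = es$ba_loa_high,
    aami_pass = es$aami_pass), path, row.names = FALSE)
  invisible(path)
}
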