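# Feed-forward inhibition quantification: %SI, time-course assembly,
# peak / half-decay / AUC metrics.

#' Shunting-inhibition percentage
#'
#' `%SI = 100 - 100 * ap_test / ap_control`: the percentage reduction of an
#' antidromically evoked test action potential's amplitude relative to the
#' control AP. Negative values (facilitation) are not clipped.
#'
#' @param ap_test_mV test-AP amplitude(s) after a conditioning stimulus (mV).
#' @param ap_control_mV control-AP amplitude(s), > 0.
#' @return %SI, vectorized.
#' @export
percent_si <- function(ap_test_mV, ap_control_mV) {
  if (any(!is.finite(ap_control_mV)) || any(ap_control_mV <= 0))
    stop("ap_control_mV must be positive", call. = FALSE)
  100 - 100 * ap_test_mV / ap_control_mV
}

#' Single FFI probe measurement
#'
#' @param delay_ms probe delay after the conditioning stimulus (ms).
#' @param ap_test_mV,ap_control_mV test / control AP amplitudes (mV).
#' @param modality conditioning-stimulus modality.
#' @return object of class `ffi_measurement` with `si_percent` satisfying the
#'   %SI identity.
#' @export
ffi_measurement <- function(delay_ms, ap_test_mV, ap_control_mV,
                            modality = NA_character_) {
  structure(list(delay_ms = as.numeric(delay_ms),
                 ap_test_mV = as.numeric(ap_test_mV),
                 ap_control_mV = as.numeric(ap_control_mV),
                 si_percent = percent_si(ap_test_mV, ap_control_mV),
                 modality = modality),
            class = "ffi_measurement")
}

#' @export
print.ffi_measurement <- function(x, ...) {
  cat(sprintf("<ffi_measurement> %s, delay %g ms: AP %.2f / %.2f mV -> %%SI %.2f\n",
              x$modality, x$delay_ms, x$ap_test_mV, x$ap_control_mV,
              x$si_percent))
  invisible(x)
}

# coerce a list of ffi_measurement or a data frame into delay/si columns
as_ffi_table <- function(measurements) {
  if (is.data.frame(measurements)) {
    stopifnot(all(c("delay_ms", "si_percent") %in% names(measurements)))
    measurements[, c("delay_ms", "si_percent")]
  } else {
    stopifnot(is.list(measurements),
              all(vapply(measurements, inherits, TRUE, "ffi_measurement")))
    data.frame(delay_ms = vapply(measurements, `[[`, 1, "delay_ms"),
               si_percent = vapply(measurements, `[[`, 1, "si_percent"))
  }
}

#' Assemble an FFI time course
#'
#' Groups probe measurements by delay, computes the per-delay mean and SEM of
#' %SI, and derives the time-course metrics: peak %SI (earliest delay on
#' ties), time of peak, half-decay time (see [half_decay_time()]) and the
#' 0-70 ms area under the curve (see [auc_0_70()]).
#'
#' @param measurements list of [ffi_measurement()]s or a data frame with
#'   columns `delay_ms`, `si_percent`; at least 3 distinct delays.
#' @param modality conditioning modality tag.
#' @return object of class `ffi_time_course`: list with `delays_ms`,
#'   `mean_si_percent`, `sem_si_percent`, `n_per_delay`, `modality`,
#'   `peak_si_percent`, `t_peak_ms`, `t_half_ms` (absolute delay),
#'   `t_half_elapsed_ms` (from the peak), `auc_percent_ms`, `undefined`
#'   (TRUE when no half-decay crossing exists within the sampled range).
#' @export
assemble_time_course <- function(measurements, modality = NA_character_) {
  tab <- as_ffi_table(measurements)
  delays <- sort(unique(tab$delay_ms))
  if (length(delays) < 3)
    stop("need at least 3 distinct probe delays", call. = FALSE)
  mean_si <- vapply(delays, function(d) mean(tab$si_percent[tab$delay_ms == d]), 1)
  n_per <- vapply(delays, function(d) sum(tab$delay_ms == d), 1L)
  sem_si <- vapply(delays, function(d) {
    x <- tab$si_percent[tab$delay_ms == d]
    if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  }, 1)
  ipk <- which.max(mean_si)  # which.max takes the earliest delay on ties
  peak <- mean_si[ipk]
  hd <- half_decay_time(delays, mean_si)
  auc <- auc_0_70(delays, mean_si)
  structure(list(delays_ms = delays, mean_si_percent = mean_si,
                 sem_si_percent = sem_si, n_per_delay = n_per,
                 modality = modality,
                 peak_si_percent = peak, t_peak_ms = delays[ipk],
                 t_half_ms = unname(hd["t_half_ms"]),
                 t_half_elapsed_ms = unname(hd["t_half_elapsed_ms"]),
                 auc_percent_ms = auc,
                 undefined = is.na(hd["t_half_ms"])),
            class = "ffi_time_course")
}

#' @export
print.ffi_time_course <- function(x, ...) {
  cat(sprintf("<ffi_time_course> %s, %d delays in [%g, %g] ms\n",
              x$modality, length(x$delays_ms), min(x$delays_ms),
              max(x$delays_ms)))
  cat(sprintf("  peak %.2f %%SI at %g ms; half-decay %s; AUC[0,70] %.1f %%*ms\n",
              x$peak_si_percent, x$t_peak_ms,
              if (isTRUE(x$undefined)) "undefined within sampled range"
              else sprintf("at %.2f ms (%.2f ms after peak)",
                           x$t_half_ms, x$t_half_elapsed_ms),
              x$auc_percent_ms))
  invisible(x)
}

#' @export
plot.ffi_time_course <- function(x, ..., xlab = "probe delay (ms)",
                                 ylab = "%SI", type = "b") {
  plot(x$delays_ms, x$mean_si_percent, type = type, xlab = xlab, ylab = ylab, ...)
  if (!isTRUE(x$undefined))
    graphics::abline(v = x$t_half_ms, h = x$peak_si_percent / 2, lty = 3)
  invisible(x)
}

#' Half-decay time of an FFI time course
#'
#' First post-peak crossing of 50% of the peak %SI, linearly interpolated
#' between the bracketing sampled delays. Reported both as the absolute delay
#' of the crossing (`t_half_ms`, the delay-axis convention) and as time
#' elapsed since the peak (`t_half_elapsed_ms`). When the curve never falls
#' below half-peak within the sampled range, or the peak is not positive, the
#' result is `NA` (undefined-flagged, not an error).
#'
#' @param delays_ms sorted probe delays, or an `ffi_time_course`.
#' @param si_percent mean %SI at each delay (ignored when `delays_ms` is a
#'   time course).
#' @return named numeric vector `c(t_half_ms, t_half_elapsed_ms)`.
#' @export
half_decay_time <- function(delays_ms, si_percent = NULL) {
  if (inherits(delays_ms, "ffi_time_course")) {
    si_percent <- delays_ms$mean_si_percent
    delays_ms <- delays_ms$delays_ms
  }
  stopifnot(length(delays_ms) == length(si_percent),
            !is.unsorted(delays_ms))
  ipk <- which.max(si_percent)
  peak <- si_percent[ipk]
  out <- c(t_half_ms = NA_real_, t_half_elapsed_ms = NA_real_)
  if (!is.finite(peak) || peak <= 0) return(out)
  half <- peak / 2
  if (ipk < length(si_percent)) {
    after <- si_percent[ipk:length(si_percent)]
    td <- delays_ms[ipk:length(delays_ms)]
    below <- which(after <= half)
    if (length(below) > 0) {
      j <- below[1]
      t_half <- td[j - 1] + (half - after[j - 1]) * (td[j] - td[j - 1]) /
        (after[j] - after[j - 1])
      out <- c(t_half_ms = t_half, t_half_elapsed_ms = t_half - delays_ms[ipk])
    }
  }
  out
}

#' Area under the FFI time course, 0-70 ms
#'
#' Trapezoidal integral of the mean %SI over probe delays 0-70 ms. If delay 0
#' is unsampled the curve is extended with %SI = 0 at delay 0 (inhibition
#' cannot precede the stimulus); the value at 70 ms is interpolated from the
#' bracketing samples when 70 ms itself is unsampled.
#'
#' @inheritParams half_decay_time
#' @return area in percent * ms.
#' @export
auc_0_70 <- function(delays_ms, si_percent = NULL) {
  if (inherits(delays_ms, "ffi_time_course")) {
    si_percent <- delays_ms$mean_si_percent
    delays_ms <- delays_ms$delays_ms
  }
  stopifnot(length(delays_ms) == length(si_percent),
            !is.unsorted(delays_ms))
  if (all(delays_ms > 70))
    stop("no measurements at or below 70 ms", call. = FALSE)
  d <- delays_ms; s <- si_percent
  if (d[1] > 0) { d <- c(0, d); s <- c(0, s) }
  if (max(d) > 70) {
    s70 <- stats::approx(d, s, xout = 70)$y
    keep <- d < 70
    d <- c(d[keep], 70); s <- c(s[keep], s70)
  }
  keep <- d <= 70
  d <- d[keep]; s <- s[keep]
  sum(diff(d) * (utils::head(s, -1) + utils::tail(s, -1)) / 2)
}
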