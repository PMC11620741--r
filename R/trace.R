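#' Membrane-potential traces and trial recordings
#'
#' A trace is a uniformly sampled membrane-potential series in absolute mV
#' (not baseline-subtracted). Sample 0 falls at `t0_ms` relative to the first
#' stimulus event of the trial, so pre-stimulus baselines have negative times.
#'
#' @param samples_mV numeric vector of membrane potential (mV), all finite.
#' @param fs_hz sampling rate in Hz (> 0); the experiments this package
#'   targets use 25 kHz.
#' @param t0_ms time of the first sample relative to the first stimulus event.
#' @return `mcell_trace()` returns an object of class `mcell_trace`.
#' @export
mcell_trace <- function(samples_mV, fs_hz, t0_ms = 0) {
  samples_mV <- as.numeric(samples_mV)
  if (length(samples_mV) == 0) stop("trace must be non-empty", call. = FALSE)
  if (!all(is.finite(samples_mV)))
    stop("trace samples must all be finite", call. = FALSE)
  if (!is.finite(fs_hz) || fs_hz <= 0) stop("fs_hz must be > 0", call. = FALSE)
  structure(list(samples_mV = samples_mV, fs_hz = as.numeric(fs_hz),
                 t0_ms = as.numeric(t0_ms)),
            class = "mcell_trace")
}

#' Time axis of a trace
#' @param trace an [mcell_trace()].
#' @return numeric vector of sample times in ms.
#' @export
trace_time_ms <- function(trace) {
  stopifnot(inherits(trace, "mcell_trace"))
  trace$t0_ms + (seq_along(trace$samples_mV) - 1) * 1000 / trace$fs_hz
}

#' @export
print.mcell_trace <- function(x, ...) {
  t <- trace_time_ms(x)
  cat(sprintf("<mcell_trace> %d samples @ %g kHz, t = [%.2f, %.2f] ms, V in [%.2f, %.2f] mV\n",
              length(x$samples_mV), x$fs_hz / 1000, t[1], t[length(t)],
              min(x$samples_mV), max(x$samples_mV)))
  invisible(x)
}

#' @export
plot.mcell_trace <- function(x, ..., xlab = "time (ms)",
                             ylab = "membrane potential (mV)", type = "l") {
  plot(trace_time_ms(x), x$samples_mV, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Trial recording
#'
#' Bundles one trace with its stimulus protocol, per-cell metadata, the
#' suprathreshold-firing flag and a trial index.
#'
#' @param trace an [mcell_trace()].
#' @param protocol a [stimulus_protocol()]; all events must fall within the
#'   trace's time span.
#' @param cell a [cell_meta()].
#' @param fired logical: did the membrane potential cross the action-potential
#'   threshold in this trial?
#' @param trial_index integer index within its condition.
#' @return an object of class `trial_recording`.
#' @export
trial_recording <- function(trace, protocol, cell, fired = FALSE,
                            trial_index = 1L) {
  stopifnot(inherits(trace, "mcell_trace"),
            inherits(protocol, "stimulus_protocol"),
            inherits(cell, "cell_meta"))
  t <- trace_time_ms(trace)
  ev <- protocol$events$time_ms
  if (length(ev) > 0 && (min(ev) < t[1] - 1e-9 || max(ev) > t[length(t)] + 1e-9))
    stop("protocol events fall outside the trace's time span", call. = FALSE)
  structure(list(trace = trace, protocol = protocol, cell = cell,
                 fired = isTRUE(fired), trial_index = as.integer(trial_index)),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> trial %d, condition '%s', fish %s (%s), fired=%s\n",
              x$trial_index, x$protocol$label, x$cell$fish_id, x$cell$cell_side,
              x$fired))
  print(x$trace)
  invisible(x)
}
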