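# Windowed quantification of single trials and trial averages.
# All windows are half-open [start, start + len) and anchored at stimulus
# event times; responses are reported above a pre-stimulus baseline.

# indices of samples with time in [from, to); tolerant to fp jitter on grid
window_idx <- function(trace, from, to) {
  t <- trace_time_ms(trace)
  which(t >= from - 1e-9 & t < to - 1e-9)
}

#' Pre-stimulus baseline
#'
#' Mean membrane potential over the `pre_window_ms` milliseconds preceding the
#' first stimulus event, i.e. samples with time in `[-pre_window_ms, 0)`.
#'
#' @param trace an [mcell_trace()] with `t0_ms <= -pre_window_ms`.
#' @param pre_window_ms baseline window length (ms), default 50.
#' @return baseline in mV.
#' @export
compute_baseline <- function(trace, pre_window_ms = 50) {
  stopifnot(inherits(trace, "mcell_trace"))
  if (trace$t0_ms > -pre_window_ms + 1e-9)
    stop("insufficient pre-stimulus data: trace must start at or before -",
         pre_window_ms, " ms", call. = FALSE)
  idx <- window_idx(trace, -pre_window_ms, 0)
  mean(trace$samples_mV[idx])
}

#' Windowed response quantification
#'
#' Mean and peak depolarization above baseline over the half-open window
#' `[start_ms, start_ms + len_ms)`. The 12-ms default is the unit of response
#' quantification used throughout: after sound onset for auditory trials and
#' after the last tectal pulse for tectal-only and multisensory trials.
#'
#' @param trace an [mcell_trace()].
#' @param start_ms window start (ms; the anchoring event time itself).
#' @param len_ms window length (ms), default 12.
#' @param baseline baseline in mV, from [compute_baseline()].
#' @return an object of class `window_quant`: list with `mean_depol_mV`,
#'   `peak_depol_mV`, `baseline_mV`, `window_start_ms`, `window_len_ms`.
#' @export
window_response <- function(trace, start_ms, len_ms = 12, baseline) {
  stopifnot(inherits(trace, "mcell_trace"), len_ms > 0)
  t <- trace_time_ms(trace)
  if (start_ms < t[1] - 1e-9 || start_ms + len_ms > t[length(t)] + 1000 / trace$fs_hz + 1e-9)
    stop("window outside trace span", call. = FALSE)
  idx <- window_idx(trace, start_ms, start_ms + len_ms)
  if (length(idx) == 0) stop("window contains no samples", call. = FALSE)
  v <- trace$samples_mV[idx] - baseline
  structure(list(mean_depol_mV = mean(v), peak_depol_mV = max(v),
                 baseline_mV = baseline, window_start_ms = start_ms,
                 window_len_ms = len_ms),
            class = "window_quant")
}

#' @export
print.window_quant <- function(x, ...) {
  cat(sprintf("<window_quant> [%g, %g) ms: mean %.3f mV, peak %.3f mV (baseline %.2f mV)\n",
              x$window_start_ms, x$window_start_ms + x$window_len_ms,
              x$mean_depol_mV, x$peak_depol_mV, x$baseline_mV))
  invisible(x)
}

#' Phasic/tonic decomposition of a train response
#'
#' Splits the response at the last tectal pulse: the tonic amplitude is the
#' membrane potential immediately before the last pulse (one sample before the
#' pulse time, 0.04 ms at 25 kHz) minus baseline; the phasic amplitude is the
#' peak within the post-last-pulse window minus that pre-pulse potential. By
#' construction `tonic + phasic` equals the peak depolarization above baseline
#' in the window.
#'
#' @param trace an [mcell_trace()].
#' @param protocol the trial's [stimulus_protocol()]; must contain at least
#'   one tectal event.
#' @param baseline baseline in mV.
#' @param window_len_ms post-pulse window length (ms), default 12.
#' @return an object of class `phasic_tonic`: list with `tonic_mV`,
#'   `phasic_mV`, `t_last_pulse_ms`.
#' @export
phasic_tonic <- function(trace, protocol, baseline, window_len_ms = 12) {
  stopifnot(inherits(trace, "mcell_trace"),
            inherits(protocol, "stimulus_protocol"))
  tec <- protocol$events[protocol$events$modality == "tectal", , drop = FALSE]
  if (nrow(tec) == 0)
    stop("protocol has no tectal event", call. = FALSE)
  t_last <- max(tec$time_ms)
  t <- trace_time_ms(trace)
  i_pulse <- which(t >= t_last - 1e-9)[1]
  if (is.na(i_pulse) || i_pulse < 2)
    stop("last pulse not within trace span", call. = FALSE)
  v_before <- trace$samples_mV[i_pulse - 1]
  wq <- window_response(trace, t_last, window_len_ms, baseline)
  structure(list(tonic_mV = v_before - baseline,
                 phasic_mV = wq$peak_depol_mV - (v_before - baseline),
                 t_last_pulse_ms = t_last),
            class = "phasic_tonic")
}

#' @export
print.phasic_tonic <- function(x, ...) {
  cat(sprintf("<phasic_tonic> tonic %.3f mV + phasic %.3f mV (last pulse at %g ms)\n",
              x$tonic_mV, x$phasic_mV, x$t_last_pulse_ms))
  invisible(x)
}

#' Lingering depolarization
#'
#' Depolarization above baseline remaining `t_ms` after stimulus onset,
#' averaged over a 1-ms neighborhood centred on `t_ms`. Used to measure the
#' residual of a first response immediately before a second stimulus in
#' paired-stimulus (prepulse) protocols.
#'
#' @param trace an [mcell_trace()].
#' @param t_ms time point (ms), default 50.
#' @param baseline baseline in mV.
#' @return lingering depolarization in mV.
#' @export
lingering_depolarization <- function(trace, t_ms = 50, baseline) {
  stopifnot(inherits(trace, "mcell_trace"))
  t <- trace_time_ms(trace)
  if (t_ms < t[1] - 1e-9 || t_ms > t[length(t)] + 1e-9)
    stop("time point outside trace span", call. = FALSE)
  idx <- window_idx(trace, t_ms - 0.5, t_ms + 0.5)
  mean(trace$samples_mV[idx]) - baseline
}

#' Action-potential detection
#'
#' A trial counts as fired when any sample strictly exceeds
#' `baseline + threshold_mV` (a sample exactly at threshold does not count).
#'
#' @param trace an [mcell_trace()].
#' @param baseline baseline in mV.
#' @param threshold_mV depolarization threshold above baseline, default 25.
#' @return list with `fired` (logical) and `t_cross_ms` (time of the first
#'   suprathreshold sample, `NA` when none).
#' @export
detect_ap <- function(trace, baseline, threshold_mV = 25) {
  stopifnot(inherits(trace, "mcell_trace"))
  over <- trace$samples_mV > baseline + threshold_mV
  if (any(over)) {
    list(fired = TRUE, t_cross_ms = trace_time_ms(trace)[which(over)[1]])
  } else {
    list(fired = FALSE, t_cross_ms = NA_real_)
  }
}

#' Average trials of one condition
#'
#' Pointwise mean trace across trials of a single condition, aligned on
#' stimulus time (all traces must share the sampling grid). Trials flagged as
#' fired are excluded first, matching the convention of averaging 5-10
#' subthreshold responses per condition before statistics.
#'
#' @param trials list of [trial_recording()]s of one condition.
#' @return list with `trace` (mean [mcell_trace()]), `n` (trials averaged) and
#'   `n_excluded` (fired trials dropped).
#' @export
average_trials <- function(trials) {
  stopifnot(is.list(trials), length(trials) > 0,
            all(vapply(trials, inherits, TRUE, "trial_recording")))
  labels <- vapply(trials, function(tr) tr$protocol$label, "")
  if (length(unique(labels)) > 1)
    stop("mixed conditions: ", paste(unique(labels), collapse = ", "),
         call. = FALSE)
  fired <- vapply(trials, function(tr) tr$fired, TRUE)
  kept <- trials[!fired]
  if (length(kept) == 0)
    stop("no subthreshold trials left to average", call. = FALSE)
  fs <- vapply(kept, function(tr) tr$trace$fs_hz, 1)
  t0 <- vapply(kept, function(tr) tr$trace$t0_ms, 1)
  ns <- vapply(kept, function(tr) length(tr$trace$samples_mV), 1L)
  if (length(unique(fs)) > 1 || diff(range(t0)) > 1e-9 || length(unique(ns)) > 1)
    stop("trials must share the sampling grid", call. = FALSE)
  n <- length(kept)
  if (n < 2 || n > 20)
    warning("averaging ", n, " trials (outside the usual 2-20 range)",
            call. = FALSE)
  m <- rowMeans(vapply(kept, function(tr) tr$trace$samples_mV,
                       numeric(ns[1])))
  list(trace = mcell_trace(m, fs[1], t0[1]), n = n,
       n_excluded = sum(fired))
}
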