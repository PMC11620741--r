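#' @useDynLib mcellmsi, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# --- synaptic kernels ------------------------------------------------------
# All kernels are normalized to unit peak so that `gain` is the peak
# conductance contributed by one event of amplitude 1.

# difference of exponentials, unit peak, 0 for t < 0
diffexp_kernel <- function(t, tau_rise, tau_decay) {
  tpk <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  norm <- exp(-tpk / tau_decay) - exp(-tpk / tau_rise)
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (exp(-t[pos] / tau_decay) - exp(-t[pos] / tau_rise)) / norm
  out
}

# (1 - exp(-t/tau_rise)) * exp(-t/tau_decay), unit peak; closed-form peak time
rise_single_decay_kernel <- function(t, tau_rise, tau_decay) {
  tpk <- tau_rise * log((tau_decay + tau_rise) / tau_rise)
  norm <- (1 - exp(-tpk / tau_rise)) * exp(-tpk / tau_decay)
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (1 - exp(-t[pos] / tau_rise)) * exp(-t[pos] / tau_decay) / norm
  out
}

# (1 - exp(-t/tau_rise)) * (w exp(-t/tau_fast) + (1-w) exp(-t/tau_slow)),
# unit peak (peak located numerically; the shape is unimodal)
rise_double_decay_kernel <- function(t, tau_rise, w, tau_fast, tau_slow) {
  f <- function(u) (1 - exp(-u / tau_rise)) *
    (w * exp(-u / tau_fast) + (1 - w) * exp(-u / tau_slow))
  norm <- stats::optimize(f, c(0, tau_slow), maximum = TRUE)$objective
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- f(t[pos]) / norm
  out
}

# FFI conductance contributed by a single event of one modality, evaluated at
# time dt after event onset (synaptic latency included here)
ffi_kernel_value <- function(modality, dt, params) {
  if (modality == "auditory") {
    k <- params$ffi_aud
    k$gain * rise_double_decay_kernel(dt - k$latency_ms, k$tau_rise_ms,
                                      k$w_fast, k$tau_fast_ms, k$tau_slow_ms)
  } else if (modality == "tectal") {
    k <- params$ffi_tec
    k$gain * rise_single_decay_kernel(dt - k$latency_ms, k$tau_rise_ms,
                                      k$tau_decay_ms)
  } else if (modality == "antidromic") {
    numeric(length(dt))
  } else {
    stop("unknown modality: ", modality, call. = FALSE)
  }
}

# --- conductance series ----------------------------------------------------

#' Conductance series container
#'
#' A uniformly sampled conductance time series (dimensionless, relative to the
#' leak conductance) on the same grid convention as [mcell_trace()].
#'
#' @param values numeric conductance values.
#' @param fs_hz sampling rate (Hz).
#' @param t0_ms time of sample 0 relative to the first stimulus event.
#' @return an object of class `conductance_series`.
#' @export
conductance_series <- function(values, fs_hz, t0_ms) {
  structure(list(values = values, fs_hz = fs_hz, t0_ms = t0_ms),
            class = "conductance_series")
}

#' @export
print.conductance_series <- function(x, ...) {
  cat(sprintf("<conductance_series> %d samples @ %g kHz, t0 %.1f ms, peak %.4g\n",
              length(x$values), x$fs_hz / 1000, x$t0_ms, max(x$values)))
  invisible(x)
}

sim_time_grid <- function(protocol, params, pre_ms, post_ms) {
  if (nrow(protocol$events) == 0)
    stop("protocol has no events", call. = FALSE)
  dt <- 1000 / params$fs_hz
  t_end <- max(protocol$events$time_ms) + post_ms
  seq(-pre_ms, t_end, by = dt)
}

#' Excitatory synaptic conductance evoked by a protocol
#'
#' Sums modality-appropriate kernels over the protocol's events, relative to
#' the leak conductance. Auditory events contribute a fast (electrotonic-like)
#' plus a slow (chemical, depolarizing-envelope) difference-of-exponentials
#' kernel; tectal pulses contribute a fast phasic kernel plus a saturating
#' tonic state that increments at each pulse as
#' `s <- s + inc * amplitude * (1 - s/saturation_level)` and decays
#' exponentially between pulses. The series spans `[-pre_ms, last event +
#' post_ms]`.
#'
#' @param protocol a non-empty [stimulus_protocol()].
#' @param params a [sim_params()].
#' @param pre_ms,post_ms padding before the first and after the last event (ms).
#' @param gain_mult multiplier applied to all excitatory gains (used for
#'   per-trial/per-cell gain jitter and stimulus-strength sweeps).
#' @return a `conductance_series` (values, `fs_hz`, `t0_ms`).
#' @export
excitatory_conductance <- function(protocol, params = sim_params(),
                                   pre_ms = 100, post_ms = 400,
                                   gain_mult = 1) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  t <- sim_time_grid(protocol, params, pre_ms, post_ms)
  g <- numeric(length(t))
  ev <- protocol$events
  bad <- setdiff(unique(ev$modality), c("auditory", "tectal", "antidromic"))
  if (length(bad) > 0) stop("unknown modality: ", bad[1], call. = FALSE)
  for (i in seq_len(nrow(ev))) {
    dt <- t - ev$time_ms[i]
    a <- ev$amplitude[i] * gain_mult
    if (ev$modality[i] == "auditory") {
      g <- g + a * (params$aud_fast$gain *
                      diffexp_kernel(dt, params$aud_fast$tau_rise_ms,
                                     params$aud_fast$tau_decay_ms) +
                    params$aud_slow$gain *
                      diffexp_kernel(dt, params$aud_slow$tau_rise_ms,
                                     params$aud_slow$tau_decay_ms))
    } else if (ev$modality[i] == "tectal") {
      g <- g + a * params$tec_phasic$gain *
        diffexp_kernel(dt, params$tec_phasic$tau_rise_ms,
                       params$tec_phasic$tau_decay_ms)
    }
  }
  # tectal tonic state: sequential per-pulse saturation recursion
  tec <- ev[ev$modality == "tectal", , drop = FALSE]
  if (nrow(tec) > 0) {
    tau <- params$tec_tonic$tau_decay_ms
    sat <- params$tec_tonic$saturation_level
    inc <- params$tec_tonic$per_pulse_increment * gain_mult
    s <- 0
    s_after <- numeric(nrow(tec))
    for (k in seq_len(nrow(tec))) {
      if (k > 1) s <- s * exp(-(tec$time_ms[k] - tec$time_ms[k - 1]) / tau)
      s <- s + inc * tec$amplitude[k] * max(0, 1 - s / sat)
      s_after[k] <- s
    }
    seg <- findInterval(t, tec$time_ms + 1e-12)  # 0 before first pulse
    in_seg <- seg > 0
    g[in_seg] <- g[in_seg] + s_after[seg[in_seg]] *
      exp(-(t[in_seg] - tec$time_ms[seg[in_seg]]) / tau)
  }
  conductance_series(g, params$fs_hz, t[1])
}

#' Feed-forward inhibitory conductance evoked by a protocol
#'
#' As [excitatory_conductance()] but with the modality-specific FFI kernels:
#' auditory FFI decays as a two-exponential mixture (fast + very slow plateau
#' component), tectal FFI as a single fast exponential; both rise with
#' `tau_rise_ms` after a fixed synaptic `latency_ms`.
#'
#' @inheritParams excitatory_conductance
#' @return a `conductance_series`.
#' @export
ffi_conductance <- function(protocol, params = sim_params(),
                            pre_ms = 100, post_ms = 400, gain_mult = 1) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  t <- sim_time_grid(protocol, params, pre_ms, post_ms)
  g <- numeric(length(t))
  ev <- protocol$events
  for (i in seq_len(nrow(ev))) {
    g <- g + ev$amplitude[i] * gain_mult *
      ffi_kernel_value(ev$modality[i], t - ev$time_ms[i], params)
  }
  conductance_series(g, params$fs_hz, t[1])
}

# pointwise FFI conductance at arbitrary times (no series allocation)
ffi_g_at <- function(protocol, params, t_ms, gain_mult = 1) {
  ev <- protocol$events
  g <- numeric(length(t_ms))
  for (i in seq_len(nrow(ev))) {
    g <- g + ev$amplitude[i] * gain_mult *
      ffi_kernel_value(ev$modality[i], t_ms - ev$time_ms[i], params)
  }
  g
}

# --- membrane integration --------------------------------------------------

#' Integrate the membrane equation
#'
#' Exponential-Euler integration of
#' `tau_m dV/dt = -(V - V_rest) - g_exc (V - E_exc) - g_ffi (V - V_rest)`
#' per sample (leak conductance 1). FFI reverses at rest, making it a pure
#' shunt: it divides depolarization without hyperpolarizing. Gaussian
#' measurement noise (`params$noise_sd_mV`) is added to the integrated voltage
#' when `seed` is given; with `seed = NULL` the trace is noise-free.
#'
#' @param g_exc,g_ffi `conductance_series` on the same time grid.
#' @param params a [sim_params()].
#' @param seed integer seed for the measurement noise, or `NULL` for none.
#' @return an [mcell_trace()].
#' @export
simulate_membrane <- function(g_exc, g_ffi, params = sim_params(), seed = NULL) {
  stopifnot(inherits(g_exc, "conductance_series"),
            inherits(g_ffi, "conductance_series"))
  if (length(g_exc$values) != length(g_ffi$values))
    stop("conductance series must have equal length", call. = FALSE)
  if (g_exc$fs_hz != g_ffi$fs_hz || abs(g_exc$t0_ms - g_ffi$t0_ms) > 1e-9)
    stop("conductance series must share sampling rate and time origin",
         call. = FALSE)
  v <- membrane_integrate(g_exc$values, g_ffi$values, 1000 / params$fs_hz,
                          params$tau_m_ms, params$V_rest_mV, params$E_exc_mV,
                          isTRUE(params$dendritic_boost$enabled),
                          params$dendritic_boost$threshold_mV,
                          params$dendritic_boost$gain)
  if (!is.null(seed) && params$noise_sd_mV > 0)
    v <- v + with_seed(seed, stats::rnorm(length(v), 0, params$noise_sd_mV))
  mcell_trace(v, params$fs_hz, g_exc$t0_ms)
}

#' Simulate one trial
#'
#' Composes conductance generation and membrane integration for one protocol
#' presentation. Per-trial variability is a lognormal multiplicative jitter
#' (sd `params$trial_gain_sd` on the log scale) applied to the excitatory and
#' FFI gains (independent draws), plus Gaussian measurement noise on the
#' voltage. Deterministic given `(protocol, params, seed)`.
#'
#' @param protocol a non-empty [stimulus_protocol()].
#' @param params a [sim_params()].
#' @param seed integer seed for this trial (see [child_seed()]).
#' @param cell a [cell_meta()]; default is a generic simulated cell resting at
#'   `params$V_rest_mV`.
#' @param trial_index stored in the [trial_recording()].
#' @param pre_ms,post_ms trace padding (ms).
#' @param gain_mult extra deterministic multiplier on excitatory gains (cell
#'   strength / stimulus intensity sweeps).
#' @return a [trial_recording()]; `fired` is `TRUE` when the voltage crosses
#'   `V_rest + params$ap_threshold_mV`.
#' @export
simulate_trial <- function(protocol, params = sim_params(), seed = 1L,
                           cell = NULL, trial_index = 1L,
                           pre_ms = 100, post_ms = 400, gain_mult = 1) {
  if (is.null(cell))
    cell <- cell_meta("sim", "left", params$V_rest_mV)
  draws <- with_seed(seed, {
    list(m_exc = exp(stats::rnorm(1, 0, params$trial_gain_sd)),
         m_ffi = exp(stats::rnorm(1, 0, params$trial_gain_sd)),
         noise_seed = sample.int(.Machine$integer.max - 1L, 1))
  })
  ge <- excitatory_conductance(protocol, params, pre_ms, post_ms,
                               gain_mult = gain_mult * draws$m_exc)
  gi <- ffi_conductance(protocol, params, pre_ms, post_ms,
                        gain_mult = draws$m_ffi)
  trace <- simulate_membrane(ge, gi, params,
                             seed = if (params$noise_sd_mV > 0) draws$noise_seed else NULL)
  fired <- any(trace$samples_mV > params$V_rest_mV + params$ap_threshold_mV)
  trial_recording(trace, protocol, cell, fired = fired,
                  trial_index = trial_index)
}

#' Simulate one FFI probe measurement
#'
#' Emulates the antidromic test-AP protocol: an antidromic action potential of
#' control amplitude `params$ap_control_mV` is evoked `delay_ms` after the
#' onset of a conditioning sensory stimulus, and its amplitude is divided by
#' the total somatic conductance: `ap_test = ap_control / (1 + g_ffi(t))`.
#' With `seed` given, per-trial FFI gain jitter and Gaussian measurement noise
#' (sd `params$noise_sd_mV`) on the test-AP amplitude are applied.
#'
#' @param cond_protocol conditioning [stimulus_protocol()] (single modality).
#' @param delay_ms probe delay after conditioning-stimulus onset (>= 0).
#' @param params a [sim_params()].
#' @param seed integer seed, or `NULL` for a noise-free measurement.
#' @return an [ffi_measurement()].
#' @export
simulate_ffi_probe <- function(cond_protocol, delay_ms, params = sim_params(),
                               seed = NULL) {
  stopifnot(inherits(cond_protocol, "stimulus_protocol"))
  if (!is.finite(delay_ms) || delay_ms < 0)
    stop("probe delay must be >= 0", call. = FALSE)
  mods <- unique(cond_protocol$events$modality)
  modality <- if (length(mods) == 1) mods else "mixed"
  t_probe <- min(cond_protocol$events$time_ms) + delay_ms
  if (is.null(seed)) {
    g <- ffi_g_at(cond_protocol, params, t_probe)
    ap_test <- params$ap_control_mV / (1 + g)
  } else {
    draws <- with_seed(seed, {
      list(m = exp(stats::rnorm(1, 0, params$trial_gain_sd)),
           eps = stats::rnorm(1, 0, params$noise_sd_mV))
    })
    g <- ffi_g_at(cond_protocol, params, t_probe, gain_mult = draws$m)
    ap_test <- params$ap_control_mV / (1 + g) + draws$eps
  }
  ffi_measurement(delay_ms, ap_test, params$ap_control_mV, modality = modality)
}

#' Analytic FFI ground truth
#'
#' Metrics implied by the noise-free FFI kernel of one modality, computed on a
#' 0.1-ms grid directly from the kernel and the conductance-divider %SI
#' formula, independently of the probe-measurement pipeline: peak %SI, time of
#' peak, first post-peak 50%-of-peak crossing (absolute delay and elapsed from
#' peak, linearly interpolated), and the trapezoidal 0-70 ms area under the
#' %SI curve.
#'
#' @param params a [sim_params()].
#' @param modality `"auditory"` or `"tectal"`.
#' @return an object of class `ffi_ground_truth`: list with `peak_si_percent`,
#'   `t_peak_ms`, `t_half_ms`, `t_half_elapsed_ms`, `auc_percent_ms`,
#'   `undefined`.
#' @export
ffi_ground_truth <- function(params = sim_params(),
                             modality = c("auditory", "tectal")) {
  modality <- match.arg(modality)
  t <- seq(0, 150, by = 0.1)
  g <- ffi_kernel_value(modality, t, params)
  si <- 100 * (1 - 1 / (1 + g))
  if (max(si) <= 0) {
    return(structure(list(peak_si_percent = 0, t_peak_ms = NA_real_,
                          t_half_ms = NA_real_, t_half_elapsed_ms = NA_real_,
                          auc_percent_ms = 0, undefined = TRUE,
                          modality = modality),
                     class = "ffi_ground_truth"))
  }
  ipk <- which.max(si)
  peak <- si[ipk]
  half <- peak / 2
  t_half <- NA_real_
  after <- si[ipk:length(si)]
  tt <- t[ipk:length(t)]
  below <- which(after <= half)
  if (length(below) > 0) {
    j <- below[1]
    # linear interpolation between the bracketing grid points
    t_half <- tt[j - 1] + (half - after[j - 1]) * (tt[j] - tt[j - 1]) /
      (after[j] - after[j - 1])
  }
  in70 <- t <= 70
  auc <- sum(diff(t[in70]) * (utils::head(si[in70], -1) + utils::tail(si[in70], -1)) / 2)
  structure(list(peak_si_percent = peak, t_peak_ms = t[ipk],
                 t_half_ms = t_half, t_half_elapsed_ms = t_half - t[ipk],
                 auc_percent_ms = auc, undefined = FALSE, modality = modality),
            class = "ffi_ground_truth")
}

#' @export
print.ffi_ground_truth <- function(x, ...) {
  cat(sprintf("<ffi_ground_truth> %s kernel\n", x$modality))
  if (isTRUE(x$undefined)) {
    cat("  zero-gain kernel: metrics undefined\n")
  } else {
    cat(sprintf("  peak %.2f %%SI at %.2f ms; half-decay at %.2f ms (%.2f ms after peak)\n",
                x$peak_si_percent, x$t_peak_ms, x$t_half_ms, x$t_half_elapsed_ms))
    cat(sprintf("  AUC[0,70] = %.1f %%*ms\n", x$auc_percent_ms))
  }
  invisible(x)
}
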