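#' Simulator parameters
#'
#' Parameters of the single-compartment conductance-based M-cell model. The
#' defaults are read from the package's calibration file
#' (`system.file("extdata", "default_params.yaml", package = "mcellmsi")`),
#' which is the single place all kernel calibration constants live. Any field
#' can be overridden; nested lists are merged field-wise, so
#' `sim_params(ffi_aud = list(gain = 0))` changes only that gain.
#'
#' Membrane: leak conductance 1 (all synaptic conductances are relative to it),
#' time constant `tau_m_ms`, rest `V_rest_mV`, excitatory reversal `E_exc_mV`.
#' FFI reverses at rest, i.e. it is a pure shunt. Excitatory kernels are
#' difference-of-exponentials normalized to unit peak; the tectal tonic state
#' increments per pulse as `s <- s + inc * (1 - s/saturation_level)` and decays
#' exponentially between pulses. The optional dendritic boost adds excitatory
#' conductance proportional to suprathreshold depolarization.
#'
#' @param ... named overrides of the default fields (scalars or nested lists).
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(...) {
  defaults <- yaml::read_yaml(system.file("extdata", "default_params.yaml",
                                          package = "mcellmsi", mustWork = TRUE))
  overrides <- list(...)
  if (length(overrides) > 0) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("sim_params overrides must be named", call. = FALSE)
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown) > 0)
      stop("unknown sim_params field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    defaults <- utils::modifyList(defaults, overrides)
  }
  validate_sim_params(structure(defaults, class = "sim_params"))
}

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  pos <- function(x, what) if (!is.numeric(x) || x <= 0)
    stop("sim_params: ", what, " must be > 0", call. = FALSE)
  pos(p$tau_m_ms, "tau_m_ms")
  if (p$fs_hz < 1000) stop("sim_params: fs_hz must be >= 1000", call. = FALSE)
  if (p$noise_sd_mV < 0) stop("sim_params: noise_sd_mV must be >= 0", call. = FALSE)
  for (k in c("aud_fast", "aud_slow", "tec_phasic", "ffi_aud", "ffi_tec")) {
    pos(p[[k]]$tau_rise_ms, paste0(k, "$tau_rise_ms"))
  }
  for (k in c("aud_fast", "aud_slow", "tec_phasic")) {
    if (p[[k]]$tau_rise_ms >= p[[k]]$tau_decay_ms)
      stop("sim_params: ", k, " requires tau_rise < tau_decay", call. = FALSE)
  }
  if (p$ffi_tec$tau_rise_ms >= p$ffi_tec$tau_decay_ms)
    stop("sim_params: ffi_tec requires tau_rise < tau_decay", call. = FALSE)
  if (p$ffi_aud$tau_rise_ms >= p$ffi_aud$tau_fast_ms ||
      p$ffi_aud$tau_fast_ms >= p$ffi_aud$tau_slow_ms)
    stop("sim_params: ffi_aud requires tau_rise < tau_fast < tau_slow",
         call. = FALSE)
  pos(p$tec_tonic$saturation_level, "tec_tonic$saturation_level")
  pos(p$tec_tonic$tau_decay_ms, "tec_tonic$tau_decay_ms")
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> single-compartment M-cell model\n")
  cat(sprintf("  membrane: tau_m %g ms, V_rest %g mV, E_exc %g mV, fs %g Hz\n",
              x$tau_m_ms, x$V_rest_mV, x$E_exc_mV, x$fs_hz))
  cat(sprintf("  aud kernels: fast g=%g (%g/%g ms), slow g=%g (%g/%g ms)\n",
              x$aud_fast$gain, x$aud_fast$tau_rise_ms, x$aud_fast$tau_decay_ms,
              x$aud_slow$gain, x$aud_slow$tau_rise_ms, x$aud_slow$tau_decay_ms))
  cat(sprintf("  tec kernels: phasic g=%g, tonic inc=%g sat=%g tau=%g ms\n",
              x$tec_phasic$gain, x$tec_tonic$per_pulse_increment,
              x$tec_tonic$saturation_level, x$tec_tonic$tau_decay_ms))
  cat(sprintf("  FFI: aud g=%g (tau_f %g, tau_s %g), tec g=%g (tau %g), latency %g ms\n",
              x$ffi_aud$gain, x$ffi_aud$tau_fast_ms, x$ffi_aud$tau_slow_ms,
              x$ffi_tec$gain, x$ffi_tec$tau_decay_ms, x$ffi_aud$latency_ms))
  cat(sprintf("  noise sd %g mV, trial gain sd %g, boost %s\n",
              x$noise_sd_mV, x$trial_gain_sd,
              if (isTRUE(x$dendritic_boost$enabled)) "on" else "off"))
  invisible(x)
}

#' Deterministic child seeds
#'
#' Splits one root seed into reproducible child seeds: the root and the index
#' path are folded through a fixed linear-congruential rule, so any trial (or
#' pipeline stage) can be re-simulated in isolation regardless of ordering.
#' Results stay in `[1, 2^31 - 2]`.
#'
#' @param root integer root seed.
#' @param ... integer indices identifying the consumer (e.g. cell, condition,
#'   trial).
#' @return an integer seed.
#' @export
child_seed <- function(root, ...) {
  m <- 2147483647  # 2^31 - 1, prime
  s <- as.numeric(root) %% m
  for (idx in c(...)) {
    # 48271 and 69621 are classic Lehmer multipliers; all arithmetic stays
    # below 2^53 so the double-precision modulo is exact
    s <- (s * 48271 + (as.numeric(idx) + 1) * 69621) %% m
  }
  as.integer(if (s == 0) 1 else s)
}

# Evaluate an expression with a fixed RNG seed, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
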