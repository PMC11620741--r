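# Shared fixtures: tiny analytic traces, noise-free parameter sets, simulated
# trial sets and synthetic ABF1 files, all built in code at test time.

# noise-free deterministic parameter set for analytic checks
quiet_params <- function(...) {
  sim_params(noise_sd_mV = 0, trial_gain_sd = 0, ...)
}

# trace from a function of time (ms), sampled on [-pre, dur] at fs
fn_trace <- function(f, pre_ms = 100, dur_ms = 200, fs_hz = 25000) {
  t <- seq(-pre_ms, dur_ms, by = 1000 / fs_hz)
  mcell_trace(f(t), fs_hz, t0_ms = -pre_ms)
}

flat_trace <- function(level = -80, ...) fn_trace(function(t) rep(level, length(t)), ...)

# quick simulated trial set for one protocol
sim_trials <- function(protocol, params, n = 3, seed0 = 100) {
  lapply(seq_len(n), function(k)
    simulate_trial(protocol, params, seed = child_seed(seed0, k),
                   trial_index = k))
}

# --- synthetic ABF1 writer --------------------------------------------------
# Minimal episodic ABF version-1 file: 2048-byte header, data from block 4.
# `sweeps` is a list of episodes; each episode is a list of per-channel
# numeric vectors (mV before unit/scale encoding). Channel scaling for int16:
# raw = value / unit_factor / (range/res) * iscale  (pgain = sgain = 1).
write_abf1 <- function(path, sweeps, channel_names = "Vm",
                       channel_units = "mV", fs_hz = 25000,
                       data_format = 1L, iscale = 0.05,
                       adc_range = 10, adc_res = 32768L) {
  n_chan <- length(channel_names)
  n_per_chan <- length(sweeps[[1]][[1]])
  per_episode <- n_per_chan * n_chan
  acq_len <- per_episode * length(sweeps)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(2048), con)  # header placeholder
  poke <- function(offset, value, what, size) {
    seek(con, where = offset, origin = "start")
    if (what == "char") writeBin(charToRaw(value), con)
    else writeBin(value, con, size = size, endian = "little")
  }
  poke(0L, "ABF ", "char")
  poke(4L, 1.83, "numeric", 4L)
  poke(8L, 5L, "integer", 2L)                 # episodic
  poke(10L, as.integer(acq_len), "integer", 4L)
  poke(16L, length(sweeps), "integer", 4L)
  poke(40L, 4L, "integer", 4L)                # data at block 4 = byte 2048
  poke(100L, as.integer(data_format), "integer", 2L)
  poke(120L, as.integer(n_chan), "integer", 2L)
  poke(122L, 1e6 / (fs_hz * n_chan), "numeric", 4L)  # multiplexed interval, us
  poke(138L, as.integer(per_episode), "integer", 4L)
  poke(244L, adc_range, "numeric", 4L)
  poke(252L, as.integer(adc_res), "integer", 4L)
  poke(378L, 0:15, "integer", 2L)             # sampling sequence
  for (i in seq_len(n_chan)) {
    nm <- substr(channel_names[i], 1, 9)
    poke(410L + (i - 1L) * 10L, nm, "char")
    un <- substr(channel_units[i], 1, 7)
    poke(602L + (i - 1L) * 8L, un, "char")
  }
  poke(922L, rep(1, 16), "numeric", 4L)       # programmable gain
  poke(1050L, rep(iscale, 16), "numeric", 4L) # instrument scale factor
  poke(1114L, rep(0, 16), "numeric", 4L)      # instrument offset
  poke(1178L, rep(1, 16), "numeric", 4L)      # signal gain
  seek(con, where = 2048, origin = "start")
  unit_factor <- function(u) {
    m <- regmatches(u, regexec("^([0-9.]*)\\s*(uV|mV|V)$", u))[[1]]
    pf <- if (nzchar(m[2])) as.numeric(m[2]) else 1
    pf * switch(m[3], uV = 1e-3, mV = 1, V = 1e3)
  }
  for (ep in sweeps) {
    inter <- matrix(NA_real_, nrow = n_chan, ncol = n_per_chan)
    for (i in seq_len(n_chan)) {
      v <- ep[[i]] / unit_factor(channel_units[i])  # value in recorded units
      inter[i, ] <- v
    }
    flat <- as.numeric(inter)
    if (data_format == 0L) {
      raw16 <- as.integer(round(flat * iscale / (adc_range / adc_res)))
      writeBin(raw16, con, size = 2L, endian = "little")
    } else {
      writeBin(flat, con, size = 4L, endian = "little")
    }
  }
  invisible(path)
}
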