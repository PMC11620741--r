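p0 <- quiet_params()

test_that("excitatory kernels: closed-form peak, build-up and extinction", {
  # phasic kernel alone peaks at exactly its gain (unit-peak normalization)
  p <- quiet_params(tec_tonic = list(per_pulse_increment = 0))
  g <- excitatory_conductance(build_tectal_train(60, 1), p)
  expect_equal(max(g$values), p$tec_phasic$gain, tolerance = 1e-4)
  # closed-form peak time of the difference of exponentials
  tr <- p$tec_phasic$tau_rise_ms; td <- p$tec_phasic$tau_decay_ms
  tpk <- tr * td / (td - tr) * log(td / tr)
  t <- g$t0_ms + (seq_along(g$values) - 1) * 1000 / g$fs_hz
  expect_equal(t[which.max(g$values)], tpk, tolerance = 0.05)

  # tonic state builds monotonically with train duration
  g_at_end <- function(d) {
    gg <- excitatory_conductance(build_tectal_train(60, d), p0, post_ms = 50)
    t <- gg$t0_ms + (seq_along(gg$values) - 1) * 1000 / gg$fs_hz
    gg$values[which.min(abs(t - (d + 10)))]
  }
  expect_gt(g_at_end(200), g_at_end(33))

  # all kernels extinguish: conductance ~ 0 at the end of the padding
  g2 <- excitatory_conductance(build_tectal_train(60, 33), p0, post_ms = 600)
  expect_lt(utils::tail(g2$values, 1), 1e-3 * max(g2$values))

  expect_error(excitatory_conductance(
    stimulus_protocol(build_auditory_pip(0)$events[0, ], "empty"), p0),
    "no events")
})

test_that("FFI kernels: modality-specific decay and zero-gain degeneracy", {
  # tectal FFI is essentially extinct 50 ms post-stimulus
  g50 <- mcellmsi:::ffi_g_at(build_tectal_train(60, 1), p0, 50)
  expect_lt(g50, 0.01 * p0$ffi_tec$gain)
  # auditory FFI retains at least a quarter of its peak at 50 ms
  tg <- seq(0, 100, by = 0.1)
  aud <- mcellmsi:::ffi_g_at(build_auditory_pip(0), p0, tg)
  expect_gte(aud[tg == 50] / max(aud), 0.25)
  # zero gain -> identically zero series
  pz <- quiet_params(ffi_aud = list(gain = 0), ffi_tec = list(gain = 0))
  gz <- ffi_conductance(build_multisensory(build_tectal_train(60, 33)), pz)
  expect_true(all(gz$values == 0))
})

test_that("membrane integrator: rest, fixed point, sublinearity, length guard", {
  n <- 5000; fs <- p0$fs_hz
  zero <- conductance_series(numeric(n), fs, 0)
  flat <- simulate_membrane(zero, zero, p0)
  expect_equal(flat$samples_mV, rep(p0$V_rest_mV, n), tolerance = 1e-9)

  # steady state under constant drive: V = V_rest + g (E - V_rest) / (1 + g)
  g <- 0.2
  const <- conductance_series(rep(g, n), fs, 0)
  v <- simulate_membrane(const, zero, p0)$samples_mV
  expect_equal(utils::tail(v, 1),
               p0$V_rest_mV + g * (p0$E_exc_mV - p0$V_rest_mV) / (1 + g),
               tolerance = 1e-6)
  # doubling the drive less than doubles the steady-state depolarization
  v2 <- simulate_membrane(conductance_series(rep(2 * g, n), fs, 0), zero,
                          p0)$samples_mV
  d1 <- utils::tail(v, 1) - p0$V_rest_mV
  d2 <- utils::tail(v2, 1) - p0$V_rest_mV
  expect_lt(d2, 2 * d1)
  # a pure shunt on its own leaves the cell at rest
  shunted <- simulate_membrane(zero, const, p0)$samples_mV
  expect_equal(utils::tail(shunted, 1), p0$V_rest_mV, tolerance = 1e-9)

  expect_error(simulate_membrane(conductance_series(numeric(10), fs, 0),
                                 conductance_series(numeric(11), fs, 0), p0),
               "equal length")
})

test_that("trial simulation is bit-identical under the same seed", {
  prm <- sim_params()  # noise and jitter on
  proto <- build_multisensory(build_tectal_train(60, 33))
  a <- simulate_trial(proto, prm, seed = 42)
  b <- simulate_trial(proto, prm, seed = 42)
  expect_identical(a$trace$samples_mV, b$trace$samples_mV)
  c <- simulate_trial(proto, prm, seed = 43)
  expect_false(identical(a$trace$samples_mV, c$trace$samples_mV))
})

test_that("calibrated defaults: pip peak, lingering, and bounded summation", {
  tr <- simulate_trial(build_auditory_pip(0), p0, seed = 1)$trace
  b <- compute_baseline(tr)
  wq <- window_response(tr, 0, 12, b)
  expect_gte(wq$peak_depol_mV, 4); expect_lte(wq$peak_depol_mV, 6)
  expect_equal(lingering_depolarization(tr, 50, b), 1.5, tolerance = 0.25)

  # multisensory response between the largest component and the sum
  train <- build_tectal_train(60, 100); lastp <- 100
  q <- function(pr, w) {
    trq <- simulate_trial(pr, p0, seed = 1)$trace
    window_response(trq, w, 12, compute_baseline(trq))$mean_depol_mV
  }
  m <- q(build_multisensory(train), lastp)
  tt <- q(train, lastp); a <- q(build_auditory_pip(0), 0)
  expect_gte(m, max(tt, a))
  expect_lte(m, tt + a)
})

test_that("FFI probe: divider arithmetic and kernel-shape recovery", {
  pz <- quiet_params(ffi_aud = list(gain = 0), ffi_tec = list(gain = 0))
  m0 <- simulate_ffi_probe(build_auditory_pip(0), 10, pz)
  expect_equal(m0$ap_test_mV, pz$ap_control_mV)
  expect_equal(m0$si_percent, 0)

  # g = 0.25 at the probe -> %SI = 100 (1 - 1/1.25) = 20, via a scaled kernel
  # evaluated exactly at its peak
  tgrid <- seq(0, 60, by = 0.01)
  gk <- mcellmsi:::ffi_g_at(build_tectal_train(60, 1), p0, tgrid)
  tpk <- tgrid[which.max(gk)]
  pscaled <- quiet_params(ffi_tec = list(gain = 0.25))
  m <- simulate_ffi_probe(build_tectal_train(60, 1), tpk, pscaled)
  expect_equal(m$si_percent, 20, tolerance = 1e-6)

  # noise-free probe sweep reproduces the kernel up to the divider nonlinearity
  delays <- seq(2, 80, by = 2)
  si <- vapply(delays, function(d)
    simulate_ffi_probe(build_auditory_pip(0), d, p0)$si_percent, 1)
  gref <- mcellmsi:::ffi_g_at(build_auditory_pip(0), p0, delays)
  expect_equal(si, 100 * (1 - 1 / (1 + gref)), tolerance = 1e-9)
  expect_error(simulate_ffi_probe(build_auditory_pip(0), -1, p0), "delay")
})

test_that("analytic FFI ground truth matches closed forms and orderings", {
  gt_tec <- ffi_ground_truth(p0, "tectal")
  gt_aud <- ffi_ground_truth(p0, "auditory")
  # auditory inhibition outlasts tectal; both peak early
  expect_gt(gt_aud$t_half_ms, gt_tec$t_half_ms)
  expect_gt(gt_aud$auc_percent_ms, gt_tec$auc_percent_ms)
  expect_gt(gt_tec$t_half_ms, gt_tec$t_peak_ms)
  # peak %SI equals the divider of the kernel peak conductance
  expect_equal(gt_tec$peak_si_percent,
               100 * (1 - 1 / (1 + p0$ffi_tec$gain)), tolerance = 1e-3)

  # small-gain single-exponential limit: elapsed half-decay ~ tau ln 2 once
  # the rise has saturated (slow rise relative to decay removed)
  psmall <- quiet_params(ffi_tec = list(gain = 0.001, tau_rise_ms = 0.1,
                                        tau_decay_ms = 9))
  gt <- ffi_ground_truth(psmall, "tectal")
  expect_equal(gt$t_half_elapsed_ms, 9 * log(2), tolerance = 0.3)

  gz <- ffi_ground_truth(quiet_params(ffi_aud = list(gain = 0)), "auditory")
  expect_true(gz$undefined)
  expect_equal(gz$peak_si_percent, 0)
})

test_that("summation is sublinear for conductance drive with boost off", {
  # windowed response to a combination never exceeds the sum of components
  combos <- list(
    list(build_auditory_pip(0), build_tectal_train(60, 1), 0),
    list(build_auditory_pip(0), build_auditory_pip(0), 50),
    list(build_tectal_train(60, 33), build_auditory_pip(0), 33),
    list(build_tectal_train(100, 100), build_tectal_train(60, 1), 50))
  for (cmb in combos) {
    both <- combine_protocols(cmb[[1]], cmb[[2]], cmb[[3]])
    t2 <- cmb[[3]]
    q <- function(pr, w) {
      tr <- simulate_trial(pr, p0, seed = 1)$trace
      window_response(tr, w, 12, compute_baseline(tr))$mean_depol_mV
    }
    r_both <- q(both, t2)
    r1 <- q(cmb[[1]], t2)   # component 1 measured in the same window
    r2 <- q(cmb[[2]], 0)
    expect_lte(r_both, r1 + r2 + 1e-6)
  }
})

test_that("child seeds are deterministic, order-free and in integer range", {
  expect_identical(child_seed(1, 2, 3), child_seed(1, 2, 3))
  expect_false(child_seed(1, 2, 3) == child_seed(1, 3, 2))
  s <- vapply(1:500, function(i) child_seed(7, i), 1L)
  expect_true(all(s >= 1 & s <= 2147483646))
  expect_equal(length(unique(s)), 500)
})
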