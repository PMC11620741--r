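test_that("baseline: flat trace, noise scaling, and missing pre-stimulus data", {
  expect_equal(compute_baseline(flat_trace(-80)), -80)
  # sd of the baseline mean ~ sigma/sqrt(n)
  set.seed(11)
  n_rep <- 200
  ests <- replicate(n_rep, {
    tr <- fn_trace(function(t) -80 + stats::rnorm(length(t), 0, 0.2),
                   pre_ms = 50, dur_ms = 1)
    compute_baseline(tr)
  })
  n_samp <- 50 * 25  # samples in the 50-ms window at 25 kHz
  expect_lt(abs(mean(ests) + 80), 3 * 0.2 / sqrt(n_samp * n_rep))
  expect_lt(stats::sd(ests), 2 * 0.2 / sqrt(n_samp))

  no_pre <- mcell_trace(rep(-80, 100), 25000, t0_ms = 0)
  expect_error(compute_baseline(no_pre), "pre-stimulus")
})

test_that("window_response: analytic cases and brute-force oracle equivalence", {
  tr <- fn_trace(function(t) ifelse(t >= 0 & t < 12, -75, -80))
  wq <- window_response(tr, 0, 12, -80)
  expect_equal(wq$mean_depol_mV, 5)
  expect_equal(wq$peak_depol_mV, 5)

  # linear ramp 0 -> 12 mV across the window: mean 6, peak 12
  ramp <- fn_trace(function(t) -80 + pmax(0, pmin(t, 12)))
  wr <- window_response(ramp, 0, 12, -80)
  expect_equal(wr$peak_depol_mV, 12, tolerance = 0.005)  # half-open window
  expect_equal(wr$mean_depol_mV, 6, tolerance = 1e-2)

  # oracle: direct loop over samples of a simulated auditory trial
  tr2 <- simulate_trial(build_auditory_pip(0), sim_params(), seed = 5)$trace
  b <- compute_baseline(tr2)
  wq2 <- window_response(tr2, 0, 12, b)
  tt <- trace_time_ms(tr2)
  keep <- tt >= -1e-9 & tt < 12 - 1e-9
  brute_mean <- sum(tr2$samples_mV[keep] - b) / sum(keep)
  expect_equal(wq2$mean_depol_mV, brute_mean, tolerance = 1e-12)
  expect_equal(wq2$peak_depol_mV, max(tr2$samples_mV[keep] - b),
               tolerance = 1e-12)

  expect_error(window_response(tr, 300, 12, -80), "outside")
})

test_that("phasic/tonic decomposition: constructed trace and identity", {
  # V = baseline + 3 just before the last pulse at 50 ms, peak baseline + 5
  tr <- fn_trace(function(t) -80 + ifelse(t < 0, 0, ifelse(t < 50, 3,
                                          ifelse(t < 62, 5, 0))), dur_ms = 100)
  proto <- combine_protocols(build_tectal_train(60, 1),
                             build_tectal_train(60, 1), 50)
  pt <- phasic_tonic(tr, proto, -80)
  expect_equal(pt$tonic_mV, 3)
  expect_equal(pt$phasic_mV, 2)

  # single pulse at t = 0 with flat pre-stimulus: tonic 0, phasic = peak
  single <- build_tectal_train(60, 1)
  tr1 <- simulate_trial(single, quiet_params(), seed = 1)$trace
  b <- compute_baseline(tr1)
  pt1 <- phasic_tonic(tr1, single, b)
  expect_equal(pt1$tonic_mV, 0, tolerance = 1e-9)
  expect_equal(pt1$phasic_mV, window_response(tr1, 0, 12, b)$peak_depol_mV,
               tolerance = 1e-9)

  # identity tonic + phasic = peak-above-baseline holds on train responses
  for (d in c(33, 200)) {
    pr <- build_tectal_train(60, d)
    tr2 <- simulate_trial(pr, sim_params(), seed = d)$trace
    b2 <- compute_baseline(tr2)
    pt2 <- phasic_tonic(tr2, pr, b2)
    expect_equal(pt2$tonic_mV + pt2$phasic_mV,
                 window_response(tr2, pt2$t_last_pulse_ms, 12,
                                 b2)$peak_depol_mV,
                 tolerance = 1e-9)
  }
  expect_error(phasic_tonic(tr1, build_auditory_pip(0), -80), "tectal")
})

test_that("longer trains grow the tonic component, not the phasic one", {
  p <- quiet_params()
  pt_of <- function(d) {
    pr <- build_tectal_train(60, d)
    tr <- simulate_trial(pr, p, seed = 1)$trace
    phasic_tonic(tr, pr, compute_baseline(tr))
  }
  a <- pt_of(33); b <- pt_of(200)
  expect_gt(b$tonic_mV, a$tonic_mV)
  expect_lt(abs(b$phasic_mV - a$phasic_mV) / a$phasic_mV, 0.1)
})

test_that("lingering depolarization: flat, closed-form exponential, ordering", {
  expect_equal(lingering_depolarization(flat_trace(-80), 50, -80), 0)
  # pure exponential decay from 5 mV with tau 45: 5 exp(-50/45) at 50 ms
  tr <- fn_trace(function(t) -80 + ifelse(t < 0, 0, 5 * exp(-t / 45)),
                 dur_ms = 100)
  expect_equal(lingering_depolarization(tr, 50, -80), 5 * exp(-50 / 45),
               tolerance = 0.01)
  # auditory lingering exceeds tectal at matched defaults
  p <- quiet_params()
  la <- local({
    t <- simulate_trial(build_auditory_pip(0), p, seed = 1)$trace
    lingering_depolarization(t, 50, compute_baseline(t))
  })
  lt <- local({
    t <- simulate_trial(build_tectal_train(60, 1), p, seed = 1)$trace
    lingering_depolarization(t, 50, compute_baseline(t))
  })
  expect_gt(la, lt)
  expect_error(lingering_depolarization(flat_trace(), 500, -80), "span")
})

test_that("AP detection uses a strict threshold and reports crossing time", {
  sub <- fn_trace(function(t) -80 + ifelse(t >= 0 & t < 10, 8, 0))
  expect_false(detect_ap(sub, -80)$fired)
  spike <- fn_trace(function(t) -80 + ifelse(t >= 5 & t < 6, 60, 0))
  d <- detect_ap(spike, -80)
  expect_true(d$fired)
  expect_equal(d$t_cross_ms, 5, tolerance = 0.05)
  # exactly at threshold does not fire
  at <- fn_trace(function(t) -80 + ifelse(t >= 0 & t < 5, 25, 0))
  expect_false(detect_ap(at, -80, 25)$fired)
})

test_that("trial averaging: identity, cancellation, variance, exclusions", {
  p <- quiet_params()
  proto <- build_auditory_pip(0)
  base <- simulate_trial(proto, p, seed = 1)
  five <- lapply(1:5, function(k) {
    tr <- base; tr$trial_index <- k; tr
  })
  avg <- average_trials(five)
  expect_equal(avg$trace$samples_mV, base$trace$samples_mV)
  expect_equal(avg$n, 5)

  # alternating +1/-1 offsets cancel
  offs <- lapply(1:6, function(k) {
    tr <- base
    tr$trace$samples_mV <- tr$trace$samples_mV + ifelse(k %% 2 == 0, 1, -1)
    tr$trial_index <- k; tr
  })
  expect_equal(average_trials(offs)$trace$samples_mV, base$trace$samples_mV)

  # variance of the mean of 8 noisy trials ~ sigma^2 / 8
  pn <- sim_params(trial_gain_sd = 0)
  eight <- sim_trials(proto, pn, n = 8)
  avg8 <- average_trials(eight)
  resid <- avg8$trace$samples_mV - simulate_trial(proto, quiet_params(),
                                                  seed = 1)$trace$samples_mV
  expect_equal(stats::var(resid), pn$noise_sd_mV^2 / 8, tolerance = 0.25)

  # fired trials are excluded before averaging
  fired <- base; fired$fired <- TRUE; fired$trial_index <- 9L
  avg_f <- suppressWarnings(average_trials(c(five, list(fired))))
  expect_equal(avg_f$n, 5)
  expect_equal(avg_f$n_excluded, 1)

  other <- simulate_trial(build_tectal_train(60, 1), p, seed = 2)
  expect_error(average_trials(list(base, other)), "mixed conditions")
  expect_warning(average_trials(list(base)), "outside")
})

test_that("quantification is invariant to a constant shift of the trace", {
  p <- sim_params()
  pr <- build_tectal_train(60, 33)
  tr <- simulate_trial(pr, p, seed = 3)$trace
  shifted <- tr; shifted$samples_mV <- tr$samples_mV + 7.5
  b <- compute_baseline(tr); bs <- compute_baseline(shifted)
  expect_equal(bs, b + 7.5)
  expect_equal(window_response(shifted, 33, 12, bs)$mean_depol_mV,
               window_response(tr, 33, 12, b)$mean_depol_mV, tolerance = 1e-12)
  expect_equal(phasic_tonic(shifted, pr, bs)$tonic_mV,
               phasic_tonic(tr, pr, b)$tonic_mV, tolerance = 1e-12)
  expect_equal(lingering_depolarization(shifted, 50, bs),
               lingering_depolarization(tr, 50, b), tolerance = 1e-12)
})
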