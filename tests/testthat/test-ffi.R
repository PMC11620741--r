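test_that("%SI arithmetic and identity invariant", {
  expect_equal(percent_si(17, 20), 15)
  expect_equal(percent_si(20, 20), 0)
  expect_equal(percent_si(0, 20), 100)
  expect_equal(percent_si(22, 20), -10)   # facilitation is not clipped
  expect_error(percent_si(10, 0), "positive")

  set.seed(41)
  for (i in 1:100) {
    m <- ffi_measurement(runif(1, 0, 80), runif(1, 0, 25), runif(1, 10, 25))
    expect_equal(m$si_percent, 100 - 100 * m$ap_test_mV / m$ap_control_mV,
                 tolerance = 1e-9)
  }
})

test_that("time-course assembly: degenerate, triangular and error cases", {
  mk <- function(delays, si) data.frame(delay_ms = delays, si_percent = si)

  # identical %SI everywhere: peak at the first delay, half-decay undefined
  tc <- assemble_time_course(mk(c(0, 10, 20), c(7, 7, 7)))
  expect_equal(tc$t_peak_ms, 0)
  expect_true(tc$undefined)
  expect_true(is.na(tc$t_half_ms))

  # triangular 0 -> 20 -> 0
  tri <- assemble_time_course(mk(c(0, 10, 20), c(0, 20, 0)))
  expect_equal(tri$peak_si_percent, 20)
  expect_equal(tri$t_peak_ms, 10)
  expect_equal(tri$t_half_ms, 15)  # midpoint of the falling edge

  expect_error(assemble_time_course(mk(c(0, 10), c(1, 2))), "3 distinct")

  # per-delay averaging: mean and SEM
  reps <- mk(c(2, 2, 10, 10, 30, 30), c(4, 6, 19, 21, 9, 11))
  tcr <- assemble_time_course(reps)
  expect_equal(tcr$mean_si_percent, c(5, 20, 10))
  expect_equal(tcr$sem_si_percent,
               rep(stats::sd(c(-1, 1)) / sqrt(2), 3))
})

test_that("half-decay crossing is linearly interpolated", {
  expect_equal(unname(half_decay_time(c(10, 20), c(20, 10))["t_half_ms"]), 20)
  expect_equal(unname(half_decay_time(c(10, 30), c(20, 0))["t_half_ms"]), 20)
  hd <- half_decay_time(c(5, 10, 18, 40), c(10, 20, 14, 2))
  # crossing of 10 between 18 and 40 ms: 18 + 4/12 * 22
  expect_equal(unname(hd["t_half_ms"]), 18 + 4 / 12 * 22, tolerance = 1e-9)
  expect_equal(unname(hd["t_half_elapsed_ms"]), unname(hd["t_half_ms"]) - 10,
               tolerance = 1e-9)

  # exponential curve sampled at discrete delays: elapsed half-decay within
  # 0.5 ms of tau ln 2
  tau <- 9
  d <- seq(0, 60, by = 2)
  hd2 <- half_decay_time(d, 20 * exp(-d / tau))
  expect_equal(unname(hd2["t_half_elapsed_ms"]), tau * log(2), tolerance = 0.5)

  # never falling below half peak: undefined, not an error
  expect_true(is.na(half_decay_time(c(0, 10, 20), c(10, 20, 15))["t_half_ms"]))
})

test_that("trapezoidal AUC with boundary extension equals polygon area", {
  expect_equal(auc_0_70(c(0, 70), c(10, 10)), 700)
  expect_equal(auc_0_70(c(0, 35, 70), c(0, 20, 0)), 700)

  # unsampled delay 0 extends with %SI = 0; value at 70 interpolated
  expect_equal(auc_0_70(c(10, 80), c(10, 10)),
               0.5 * 10 * 10 + 60 * 10)  # rise triangle + plateau to 70

  # piecewise-linear fixture vs closed-form polygon (shoelace) area
  d <- c(0, 5, 12, 30, 44, 70)
  s <- c(0, 14, 9, 6, 3, 1)
  shoelace <- sum(diff(d) * (utils::head(s, -1) + utils::tail(s, -1)) / 2)
  expect_equal(auc_0_70(d, s), shoelace, tolerance = 1e-9)

  expect_error(auc_0_70(c(75, 80), c(1, 2)), "70")
})

test_that("stronger FFI gains strictly increase peak %SI and AUC", {
  scales <- seq(0.2, 2, length.out = 10)
  delays <- c(2, 5, 8, 12, 16, 20, 30, 40, 50, 60, 70)
  peaks <- numeric(0); aucs <- numeric(0)
  for (sc in scales) {
    p <- quiet_params()
    p$ffi_tec$gain <- p$ffi_tec$gain * sc
    meas <- lapply(delays, function(d)
      simulate_ffi_probe(build_tectal_train(60, 1), d, p))
    tc <- assemble_time_course(meas, "tectal")
    peaks <- c(peaks, tc$peak_si_percent)
    aucs <- c(aucs, tc$auc_percent_ms)
  }
  expect_true(all(diff(peaks) > 0))
  expect_true(all(diff(aucs) > 0))
})

test_that("probe-sweep pipeline recovers the analytic kernel metrics", {
  p <- sim_params()
  delays <- c(2, 5, 8, 12, 16, 20, 30, 40, 50, 60, 70, 80)
  for (mod in c("tectal", "auditory")) {
    cond <- if (mod == "tectal") build_tectal_train(60, 1) else build_auditory_pip(0)
    gt <- ffi_ground_truth(p, mod)
    meas <- list()
    for (di in seq_along(delays)) for (r in 1:10)
      meas[[length(meas) + 1L]] <- simulate_ffi_probe(
        cond, delays[di], p, seed = child_seed(1, di, r))
    tc <- assemble_time_course(meas, mod)
    expect_lt(abs(tc$t_half_ms - gt$t_half_ms), 2)
    expect_lt(abs(tc$auc_percent_ms / gt$auc_percent_ms - 1), 0.1)
  }
})
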