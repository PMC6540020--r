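test_that("impedance_series enforces its invariants", {
  expect_error(impedance_series(c(800, 810)), "at least 3")
  expect_error(impedance_series(c(800, -1, 820)), "finite and > 0")
  expect_error(impedance_series(c(800, NA, 820)), "finite and > 0")
  expect_error(impedance_series(c(800, 810, 820), times = c(1, 2, 3.5)),
               "uniformly")
  s <- impedance_series(c(800, 810, 820, 830, 840))
  expect_equal(s$times, 1:5)
  expect_equal(s$delta_s, 1)
})

test_that("feasibility screening matches the two-condition truth table", {
  inc <- check_feasibility(impedance_series(c(800, 810, 820, 830, 840)))
  expect_false(inc$valid)
  expect_equal(inc$violations, "CONDITION_1_INCREASING")

  oor <- check_feasibility(impedance_series(c(900, 880, 875, 873, 2100)))
  expect_false(oor$valid)
  expect_equal(oor$violations, "CONDITION_2_RANGE")

  ok <- check_feasibility(impedance_series(c(850, 840, 835, 833, 832)))
  expect_true(ok$valid)
  expect_length(ok$violations, 0)

  # below-range final value is also flagged
  low <- check_feasibility(impedance_series(c(600, 550, 510, 490, 480)))
  expect_equal(low$violations, "CONDITION_2_RANGE")

  # a series both increasing and ending out of range carries both flags
  both <- check_feasibility(impedance_series(c(1800, 1900, 2000, 2050, 2100)))
  expect_setequal(both$violations,
                  c("CONDITION_1_INCREASING", "CONDITION_2_RANGE"))
})

test_that("deltas follow the earlier-minus-later convention", {
  s <- exact_series(1000, 200, 0.5)
  expect_equal(round(s$values, 3),
               c(1121.306, 1073.576, 1044.626, 1027.067, 1016.417))
  expect_equal(round(compute_deltas(s), 3),
               c(47.730, 28.950, 17.559, 10.650))
  expect_equal(compute_deltas(impedance_series(rep(800, 5))), rep(0, 4))
  expect_equal(compute_deltas(impedance_series(c(900, 890, 880, 870, 860))),
               rep(10, 4))
})

test_that("delta ratios recover exp(a * delta) and flag zero denominators", {
  d <- compute_deltas(exact_series(1000, 200, 0.5))
  expect_equal(compute_delta_ratios(d), rep(exp(0.5), 3), tolerance = 1e-4)
  expect_equal(compute_delta_ratios(c(10, 10, 10, 10)), rep(1, 3))
  expect_error(compute_delta_ratios(c(5, 0, 3)),
               class = "biafit_degenerate_delta")
  expect_error(compute_delta_ratios(5), "at least 2")
})

test_that("settling cascade routes each series to the documented path", {
  # already settled: flat series, and a last gap of exactly 1.0 <= 5
  flat <- estimate_settled_value(impedance_series(rep(800, 5)))
  expect_equal(flat$method, "ALREADY_SETTLED")
  expect_equal(flat$settled_ohms, 800)

  near <- estimate_settled_value(
    impedance_series(c(910, 905, 902, 900.5, 899.5)))
  expect_equal(near$method, "ALREADY_SETTLED")
  expect_equal(near$settled_ohms, 899.5)

  # mixed-sign deltas fall back to the last sample
  mixed <- estimate_settled_value(
    impedance_series(c(900, 880, 890, 870, 880)), extrapolation_config())
  expect_equal(mixed$method, "FALLBACK_LAST")
  expect_equal(mixed$settled_ohms, 880)

  # constant drift: all ratios equal 1, inside the band
  drift <- estimate_settled_value(
    impedance_series(c(900, 890, 880, 870, 860)))
  expect_equal(drift$method, "RATIO_IN_BAND")
  expect_equal(drift$settled_ohms, 860)

  # clean exponential extrapolates to the generating parameters
  est <- estimate_settled_value(exact_series(1000, 200, 0.5))
  expect_equal(est$method, "EXTRAPOLATED")
  expect_equal(est$settled_ohms, 1000, tolerance = 1e-6)
  expect_equal(est$decay_rate, 0.5, tolerance = 1e-6)
  expect_equal(est$amplitude, 200, tolerance = 1e-4)
  expect_length(est$delta_ratios, 3)

  # growing-magnitude transients never report a non-positive decay rate
  grow <- estimate_settled_value(
    impedance_series(c(1000, 990, 975, 950, 910)), extrapolation_config())
  expect_equal(grow$method, "FALLBACK_LAST")

  # extrapolation with fewer than 3 deltas is refused
  expect_error(
    estimate_settled_value(impedance_series(c(1000, 900, 850)),
                           extrapolation_config()),
    class = "biafit_insufficient_samples")
})

test_that("extrapolation recovers noise-free generating parameters exactly", {
  set.seed(42)
  cfg <- extrapolation_config()
  for (i in 1:50) {
    a <- runif(1, 0.1, 1.5)
    b <- runif(1, 500, 2000)
    c_amp <- sample(c(-1, 1), 1) * runif(1, 20, 400)
    s <- exact_series(b, c_amp, a)
    est <- estimate_settled_value(s, cfg)
    expect_equal(est$method, "EXTRAPOLATED")
    expect_lt(abs(est$settled_ohms - b), 1e-6)
    expect_lt(abs(est$decay_rate - a), 1e-6)
    expect_equal(sign(est$amplitude), sign(c_amp))
    # ratio identity on the same draw
    r <- compute_delta_ratios(compute_deltas(s))
    expect_lt(max(abs(r - exp(a))), 1e-9)
  }
})

test_that("extrapolation beats the last-sample readout under noise", {
  set.seed(99)
  err_est <- err_last <- numeric(200)
  for (i in 1:200) {
    a <- runif(1, 0.3, 0.8)
    c_amp <- runif(1, 100, 300)
    b <- runif(1, 500, 2000)
    s <- simulate_transient(transient_params(b, c_amp, a, noise_sd = 2))
    est <- estimate_settled_value(s)
    err_est[i] <- abs(est$settled_ohms - b)
    err_last[i] <- abs(s$values[5] - b)
  }
  expect_lt(median(err_est), median(err_last))
})

test_that("calibrate_series reports per-subject feasibility and estimates", {
  series <- list(ok = impedance_series(c(850, 840, 835, 833, 832),
                                       subject_id = "ok"),
                 bad = impedance_series(c(800, 810, 820, 830, 840),
                                        subject_id = "bad"))
  cal <- calibrate_series(series)
  expect_equal(nrow(cal), 2)
  expect_true(cal$valid[cal$subject_id == "ok"])
  expect_false(cal$valid[cal$subject_id == "bad"])
  expect_equal(cal$violations[cal$subject_id == "bad"],
               "CONDITION_1_INCREASING")
  expect_true(is.na(cal$settled_ohms[cal$subject_id == "bad"]))
})
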