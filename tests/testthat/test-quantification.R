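# dense long acquisition used where Logan estimates are compared with the
# closed-form distribution volume (the graphical method is asymptotic and
# needs data well past equilibration)
long_schedule <- function(minutes = 300) {
  dur <- rep(60, minutes)
  frame_schedule((seq_len(minutes) - 1) * 60, seq_len(minutes) * 60)
}

test_feng <- function() feng_params(0.5, 141.8, 3.65, 3.47, 4.1339, 0.1191, 0.0104)

test_that("running integral is exact for constants and ramps", {
  tg <- seq(0, 10, by = 0.1)
  expect_equal(integrate_tac(tg, rep(3, length(tg)))[length(tg)], 30)
  expect_equal(integrate_tac(tg, 2 * tg), tg^2, tolerance = 1e-12)

  # leading triangle when the first sample is after zero
  expect_equal(integrate_tac(c(2, 4), c(6, 6)), c(6, 18))

  # grid refinement stability on a smooth curve
  sm <- function(t) exp(-t / 15) * (2 + sin(t / 3))
  t1 <- seq(0, 60, by = 0.02); t2 <- seq(0, 60, by = 0.01)
  i1 <- integrate_tac(t1, sm(t1)); i2 <- integrate_tac(t2, sm(t2))
  expect_lt(abs(i1[length(i1)] - i2[length(i2)]) / i2[length(i2)], 1e-6)
})

test_that("Logan slope is one for tissue identical to the input", {
  fs <- default_frame_schedule()
  p <- test_feng()
  vals <- model_frame_curve(p, fs)
  tc <- tac(frame_midpoints(fs), frame_durations(fs), vals)
  inp <- input_function(frame_midpoints(fs) / 60, vals, "metab_corrected_plasma")
  fit <- logan_vt(tc, inp, t_star = 30)
  expect_equal(fit$vt, 1, tolerance = 1e-6)
  expect_equal(fit$intercept, 0, tolerance = 1e-6)
  expect_equal(fit$n_points, 6L)
})

test_that("Logan slope recovers the closed-form distribution volume", {
  p <- test_feng()
  fs <- long_schedule()
  tg <- seq(0, 300, by = 0.01)
  inp <- input_function(tg, feng_aif(p, tg), "metab_corrected_plasma")

  k1tc <- two_tc_params(0.2, 0.4, 0, 0)
  tc1 <- tac(frame_midpoints(fs), frame_durations(fs), model_frame_curve(p, fs, k = k1tc))
  expect_equal(logan_vt(tc1, inp, 30)$vt, closed_form_vt(k1tc), tolerance = 0.02)

  k2tc <- two_tc_params(0.2, 0.4, 0.06, 0.03)
  tc2 <- tac(frame_midpoints(fs), frame_durations(fs), model_frame_curve(p, fs, k = k2tc))
  expect_equal(logan_vt(tc2, inp, 30)$vt, closed_form_vt(k2tc), tolerance = 0.03)

  # equilibration bias shrinks monotonically as the window starts later
  slopes <- vapply(c(20, 30, 40), function(ts) logan_vt(tc2, inp, ts)$vt, numeric(1))
  expect_true(all(diff(slopes) > 0))
  expect_true(all(slopes < closed_form_vt(k2tc)))

  # joint positive rescaling of tissue and input leaves the slope unchanged
  tc2s <- tac(tc2$midpoint_s, tc2$duration_s, 3.2 * tc2$value)
  inps <- input_function(inp$time_min, 3.2 * inp$value, "metab_corrected_plasma")
  expect_equal(logan_vt(tc2s, inps, 30)$vt, logan_vt(tc2, inp, 30)$vt,
               tolerance = 1e-10)

  expect_error(logan_vt(tc2, inp, 299), "fewer than 3")
  expect_error(logan_vt(tc2, input_function(tg, feng_aif(p, tg), "normalized"), 30),
               "state")
})

test_that("reference Logan estimates the distribution-volume ratio", {
  p <- test_feng()
  fs <- long_schedule()
  ka <- two_tc_params(0.2, 0.4, 0.06, 0.03)   # V_T 1.5
  kb <- two_tc_params(0.2, 0.5, 0.06, 0.04)   # V_T 1.0
  ta <- tac(frame_midpoints(fs), frame_durations(fs), model_frame_curve(p, fs, k = ka))
  tb <- tac(frame_midpoints(fs), frame_durations(fs), model_frame_curve(p, fs, k = kb))
  expect_equal(logan_ref(ta, tb, 30)$vt, 1.5, tolerance = 0.05)
  expect_equal(logan_ref(ta, ta, 30)$vt, 1, tolerance = 1e-8)
})

test_that("SUV normalizes activity by dose per body weight", {
  fs <- default_frame_schedule()
  dose <- 185; weight <- 75
  conc <- dose * 1000 / (weight * 1000)  # kBq per g
  tc <- tac(frame_midpoints(fs), frame_durations(fs), rep(conc, 36))
  expect_equal(compute_suv(tc, dose, weight), 1.0)
  expect_equal(compute_suv(tc, 2 * dose, weight), 0.5)

  # exactly four 5-minute frames have midpoints in [40, 60] min
  mids <- frame_midpoints(fs) / 60
  expect_equal(sum(mids >= 40 & mids <= 60), 4L)
  vals <- rep(0, 36); vals[mids >= 40 & mids <= 60] <- conc
  expect_equal(compute_suv(tac(frame_midpoints(fs), frame_durations(fs), vals),
                           dose, weight), 1.0)
  expect_error(compute_suv(tc, dose, weight, window_min = c(70, 80)), "window")
  expect_error(compute_suv(tc, -1, weight), "positive")
})

test_that("percent error follows the gold-standard convention", {
  expect_equal(percent_error(2.30, 2.44), -5.7, tolerance = 0.01)
  expect_equal(percent_error(2, 2), 0)
  expect_equal(percent_error(3, 2), 50)
  expect_error(percent_error(1, 0), "> 0")
  # antisymmetry up to the denominator convention
  expect_equal(percent_error(2.3, 2.44) / 100,
               -(percent_error(2.44, 2.3) / 100) / (1 + percent_error(2.44, 2.3) / 100),
               tolerance = 1e-12)
})

test_that("group comparison matches the hand-worked pooled t-test", {
  a <- c(2, 4, 6); b <- c(1, 3)
  res <- compare_groups(a, b)
  # pooled s^2 = (2*4 + 1*2)/3 = 10/3; t = 2 / sqrt(10/3 * (1/3 + 1/2)) = 1.2
  expect_equal(res$t, 1.2, tolerance = 1e-12)
  expect_equal(res$p, 2 * stats::pt(-1.2, df = 3), tolerance = 1e-12)
  expect_equal(res$percent_diff, 100)

  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  expect_equal(same$percent_diff, 0)

  deg <- compare_groups(c(2, 2, 2, 2), c(1, 1, 1, 1))
  expect_lt(deg$p, 1e-12)
  expect_equal(deg$percent_diff, 100)
  expect_equal(compare_groups(c(2, 2), c(2, 2))$p, 1)
  expect_error(compare_groups(1, c(1, 2)), "n >= 2")
})
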