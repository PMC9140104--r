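test_that("Feng input model matches its closed forms", {
  p <- feng_params(tau = 0, A1 = 1, A2 = 0, A3 = 0,
                   lambda1 = 1, lambda2 = 0.5, lambda3 = 0.1)
  # with only the ramp term the curve is t * exp(-t)
  expect_equal(feng_aif(p, 1), exp(-1), tolerance = 1e-12)
  expect_equal(feng_aif(p, c(0.5, 2)), c(0.5, 2) * exp(-c(0.5, 2)))
  # global maximum of t*exp(-t) at t = 1
  opt <- stats::optimize(function(t) -feng_aif(p, t), c(0, 5))
  expect_equal(opt$minimum, 1, tolerance = 1e-5)

  # curve is 0 at and before the delay, continuous at tau
  p2 <- feng_params(0.7, 100, 5, 4, 4, 0.1, 0.01)
  expect_equal(feng_aif(p2, c(0, 0.3, 0.7)), c(0, 0, 0))
  expect_lt(abs(feng_aif(p2, 0.7 + 1e-9)), 1e-5)

  expect_error(feng_params(0, 1, 0, 0, 0.5, 0.6, 0.1), "lambda1 > lambda2")
  expect_error(feng_params(-1, 1, 0, 0, 1, 0.5, 0.1), "tau")
})

test_that("Feng curve integrates to its analytic total (quadrature check)", {
  set.seed(11)
  for (i in 1:5) {
    p <- feng_params(tau = stats::runif(1, 0, 1), A1 = stats::runif(1, 50, 200),
                     A2 = stats::runif(1, 1, 6), A3 = stats::runif(1, 1, 6),
                     lambda1 = stats::runif(1, 2, 6),
                     lambda2 = stats::runif(1, 0.08, 0.3),
                     lambda3 = stats::runif(1, 0.005, 0.02))
    analytic <- p$A1 / p$lambda1^2 - (p$A2 + p$A3) / p$lambda1 +
      p$A2 / p$lambda2 + p$A3 / p$lambda3
    quad <- stats::integrate(function(t) feng_aif(p, t), p$tau, Inf,
                             rel.tol = 1e-10)$value
    expect_equal(quad, analytic, tolerance = 1e-7)
  }
})

test_that("eigenrates satisfy the characteristic quadratic", {
  k <- two_tc_params(0.1, 0.5, 0.3, 0.2)
  B <- eigenrates(k)
  expect_equal(unname(B), c(0.1127017, 0.8872983), tolerance = 1e-6)
  expect_equal(sum(B), 1.0)
  expect_equal(prod(B), 0.1)

  # degenerate 1TC: k3 = k4 = 0 -> (0, k2)
  expect_equal(unname(eigenrates(two_tc_params(0.1, 0.4, 0, 0))), c(0, 0.4))

  # Vieta identities over random valid parameter sets
  set.seed(3)
  for (i in 1:20) {
    k <- two_tc_params(stats::runif(1, 0.01, 1), stats::runif(1, 0.05, 1),
                       stats::runif(1, 0, 0.5), stats::runif(1, 0, 0.5))
    B <- eigenrates(k)
    expect_equal(sum(B), k$k2 + k$k3 + k$k4, tolerance = 1e-12)
    expect_equal(prod(B), k$k2 * k$k4, tolerance = 1e-12)
    expect_true(B[1] <= B[2] && all(B >= 0))
  }
})

test_that("analytic tissue response matches a numeric convolution oracle", {
  p <- feng_params(0.5, 141.8, 3.65, 3.47, 4.1339, 0.1191, 0.0104)
  tt <- c(0.6, 1, 2, 5, 15, 40, 59)
  cases <- list(
    two_tc_params(0.2, 0.4, 0.06, 0.03),
    two_tc_params(0.15, 0.11, 0.06, 0.04),
    two_tc_params(0.3, 0.25, 0, 0)       # 1TC limit
  )
  for (k in cases) {
    ana <- two_tc_tissue(p, k, tt)
    num <- numeric_tissue_oracle(p, k, tt)
    expect_equal(ana, num, tolerance = 1e-4)
    expect_true(all(ana >= 0))
  }
  # metabolite-corrected driving input
  mm <- metabolite_model()
  ana_m <- two_tc_tissue(p, cases[[1]], tt, metab = mm)
  num_m <- numeric_tissue_oracle(p, cases[[1]], tt, metab = mm)
  expect_equal(ana_m, num_m, tolerance = 1e-4)

  # K1 = 0 -> identically zero; linear in K1
  expect_equal(two_tc_tissue(p, two_tc_params(0, 0.4, 0.1, 0.1), tt),
               rep(0, length(tt)))
  k1 <- two_tc_params(0.1, 0.4, 0.06, 0.03)
  k2 <- two_tc_params(0.2, 0.4, 0.06, 0.03)
  expect_equal(2 * two_tc_tissue(p, k1, tt), two_tc_tissue(p, k2, tt))
})

test_that("repeated eigenrate limit agrees with a nearby distinct-rate system", {
  p <- feng_params(0.2, 100, 3, 3, 4, 0.12, 0.01)
  # B1 == B2 requires k3 = 0 and k2 = k4
  k_rep <- two_tc_params(0.1, 0.3, 0, 0.3)
  k_near <- two_tc_params(0.1, 0.3 + 1e-7, 0, 0.3 - 1e-7)
  tt <- c(1, 5, 20, 50)
  expect_equal(two_tc_tissue(p, k_rep, tt), two_tc_tissue(p, k_near, tt),
               tolerance = 1e-6)
  expect_equal(two_tc_tissue(p, k_rep, tt),
               numeric_tissue_oracle(p, k_rep, tt), tolerance = 1e-4)
})

test_that("tissue response commutes with a shift of the input delay", {
  base <- feng_params(0.3, 100, 3, 3, 4, 0.12, 0.01)
  shifted <- feng_params(0.8, 100, 3, 3, 4, 0.12, 0.01)
  k <- two_tc_params(0.15, 0.2, 0.05, 0.03)
  tt <- seq(1, 50, by = 0.5)
  expect_equal(two_tc_tissue(base, k, tt), two_tc_tissue(shifted, k, tt + 0.5),
               tolerance = 1e-10)
})

test_that("frame averaging is exact for constants and linear ramps", {
  fs <- frame_schedule(c(0, 10), c(10, 30))
  tg <- seq(0, 0.5, by = 0.001)
  expect_equal(frame_average(tg, rep(4, length(tg)), fs), c(4, 4))
  # linear ramp a*t over [0, T] averages to a*T/2
  a <- 3
  got <- frame_average(tg, a * tg, fs)
  expect_equal(got[1], a * (10 / 60) / 2, tolerance = 1e-9)
  expect_equal(got[2], a * (10 + 30) / 60 / 2, tolerance = 1e-9)

  # grid refinement on an infinitely smooth curve converges below 1e-6
  fs36 <- default_frame_schedule()
  smooth <- function(t) exp(-t / 15) * (2 + sin(t / 3))
  t1 <- seq(0, 60, by = 0.002); t2 <- seq(0, 60, by = 0.001)
  v1 <- frame_average(t1, smooth(t1), fs36)
  v2 <- frame_average(t2, smooth(t2), fs36)
  expect_lt(max(abs(v1 - v2) / abs(v2)), 1e-6)

  # the input curve has a kink at the delay; convergence there is slower
  # but still second order
  p <- feng_params(0.5, 141.8, 3.65, 3.47, 4.1339, 0.1191, 0.0104)
  f1 <- frame_average(t1, feng_aif(p, t1), fs36)
  f2 <- frame_average(t2, feng_aif(p, t2), fs36)
  expect_lt(max(abs(f1 - f2) / pmax(abs(f2), 1e-12)), 1e-4)

  expect_error(frame_average(seq(0, 0.1, 0.01), rep(1, 11), fs), "cover")
})

test_that("model_frame_curve agrees with generic frame averaging", {
  p <- feng_params(0.5, 141.8, 3.65, 3.47, 4.1339, 0.1191, 0.0104)
  k <- two_tc_params(0.15, 0.15, 0.06, 0.04)
  fs <- default_frame_schedule()
  tg <- seq(0, 60, by = 0.001)
  expect_equal(model_frame_curve(p, fs, points_per_frame = 41),
               frame_average(tg, feng_aif(p, tg), fs), tolerance = 1e-3)
  expect_equal(model_frame_curve(p, fs, k = k, points_per_frame = 41),
               frame_average(tg, two_tc_tissue(p, k, tg), fs), tolerance = 1e-4)
})

test_that("closed-form distribution volume follows the 2TC formula", {
  expect_equal(closed_form_vt(two_tc_params(0.2, 0.4, 0, 0.1)), 0.5)
  expect_equal(closed_form_vt(two_tc_params(0.2, 0.4, 0.06, 0.03)), 1.5)
  expect_equal(closed_form_vt(two_tc_params(0.4, 0.4, 0.06, 0.03)), 3.0)
  expect_error(closed_form_vt(two_tc_params(0.2, 0.4, 0.06, 0)), "irreversible")
})
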