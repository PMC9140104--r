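test_that("scaling optimization solves the mixing-fraction constraint exactly", {
  alpha <- c(0.2, 0.5, 0.8)
  W <- cbind(alpha / 2, (1 - alpha) / 4)
  sc <- optimize_scaling(W)
  expect_equal(c(sc$s_aif, sc$s_tissue), c(2, 4), tolerance = 1e-10)
  expect_equal(sc$objective_value, 0, tolerance = 1e-12)

  # rank-1 weight matrix is not identifiable
  W1 <- cbind(c(0.5, 0.25, 0.1), 0)
  expect_error(optimize_scaling(W1), "rank 1")
  W2 <- cbind(c(0.5, 0.25, 0.1), 2 * c(0.5, 0.25, 0.1))
  expect_error(optimize_scaling(W2), "rank 1")
})

test_that("closed-form scaling equals the grid-search and optimizer oracles", {
  set.seed(21)
  for (i in 1:5) {
    alpha <- stats::runif(6)
    sa <- stats::runif(1, 0.3, 3); st <- stats::runif(1, 0.3, 3)
    W <- cbind(alpha / sa, (1 - alpha) / st) +
      matrix(stats::rnorm(12, sd = 0.02), 6, 2)
    cf <- optimize_scaling(W)
    gs <- grid_search_scaling(W)
    expect_equal(c(cf$s_aif, cf$s_tissue), gs, tolerance = 5e-3)
    it <- optimize_scaling(W, method = "optim")
    expect_equal(c(cf$s_aif, cf$s_tissue), c(it$s_aif, it$s_tissue),
                 tolerance = 1e-6)
  }
})

test_that("printed and reciprocal conventions restore identical physical units", {
  alpha <- c(0.1, 0.4, 0.7, 0.9)
  W <- cbind(alpha * 120, (1 - alpha) * 45)  # unit-sum-normalized geometry
  pr <- optimize_scaling(W, convention = "printed")
  rc <- optimize_scaling(W, convention = "reciprocal")
  expect_equal(pr$s_aif, 1 / rc$s_aif, tolerance = 1e-10)
  expect_equal(pr$unit_scale_aif, rc$unit_scale_aif, tolerance = 1e-10)
  expect_equal(rc$s_aif, 120, tolerance = 1e-10)
})

test_that("scaled input function is linear in the unit scale and tracks state", {
  ph <- get_noisefree_phantom()
  tr <- ph$truth
  vm <- build_matrix(ph$image, segment_carotid(ph$image, ph$labels))
  fit <- fit_mbmf(vm, n_starts = 1, seed = 1, metab = tr$metab)
  sc <- optimize_scaling(fit$W, convention = "reciprocal")
  wb <- scale_idif(fit, sc)
  expect_equal(wb$state, "whole_blood")

  # reciprocal convention: values are s_aif times the normalized curve
  sc1 <- sc; sc1$s_aif <- 1; sc1$unit_scale_aif <- 1
  base <- scale_idif(fit, sc1)
  expect_equal(wb$value, sc$s_aif * base$value)
  sc2 <- sc; sc2$s_aif <- 2 * sc$s_aif; sc2$unit_scale_aif <- 2 * sc$unit_scale_aif
  expect_equal(scale_idif(fit, sc2)$value, 2 * wb$value)

  # end-to-end on the noise-free phantom the restored curve is the truth
  expect_equal(wb$value, feng_aif(tr$feng, wb$time_min), tolerance = 1e-4)
})

test_that("metabolite multiplier has the documented limits and monotonicity", {
  mm <- metabolite_model()
  expect_equal(mm$a, 0.29)
  expect_equal(mm$b, 0.03)
  expect_equal(metab_multiplier(mm, 0), 1)
  expect_equal(1 - metab_multiplier(mm, 1e9), 0.29, tolerance = 1e-12)
  tt <- seq(0, 90, by = 0.5)
  expect_true(all(diff(metab_multiplier(mm, tt)) < 0))
  expect_true(all(metab_multiplier(mm, tt) >= 1 - mm$a))
  expect_error(metabolite_model(a = 1.2), "\\[0, 1\\]")
})

test_that("composite-fraction fitting inverts the generative model", {
  tr <- default_truth("HAB")
  tabs <- lapply(1:4, function(i) simulate_blood_samples(tr))
  mm <- fit_composite_fraction(tabs)
  expect_equal(mm$a, 0.29, tolerance = 1e-6)
  expect_equal(mm$b, 0.03, tolerance = 1e-6)
  expect_equal(mm$source, "fitted")

  # composite fraction identically one -> a = 0
  t_s <- c(5, 15, 30, 60) * 60
  ones <- blood_table(t_s, rep(10, 4), rep(10, 4), rep(1, 4))
  expect_equal(fit_composite_fraction(list(ones))$a, 0, tolerance = 1e-8)

  # subject-level assay noise (sd 0.02 on the composite fraction, four
  # subjects): the fitted amplitude is unbiased, with its replicate mean
  # within 0.05 of the generating value
  set.seed(99)
  devs <- replicate(100, {
    tabs_n <- lapply(1:4, function(i) {
      bt <- simulate_blood_samples(tr)
      j <- match(t_s, bt$time_s)
      bt$plasma_kBq_mL[j] <- bt$plasma_kBq_mL[j] +
        bt$wb_kBq_mL[j] / bt$parent_fraction[j] * stats::rnorm(4, 0, 0.02)
      bt
    })
    fit_composite_fraction(tabs_n)$a
  })
  expect_lt(abs(mean(devs) - 0.29), 0.05)
  expect_lt(stats::sd(devs), 0.1)

  # a missing time point drops the subject with a warning
  short <- blood_table(t_s[1:3], rep(10, 3), rep(9, 3), rep(0.9, 3))
  expect_warning(fit_composite_fraction(list(ones, short)), "dropped")
  expect_error(suppressWarnings(fit_composite_fraction(list(short))),
               "no subject")
})

test_that("metabolite correction multiplies pointwise and enforces state", {
  mm <- metabolite_model()
  wb <- input_function(c(0, 1, 30, 60), c(0, 20, 5, 3), "whole_blood")
  out <- apply_metabolite_correction(wb, mm)
  expect_equal(out$state, "metab_corrected_plasma")
  expect_equal(out$value, wb$value * metab_multiplier(mm, wb$time_min))
  expect_equal(out$value[1], wb$value[1])  # t = 0 unchanged
  expect_error(apply_metabolite_correction(out, mm), "whole_blood")
})

test_that("measured blood input interpolates the parent fraction", {
  t_s <- c(60, 300, 900, 1800, 3600)
  pf <- c(NA, 0.9, NA, 0.7, 0.5)
  bt <- blood_table(t_s, rep(10, 5), rep(8, 5), pf)
  inp <- input_from_blood_table(bt)
  expect_equal(inp$state, "metab_corrected_plasma")
  expect_equal(inp$value[2], 8 * 0.9)
  expect_equal(inp$value[3], 8 * 0.82)  # linear in time between 0.9 and 0.7
  expect_equal(inp$value[1], 8 * 0.9)   # constant extrapolation
})
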