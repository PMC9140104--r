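#' Running trapezoidal integral from time zero
#'
#' Cumulative trapezoid over the samples, with a leading triangle from
#' (0, 0) to the first sample (activity is zero at injection).
#'
#' @param t sample times, strictly increasing, first > 0 (or equal 0).
#' @param y values at `t`.
#' @return Cumulative integral evaluated at each `t`.
#' @export
integrate_tac <- function(t, y) {
  if (is.unsorted(t, strictly = TRUE)) stop("times must increase", call. = FALSE)
  if (t[1] > 0) {
    cs <- pracma::cumtrapz(c(0, t), c(0, y))
    as.numeric(cs[-1])
  } else {
    as.numeric(pracma::cumtrapz(t, y))
  }
}

# interpolated running integral of an input function at arbitrary times
input_integral_at <- function(input, t_min) {
  ci <- integrate_tac(input$time_min, input$value)
  stats::approx(input$time_min, ci, xout = t_min, rule = 2)$y
}

input_value_at <- function(input, t_min) {
  stats::approx(input$time_min, input$value, xout = t_min, rule = 2)$y
}

#' Logan graphical analysis with a blood input
#'
#' Ordinary least-squares slope of
#' \eqn{\int_0^t C_T / C_T(t)} against \eqn{\int_0^t C_p / C_T(t)} over
#' frames whose midpoint is at or after `t_star`; for reversible tracers
#' the slope estimates the total distribution volume V_T.
#'
#' @param tissue a [tac()] (times in seconds).
#' @param input an [input_function()] in `metab_corrected_plasma` state
#'   (pass `allow_whole_blood = TRUE` for sensitivity runs on whole
#'   blood).
#' @param t_star start of the linear window, minutes.
#' @param allow_whole_blood accept a `whole_blood`-state input.
#' @return An object of class `logan_fit`: `vt` (slope), `intercept`,
#'   `r_squared`, `n_points`, `t_star`.
#' @export
logan_vt <- function(tissue, input, t_star = 30, allow_whole_blood = FALSE) {
  ok_states <- c("metab_corrected_plasma", if (allow_whole_blood) "whole_blood")
  if (!inherits(input, "input_function") || !input$state %in% ok_states) {
    stop("input must be an input_function in metab_corrected_plasma state",
         call. = FALSE)
  }
  tm <- tissue$midpoint_s / 60
  ct <- tissue$value
  int_t <- integrate_tac(tm, ct)
  int_p <- input_integral_at(input, tm)
  logan_ols(tm, ct, int_t, int_p, t_star)
}

#' Reference-region Logan analysis
#'
#' Slope of \eqn{\int_0^t C_T / C_T(t)} against
#' \eqn{\int_0^t C_{REF} / C_T(t)} over the linear window (no efflux-rate
#' correction term). For reversible tracers the slope approximates the
#' distribution-volume ratio target/reference.
#'
#' @param tissue,reference [tac()]s on the same schedule.
#' @inheritParams logan_vt
#' @return A `logan_fit` (slope stored in `vt`).
#' @export
logan_ref <- function(tissue, reference, t_star = 30) {
  if (!isTRUE(all.equal(tissue$midpoint_s, reference$midpoint_s))) {
    stop("tissue and reference must share a schedule", call. = FALSE)
  }
  tm <- tissue$midpoint_s / 60
  ct <- tissue$value
  int_t <- integrate_tac(tm, ct)
  int_r <- integrate_tac(tm, reference$value)
  if (any(reference$value[tm >= t_star] <= 0)) {
    stop("reference TAC must be strictly positive in the window", call. = FALSE)
  }
  logan_ols(tm, ct, int_t, int_r, t_star)
}

logan_ols <- function(tm, ct, int_tissue, int_input, t_star) {
  win <- which(tm >= t_star)
  if (length(win) < 3L) stop("fewer than 3 frames in the Logan window", call. = FALSE)
  if (any(ct[win] <= 0)) stop("non-positive tissue activity in the Logan window",
                              call. = FALSE)
  x <- int_input[win] / ct[win]
  y <- int_tissue[win] / ct[win]
  fit <- stats::lm(y ~ x)
  ssy <- sum((y - mean(y))^2)
  r2 <- if (ssy > 0) max(0, min(1, 1 - sum(stats::resid(fit)^2) / ssy)) else 1
  structure(
    list(vt = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, n_points = length(win), t_star = t_star),
    class = "logan_fit"
  )
}

#' Standardized uptake value over a late window
#'
#' Duration-weighted mean activity over frames whose midpoints fall in the
#' window, divided by injected dose per body weight (tissue density taken
#' as 1 g/mL, so kBq/mL and kBq/g are interchangeable).
#'
#' @param tissue a [tac()] in kBq/mL.
#' @param dose_MBq injected dose (MBq), > 0.
#' @param weight_kg body weight (kg), > 0.
#' @param window_min `c(start, end)` window in minutes (default 40-60).
#' @return Scalar SUV (g/mL).
#' @export
compute_suv <- function(tissue, dose_MBq, weight_kg, window_min = c(40, 60)) {
  if (dose_MBq <= 0 || weight_kg <= 0) {
    stop("dose and weight must be positive", call. = FALSE)
  }
  tm <- tissue$midpoint_s / 60
  win <- which(tm >= window_min[1] & tm <= window_min[2])
  if (length(win) == 0L) stop("no frame midpoint falls in the SUV window",
                              call. = FALSE)
  act <- sum(tissue$value[win] * tissue$duration_s[win]) /
    sum(tissue$duration_s[win])
  conc_norm <- (dose_MBq * 1000) / (weight_kg * 1000)  # kBq per g
  act / conc_norm
}

#' Percent error against a gold standard
#'
#' `100 * (test - ref) / ref`; the convention used to benchmark
#' image-derived V_T against arterial-sampling V_T.
#'
#' @param vt_test,vt_ref numeric vectors (recycled).
#' @return Percentages.
#' @export
percent_error <- function(vt_test, vt_ref) {
  if (any(vt_ref <= 0)) stop("reference values must be > 0", call. = FALSE)
  100 * (vt_test - vt_ref) / vt_ref
}

#' Two-group comparison
#'
#' Unpaired two-sample t-test (equal-variance by default; Welch optional)
#' plus the percent difference of group means relative to group B. When
#' both groups are degenerate (zero variance), equal means give p = 1 and
#' unequal means give p = 0 (difference certain at machine precision).
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @param var_equal pooled-variance t-test when `TRUE`.
#' @return List with `t`, `p`, `percent_diff`, `mean_a`, `mean_b`.
#' @export
compare_groups <- function(values_a, values_b, var_equal = TRUE) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  ma <- mean(values_a); mb <- mean(values_b)
  pd <- 100 * (ma - mb) / mb
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (ma == mb) {
      return(list(t = 0, p = 1, percent_diff = pd, mean_a = ma, mean_b = mb))
    }
    return(list(t = sign(ma - mb) * Inf, p = 0, percent_diff = pd,
                mean_a = ma, mean_b = mb))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value, percent_diff = pd,
       mean_a = ma, mean_b = mb)
}
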