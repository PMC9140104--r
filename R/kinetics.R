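#' Feng arterial input-function parameters
#'
#' Seven-parameter arterial input model: a delayed linear-rise term times a
#' fast exponential plus two slower decaying exponentials,
#' \deqn{C(t) = (A_1 (t-\tau) - A_2 - A_3) e^{-\lambda_1 (t-\tau)} +
#'   A_2 e^{-\lambda_2 (t-\tau)} + A_3 e^{-\lambda_3 (t-\tau)}}
#' for \eqn{t > \tau} and 0 before the delay. Internal time unit is minutes.
#'
#' @param tau delay (min), >= 0.
#' @param A1 ramp amplitude (activity / min), > 0.
#' @param A2,A3 exponential amplitudes (activity units), >= 0.
#' @param lambda1,lambda2,lambda3 decay rates (1/min); must satisfy
#'   `lambda1 > lambda2 > lambda3 >= 0`.
#' @param check_nonneg sample the curve over 0-90 min and reject parameter
#'   sets that dip negative.
#' @return An object of class `feng_params`.
#' @export
feng_params <- function(tau, A1, A2, A3, lambda1, lambda2, lambda3,
                        check_nonneg = TRUE) {
  stopifnot(is.finite(c(tau, A1, A2, A3, lambda1, lambda2, lambda3)))
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  if (A1 <= 0) stop("A1 must be > 0", call. = FALSE)
  if (A2 < 0 || A3 < 0) stop("A2 and A3 must be >= 0", call. = FALSE)
  if (!(lambda1 > lambda2 && lambda2 > lambda3 && lambda3 >= 0)) {
    stop("rates must satisfy lambda1 > lambda2 > lambda3 >= 0", call. = FALSE)
  }
  p <- structure(
    list(tau = tau, A1 = A1, A2 = A2, A3 = A3,
         lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3),
    class = "feng_params"
  )
  if (check_nonneg) {
    v <- feng_aif(p, seq(0, 90, by = 0.05))
    if (min(v) < -1e-9 * max(abs(v))) {
      stop("parameter set yields a negative input curve", call. = FALSE)
    }
  }
  p
}

#' Two-tissue compartment rate constants
#'
#' @param K1 plasma-to-tissue transfer (mL cm^-3 min^-1), >= 0.
#' @param k2,k3,k4 first-order rate constants (1/min), >= 0; `k2 > 0`
#'   whenever `K1 > 0`.
#' @return An object of class `two_tc_params`.
#' @export
two_tc_params <- function(K1, k2, k3, k4) {
  stopifnot(is.finite(c(K1, k2, k3, k4)))
  if (any(c(K1, k2, k3, k4) < 0)) stop("rate constants must be >= 0", call. = FALSE)
  if (K1 > 0 && k2 <= 0) stop("k2 must be > 0 when K1 > 0", call. = FALSE)
  disc <- (k2 + k3 + k4)^2 - 4 * k2 * k4
  if (disc < -1e-12) stop("negative eigenrate discriminant", call. = FALSE)
  structure(list(K1 = K1, k2 = k2, k3 = k3, k4 = k4), class = "two_tc_params")
}

#' Evaluate the Feng arterial input function
#'
#' @param p a [feng_params()].
#' @param t_min time(s) in minutes.
#' @return Activity value(s); 0 for `t <= tau`.
#' @export
feng_aif <- function(p, t_min) {
  u <- t_min - p$tau
  out <- numeric(length(u))
  pos <- u > 0
  if (any(pos)) {
    up <- u[pos]
    out[pos] <- (p$A1 * up - p$A2 - p$A3) * exp(-p$lambda1 * up) +
      p$A2 * exp(-p$lambda2 * up) + p$A3 * exp(-p$lambda3 * up)
  }
  out
}

#' Eigenrates of the two-tissue compartment system
#'
#' Roots of the characteristic quadratic:
#' \eqn{B_{1,2} = \tfrac12[(k_2+k_3+k_4) \mp \sqrt{(k_2+k_3+k_4)^2 - 4 k_2 k_4}]}.
#' For non-negative rates the discriminant is always >= 0.
#'
#' @param k a [two_tc_params()].
#' @return Numeric `c(B1, B2)` with `B1 <= B2`.
#' @export
eigenrates <- function(k) {
  s <- k$k2 + k$k3 + k$k4
  disc <- s^2 - 4 * k$k2 * k$k4
  if (disc < 0) {
    if (disc < -1e-12 * max(1, s^2)) stop("negative discriminant", call. = FALSE)
    disc <- 0
  }
  r <- sqrt(disc)
  c(B1 = (s - r) / 2, B2 = (s + r) / 2)
}

# --- analytic convolution machinery -----------------------------------------
#
# The input curve (and its metabolite-corrected plasma variant) is a sum of
# terms (p0 + p1*u) * exp(-lam*u) in shifted time u = t - tau.  Convolving
# such a term with exp(-B*u) or u*exp(-B*u) has a closed form; the helpers
# below evaluate it in cancellation-safe combined exponential form, with a
# series fallback when lam ~ B.

# G_k(u) = int_0^u s^k exp(-lam*s) exp(-B*(u-s)) ds, k = 0, 1, 2
conv_moments <- function(lam, B, u) {
  d <- lam - B
  eB <- exp(-B * u)
  if (abs(d) * max(u, 0) < 1e-3) {
    du <- d * u
    g0 <- eB * u * (1 - du / 2 + du^2 / 6)
    g1 <- eB * u^2 * (1 / 2 - du / 3 + du^2 / 8)
    g2 <- eB * u^3 * (1 / 3 - du / 4 + du^2 / 10)
  } else {
    eL <- exp(-lam * u)
    du <- d * u
    g0 <- (eB - eL) / d
    g1 <- (eB - (1 + du) * eL) / d^2
    g2 <- (2 * eB - (2 + 2 * du + du^2) * eL) / d^3
  }
  list(g0 = g0, g1 = g1, g2 = g2)
}

# exponential-basis representation of the input in shifted time u = t - tau:
# data.frame(p0, p1, lam) meaning sum of (p0 + p1*u) exp(-lam*u)
input_basis <- function(p, metab = NULL) {
  base <- data.frame(
    p0 = c(-p$A2 - p$A3, p$A2, p$A3),
    p1 = c(p$A1, 0, 0),
    lam = c(p$lambda1, p$lambda2, p$lambda3)
  )
  if (is.null(metab)) return(base)
  # multiplier 1 - a(1 - e^{-b t}) = (1-a) + a e^{-b tau} e^{-b u}
  a <- metab$a; b <- metab$b
  shifted <- base
  shifted$p0 <- shifted$p0 * a * exp(-b * p$tau)
  shifted$p1 <- shifted$p1 * a * exp(-b * p$tau)
  shifted$lam <- shifted$lam + b
  base$p0 <- base$p0 * (1 - a)
  base$p1 <- base$p1 * (1 - a)
  rbind(base, shifted)
}

# convolution of the basis with coef * exp(-B u), evaluated at u >= 0
conv_basis_exp <- function(basis, coef, B, u) {
  out <- numeric(length(u))
  for (i in seq_len(nrow(basis))) {
    g <- conv_moments(basis$lam[i], B, u)
    out <- out + basis$p0[i] * g$g0 + basis$p1[i] * g$g1
  }
  coef * out
}

# convolution of the basis with coef * u * exp(-B u) (repeated-root kernel)
conv_basis_texp <- function(basis, coef, B, u) {
  out <- numeric(length(u))
  for (i in seq_len(nrow(basis))) {
    g <- conv_moments(basis$lam[i], B, u)
    out <- out + u * (basis$p0[i] * g$g0 + basis$p1[i] * g$g1) -
      (basis$p0[i] * g$g1 + basis$p1[i] * g$g2)
  }
  coef * out
}

#' Two-tissue compartment tissue response to a Feng input
#'
#' Convolution of the arterial input with the 2TC impulse response
#' \deqn{\frac{K_1}{B_2-B_1}[(k_3+k_4-B_1)e^{-B_1 t} + (B_2-k_3-k_4)e^{-B_2 t}],}
#' computed analytically in an exponential basis. When `metab` is supplied
#' the driving input is the metabolite-corrected plasma curve (input times
#' the metabolite multiplier) rather than whole blood. The repeated-root
#' case `B1 == B2` (within 1e-9) uses the analytic limit.
#'
#' @param p a [feng_params()].
#' @param k a [two_tc_params()].
#' @param t_min evaluation times (minutes).
#' @param metab optional [metabolite_model()] modifying the driving input.
#' @return Tissue activity values; 0 for `t <= tau`.
#' @export
two_tc_tissue <- function(p, k, t_min, metab = NULL) {
  out <- numeric(length(t_min))
  if (k$K1 == 0) return(out)
  u <- t_min - p$tau
  pos <- u > 0
  if (!any(pos)) return(out)
  up <- u[pos]
  basis <- input_basis(p, metab)
  B <- eigenrates(k)
  kb <- k$k3 + k$k4
  if (B[2] - B[1] > 1e-9) {
    q1 <- k$K1 * (kb - B[1]) / (B[2] - B[1])
    q2 <- k$K1 * (B[2] - kb) / (B[2] - B[1])
    v <- conv_basis_exp(basis, q1, B[1], up) + conv_basis_exp(basis, q2, B[2], up)
  } else {
    Bm <- mean(B)
    v <- conv_basis_exp(basis, k$K1, Bm, up) +
      conv_basis_texp(basis, k$K1 * (kb - Bm), Bm, up)
  }
  out[pos] <- v
  out
}

#' Average a finely sampled curve over acquisition frames
#'
#' Each frame reports the time-average of the curve over its `[start, end]`
#' interval, computed by trapezoidal quadrature on the supplied grid with
#' linear interpolation at the frame boundaries.
#'
#' @param t_min strictly increasing sample times (minutes) covering the
#'   schedule.
#' @param values curve values at `t_min`.
#' @param schedule a [frame_schedule()] (times in seconds).
#' @return Numeric vector of per-frame mean values.
#' @export
frame_average <- function(t_min, values, schedule) {
  start <- schedule$start_s / 60
  end <- schedule$end_s / 60
  if (start[1] < min(t_min) - 1e-9 || max(end) > max(t_min) + 1e-9) {
    stop("fine grid does not cover the frame schedule", call. = FALSE)
  }
  vapply(seq_along(start), function(j) {
    a <- start[j]; b <- end[j]
    inside <- t_min > a & t_min < b
    tt <- c(a, t_min[inside], b)
    vv <- stats::approx(t_min, values, xout = tt, rule = 2)$y
    pracma::trapz(tt, vv) / (b - a)
  }, numeric(1))
}

#' Frame-averaged model curves
#'
#' Evaluates the Feng input (or, when `k` is given, the 2TC tissue
#' response) analytically on a per-frame uniform subgrid and returns the
#' trapezoidal frame averages. This is the forward model used both by the
#' phantom generator and by the matrix-factorization objective.
#'
#' @inheritParams two_tc_tissue
#' @param schedule a [frame_schedule()].
#' @param k optional [two_tc_params()]; when `NULL` the input curve itself
#'   is averaged.
#' @param points_per_frame odd number of quadrature nodes per frame.
#' @return Numeric vector, one value per frame.
#' @export
model_frame_curve <- function(p, schedule, k = NULL, metab = NULL,
                              points_per_frame = 9) {
  grid <- frame_quad_grid(schedule, points_per_frame)
  vals <- if (is.null(k)) {
    v <- feng_aif(p, grid$t)
    if (!is.null(metab)) v <- v * metab_multiplier(metab, grid$t)
    v
  } else {
    two_tc_tissue(p, k, grid$t, metab = metab)
  }
  as.numeric(colSums(matrix(vals * grid$w, nrow = points_per_frame)))
}

# per-frame uniform quadrature nodes (minutes) and trapezoid mean-weights
frame_quad_grid <- function(schedule, points_per_frame = 9) {
  stopifnot(points_per_frame >= 3)
  m <- n_frames(schedule)
  t <- numeric(m * points_per_frame)
  for (j in seq_len(m)) {
    t[((j - 1) * points_per_frame + 1):(j * points_per_frame)] <-
      seq(schedule$start_s[j] / 60, schedule$end_s[j] / 60,
          length.out = points_per_frame)
  }
  w1 <- c(0.5, rep(1, points_per_frame - 2), 0.5) / (points_per_frame - 1)
  list(t = t, w = rep(w1, m))
}

#' Closed-form total distribution volume of a 2TC system
#'
#' \eqn{V_T = (K_1/k_2)(1 + k_3/k_4)}; the ground-truth oracle for Logan
#' estimates on reversible systems.
#'
#' @param k a [two_tc_params()].
#' @return Distribution volume (mL/cm^3).
#' @export
closed_form_vt <- function(k) {
  if (k$k2 <= 0) stop("k2 must be > 0", call. = FALSE)
  if (k$k4 <= 0) {
    if (k$k3 > 0) stop("irreversible model (k4 = 0 with k3 > 0) has no finite V_T",
                       call. = FALSE)
    return(k$K1 / k$k2)
  }
  k$K1 / k$k2 * (1 + k$k3 / k$k4)
}
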