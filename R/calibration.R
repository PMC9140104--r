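#' Time-activity input function with unit state
#'
#' Tracks the state of an input curve through the pipeline:
#' `normalized` (dimensionless factorization output) -> `whole_blood`
#' (kBq/mL) -> `metab_corrected_plasma` (kBq/mL).
#'
#' @param time_min sample times (minutes), strictly increasing.
#' @param value curve values, >= 0 up to numerical noise.
#' @param state one of `"normalized"`, `"whole_blood"`,
#'   `"metab_corrected_plasma"`.
#' @return An object of class `input_function`.
#' @export
input_function <- function(time_min, value,
                           state = c("normalized", "whole_blood",
                                     "metab_corrected_plasma")) {
  state <- match.arg(state)
  if (length(time_min) != length(value)) stop("length mismatch", call. = FALSE)
  if (is.unsorted(time_min, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  structure(list(time_min = time_min, value = value, state = state),
            class = "input_function")
}

#' Unit-restoring scaling factors from the mixing-fraction constraint
#'
#' The factorization leaves the component curves on an arbitrary
#' normalized scale; the per-voxel arterial and tissue mixing fractions,
#' however, must sum to one. The scales are recovered by minimizing
#' \deqn{\sum_i (\omega_{i,AIF} s_{AIF} + \omega_{i,TISSUE} s_{TISSUE} - 1)^2}
#' (the `"printed"` convention, linear least squares in the two unknowns),
#' or the `"reciprocal"` form with \eqn{\omega/s} in place of
#' \eqn{\omega \cdot s}. The two conventions yield reciprocal argmins and
#' the identical restored input function; `unit_scale_aif` is always the
#' multiplier that takes the normalized curve to physical units.
#'
#' @param W n x 2 weight matrix (columns arterial, tissue) from a
#'   normalized fit; must be rank 2 (voxels must differ in mixing ratio).
#' @param convention `"printed"` or `"reciprocal"`.
#' @param method closed-form least squares (default) or an iterative
#'   bound-constrained optimizer (retained for parity checks).
#' @param plaus_range optional plausibility range for the argmin; `NULL`
#'   disables the range check (the natural magnitude of the argmin depends
#'   on the component normalization: with unit-sum rows on kBq/mL data the
#'   printed-convention argmin is of order 1 / sum(AIF)).
#' @param clip clip out-of-range or non-positive solutions into
#'   `plaus_range` instead of merely warning.
#' @param strict abort instead of warn on implausible or non-positive
#'   solutions.
#' @return An object of class `scaling_factors`: `s_aif`, `s_tissue`,
#'   `objective_value`, `convention`, `unit_scale_aif`, `unit_scale_tissue`.
#' @export
optimize_scaling <- function(W, convention = c("printed", "reciprocal"),
                             method = c("closed_form", "optim"),
                             plaus_range = NULL, clip = FALSE,
                             strict = FALSE) {
  convention <- match.arg(convention)
  method <- match.arg(method)
  W <- as.matrix(W)
  if (nrow(W) < 2L) stop("need at least 2 voxels", call. = FALSE)
  if (qr(W)$rank < 2L) {
    stop("weight matrix is rank 1: mixing fractions are not identifiable",
         call. = FALSE)
  }
  ones <- rep(1, nrow(W))
  if (method == "closed_form") {
    coefs <- qr.solve(W, ones)  # OLS in the multipliers of the printed form
  } else {
    f <- function(s) sum((W[, 1] * s[1] + W[, 2] * s[2] - 1)^2)
    coefs <- stats::nlminb(c(1, 1), f, lower = rep(-1e6, 2),
                           upper = rep(1e6, 2),
                           control = list(rel.tol = 1e-12))$par
  }
  obj <- sum((W %*% coefs - 1)^2)

  s <- if (convention == "printed") coefs else 1 / coefs
  handle <- function(v, what) {
    if (!is.finite(v) || v <= 0) {
      msg <- paste0("non-positive ", what, " scale (", format(v), ")")
      if (strict) stop(msg, call. = FALSE)
      warning(msg, if (clip && !is.null(plaus_range)) "; clipped")
      if (clip && !is.null(plaus_range)) v <- plaus_range[1]
    } else if (!is.null(plaus_range) &&
               (v < plaus_range[1] || v > plaus_range[2])) {
      msg <- paste0(what, " scale ", format(v), " outside plausible range")
      if (strict) stop(msg, call. = FALSE)
      warning(msg, if (clip) "; clipped")
      if (clip) v <- min(max(v, plaus_range[1]), plaus_range[2])
    }
    v
  }
  s1 <- handle(s[1], "arterial"); s2 <- handle(s[2], "tissue")
  # the physical-unit multiplier: s itself in the reciprocal convention,
  # 1/s under the printed objective (whose argmin is the reciprocal scale)
  us <- if (convention == "printed") c(1 / s1, 1 / s2) else c(s1, s2)
  structure(
    list(s_aif = s1, s_tissue = s2, objective_value = obj,
         convention = convention, unit_scale_aif = us[1],
         unit_scale_tissue = us[2]),
    class = "scaling_factors"
  )
}

#' Scale the normalized arterial component to whole-blood units
#'
#' @param fit an `mbmf_fit` from [fit_mbmf()].
#' @param scaling a `scaling_factors` from [optimize_scaling()].
#' @param t_min evaluation grid in minutes (default: 0.05-min steps over
#'   the scan, the fine grid later used for Logan integrals).
#' @return An [input_function()] in `whole_blood` state.
#' @export
scale_idif <- function(fit, scaling,
                       t_min = seq(0, max(fit$schedule$end_s) / 60, by = 0.05)) {
  v <- scaling$unit_scale_aif * mbmf_curve(fit, t_min, "aif")
  input_function(t_min, v, state = "whole_blood")
}

#' Population metabolite-correction model
#'
#' Multiplicative conversion from whole-blood activity to metabolite-
#' corrected plasma activity: \eqn{1 - a(1 - e^{-b t})} with `t` in
#' minutes. The packaged population defaults are `a = 0.29`,
#' `b = 0.03 min^-1`.
#'
#' @param a composite-fraction amplitude, in [0, 1].
#' @param b rate (1/min), >= 0.
#' @param source provenance tag.
#' @return An object of class `metabolite_model`.
#' @export
metabolite_model <- function(a = 0.29, b = 0.03,
                             source = "population-default") {
  if (a < 0 || a > 1) stop("a must lie in [0, 1]", call. = FALSE)
  if (b < 0) stop("b must be >= 0", call. = FALSE)
  structure(list(a = a, b = b, source = source), class = "metabolite_model")
}

#' @rdname metabolite_model
#' @param mm a `metabolite_model`.
#' @param t_min time(s) in minutes.
#' @export
metab_multiplier <- function(mm, t_min) {
  1 - mm$a * (1 - exp(-mm$b * t_min))
}

#' Fit the composite plasma/metabolite fraction from blood tables
#'
#' For each subject the composite fraction at the standard sample times is
#' parent_fraction x (plasma / whole blood); the pointwise mean across
#' subjects is fitted with nonlinear least squares to
#' \eqn{1 - a(1 - e^{-b t})}.
#'
#' @param tables list of `blood_table`s (one per subject).
#' @param times_min sample times (minutes) at which the parent fraction
#'   was assayed.
#' @param tol_s matching tolerance between requested times and table rows.
#' @return A [metabolite_model()] with `source = "fitted"`.
#' @export
fit_composite_fraction <- function(tables, times_min = c(5, 15, 30, 60),
                                   tol_s = 1) {
  if (inherits(tables, "blood_table")) tables <- list(tables)
  comp <- matrix(NA_real_, nrow = length(tables), ncol = length(times_min))
  for (i in seq_along(tables)) {
    bt <- tables[[i]]
    row <- vapply(times_min, function(tm) {
      j <- which(abs(bt$time_s - tm * 60) <= tol_s)
      if (length(j) != 1L || is.na(bt$parent_fraction[j]) ||
          is.na(bt$plasma_kBq_mL[j]) || bt$wb_kBq_mL[j] <= 0) {
        return(NA_real_)
      }
      bt$parent_fraction[j] * bt$plasma_kBq_mL[j] / bt$wb_kBq_mL[j]
    }, numeric(1))
    if (anyNA(row)) {
      warning("subject ", i, " is missing a composite-fraction time point; dropped")
      next
    }
    comp[i, ] <- row
  }
  keep <- stats::complete.cases(comp)
  if (!any(keep)) stop("no subject has a complete set of time points", call. = FALSE)
  y <- colMeans(comp[keep, , drop = FALSE])
  if (length(unique(times_min)) < 2L) {
    stop("need >= 2 distinct time points to fit", call. = FALSE)
  }
  fit <- minpack.lm::nls.lm(
    par = c(a = 0.3, b = 0.03), lower = c(0, 0), upper = c(1, 5),
    fn = function(p) 1 - p[1] * (1 - exp(-p[2] * times_min)) - y,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  metabolite_model(a = unname(cf["a"]), b = unname(cf["b"]), source = "fitted")
}

#' Convert a whole-blood input function to metabolite-corrected plasma
#'
#' @param idif an [input_function()] in `whole_blood` state.
#' @param mm a [metabolite_model()].
#' @return An [input_function()] in `metab_corrected_plasma` state.
#' @export
apply_metabolite_correction <- function(idif, mm = metabolite_model()) {
  if (!inherits(idif, "input_function") || idif$state != "whole_blood") {
    stop("input must be an input_function in whole_blood state", call. = FALSE)
  }
  input_function(idif$time_min, idif$value * metab_multiplier(mm, idif$time_min),
                 state = "metab_corrected_plasma")
}

#' Metabolite-corrected plasma input from measured blood samples
#'
#' Plasma activity times the parent fraction, with the parent fraction
#' linearly interpolated (constant-extrapolated) across sample times when
#' it was assayed only at a subset of draws.
#'
#' @param bt a `blood_table`.
#' @return An [input_function()] in `metab_corrected_plasma` state.
#' @export
input_from_blood_table <- function(bt) {
  pf <- bt$parent_fraction
  if (all(is.na(pf))) stop("blood table has no parent-fraction data", call. = FALSE)
  if (anyNA(pf)) {
    known <- !is.na(pf)
    pf <- stats::approx(bt$time_s[known], pf[known], xout = bt$time_s,
                        rule = 2)$y
  }
  if (all(is.na(bt$plasma_kBq_mL))) {
    stop("blood table has no plasma activity", call. = FALSE)
  }
  input_function(bt$time_s / 60, bt$plasma_kBq_mL * pf,
                 state = "metab_corrected_plasma")
}
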