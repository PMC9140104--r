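#' Voxel-by-frame activity matrix from a carotid mask
#'
#' @param image a [dynamic_image()].
#' @param mask a `carotid_mask` from [segment_carotid()], or an integer
#'   matrix of voxel coordinates (columns x, y, z).
#' @return An object of class `voxel_matrix`: list with `A` (n x m matrix,
#'   rows in mask voxel order), `voxels` and `schedule`.
#' @export
build_matrix <- function(image, mask) {
  vox <- if (inherits(mask, "carotid_mask")) mask$voxels else mask
  if (is.null(dim(vox)) || nrow(vox) == 0L) stop("mask is empty", call. = FALSE)
  m <- n_frames(image$schedule)
  A <- matrix(0, nrow = nrow(vox), ncol = m)
  for (j in seq_len(m)) {
    A[, j] <- image$data[, , , j][vox[, 1:3, drop = FALSE]]
  }
  if (!all(is.finite(A))) stop("non-finite activity in voxel matrix", call. = FALSE)
  structure(list(A = A, voxels = vox, schedule = image$schedule),
            class = "voxel_matrix")
}

#' Least-squares voxel weights for fixed component curves
#'
#' Solves, independently for every voxel row, the ordinary (sign-
#' unconstrained) least-squares problem `min ||w_i H - A_i||^2` for the
#' 2-row component matrix H.
#'
#' @param H 2 x m component matrix (rank 2).
#' @param A n x m voxel matrix.
#' @param nonneg clip the solution at zero via nonnegative least squares
#'   (off by default, matching a plain linear solve).
#' @return n x 2 weight matrix W.
#' @export
solve_weights <- function(H, A, nonneg = FALSE) {
  if (nrow(H) != 2L) stop("H must have 2 rows", call. = FALSE)
  G <- H %*% t(H)
  if (!is.finite(rcond(G)) || rcond(G) < 1e-12) {
    stop("component matrix H is rank deficient", call. = FALSE)
  }
  W <- A %*% t(H) %*% solve(G)
  if (nonneg) {
    bad <- which(W[, 1] < 0 | W[, 2] < 0)
    if (length(bad)) {
      # active-set for the 2-variable case, vectorized over offending rows:
      # the constrained optimum lies on one of the single-component axes
      Ab <- A[bad, , drop = FALSE]
      w1 <- pmax(0, as.numeric(Ab %*% H[1, ]) / sum(H[1, ]^2))
      w2 <- pmax(0, as.numeric(Ab %*% H[2, ]) / sum(H[2, ]^2))
      # sse difference: ||w1 h1 - a||^2 vs ||w2 h2 - a||^2
      sse1 <- rowSums(Ab^2) - 2 * w1 * as.numeric(Ab %*% H[1, ]) + w1^2 * sum(H[1, ]^2)
      sse2 <- rowSums(Ab^2) - 2 * w2 * as.numeric(Ab %*% H[2, ]) + w2^2 * sum(H[2, ]^2)
      use1 <- sse1 <= sse2
      W[bad, 1] <- ifelse(use1, w1, 0)
      W[bad, 2] <- ifelse(use1, 0, w2)
    }
  }
  W
}

# parameter packing for the factorization search --------------------------
#
# 9 free parameters (A1 and K1 are fixed at 1: row scales of H are absorbed
# by the least-squares weights, so the amplitudes are unidentifiable).
# lambda ordering lambda1 > lambda2 > lambda3 is enforced by mapping
# lambda2/lambda3 through unit-interval ratio parameters.
mbmf_bounds <- function() {
  list(
    lower = c(tau = 0, lA2 = -5, lA3 = -5, lL1 = 0, r2 = 0.001, r3 = 0.001,
              lk2 = -2, lk3 = -3, lk4 = -3),
    upper = c(tau = 3, lA2 = 2, lA3 = 2, lL1 = log10(50), r2 = 0.999,
              r3 = 0.999, lk2 = log10(2), lk3 = 0, lk4 = 0)
  )
}

mbmf_unpack <- function(x) {
  lambda1 <- 10^x[["lL1"]]
  lo2 <- 0.05
  lambda2 <- lo2 + x[["r2"]] * (min(0.9 * lambda1, 5) - lo2)
  lo3 <- 0.001
  lambda3 <- lo3 + x[["r3"]] * (min(0.9 * lambda2, 0.5) - lo3)
  list(
    feng = feng_params(tau = x[["tau"]], A1 = 1, A2 = 10^x[["lA2"]],
                       A3 = 10^x[["lA3"]], lambda1 = lambda1,
                       lambda2 = lambda2, lambda3 = lambda3,
                       check_nonneg = FALSE),
    tissue = two_tc_params(K1 = 1, k2 = 10^x[["lk2"]], k3 = 10^x[["lk3"]],
                           k4 = 10^x[["lk4"]])
  )
}

#' Model-based factorization objective
#'
#' Builds the 2 x m component matrix H from the frame-averaged input and
#' tissue model curves for a parameter set, solves the voxel weights by
#' ordinary least squares, and returns the squared Frobenius residual
#' `||W H - A||^2`.
#'
#' @param params list with elements `feng` ([feng_params()]) and `tissue`
#'   ([two_tc_params()]).
#' @param vm a [build_matrix()] result.
#' @param metab optional [metabolite_model()]: when given, the tissue
#'   component is modeled as driven by the metabolite-corrected plasma
#'   input rather than whole blood.
#' @param points_per_frame quadrature nodes per frame for the model curves.
#' @return Scalar residual.
#' @export
mbmf_objective <- function(params, vm, metab = NULL, points_per_frame = 9) {
  H <- mbmf_components(params, vm$schedule, metab, points_per_frame)
  if (is.null(H)) return(1e30)
  W <- tryCatch(solve_weights(H, vm$A), error = function(e) NULL)
  if (is.null(W)) return(1e30)
  r <- sum((W %*% H - vm$A)^2)
  if (!is.finite(r)) 1e30 else r
}

# frame-averaged, unit-sum-normalized component rows (AIF first)
mbmf_components <- function(params, schedule, metab = NULL,
                            points_per_frame = 9) {
  aif <- model_frame_curve(params$feng, schedule,
                           points_per_frame = points_per_frame)
  tis <- model_frame_curve(params$feng, schedule, k = params$tissue,
                           metab = metab, points_per_frame = points_per_frame)
  sa <- sum(aif); st <- sum(tis)
  if (!is.finite(sa) || !is.finite(st) || sa <= 0 || st <= 0) return(NULL)
  rbind(aif / sa, tis / st)
}

#' Fit the model-based matrix factorization
#'
#' Decomposes the carotid voxel matrix A into `W %*% H`, where the two rows
#' of H are frame averages of the parametric input and tissue model curves
#' and W holds per-voxel mixing weights. The 9 free shape parameters are
#' estimated by bound-constrained nonlinear least squares (Levenberg-
#' Marquardt on the full residual matrix, with the voxel weights W
#' projected out by ordinary least squares at every evaluation).
#' Multi-start: one data-informed physiological start plus seeded
#' Latin-hypercube starts; the best residual wins. By default the residual
#' columns are weighted by the square root of frame duration (inverse-
#' variance weighting for counting-limited noise); the reported residual
#' and W are always unweighted. After convergence both rows of H are
#' normalized to unit sum, with W rescaled so `W %*% H` is unchanged.
#'
#' @param vm a [build_matrix()] result with `n >= 2` voxels and `m >= 12`
#'   frames.
#' @param n_starts number of optimizer starts (>= 1).
#' @param seed integer seed controlling the Latin-hypercube starts.
#' @param metab optional [metabolite_model()]; when given, the tissue
#'   component is modeled as driven by the metabolite-corrected plasma
#'   input (population model) instead of whole blood.
#' @param frame_weighting `"duration"` (default) or `"none"`.
#' @param points_per_frame quadrature nodes per frame.
#' @param max_iter Levenberg-Marquardt iteration cap per start.
#' @return An object of class `mbmf_fit`: `params`, `H` (2 x m, rows
#'   `aif`/`tissue`, each summing to 1), `W` (n x 2), `residual`
#'   (unweighted `||WH - A||^2`), `norm_sums` (pre-normalization row sums
#'   of the model curves), `n_starts_used`, `converged`, `schedule`.
#' @export
fit_mbmf <- function(vm, n_starts = 8, seed = 1, metab = NULL,
                     frame_weighting = c("duration", "none"),
                     points_per_frame = 9, max_iter = 200) {
  frame_weighting <- match.arg(frame_weighting)
  if (nrow(vm$A) < 2L) stop("need at least 2 voxels", call. = FALSE)
  if (ncol(vm$A) < 12L) stop("need at least 12 frames", call. = FALSE)
  b <- mbmf_bounds()
  nm <- names(b$lower)

  # tau initialized from the earliest frame whose mask-mean activity
  # exceeds 10% of the mask maximum
  mean_tac <- colMeans(vm$A)
  hot <- which(mean_tac > 0.1 * max(mean_tac))
  tau0 <- if (length(hot)) vm$schedule$start_s[hot[1]] / 60 else 0.25
  tau0 <- min(max(tau0, 0), 3)

  phys <- c(tau = tau0, lA2 = log10(0.026), lA3 = log10(0.024),
            lL1 = log10(4), r2 = 0.02, r3 = 0.09,
            lk2 = log10(0.15), lk3 = log10(0.05), lk4 = log10(0.04))
  starts <- list(phys)
  if (n_starts > 1) {
    set.seed(seed)
    u <- lhs::randomLHS(n_starts - 1, length(nm))
    for (i in seq_len(n_starts - 1)) {
      x <- b$lower + u[i, ] * (b$upper - b$lower)
      names(x) <- nm
      x[["tau"]] <- min(max(tau0 + (u[i, 1] - 0.5), 0), 3)
      starts[[i + 1]] <- x
    }
  }

  wj <- if (frame_weighting == "duration") {
    sqrt(frame_durations(vm$schedule) / mean(frame_durations(vm$schedule)))
  } else {
    rep(1, n_frames(vm$schedule))
  }
  Aw <- sweep(vm$A, 2, wj, "*")
  nres <- length(Aw)

  resfun <- function(x) {
    names(x) <- nm
    p <- tryCatch(mbmf_unpack(x), error = function(e) NULL)
    if (is.null(p)) return(rep(1e6, nres))
    H <- mbmf_components(p, vm$schedule, metab, points_per_frame)
    if (is.null(H)) return(rep(1e6, nres))
    Hw <- sweep(H, 2, wj, "*")
    W <- tryCatch(solve_weights(Hw, Aw), error = function(e) NULL)
    if (is.null(W)) return(rep(1e6, nres))
    r <- as.numeric(W %*% Hw - Aw)
    if (!all(is.finite(r))) rep(1e6, nres) else r
  }

  # a candidate solution is physiologically admissible when the
  # mixing-fraction scaling (sum-to-one constraint) has a positive solution
  # for both components; degenerate flat-valley solutions in which one
  # component absorbs part of the other fail this check
  admissible <- function(fit) {
    x <- stats::coef(fit); names(x) <- nm
    p <- tryCatch(mbmf_unpack(x), error = function(e) NULL)
    if (is.null(p)) return(FALSE)
    H <- mbmf_components(p, vm$schedule, metab, points_per_frame)
    if (is.null(H)) return(FALSE)
    W <- tryCatch(solve_weights(H, vm$A), error = function(e) NULL)
    if (is.null(W)) return(FALSE)
    s <- tryCatch(qr.solve(W, rep(1, nrow(W))), error = function(e) NULL)
    !is.null(s) && all(is.finite(s)) && all(s > 0)
  }

  fits <- list()
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(s, lower = b$lower, upper = b$upper, fn = resfun,
                         control = minpack.lm::nls.lm.control(maxiter = max_iter)),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$deviance) || fit$deviance >= 1e6) next
    fits[[length(fits) + 1L]] <- fit
  }
  if (length(fits) == 0L) {
    stop("matrix factorization failed to converge from any start",
         call. = FALSE)
  }
  dev <- vapply(fits, function(f) f$deviance, numeric(1))
  ok <- vapply(fits, admissible, logical(1))
  best <- if (any(ok)) fits[ok][[which.min(dev[ok])]] else {
    warning("no start yielded a positive mixing-fraction scaling; ",
            "returning the lowest-residual solution")
    fits[[which.min(dev)]]
  }

  x <- stats::coef(best); names(x) <- nm
  params <- mbmf_unpack(x)
  aif <- model_frame_curve(params$feng, vm$schedule,
                           points_per_frame = points_per_frame)
  tis <- model_frame_curve(params$feng, vm$schedule, k = params$tissue,
                           metab = metab, points_per_frame = points_per_frame)
  norm_sums <- c(aif = sum(aif), tissue = sum(tis))
  H <- rbind(aif = aif / norm_sums[["aif"]], tissue = tis / norm_sums[["tissue"]])
  W <- solve_weights(H, vm$A)
  colnames(W) <- c("aif", "tissue")
  residual <- sum((W %*% H - vm$A)^2)

  # label identifiability: the arterial component must peak first
  if (which.max(H["aif", ]) > which.max(H["tissue", ])) {
    warning("fitted arterial component peaks after the tissue component; ",
            "component labels may be unreliable")
  }

  structure(
    list(params = params, H = H, W = W, residual = residual,
         norm_sums = norm_sums, n_starts_used = length(starts),
         converged = best$info %in% 1:4, schedule = vm$schedule,
         metab = metab, frame_weighting = frame_weighting,
         points_per_frame = points_per_frame),
    class = "mbmf_fit"
  )
}

#' Continuous normalized component curves of a fit
#'
#' Evaluates the fitted input (or tissue) model curve at arbitrary times,
#' on the same normalized scale as the corresponding row of `H` (i.e.
#' divided by the pre-normalization frame sum).
#'
#' @param fit an `mbmf_fit`.
#' @param t_min times in minutes.
#' @param component `"aif"` or `"tissue"`.
#' @return Normalized curve values.
#' @export
mbmf_curve <- function(fit, t_min, component = c("aif", "tissue")) {
  component <- match.arg(component)
  if (component == "aif") {
    feng_aif(fit$params$feng, t_min) / fit$norm_sums[["aif"]]
  } else {
    two_tc_tissue(fit$params$feng, fit$params$tissue, t_min,
                  metab = fit$metab) / fit$norm_sums[["tissue"]]
  }
}
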