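#' Arterial blood-sampling schedule
#'
#' End-of-interval draw times: every 6 s through the first minute, every
#' 10 s through the second minute, once per minute through minute 5, then
#' every 5 min to the end of the scan (30 samples for a 60-min scan).
#'
#' @param scan_minutes scan length in minutes, >= 5.
#' @return Numeric vector of sample times (s), class `blood_schedule`.
#' @export
default_blood_schedule <- function(scan_minutes = 60) {
  if (scan_minutes < 5) stop("scan must be at least 5 minutes", call. = FALSE)
  end_s <- scan_minutes * 60
  t <- c(seq(6, 60, by = 6), seq(70, 120, by = 10), seq(180, 300, by = 60))
  if (end_s >= 600) t <- c(t, seq(600, end_s, by = 300))
  structure(t[t <= end_s], class = "blood_schedule")
}

# region label dictionary used by all phantoms
phantom_region_labels <- function() {
  stats::setNames(seq_along(target_regions()), target_regions())
}

#' Ground-truth description of a synthetic dynamic-PET phantom
#'
#' Presets emulate a 60-min dynamic brain acquisition: a typical fast-
#' peaking arterial input; nine labeled brain regions whose 2TC kinetics
#' are tuned so their closed-form distribution volumes match representative
#' regional values for high-affinity binders, with the mixed-affinity
#' preset scaled down by 1.35 (binding-class separation ~35%); two
#' carotid-like tubes in the inferior slices whose voxels mix arterial and
#' surrounding-tissue activity through a radial-Gaussian partial-volume
#' fraction.
#'
#' @param preset `"HAB"` (high-affinity) or `"MAB"` (mixed-affinity).
#' @param seed integer noise seed.
#' @param noise_cv Gaussian noise coefficient of variation at the image
#'   peak (0 disables noise).
#' @param dim 3D grid size.
#' @param voxel_mm voxel edge lengths (mm).
#' @return An object of class `phantom_truth`: `feng`, `region_kinetics`
#'   (named list of [two_tc_params()], plus `background`), `alpha` (3D
#'   mixing-fraction array), `labels` (a [label_map()]), `schedule`,
#'   `metab`, `noise_cv`, `seed`, `dose_MBq`, `weight_kg`.
#' @export
default_truth <- function(preset = c("HAB", "MAB"), seed = 1, noise_cv = 0.05,
                          dim = c(48L, 48L, 40L), voxel_mm = c(2, 2, 2.78)) {
  preset <- match.arg(preset)
  # representative regional distribution volumes for a high-affinity binder
  vt_hab <- c(putamen = 2.44, caudate = 1.91, thalamus = 2.97,
              hippocampus = 2.61, frontal = 2.70, temporal = 3.45,
              occipital = 2.96, parietal = 3.13, cerebellum = 3.16)
  vt <- if (preset == "HAB") vt_hab else vt_hab / 1.35
  K1 <- 0.15; k3 <- 0.06; k4 <- 0.04
  rk <- lapply(vt, function(v) {
    two_tc_params(K1 = K1, k2 = K1 * (1 + k3 / k4) / v, k3 = k3, k4 = k4)
  })
  rk$background <- two_tc_params(K1 = 0.06, k2 = 0.3, k3 = 0.01, k4 = 0.02)

  # classic fast-peak / two-tail input shape, amplitudes in kBq/mL for a
  # ~185 MBq injection (peak ~20 kBq/mL whole blood)
  feng <- feng_params(tau = 0.5, A1 = 141.8, A2 = 3.65, A3 = 3.47,
                      lambda1 = 4.1339, lambda2 = 0.1191, lambda3 = 0.0104)

  geom <- phantom_geometry(dim, voxel_mm)
  structure(
    list(preset = preset, feng = feng, region_kinetics = rk,
         alpha = geom$alpha, labels = geom$labels,
         schedule = default_frame_schedule(), metab = metabolite_model(),
         noise_cv = noise_cv, seed = as.integer(seed),
         dose_MBq = 185, weight_kg = 75,
         dim = dim, voxel_mm = voxel_mm),
    class = "phantom_truth"
  )
}

# carotid tubes + labeled brain blobs; alpha is the arterial mixing fraction
phantom_geometry <- function(dim, voxel_mm) {
  nx <- dim[1]; ny <- dim[2]; nz <- dim[3]
  if (nz < 39 || nx < 40 || ny < 40) {
    stop("phantom grid too small for tubes plus cerebellum", call. = FALSE)
  }
  tube_z <- 1:20
  cereb_z <- 22:27
  centers_x <- c(round(nx * 0.35), round(nx * 0.65))
  cy <- round(ny / 2)

  xs <- (seq_len(nx) - 0.5) * voxel_mm[1]
  ys <- (seq_len(ny) - 0.5) * voxel_mm[2]
  r2 <- outer(xs, ys, function(x, y) {
    d1 <- (x - (centers_x[1] - 0.5) * voxel_mm[1])^2 + (y - (cy - 0.5) * voxel_mm[2])^2
    d2 <- (x - (centers_x[2] - 0.5) * voxel_mm[1])^2 + (y - (cy - 0.5) * voxel_mm[2])^2
    pmin(d1, d2)
  })
  prof <- 0.95 * exp(-r2 / (2 * 2.5^2))
  prof[r2 > 6^2] <- 0
  alpha <- array(0, dim)
  for (z in tube_z) alpha[, , z] <- prof

  labels <- array(0L, dim)
  labs <- phantom_region_labels()
  cx <- round(nx / 2)
  labels[(cx - 10):(cx + 9), (cy - 10):(cy + 9), cereb_z] <- labs[["cerebellum"]]
  quad_x <- list((cx - 17):(cx - 3), (cx + 3):(cx + 17))
  quad_y <- list((cy - 17):(cy - 3), (cy + 3):(cy + 17))
  layer_z <- list(29:33, 35:39)
  other <- setdiff(target_regions(), "cerebellum")
  i <- 0L
  for (lz in layer_z) for (qx in quad_x) for (qy in quad_y) {
    i <- i + 1L
    labels[qx, qy, lz] <- labs[[other[i]]]
  }
  list(alpha = alpha, labels = label_map(labels, labs))
}

#' Simulate a dynamic PET phantom
#'
#' Every voxel's frame value is the frame average of
#' \eqn{\alpha_i C_{AIF}(t) + (1-\alpha_i) C_{TISSUE}(t)}, where the
#' tissue curve of brain regions and of the single tissue type surrounding
#' the tubes follows the region's 2TC kinetics driven by the metabolite-
#' corrected plasma input. Seeded Gaussian noise with variance
#' proportional to value / frame duration is added so the coefficient of
#' variation at the image peak equals `noise_cv`.
#'
#' @param truth a [default_truth()] (or modified copy).
#' @return List with `image` (a [dynamic_image()]), `labels` (a
#'   [label_map()]) and `truth`.
#' @export
simulate_phantom <- function(truth) {
  sched <- truth$schedule
  m <- n_frames(sched)
  nvox <- prod(truth$dim)

  aif_fa <- model_frame_curve(truth$feng, sched)
  curves <- lapply(truth$region_kinetics, function(k) {
    model_frame_curve(truth$feng, sched, k = k, metab = truth$metab)
  })

  flat <- matrix(rep(curves$background, each = nvox), nrow = nvox)
  labs <- truth$labels$region_names
  for (nmr in names(labs)) {
    idx <- which(truth$labels$labels == labs[[nmr]])
    if (length(idx)) {
      flat[idx, ] <- matrix(curves[[nmr]], length(idx), m, byrow = TRUE)
    }
  }
  tube <- which(truth$alpha > 0)
  if (length(tube)) {
    a <- truth$alpha[tube]
    flat[tube, ] <- a %o% aif_fa + (1 - a) %o% curves$background
  }

  if (truth$noise_cv > 0) {
    set.seed(truth$seed)
    dur <- frame_durations(sched)
    jmax <- arrayInd(which.max(flat), dim(flat))[2]
    vmax <- max(flat)
    sdmat <- truth$noise_cv *
      sqrt(pmax(flat, 0) * vmax) *
      matrix(rep(sqrt(dur[jmax] / dur), each = nvox), nrow = nvox)
    flat <- flat + matrix(stats::rnorm(nvox * m, sd = sdmat), nrow = nvox)
  }

  img <- dynamic_image(array(flat, c(truth$dim, m)), truth$voxel_mm, sched)
  list(image = img, labels = truth$labels, truth = truth)
}

#' Simulate arterial blood samples from phantom truth
#'
#' Whole blood is the input model evaluated exactly at the draw times (no
#' frame averaging for blood draws). The plasma-to-whole-blood ratio and
#' parent fraction are plausible decreasing factors whose product is
#' exactly the truth's composite metabolite model.
#'
#' @param truth a `phantom_truth`.
#' @param schedule a [default_blood_schedule()] (s).
#' @param split exponent in (0, 1) dividing the composite fraction between
#'   the parent fraction (`split`) and the plasma ratio (`1 - split`).
#' @return A `blood_table`.
#' @export
simulate_blood_samples <- function(truth, schedule = default_blood_schedule(),
                                   split = 0.7) {
  t_min <- as.numeric(schedule) / 60
  wb <- feng_aif(truth$feng, t_min)
  comp <- metab_multiplier(truth$metab, t_min)
  pf <- comp^split
  ratio <- comp^(1 - split)
  blood_table(as.numeric(schedule), wb, plasma_kBq_mL = wb * ratio,
              parent_fraction = pf)
}

#' Simulate a genotype cohort of phantoms
#'
#' Draws `n` subject-level variations of a preset: a common multiplicative
#' lognormal factor on all regional K1 (between-subject binding spread)
#' and an independent lognormal factor on the input-function amplitudes.
#'
#' @param preset `"HAB"` or `"MAB"`.
#' @param n subjects.
#' @param seed cohort seed; subject i uses noise seed `seed * 1000 + i`.
#' @param k1_sd,amp_sd lognormal sigma of the K1 and amplitude factors.
#' @param noise_cv per-subject image noise level.
#' @return List of `phantom_truth` objects.
#' @export
sample_cohort <- function(preset, n, seed = 1, k1_sd = 0.08, amp_sd = 0.10,
                          noise_cv = 0.05) {
  set.seed(seed)
  fk <- exp(stats::rnorm(n, 0, k1_sd))
  fa <- exp(stats::rnorm(n, 0, amp_sd))
  lapply(seq_len(n), function(i) {
    tr <- default_truth(preset, seed = seed * 1000L + i, noise_cv = noise_cv)
    tr$region_kinetics <- lapply(tr$region_kinetics, function(k) {
      two_tc_params(k$K1 * fk[i], k$k2, k$k3, k$k4)
    })
    f <- tr$feng
    tr$feng <- feng_params(f$tau, f$A1 * fa[i], f$A2 * fa[i], f$A3 * fa[i],
                           f$lambda1, f$lambda2, f$lambda3)
    tr
  })
}
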