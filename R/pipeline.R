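#' Run the three-step input-function extraction end-to-end
#'
#' Segmentation of carotid voxels from the early frames, model-based
#' matrix factorization of the voxel matrix, unit-restoring scaling from
#' the mixing-fraction constraint, and population metabolite correction.
#'
#' @param image a [dynamic_image()], or a NIfTI path (then `timing` must
#'   be the timing-TSV path).
#' @param labels a [label_map()], or a NIfTI path (then `region_names`
#'   must be given).
#' @param timing,region_names used only when paths are passed.
#' @param n_starts,seed,points_per_frame factorization settings, see
#'   [fit_mbmf()].
#' @param convention scaling convention, see [optimize_scaling()].
#' @param metab a [metabolite_model()].
#' @param strict abort on implausible scaling solutions.
#' @param out_dir optional directory; when given, the mask, component
#'   curves, weights and input functions are written there.
#' @return List with `idif` (metabolite-corrected plasma
#'   [input_function()]), `whole_blood`, `fit` (`mbmf_fit`), `scaling`,
#'   `mask`, and a one-line-per-stage `log` character vector.
#' @export
run_idif <- function(image, labels, timing = NULL, region_names = NULL,
                     n_starts = 8, seed = 1, points_per_frame = 9,
                     convention = "printed", metab = metabolite_model(),
                     strict = FALSE, out_dir = NULL) {
  if (is.character(image)) {
    if (is.null(timing)) stop("timing path required with an image path", call. = FALSE)
    image <- load_dynamic(image, timing)
  }
  if (is.character(labels)) {
    if (is.null(region_names)) stop("region_names required with a label path",
                                    call. = FALSE)
    labels <- load_label_map(labels, region_names)
  }
  log <- character()
  mask <- segment_carotid(image, labels)
  log <- c(log, sprintf("segment: %d voxels over slices %d-%d", mask$n,
                        mask$slice_range[["first"]], mask$slice_range[["last"]]))
  vm <- build_matrix(image, mask)
  fit <- fit_mbmf(vm, n_starts = n_starts, seed = seed, metab = metab,
                  points_per_frame = points_per_frame)
  log <- c(log, sprintf("mbmf: residual %.6g, %d starts, converged %s",
                        fit$residual, fit$n_starts_used, fit$converged))
  scaling <- optimize_scaling(fit$W, convention = convention, strict = strict)
  log <- c(log, sprintf("scaling (%s): s_aif %.4g, s_tissue %.4g, objective %.4g",
                        scaling$convention, scaling$s_aif, scaling$s_tissue,
                        scaling$objective_value))
  wb <- scale_idif(fit, scaling)
  idif <- apply_metabolite_correction(wb, metab)
  log <- c(log, sprintf("metabolite correction: a %.3g, b %.3g (%s)",
                        metab$a, metab$b, metab$source))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_mask(mask, file.path(out_dir, "carotid_mask.nii.gz"))
    utils::write.table(
      data.frame(frame = seq_len(ncol(fit$H)), aif = fit$H["aif", ],
                 tissue = fit$H["tissue", ]),
      file.path(out_dir, "components.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE
    )
    utils::write.table(cbind(as.data.frame(mask$voxels), as.data.frame(fit$W)),
                       file.path(out_dir, "weights.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(data.frame(time_min = idif$time_min, value = idif$value),
                       file.path(out_dir, "idif.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(params = fit$params, residual = fit$residual,
           scaling = unclass(scaling), log = log),
      file.path(out_dir, "idif_fit.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE
    )
  }
  list(idif = idif, whole_blood = wb, fit = fit, scaling = scaling,
       mask = mask, log = log)
}

#' Regional quantification table
#'
#' Logan distribution volumes from the image-derived input for every
#' target region, the reference-region Logan slope against the cerebellum,
#' and optionally SUV (when dose and weight are given) and the
#' arterial-sampling gold standard with percent errors (when a blood table
#' is given).
#'
#' @param image a [dynamic_image()].
#' @param labels a [label_map()].
#' @param idif a metabolite-corrected [input_function()] (from
#'   [run_idif()]).
#' @param blood optional `blood_table` for V_T,AIF.
#' @param dose_MBq,weight_kg optional, enable SUV rows.
#' @param t_star Logan linearization start (min).
#' @param suv_window SUV window (min).
#' @param reference reference-region name.
#' @param subject subject identifier carried into the table.
#' @return Data frame with columns `subject`, `region`, `metric`
#'   (`VT_IDIF`, `VT_REF`, `VT_AIF`, `ERR_PCT`, `SUV`), `value`.
#' @export
run_quantification <- function(image, labels, idif, blood = NULL,
                               dose_MBq = NULL, weight_kg = NULL,
                               t_star = 30, suv_window = c(40, 60),
                               reference = "cerebellum",
                               subject = "subject1") {
  if (!is.null(dose_MBq) && is.na(dose_MBq)) dose_MBq <- NULL
  if (!is.null(weight_kg) && is.na(weight_kg)) weight_kg <- NULL
  regions <- intersect(target_regions(), names(labels$region_names))
  tacs <- lapply(regions, function(r) extract_tac(image, labels, r))
  names(tacs) <- regions

  have_ref <- reference %in% regions
  if (!have_ref) warning("reference region '", reference,
                         "' missing; reference Logan skipped")
  aif_input <- if (!is.null(blood)) input_from_blood_table(blood)

  rows <- list()
  add <- function(region, metric, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject = subject, region = region, metric = metric, value = value
    )
  }
  for (r in regions) {
    vt_idif <- logan_vt(tacs[[r]], idif, t_star = t_star)$vt
    add(r, "VT_IDIF", vt_idif)
    if (have_ref) {
      add(r, "VT_REF", logan_ref(tacs[[r]], tacs[[reference]], t_star = t_star)$vt)
    }
    if (!is.null(aif_input)) {
      vt_aif <- logan_vt(tacs[[r]], aif_input, t_star = t_star)$vt
      add(r, "VT_AIF", vt_aif)
      add(r, "ERR_PCT", percent_error(vt_idif, vt_aif))
    }
    if (!is.null(dose_MBq) && !is.null(weight_kg)) {
      add(r, "SUV", compute_suv(tacs[[r]], dose_MBq, weight_kg, suv_window))
    }
  }
  do.call(rbind, rows)
}

#' Simulate and quantify a phantom cohort
#'
#' Runs the full extraction and quantification pipeline over a simulated
#' genotype cohort (see [sample_cohort()]) and returns one row per
#' subject, region and metric.
#'
#' @param preset `"HAB"` or `"MAB"`.
#' @param n number of subjects.
#' @param seed cohort seed (drives subject variation, image noise and the
#'   factorization starts).
#' @param n_starts factorization starts per subject.
#' @param noise_cv image noise level.
#' @return Data frame as from [run_quantification()], with subject ids
#'   `"<preset>_<i>"`.
#' @export
run_cohort <- function(preset, n, seed = 1, n_starts = 3, noise_cv = 0.05) {
  truths <- sample_cohort(preset, n, seed = seed, noise_cv = noise_cv)
  out <- lapply(seq_along(truths), function(i) {
    tr <- truths[[i]]
    ph <- simulate_phantom(tr)
    res <- run_idif(ph$image, ph$labels, n_starts = n_starts,
                    seed = seed * 100L + i)
    run_quantification(ph$image, ph$labels, res$idif,
                       dose_MBq = tr$dose_MBq, weight_kg = tr$weight_kg,
                       subject = paste0(preset, "_", i))
  })
  do.call(rbind, out)
}

#' Per-subject mean of a metric across regions
#'
#' @param table a [run_quantification()] / [run_cohort()] table.
#' @param metric metric name, e.g. `"VT_IDIF"`.
#' @return Named numeric vector, one mean value per subject.
#' @export
subject_means <- function(table, metric) {
  sub <- table[table$metric == metric, ]
  tapply(sub$value, sub$subject, mean)
}

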