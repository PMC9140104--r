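#' Dynamic PET image container
#'
#' Bundles a 4D activity array (x, y, z, frame; kBq/mL, decay-corrected)
#' with its voxel size and frame schedule. The fourth axis must match the
#' schedule length. Axis orientation follows the array-index convention:
#' first axis patient left-to-right, second posterior-to-anterior, third
#' inferior-to-superior, unless overridden.
#'
#' @param data 4D numeric array of activity concentration (kBq/mL).
#' @param voxel_size_mm numeric length-3 voxel edge lengths in mm.
#' @param schedule a [frame_schedule()].
#' @param orientation character length-3 axis labels.
#' @return An object of class `dynamic_image`.
#' @export
dynamic_image <- function(data, voxel_size_mm, schedule,
                          orientation = c("left-right", "posterior-anterior",
                                          "inferior-superior")) {
  if (length(dim(data)) != 4L) stop("data must be a 4D array", call. = FALSE)
  if (dim(data)[4] != n_frames(schedule)) {
    stop("frame axis length (", dim(data)[4], ") does not match schedule length (",
         n_frames(schedule), ")", call. = FALSE)
  }
  if (!all(is.finite(data))) stop("activity values must be finite", call. = FALSE)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) {
    stop("voxel_size_mm must be three positive lengths", call. = FALSE)
  }
  structure(
    list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
         schedule = schedule, orientation = orientation),
    class = "dynamic_image"
  )
}

#' Integer label map aligned with a dynamic image
#'
#' @param labels 3D integer array; 0 is reserved for background.
#' @param region_names named integer vector mapping region name to label.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, region_names) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array", call. = FALSE)
  if (is.null(names(region_names)) || any(names(region_names) == "")) {
    stop("region_names must be a fully named integer vector", call. = FALSE)
  }
  if (any(region_names == 0)) stop("label 0 is reserved for background", call. = FALSE)
  structure(list(labels = labels, region_names = region_names),
            class = "label_map")
}

#' Load a 4D dynamic PET volume with its timing sidecar
#'
#' @param image_path path to a 4D NIfTI volume (kBq/mL, decay-corrected).
#' @param timing_path path to the frame-timing TSV (`start_s`, `end_s`).
#' @return A [dynamic_image()].
#' @export
load_dynamic <- function(image_path, timing_path) {
  nii <- RNifti::readNifti(image_path)
  arr <- as.array(nii)
  if (length(dim(arr)) != 4L) {
    stop("expected a 4D NIfTI image, got ", length(dim(arr)), "D", call. = FALSE)
  }
  schedule <- read_frame_schedule(timing_path)
  pix <- attr(nii, "pixdim")
  if (is.null(pix)) pix <- RNifti::pixdim(nii)
  dynamic_image(arr, voxel_size_mm = abs(pix[1:3]), schedule = schedule)
}

#' Write a dynamic image (and its timing sidecar) to disk
#'
#' @param image a [dynamic_image()].
#' @param image_path output NIfTI path.
#' @param timing_path optional output TSV path for the schedule.
#' @return `image_path`, invisibly.
#' @export
write_dynamic <- function(image, image_path, timing_path = NULL) {
  nii <- RNifti::asNifti(image$data,
    pixdim = c(image$voxel_size_mm, mean(frame_durations(image$schedule)))
  )
  RNifti::writeNifti(nii, image_path, datatype = "double")
  if (!is.null(timing_path)) write_frame_schedule(image$schedule, timing_path)
  invisible(image_path)
}

#' Load a 3D label map
#'
#' @param label_path path to a 3D integer NIfTI.
#' @param region_names named integer vector of region labels.
#' @return A [label_map()].
#' @export
load_label_map <- function(label_path, region_names) {
  arr <- as.array(RNifti::readNifti(label_path))
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  label_map(round(arr), region_names)
}

#' @rdname load_label_map
#' @param map a [label_map()] to write.
#' @param path output NIfTI path.
#' @export
write_label_map <- function(map, path) {
  RNifti::writeNifti(RNifti::asNifti(map$labels), path, datatype = "int16")
  invisible(path)
}

#' Region time-activity curve
#'
#' @param midpoint_s frame midpoint times (s), strictly increasing.
#' @param duration_s frame durations (s).
#' @param value activity (kBq/mL) per frame.
#' @return An object of class `tac`: a data frame with those columns.
#' @export
tac <- function(midpoint_s, duration_s, value) {
  if (!(length(midpoint_s) == length(duration_s) &&
        length(duration_s) == length(value))) {
    stop("tac columns must have equal length", call. = FALSE)
  }
  if (is.unsorted(midpoint_s, strictly = TRUE)) {
    stop("midpoints must be strictly increasing", call. = FALSE)
  }
  structure(
    data.frame(midpoint_s = midpoint_s, duration_s = duration_s, value = value),
    class = c("tac", "data.frame")
  )
}

#' Extract a regional time-activity curve
#'
#' The regional value for each frame is the unweighted arithmetic mean over
#' the region's voxels.
#'
#' @param image a [dynamic_image()].
#' @param map a [label_map()] spatially aligned with `image`.
#' @param region_name region to extract (must exist in `map$region_names`).
#' @return A [tac()].
#' @export
extract_tac <- function(image, map, region_name) {
  if (!identical(dim(image$data)[1:3], dim(map$labels))) {
    stop("label map shape does not match image spatial shape", call. = FALSE)
  }
  if (!region_name %in% names(map$region_names)) {
    stop("unknown region: ", region_name, call. = FALSE)
  }
  lab <- map$region_names[[region_name]]
  idx <- which(map$labels == lab)
  if (length(idx) == 0L) stop("region '", region_name, "' is empty", call. = FALSE)
  m <- n_frames(image$schedule)
  nvox <- prod(dim(image$data)[1:3])
  flat <- matrix(image$data, nrow = nvox, ncol = m)
  vals <- colMeans(flat[idx, , drop = FALSE])
  tac(frame_midpoints(image$schedule), frame_durations(image$schedule), vals)
}

#' Read or write an arterial blood-sample table
#'
#' Tab-separated with columns `time_s`, `wb_kBq_mL`, `plasma_kBq_mL`,
#' `parent_fraction` (the latter two may be NA where unmeasured). Times
#' must be strictly increasing and activities non-negative.
#'
#' @param path file path.
#' @return A data frame of class `blood_table`.
#' @export
read_blood_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t")
  blood_table(tab$time_s, tab$wb_kBq_mL, tab$plasma_kBq_mL, tab$parent_fraction)
}

#' @rdname read_blood_table
#' @param time_s sample draw times (s).
#' @param wb_kBq_mL whole-blood activity (kBq/mL).
#' @param plasma_kBq_mL plasma activity (kBq/mL).
#' @param parent_fraction fraction of unmetabolized parent tracer in [0, 1].
#' @export
blood_table <- function(time_s, wb_kBq_mL, plasma_kBq_mL = NA_real_,
                        parent_fraction = NA_real_) {
  if (is.unsorted(time_s, strictly = TRUE)) {
    stop("sample times must be strictly increasing", call. = FALSE)
  }
  if (any(wb_kBq_mL < 0, na.rm = TRUE) || any(plasma_kBq_mL < 0, na.rm = TRUE)) {
    stop("activities must be >= 0", call. = FALSE)
  }
  pf <- parent_fraction
  if (any(pf < 0 | pf > 1, na.rm = TRUE)) {
    stop("parent_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(
    data.frame(time_s = time_s, wb_kBq_mL = wb_kBq_mL,
               plasma_kBq_mL = plasma_kBq_mL, parent_fraction = pf),
    class = c("blood_table", "data.frame")
  )
}

#' @rdname read_blood_table
#' @param table a `blood_table`.
#' @export
write_blood_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' The canonical target regions
#'
#' Nine brain regions used for quantification, with the cerebellum doubling
#' as the reference region.
#'
#' @return Character vector of region names.
#' @export
target_regions <- function() {
  c("putamen", "caudate", "thalamus", "hippocampus", "frontal",
    "temporal", "occipital", "parietal", "cerebellum")
}
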