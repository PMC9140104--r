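#' Axial slice range for carotid segmentation
#'
#' The carotid search is restricted to slices below the cerebellum: from
#' the lowest slice in the field of view up to the slice just beneath the
#' lowest cerebellum slice (inclusive; 1-based indices along the
#' inferior-superior axis, the third array axis).
#'
#' @param map a [label_map()] containing a `cerebellum` region.
#' @return Integer `c(first, last)` slice range.
#' @export
select_slice_range <- function(map) {
  if (!"cerebellum" %in% names(map$region_names)) {
    stop("label map has no cerebellum region", call. = FALSE)
  }
  lab <- map$region_names[["cerebellum"]]
  zs <- which(apply(map$labels == lab, 3, any))
  if (length(zs) == 0L) stop("cerebellum region is empty", call. = FALSE)
  lowest_cereb <- min(zs)
  if (lowest_cereb <= 1L) {
    stop("cerebellum reaches the bottom of the field of view; no slices to segment",
         call. = FALSE)
  }
  c(first = 1L, last = lowest_cereb - 1L)
}

#' Early-frame intensity volume
#'
#' Per-voxel duration-weighted mean activity over all frames whose interval
#' lies entirely within the first `window_s` seconds of the scan. With the
#' default schedule this is the six 10-second frames of the first minute.
#'
#' @param image a [dynamic_image()].
#' @param window_s length of the early window in seconds.
#' @return 3D array of mean early activity.
#' @export
early_intensity_volume <- function(image, window_s = 60) {
  sched <- image$schedule
  keep <- which(sched$start_s >= -1e-9 & sched$end_s <= window_s + 1e-9)
  if (length(keep) == 0L) {
    stop("no frame lies within the first ", window_s, " s", call. = FALSE)
  }
  dur <- frame_durations(sched)[keep]
  w <- dur / sum(dur)
  dims <- dim(image$data)[1:3]
  out <- array(0, dims)
  for (i in seq_along(keep)) {
    vol <- image$data[, , , keep[i], drop = FALSE]
    dim(vol) <- dims
    out <- out + w[i] * vol
  }
  out
}

#' Locate a per-slice carotid seed
#'
#' Finds the hottest early-frame voxel within the left or right half of an
#' axial slice. The midline column belongs to the left half; ties resolve
#' to the lowest linear index within the slice (column-major), for
#' reproducibility.
#'
#' @param early 3D early-intensity array from [early_intensity_volume()].
#' @param slice 1-based axial slice index.
#' @param side `"left"` or `"right"` (first array axis, left-to-right).
#' @return Integer `c(x, y)` in-plane seed coordinate, or `NULL` when the
#'   half-slice is entirely zero (flagged and excluded downstream).
#' @export
find_seed <- function(early, slice, side = c("left", "right")) {
  side <- match.arg(side)
  sl <- early[, , slice, drop = TRUE]
  nx <- nrow(sl)
  cols <- if (side == "left") seq_len(ceiling(nx / 2)) else (ceiling(nx / 2) + 1L):nx
  half <- sl[cols, , drop = FALSE]
  if (all(half == 0)) return(NULL)
  idx <- which.max(half)  # first maximum = lowest linear index
  x <- ((idx - 1L) %% length(cols)) + 1L
  y <- ((idx - 1L) %/% length(cols)) + 1L
  c(x = cols[x], y = y)
}

#' 5x5 diamond dilation of a seed
#'
#' All in-plane voxels within Manhattan distance 2 of the seed (a 13-voxel
#' diamond for interior seeds), clipped to the slice bounds.
#'
#' @param seed integer `c(x, y)`.
#' @param dim_xy slice dimensions `c(nx, ny)`.
#' @return Integer matrix with columns `x`, `y`.
#' @export
dilate_diamond <- function(seed, dim_xy) {
  offs <- expand.grid(dx = -2:2, dy = -2:2)
  offs <- offs[abs(offs$dx) + abs(offs$dy) <= 2, ]
  x <- seed[[1]] + offs$dx
  y <- seed[[2]] + offs$dy
  ok <- x >= 1 & x <= dim_xy[1] & y >= 1 & y <= dim_xy[2]
  cbind(x = as.integer(x[ok]), y = as.integer(y[ok]))
}

#' Automatic carotid segmentation from early dynamic frames
#'
#' For every axial slice below the cerebellum, takes the hottest
#' first-minute voxel on each side of the midline and dilates it with a
#' 5x5 diamond structuring element; the union over slices and sides is the
#' carotid mask.
#'
#' @param image a [dynamic_image()].
#' @param map a [label_map()] with a cerebellum region.
#' @return An object of class `carotid_mask`: list with `voxels` (integer
#'   matrix, columns x/y/z), `seeds` (per-slice seed table), `slice_range`
#'   and `n` (voxel count).
#' @export
segment_carotid <- function(image, map) {
  if (!identical(dim(image$data)[1:3], dim(map$labels))) {
    stop("label map shape does not match image spatial shape", call. = FALSE)
  }
  rng <- select_slice_range(map)
  early <- early_intensity_volume(image)
  dims <- dim(early)
  vox <- list(); seeds <- list()
  for (z in rng[["first"]]:rng[["last"]]) {
    for (side in c("left", "right")) {
      s <- find_seed(early, z, side)
      if (is.null(s)) next
      d <- dilate_diamond(s, dims[1:2])
      vox[[length(vox) + 1L]] <- cbind(d, z = z)
      seeds[[length(seeds) + 1L]] <-
        data.frame(z = z, side = side, x = s[["x"]], y = s[["y"]])
    }
  }
  if (length(vox) == 0L) stop("no carotid seeds found", call. = FALSE)
  all_vox <- do.call(rbind, vox)
  all_vox <- unique(all_vox)  # overlapping dilations are unioned
  all_vox <- all_vox[order(all_vox[, "z"], all_vox[, "y"], all_vox[, "x"]), ,
                     drop = FALSE]
  structure(
    list(voxels = all_vox, seeds = do.call(rbind, seeds),
         slice_range = rng, n = nrow(all_vox), dim = dims,
         side_convention = "array-left = patient-left (index convention)"),
    class = "carotid_mask"
  )
}

#' Export a carotid mask as a binary volume
#'
#' @param mask a `carotid_mask`.
#' @return 3D 0/1 integer array.
#' @export
mask_to_array <- function(mask) {
  arr <- array(0L, mask$dim)
  arr[mask$voxels] <- 1L
  arr
}

#' @rdname mask_to_array
#' @param path output NIfTI path.
#' @export
write_mask <- function(mask, path) {
  RNifti::writeNifti(RNifti::asNifti(mask_to_array(mask)), path,
                     datatype = "uint8")
  invisible(path)
}
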