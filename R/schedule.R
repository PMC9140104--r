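#' Frame schedules for dynamic PET acquisitions
#'
#' A frame schedule is an ordered table of frame start/end times in seconds.
#' Frames must be non-overlapping, strictly positive in duration and sorted
#' by start time.
#'
#' @param start_s,end_s numeric vectors of frame start and end times (s).
#' @return An object of class `frame_schedule`: a data frame with columns
#'   `start_s` and `end_s`.
#' @examples
#' fs <- frame_schedule(c(0, 10), c(10, 20))
#' frame_midpoints(fs)
#' @export
frame_schedule <- function(start_s, end_s) {
  if (length(start_s) != length(end_s)) {
    stop("start_s and end_s must have equal length", call. = FALSE)
  }
  if (length(start_s) == 0L) stop("schedule must contain >= 1 frame", call. = FALSE)
  if (!all(is.finite(start_s)) || !all(is.finite(end_s))) {
    stop("frame times must be finite", call. = FALSE)
  }
  if (any(end_s <= start_s)) stop("frame durations must be strictly positive", call. = FALSE)
  if (is.unsorted(start_s, strictly = TRUE)) {
    stop("frames must be in strictly increasing start order", call. = FALSE)
  }
  n <- length(start_s)
  if (n > 1L && any(start_s[-1] < end_s[-n] - 1e-9)) {
    stop("frames must not overlap", call. = FALSE)
  }
  structure(
    data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s)),
    class = c("frame_schedule", "data.frame")
  )
}

#' @rdname frame_schedule
#' @param x a `frame_schedule`.
#' @export
frame_midpoints <- function(x) (x$start_s + x$end_s) / 2

#' @rdname frame_schedule
#' @export
frame_durations <- function(x) x$end_s - x$start_s

#' @rdname frame_schedule
#' @export
n_frames <- function(x) nrow(x)

#' Default 60-minute dynamic acquisition schedule
#'
#' The standard schedule used throughout the package: 12 ten-second frames,
#' 9 twenty-second frames, 5 one-minute frames and 10 five-minute frames,
#' contiguous from injection at t = 0 (36 frames, 60 min total).
#'
#' @return A [frame_schedule()].
#' @export
default_frame_schedule <- function() {
  dur <- c(rep(10, 12), rep(20, 9), rep(60, 5), rep(300, 10))
  end <- cumsum(dur)
  frame_schedule(start_s = end - dur, end_s = end)
}

#' Read or write a frame-timing sidecar
#'
#' Frame timing travels as a two-column tab-separated table with header
#' columns `start_s` and `end_s`, in seconds.
#'
#' @param path file path of the TSV.
#' @return `read_frame_schedule` returns a [frame_schedule()];
#'   `write_frame_schedule` returns `path` invisibly.
#' @export
read_frame_schedule <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  if (!all(c("start_s", "end_s") %in% names(tab))) {
    stop("timing table must have columns start_s and end_s", call. = FALSE)
  }
  frame_schedule(tab$start_s, tab$end_s)
}

#' @rdname read_frame_schedule
#' @param schedule a [frame_schedule()] to serialize.
#' @export
write_frame_schedule <- function(schedule, path) {
  utils::write.table(as.data.frame(schedule), path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
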