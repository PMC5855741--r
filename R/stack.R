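#' Time-lapse image stack
#'
#' Container for a 2D grayscale time-lapse of one nucleus: a
#' `rows x cols x frames` intensity array (arbitrary units) with its pixel
#' size and frame interval.
#'
#' @param frames numeric array `rows x cols x n_frames` (a matrix is treated
#'   as a single frame).
#' @param pixel_size micrometres per pixel.
#' @param frame_interval minutes per frame.
#' @param condition optional condition label.
#' @return object of class `timelapse_stack`.
#' @export
timelapse_stack <- function(frames, pixel_size, frame_interval,
                            condition = NA_character_) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  stopifnot(length(dim(frames)) == 3L, pixel_size > 0, frame_interval > 0)
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval, condition = condition),
            class = "timelapse_stack")
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("timelapse_stack: %d frames of %dx%d px", d[3], d[1], d[2]))
  if (!is.na(x$condition)) cat(" (", x$condition, ")", sep = "")
  cat(sprintf("\n  %.3f um/px, %.1f min/frame, intensity %.1f-%.1f AU\n",
              x$pixel_size, x$frame_interval,
              min(x$frames), max(x$frames)))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack a `timelapse_stack`.
#' @return integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' Acquisition times of a stack
#' @param stack a `timelapse_stack`.
#' @return minutes since the first frame, one value per frame.
#' @export
stack_minutes <- function(stack) {
  (seq_len(n_frames(stack)) - 1) * stack$frame_interval
}

#' Read / write a stack as multi-page 16-bit grayscale TIFF
#'
#' Intensities are stored as 16-bit integers (AU are rounded to the nearest
#' integer and clipped to 0..65535).
#'
#' @param stack a `timelapse_stack`.
#' @param path TIFF file path.
#' @param pixel_size,frame_interval,condition metadata for [timelapse_stack()]
#'   (TIFF files do not carry them).
#' @return `write_stack` returns `path` invisibly; `read_stack` a
#'   `timelapse_stack`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "timelapse_stack"))
  nT <- n_frames(stack)
  pages <- lapply(seq_len(nT), function(t) {
    m <- round(stack$frames[, , t])
    m[m < 0] <- 0
    m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, pixel_size, frame_interval,
                       condition = NA_character_) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (t in seq_along(pages)) {
    pg <- pages[[t]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]
    frames[, , t] <- pg * 65535
  }
  timelapse_stack(frames, pixel_size, frame_interval, condition)
}

#' Reverse the time order of a stack
#'
#' Used for time-symmetry checks: on a reversed stack, merge and split events
#' exchange roles exactly.
#'
#' @param stack a `timelapse_stack`.
#' @return the reversed `timelapse_stack`.
#' @export
reverse_stack <- function(stack) {
  stack$frames <- stack$frames[, , rev(seq_len(n_frames(stack))), drop = FALSE]
  stack
}
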