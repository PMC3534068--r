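#' Frame stacks
#'
#' A frame stack is the model input \eqn{I(x, y, t)}: a `H x W x T` array of
#' grayscale intensities in `[0, 1]`. The first array axis is the image row
#' `y` (increasing downward), the second the column `x` (increasing
#' rightward), the third the frame index. Motion directions throughout the
#' package are measured in degrees with 0\eqn{^\circ} pointing rightward
#' (+x) and 90\eqn{^\circ} pointing upward on screen, so a motion of speed
#' `s` and direction `theta` displaces image content by
#' `s * c(cos(theta), -sin(theta))` in (column, row) units per frame.
#'
#' @param frames numeric `H x W x T` array with values in `[0, 1]`.
#' @return `frame_stack()` returns a validated object of class
#'   `"frame_stack"` (an array with a class attribute).
#' @examples
#' fs <- frame_stack(array(0, c(16, 16, 2)))
#' dim(fs)
#' @export
frame_stack <- function(frames) {
  frames <- unclass(frames)
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  d <- dim(frames)
  if (d[3] < 2) stop("a frame stack needs at least T = 2 frames")
  if (d[1] < 16 || d[2] < 16) stop("frames must be at least 16 x 16 pixels")
  if (!all(is.finite(frames))) stop("frame intensities must be finite")
  if (min(frames) < 0 || max(frames) > 1) {
    stop("frame intensities must lie in [0, 1]")
  }
  structure(frames, class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<frame_stack> %d frames of %d x %d px, intensity range [%.3f, %.3f]\n",
    d[3], d[1], d[2], min(x), max(x)
  ))
  invisible(x)
}

#' @rdname frame_stack
#' @param x object to test or convert.
#' @export
is_frame_stack <- function(x) inherits(x, "frame_stack")

#' @rdname frame_stack
#' @export
as_frame_stack <- function(x) {
  if (is_frame_stack(x)) x else frame_stack(x)
}

# Number of frames / spatial size helpers used internally.
n_frames <- function(fs) dim(fs)[3]
frame_size <- function(fs) dim(fs)[1:2]
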