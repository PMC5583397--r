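#' Time-lapse image stack
#'
#' Ordered sequence of single-channel frames with the acquisition frame rate.
#' Frames are stored as a numeric \code{height x width x n} array; pixel
#' values keep their original intensity scale, recorded in \code{range}.
#'
#' @param frames A numeric 3-D array (\code{H x W x T}) or list of equally
#'   shaped matrices.
#' @param fps Frames per second (default 10, the typical acquisition rate).
#' @param range Original intensity range; defaults to the observed range.
#' @return Object of class \code{image_stack}.
#' @export
image_stack <- function(frames, fps = 10, range = NULL) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1) stop("image_stack: frames differ in shape")
    frames <- array(unlist(frames), dim = c(dims[[1]], length(frames)))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (dim(frames)[3] < 1) stop("image_stack: zero frames")
  if (!all(is.finite(frames))) stop("image_stack: intensities must be finite")
  if (fps <= 0) stop("image_stack: fps must be > 0")
  if (is.null(range)) range <- base::range(frames)
  structure(list(frames = frames, fps = fps, range = range),
            class = "image_stack")
}

#' Number of frames in a stack
#' @param stack An [image_stack()].
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' Extract one frame as a matrix
#' @param stack An [image_stack()].
#' @param i Frame index (1-based).
#' @export
get_frame <- function(stack, i) {
  if (i < 1 || i > n_frames(stack)) stop("get_frame: frame index out of range")
  stack$frames[, , i]
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Image stack: %d frames of %d x %d px @ %g fps, intensity [%g, %g]\n",
              d[3], d[1], d[2], x$fps, x$range[1], x$range[2]))
  invisible(x)
}
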