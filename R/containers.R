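#' Video, mask and flow containers
#'
#' Light S3 containers used throughout the pipeline. A video sequence is an
#' `H x W x T` array of grayscale intensities in `[0, 1]` with a
#' `pixel_spacing` attribute (mm/px); a mask sequence is an `H x W x T` array
#' of 0/1 myocardial labels; a flow field is an `H x W x 2` array holding the
#' per-pixel displacement between two consecutive frames, channel order
#' `(dx, dy)` in px/frame. Coordinates are `(x, y) = (column, row)`, 0-based,
#' with pixel centers at integers, so pixel `(x, y)` lives at `a[y + 1, x + 1]`.
#'
#' @param frames numeric `H x W x T` array (or `H x W` matrix for one frame).
#' @param pixel_spacing physical pixel size in mm/px.
#' @return `video_sequence()` returns a classed array of intensities;
#'   `mask_sequence()` a classed integer array; `flow_field()` a classed
#'   `H x W x 2` array.
#' @examples
#' v <- video_sequence(array(runif(32 * 32 * 4), c(32, 32, 4)), pixel_spacing = 0.3)
#' n_frames(v)
#' @export
video_sequence <- function(frames, pixel_spacing = 1) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (length(dim(frames)) != 3L) stop_shape("video frames must be an H x W x T array")
  if (pixel_spacing <= 0) stop_input("pixel_spacing must be > 0")
  structure(frames, pixel_spacing = pixel_spacing,
            class = c("video_sequence", "array"))
}

#' @rdname video_sequence
#' @param masks integer/logical `H x W x T` array of 0/1 labels.
#' @export
mask_sequence <- function(masks, pixel_spacing = 1) {
  if (is.matrix(masks)) masks <- array(masks, c(dim(masks), 1L))
  if (length(dim(masks)) != 3L) stop_shape("masks must be an H x W x T array")
  storage.mode(masks) <- "integer"
  if (!all(masks %in% c(0L, 1L))) stop_input("mask values must be 0/1")
  structure(masks, pixel_spacing = pixel_spacing,
            class = c("mask_sequence", "array"))
}

#' @rdname video_sequence
#' @param field numeric `H x W x 2` array, channels `(dx, dy)`.
#' @export
flow_field <- function(field) {
  if (length(dim(field)) != 3L || dim(field)[3] != 2L)
    stop_shape("a flow field must be an H x W x 2 array (dx, dy)")
  structure(field, class = c("flow_field", "array"))
}

#' @rdname video_sequence
#' @param x a video or mask sequence.
#' @export
n_frames <- function(x) dim(x)[3]

#' @rdname video_sequence
#' @export
pixel_spacing <- function(x) attr(x, "pixel_spacing") %||% 1

frame_of <- function(x, t) x[, , t, drop = TRUE]

# Sample a flow field at 0-based sub-pixel positions; returns n x 2 (dx, dy).
sample_flow <- function(flow, pts) {
  cbind(bilinear_sample(flow[, , 1], pts[, 1], pts[, 2]),
        bilinear_sample(flow[, , 2], pts[, 1], pts[, 2]))
}

#' @export
print.video_sequence <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<video_sequence> %d x %d px, %d frames, %.3g mm/px\n",
              d[2], d[1], d[3], pixel_spacing(x)))
  invisible(x)
}

#' @export
print.mask_sequence <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<mask_sequence> %d x %d px, %d frames, %d foreground px in frame 1\n",
              d[2], d[1], d[3], sum(x[, , 1])))
  invisible(x)
}

#' @export
print.flow_field <- function(x, ...) {
  d <- dim(x)
  mag <- sqrt(x[, , 1]^2 + x[, , 2]^2)
  cat(sprintf("<flow_field> %d x %d px, |f| max %.3g px/frame\n", d[2], d[1], max(mag)))
  invisible(x)
}
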