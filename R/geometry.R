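#' Scene-camera frame geometry
#'
#' Describes the eye-tracker scene video: frame size in pixels, video frame
#' rate and nominal gaze sampling rate. Defaults follow a 960 x 540 scene
#' camera sampled at 50 Hz, with the video and the gaze stream sharing the
#' 50 Hz clock.
#'
#' @param width_px,height_px Frame size in pixels.
#' @param fps Video frame rate (frames per second).
#' @param gaze_rate_hz Nominal gaze sampling rate (Hz).
#' @return A `frame_geometry` object (a named list).
#' @examples
#' frame_geometry()
#' frame_geometry(fps = 25)
#' @export
frame_geometry <- function(width_px = 960, height_px = 540,
                           fps = 50, gaze_rate_hz = 50) {
  if (width_px <= 0 || height_px <= 0) {
    abort("frame dimensions must be positive")
  }
  if (fps <= 0 || gaze_rate_hz <= 0) {
    abort("fps and gaze_rate_hz must be positive")
  }
  structure(
    list(width_px = width_px, height_px = height_px,
         fps = fps, gaze_rate_hz = gaze_rate_hz),
    class = "frame_geometry"
  )
}

#' @export
print.frame_geometry <- function(x, ...) {
  cat(sprintf("<frame_geometry> %d x %d px, %g fps, gaze %g Hz\n",
              x$width_px, x$height_px, x$fps, x$gaze_rate_hz))
  invisible(x)
}

#' Map timestamps onto video frames
#'
#' Frames are half-open intervals `[i/fps, (i+1)/fps)` so every timestamp
#' belongs to exactly one frame: `frame = floor(t_ms * fps / 1000)`.
#'
#' @param t_ms Timestamps in milliseconds (vectorised), all `>= 0`.
#' @param geometry A [frame_geometry()], or a single fps value.
#' @return Integer frame indices.
#' @examples
#' time_to_frame(c(0, 19.9, 20), frame_geometry())
#' @export
time_to_frame <- function(t_ms, geometry = frame_geometry()) {
  fps <- if (inherits(geometry, "frame_geometry")) geometry$fps else geometry
  if (any(is.na(t_ms)) || any(t_ms < 0)) {
    abort("t_ms must be non-negative and non-missing")
  }
  as.integer(floor(t_ms * fps / 1000))
}

#' Start time of a video frame
#'
#' Inverse anchor of [time_to_frame()]: the left edge of frame `i` is
#' `i * 1000 / fps` milliseconds.
#'
#' @param frame_index Integer frame indices (vectorised).
#' @param geometry A [frame_geometry()], or a single fps value.
#' @return Times in milliseconds.
#' @export
frame_to_time <- function(frame_index, geometry = frame_geometry()) {
  fps <- if (inherits(geometry, "frame_geometry")) geometry$fps else geometry
  frame_index * 1000 / fps
}

#' Scene segment (analysis window)
#'
#' The hazard scene is analysed inside one time window, treated half-open:
#' `[start_ms, end_ms)`. When no segment is given the pipeline derives one
#' from the span of the hazard tracks (see [detect_segment()]).
#'
#' @param start_ms,end_ms Window bounds in milliseconds, `start_ms < end_ms`.
#' @return A `scene_segment` object.
#' @export
scene_segment <- function(start_ms, end_ms) {
  if (!is.finite(start_ms) || !is.finite(end_ms) || start_ms >= end_ms) {
    abort("scene_segment requires start_ms < end_ms")
  }
  structure(list(start_ms = start_ms, end_ms = end_ms), class = "scene_segment")
}

#' @export
print.scene_segment <- function(x, ...) {
  cat(sprintf("<scene_segment> [%g, %g) ms\n", x$start_ms, x$end_ms))
  invisible(x)
}

#' Pixel-to-visual-angle conversion factor
#'
#' Degrees of visual angle per scene-camera pixel. Unless an explicit
#' `deg_per_px` is set in the config, the factor is the scene camera's
#' horizontal field of view divided by the frame width (small-angle
#' approximation, adequate for head-mounted scene cameras).
#'
#' @param config A [pipeline_config()].
#' @param geometry A [frame_geometry()].
#' @return Degrees per pixel (scalar).
#' @export
deg_per_px <- function(config = pipeline_config(), geometry = frame_geometry()) {
  config$deg_per_px %||% (config$horizontal_fov_deg / geometry$width_px)
}
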