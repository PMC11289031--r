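#' Bundle one recording session
#'
#' Collects the three time-aligned streams of one simulator drive — gaze,
#' per-frame detections, simulator log — plus subject metadata. All streams
#' share one clock: milliseconds from recording start.
#'
#' @param subject_id Subject identifier.
#' @param gaze Gaze tibble as returned by [read_gaze_csv()]
#'   (`t_ms, x_px, y_px, valid`).
#' @param detections Detection tibble as returned by [read_detections_csv()]
#'   (`frame, track_id, class, conf, x, y, w, h, source`).
#' @param simlog Simulator-log tibble as returned by [read_simlog_csv()]
#'   (`t_ms, speed_kmh, distance_m, brake_N, stop_sign`).
#' @param geometry A [frame_geometry()].
#' @param fitness Fitness-to-drive label (`"fit"`, `"conditionally_fit"`,
#'   `"unfit"`) or `NA`.
#' @param segment Optional [scene_segment()]; when `NULL` the analysis window
#'   is derived from the hazard tracks.
#' @param corrections Optional manual-correction tibble
#'   ([read_corrections_csv()]) applied to `detections` before track assembly.
#' @return A `hazard_session` object.
#' @export
hazard_session <- function(subject_id, gaze, detections, simlog,
                           geometry = frame_geometry(),
                           fitness = NA_character_,
                           segment = NULL,
                           corrections = NULL) {
  if (!is.na(fitness) && !fitness %in% fitness_levels()) {
    abort(sprintf("unknown fitness label '%s'", fitness))
  }
  if (!is.null(segment) && !inherits(segment, "scene_segment")) {
    abort("segment must be a scene_segment()")
  }
  structure(
    list(subject_id = as.character(subject_id),
         fitness = fitness,
         geometry = geometry,
         gaze = as_tibble(gaze),
         detections = as_tibble(detections),
         simlog = as_tibble(simlog),
         segment = segment,
         corrections = if (is.null(corrections)) NULL else as_tibble(corrections)),
    class = "hazard_session"
  )
}

#' @export
print.hazard_session <- function(x, ...) {
  cat(sprintf("<hazard_session> subject %s (%s)\n", x$subject_id,
              ifelse(is.na(x$fitness), "fitness unknown", x$fitness)))
  cat(sprintf("  gaze: %d samples | detections: %d | simlog: %d samples\n",
              nrow(x$gaze), nrow(x$detections), nrow(x$simlog)))
  if (!is.null(x$segment)) {
    cat(sprintf("  segment [%g, %g) ms\n", x$segment$start_ms, x$segment$end_ms))
  }
  if (!is.null(x$corrections)) {
    cat(sprintf("  %d manual corrections pending\n", nrow(x$corrections)))
  }
  invisible(x)
}
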