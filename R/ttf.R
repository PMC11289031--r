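frame_in_segment <- function(frame, segment, geometry) {
  ft <- frame_to_time(frame, geometry)
  ft >= segment$start_ms & ft < segment$end_ms
}

#' Hazard onset time (t1)
#'
#' t1 is the time at which the pedestrian first appears: the start time of
#' the earliest tracked person detection whose frame lies inside the
#' analysis window. When several tracks start on the same frame (the scene
#' has two children) t1 is that frame's time, not track-specific.
#'
#' @param tracks Track tibble ([build_tracks()], optionally interpolated).
#' @param segment A [scene_segment()].
#' @param geometry A [frame_geometry()].
#' @return Onset time in ms, or `NA` when no detection qualifies
#'   ("no hazard onset").
#' @export
hazard_onset <- function(tracks, segment, geometry = frame_geometry()) {
  if (is.null(tracks) || nrow(tracks) == 0) return(NA_real_)
  inside <- frame_in_segment(tracks$frame, segment, geometry)
  if (!any(inside)) return(NA_real_)
  frame_to_time(min(tracks$frame[inside]), geometry)
}

#' First gaze sample on the hazard (t2)
#'
#' t2 is the timestamp of the first valid gaze sample at or after t1, and
#' before the segment end, whose point falls inside any hazard-track box of
#' the frame the sample maps to (interpolated boxes count; the test is
#' closed-rectangle, see [point_in_box()]). Invalid samples cannot certify
#' a fixation and are skipped.
#'
#' @param gaze Gaze tibble.
#' @param tracks Track tibble (after interpolation).
#' @param t1_ms Hazard onset, ms.
#' @param segment A [scene_segment()].
#' @param geometry A [frame_geometry()].
#' @return Time in ms, or `NA` when the gaze never enters a hazard box
#'   before the segment end (a miss).
#' @export
first_gaze_on_target <- function(gaze, tracks, t1_ms, segment,
                                 geometry = frame_geometry()) {
  g <- dplyr::filter(as_tibble(gaze), .data$valid,
                     .data$t_ms >= t1_ms, .data$t_ms < segment$end_ms)
  if (nrow(g) == 0 || is.null(tracks) || nrow(tracks) == 0) return(NA_real_)
  g$frame <- time_to_frame(g$t_ms, geometry)
  hits <- dplyr::inner_join(g, as_tibble(tracks), by = "frame",
                            relationship = "many-to-many") |>
    dplyr::filter(.data$x_px >= .data$x, .data$x_px <= .data$x + .data$w,
                  .data$y_px >= .data$y, .data$y_px <= .data$y + .data$h)
  if (nrow(hits) == 0) return(NA_real_)
  min(hits$t_ms)
}

ttf_flags_from <- function(t1_ms, t2_ms, ttf_min_saccade_ms) {
  if (is.na(t1_ms)) return("no_onset")
  if (is.na(t2_ms)) return("miss")
  ttf <- t2_ms - t1_ms
  if (ttf == 0) "anticipatory"
  else if (ttf < ttf_min_saccade_ms) "sub_saccade"
  else character()
}

new_ttf_result <- function(t1_ms, t2_ms, flags) {
  structure(
    list(t1_ms = t1_ms, t2_ms = t2_ms,
         ttf_ms = if (is.na(t1_ms) || is.na(t2_ms)) NA_real_ else t2_ms - t1_ms,
         flags = flags),
    class = "ttf_result"
  )
}

#' Time to fixate
#'
#' Runs the gaze-event chain on one session: manual corrections, track
#' assembly, gap interpolation, hazard onset t1, first gaze-on-target t2,
#' then `TTF = t2 - t1`. Event flags: `anticipatory` when the gaze is
#' already on the hazard at onset (TTF = 0), `sub_saccade` when
#' 0 < TTF < `ttf_min_saccade_ms` (kept, not removed — flagged as faster
#' than a saccade), `miss` when the gaze never reaches the hazard inside the
#' segment, `no_onset` when no qualifying detection exists. The three event
#' flags are mutually exclusive by construction.
#'
#' @param session A [hazard_session()].
#' @param config A [pipeline_config()].
#' @return A `ttf_result`: list with `t1_ms`, `t2_ms`, `ttf_ms`, `flags`.
#'   Use [tidy()] for a one-row tibble.
#' @examples
#' s <- generate_session(session_spec(seed = 1))
#' compute_ttf(s$session)
#' @export
compute_ttf <- function(session, config = pipeline_config()) {
  compute_ttf_resolved(session, resolve_tracks(session, config), config)
}

compute_ttf_resolved <- function(session, rt, config) {
  if (is.null(rt$segment)) {
    return(new_ttf_result(NA_real_, NA_real_, "no_onset"))
  }
  t1 <- hazard_onset(rt$tracks, rt$segment, session$geometry)
  if (is.na(t1)) return(new_ttf_result(NA_real_, NA_real_, "no_onset"))
  t2 <- first_gaze_on_target(session$gaze, rt$tracks, t1, rt$segment,
                             session$geometry)
  new_ttf_result(t1, t2, ttf_flags_from(t1, t2, config$ttf_min_saccade_ms))
}

#' @export
print.ttf_result <- function(x, ...) {
  cat("<ttf_result>\n")
  cat(sprintf("  t1 = %s ms, t2 = %s ms, TTF = %s ms\n",
              format(x$t1_ms), format(x$t2_ms), format(x$ttf_ms)))
  cat(sprintf("  flags: %s\n",
              if (length(x$flags)) paste(x$flags, collapse = ", ") else "none"))
  invisible(x)
}

#' @export
tidy.ttf_result <- function(x, ...) {
  tibble(t1_ms = x$t1_ms, t2_ms = x$t2_ms, ttf_ms = x$ttf_ms,
         flags = paste(x$flags, collapse = ";"))
}
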