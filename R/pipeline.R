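# corrected, filtered, interpolated tracks plus the analysis window
resolve_tracks <- function(session, config) {
  det <- apply_corrections(session$detections, session$corrections)
  tracks <- build_tracks(det, config) |>
    interpolate_boxes(config$max_box_gap_frames)
  segment <- session$segment %||% detect_segment(tracks, session$geometry)
  list(tracks = tracks, segment = segment)
}

onset_box <- function(tracks, t1_ms, geometry) {
  f1 <- time_to_frame(t1_ms, geometry)
  cand <- tracks[tracks$frame == f1, ]
  if (nrow(cand) == 0) return(NULL)
  cand[which.max(cand$conf), ]
}

#' Extract the full feature record for one session
#'
#' Orchestrates the per-session chain: manual corrections, track assembly
#' and interpolation, hazard onset t1, first gaze-on-target t2, TTF with
#' event flags, initial gaze distance, speed and time-to-collision at onset,
#' per-trigger brake response times averaged into one PRT, and session
#' quality control. Quality-control failures never raise; they are returned
#' as flags so cohort-level screening can account for every subject.
#'
#' @param session A [hazard_session()]; gaze and simulator streams must be
#'   non-empty.
#' @param config A [pipeline_config()].
#' @return One-row feature tibble: `subject_id, fitness, ttf_ms, speed_kmh,
#'   igd_deg, ttc_s, prt_ms, flags` (`flags` semicolon-separated; empty
#'   string when clean).
#' @examples
#' s <- generate_session(session_spec(seed = 1))
#' run_pipeline(s$session)
#' @export
run_pipeline <- function(session, config = pipeline_config()) {
  if (is.null(session$gaze) || nrow(session$gaze) == 0) {
    abort("session has no gaze stream")
  }
  if (is.null(session$simlog) || nrow(session$simlog) == 0) {
    abort("session has no simulator log")
  }
  if (is.null(session$detections)) {
    abort("session has no detection table")
  }

  rt <- resolve_tracks(session, config)
  ttf <- compute_ttf_resolved(session, rt, config)
  qc <- qc_session(session, config, ttf = ttf, resolved = rt)
  flags <- ttf$flags
  qc_fail <- qc$check[!qc$pass & qc$check %in%
                        c("frozen_gaze", "missing_gaze", "recording_pause")]
  flags <- c(flags, qc_fail)

  speed <- igd <- ttc <- NA_real_
  if (!is.na(ttf$t1_ms)) {
    speed <- speed_at_onset(session$simlog, ttf$t1_ms)
    if (is.na(speed)) flags <- c(flags, "speed_unavailable")
    sim <- nearest_sim_sample(session$simlog, ttf$t1_ms)
    if (!is.null(sim)) {
      ttc <- time_to_collision(sim$distance_m, sim$speed_kmh)
      if (is.na(ttc)) flags <- c(flags, "ttc_undefined")
    }
    g1 <- nearest_valid_gaze(session$gaze, ttf$t1_ms, config$igd_window_ms)
    box <- onset_box(rt$tracks, ttf$t1_ms, session$geometry)
    if (is.null(g1) || is.null(box)) {
      flags <- c(flags, "igd_unavailable")
    } else {
      igd <- initial_gaze_distance(g1$x_px, g1$y_px, box,
                                   deg_per_px(config, session$geometry))
    }
  }

  prts <- brake_response_times(session$simlog, config)
  prt <- average_prt(prts$prt_ms, config)
  if (is.na(prt)) flags <- c(flags, "prt_missing")

  tibble(
    subject_id = session$subject_id,
    fitness = session$fitness,
    ttf_ms = ttf$ttf_ms,
    speed_kmh = speed,
    igd_deg = igd,
    ttc_s = ttc,
    prt_ms = prt,
    flags = paste(unique(flags), collapse = ";")
  )
}

#' Batch feature extraction
#'
#' @param sessions A list of [hazard_session()] objects.
#' @param config A [pipeline_config()].
#' @return Feature tibble, one row per session.
#' @export
extract_features <- function(sessions, config = pipeline_config()) {
  dplyr::bind_rows(purrr::map(sessions, run_pipeline, config = config))
}
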