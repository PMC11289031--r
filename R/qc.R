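#' Session-level quality control
#'
#' Reproduces the exclusion taxonomy applied to real hazard segments:
#' * `frozen_gaze` — valid gaze coordinates have zero variance across the
#'   segment (the tracker stopped updating);
#' * `missing_gaze` — the invalid-sample fraction inside the segment exceeds
#'   `qc_missing_max`;
#' * `recording_pause` — some inter-sample gap exceeds
#'   `qc_pause_gap_factor` nominal gaze periods;
#' * `anticipatory`, `no_onset`, `miss` — copied from the TTF event flags.
#'
#' Any failing check excludes the subject from TTF analysis; the measured
#' quantity behind each check is retained so the reason is auditable.
#'
#' @param session A [hazard_session()].
#' @param config A [pipeline_config()].
#' @param ttf Optional precomputed [compute_ttf()] result.
#' @param resolved Internal: precomputed tracks/segment.
#' @return A `qc_report`: tibble `subject_id, check, pass, value`.
#' @export
qc_session <- function(session, config = pipeline_config(),
                       ttf = NULL, resolved = NULL) {
  rt <- resolved %||% resolve_tracks(session, config)
  ttf <- ttf %||% compute_ttf_resolved(session, rt, config)
  gaze <- session$gaze
  seg <- rt$segment %||%
    scene_segment(min(gaze$t_ms), max(gaze$t_ms) + 1e-9)
  gs <- gaze[gaze$t_ms >= seg$start_ms & gaze$t_ms < seg$end_ms, ]
  if (nrow(gs) == 0) gs <- gaze

  gv <- gs[gs$valid, ]
  frozen_val <- if (nrow(gv) >= 2) max(var(gv$x_px), var(gv$y_px)) else 0
  frozen <- frozen_val == 0

  missing_frac <- mean(!gs$valid)

  period <- 1000 / session$geometry$gaze_rate_hz
  max_gap <- if (nrow(gs) >= 2) max(diff(gs$t_ms)) else 0
  pause <- max_gap > config$qc_pause_gap_factor * period

  checks <- tibble(
    check = c("frozen_gaze", "missing_gaze", "recording_pause",
              "anticipatory", "no_onset", "miss"),
    pass = c(!frozen,
             missing_frac <= config$qc_missing_max,
             !pause,
             !"anticipatory" %in% ttf$flags,
             !"no_onset" %in% ttf$flags,
             !"miss" %in% ttf$flags),
    value = c(frozen_val, missing_frac, max_gap,
              as.numeric("anticipatory" %in% ttf$flags),
              as.numeric("no_onset" %in% ttf$flags),
              as.numeric("miss" %in% ttf$flags))
  )
  out <- dplyr::mutate(checks, subject_id = session$subject_id,
                       .before = 1)
  class(out) <- c("qc_report", class(out))
  out
}

#' Did a session pass all quality-control checks?
#'
#' @param qc A `qc_report` from [qc_session()].
#' @return Logical scalar.
#' @export
qc_pass <- function(qc) all(qc$pass)
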