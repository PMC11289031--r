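#' Pipeline configuration
#'
#' All tunable thresholds of the extraction, screening and statistics layers
#' in one place. Defaults encode the published analysis constants: a brake
#' response requires at least 75 N of pedal force, a valid TTF is below
#' 500 ms, a physiologically plausible saccadic TTF is at least 120 ms
#' (ISO 15007 saccade duration), perception response times are valid within
#' 0.5--4 s, outliers lie more than three interquartile ranges above the
#' third quartile, Tukey intervals use confidence 0.95 and the general
#' linear model a rigor alpha of 0.001.
#'
#' @param person_class Detector class label treated as the hazard (pedestrian).
#' @param min_confidence Minimum detector confidence kept, in `[0, 1]`.
#' @param horizontal_fov_deg Scene-camera horizontal field of view, degrees;
#'   used to derive the pixel-to-angle factor when `deg_per_px` is `NULL`.
#' @param deg_per_px Optional explicit degrees-per-pixel override.
#' @param ttf_valid_max_ms TTFs at or above this are screened out (ms).
#' @param ttf_min_saccade_ms TTFs below this (but positive) are flagged as
#'   faster than a saccade; they are kept, not removed (ms).
#' @param prt_valid_range_ms Length-2 range of valid per-repetition PRTs (ms).
#' @param brake_threshold_N Brake force defining a response (newtons).
#' @param iqr_multiplier One-sided outlier rule: flag values above
#'   `Q3 + iqr_multiplier * IQR`.
#' @param tukey_conf Confidence level for Tukey HSD intervals.
#' @param glm_alpha Significance level for the general linear model terms.
#' @param max_box_gap_frames Longest detection gap (frames) bridged by linear
#'   box interpolation inside a track.
#' @param iou_link_threshold Minimum intersection-over-union linking
#'   detections in consecutive frames when no track ids are supplied.
#' @param qc_missing_max Maximum tolerated fraction of invalid gaze samples.
#' @param qc_pause_gap_factor A recording pause is an inter-sample gap longer
#'   than this multiple of the nominal gaze period.
#' @param igd_window_ms Half-width of the window around hazard onset within
#'   which the nearest valid gaze sample anchors the initial gaze distance.
#' @param quantile_type Quantile algorithm for the IQR rule (see
#'   [stats::quantile()]); 7 is linear interpolation between order statistics.
#' @return A `pipeline_config` object (a named list).
#' @examples
#' cfg <- pipeline_config(min_confidence = 0.5)
#' cfg$brake_threshold_N
#' @export
pipeline_config <- function(person_class = "person",
                            min_confidence = 0.25,
                            horizontal_fov_deg = 82,
                            deg_per_px = NULL,
                            ttf_valid_max_ms = 500,
                            ttf_min_saccade_ms = 120,
                            prt_valid_range_ms = c(500, 4000),
                            brake_threshold_N = 75,
                            iqr_multiplier = 3,
                            tukey_conf = 0.95,
                            glm_alpha = 0.001,
                            max_box_gap_frames = 5,
                            iou_link_threshold = 0.3,
                            qc_missing_max = 0.5,
                            qc_pause_gap_factor = 3,
                            igd_window_ms = 100,
                            quantile_type = 7) {
  stopifnot(
    min_confidence >= 0, min_confidence <= 1,
    horizontal_fov_deg > 0,
    is.null(deg_per_px) || deg_per_px > 0,
    ttf_valid_max_ms > 0, ttf_min_saccade_ms > 0,
    length(prt_valid_range_ms) == 2,
    prt_valid_range_ms[1] > 0,
    prt_valid_range_ms[1] < prt_valid_range_ms[2],
    brake_threshold_N > 0, iqr_multiplier > 0,
    tukey_conf > 0, tukey_conf < 1,
    glm_alpha > 0, glm_alpha < 1,
    max_box_gap_frames >= 0,
    iou_link_threshold > 0, iou_link_threshold <= 1,
    qc_missing_max > 0, qc_missing_max <= 1,
    qc_pause_gap_factor > 0,
    igd_window_ms > 0
  )
  structure(
    list(person_class = person_class,
         min_confidence = min_confidence,
         horizontal_fov_deg = horizontal_fov_deg,
         deg_per_px = deg_per_px,
         ttf_valid_max_ms = ttf_valid_max_ms,
         ttf_min_saccade_ms = ttf_min_saccade_ms,
         prt_valid_range_ms = prt_valid_range_ms,
         brake_threshold_N = brake_threshold_N,
         iqr_multiplier = iqr_multiplier,
         tukey_conf = tukey_conf,
         glm_alpha = glm_alpha,
         max_box_gap_frames = max_box_gap_frames,
         iou_link_threshold = iou_link_threshold,
         qc_missing_max = qc_missing_max,
         qc_pause_gap_factor = qc_pause_gap_factor,
         igd_window_ms = igd_window_ms,
         quantile_type = quantile_type),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}

fitness_levels <- function() c("fit", "conditionally_fit", "unfit")
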