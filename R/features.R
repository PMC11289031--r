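#' Initial gaze distance
#'
#' Euclidean distance, at hazard onset, from the gaze point to the centre of
#' the hazard's bounding rectangle. The pixel distance is rounded to the
#' nearest integer before conversion to visual degrees.
#'
#' @param gaze_x_px,gaze_y_px Gaze point at (or nearest to) onset, pixels.
#' @param box The hazard box at onset (`x, y, w, h`).
#' @param deg_per_px Degrees of visual angle per pixel ([deg_per_px()]).
#' @return IGD in degrees, `NA` for a missing gaze point.
#' @examples
#' initial_gaze_distance(0, 0, list(x = 280, y = 380, w = 40, h = 40), 0.05)
#' @export
initial_gaze_distance <- function(gaze_x_px, gaze_y_px, box, deg_per_px) {
  if (is.na(gaze_x_px) || is.na(gaze_y_px)) return(NA_real_)
  cx <- box$x + box$w / 2
  cy <- box$y + box$h / 2
  d_px <- round(sqrt((gaze_x_px - cx)^2 + (gaze_y_px - cy)^2))
  d_px * deg_per_px
}

# nearest valid gaze sample to t_ms within +/- window_ms (ties -> earlier)
nearest_valid_gaze <- function(gaze, t_ms, window_ms = 100) {
  g <- gaze[gaze$valid & abs(gaze$t_ms - t_ms) <= window_ms, ]
  if (nrow(g) == 0) return(NULL)
  g[which.min(abs(g$t_ms - t_ms)), ]
}

#' Time to collision
#'
#' Ratio of the ego-vehicle-to-pedestrian distance to the ego speed at the
#' same instant.
#'
#' @param distance_m Distance in meters (vectorised).
#' @param speed_kmh Speed in km/h.
#' @return TTC in seconds; `NA` where speed is not positive (undefined).
#' @examples
#' time_to_collision(10, 36) # 1 s
#' @export
time_to_collision <- function(distance_m, speed_kmh) {
  ifelse(is.na(speed_kmh) | speed_kmh <= 0, NA_real_,
         distance_m / (speed_kmh / 3.6))
}

# simulator sample nearest in time to t_ms (ties -> earlier); NULL outside span
nearest_sim_sample <- function(simlog, t_ms) {
  if (is.na(t_ms) || nrow(simlog) == 0 ||
      t_ms < min(simlog$t_ms) || t_ms > max(simlog$t_ms)) {
    return(NULL)
  }
  simlog[which.min(abs(simlog$t_ms - t_ms)), ]
}

#' Ego speed at hazard onset
#'
#' Speed of the simulator-log sample nearest in time to t1; simulator logs
#' are dense relative to speed dynamics, so no interpolation is used. Ties
#' resolve to the earlier sample.
#'
#' @param simlog Simulator-log tibble.
#' @param t1_ms Hazard onset, ms; must lie within the log span.
#' @return Speed in km/h, `NA` when t1 is outside the log span.
#' @export
speed_at_onset <- function(simlog, t1_ms) {
  s <- nearest_sim_sample(as_tibble(simlog), t1_ms)
  if (is.null(s)) NA_real_ else s$speed_kmh
}

#' Perception response time for one stop-sign trigger
#'
#' Time from the trigger to the first log sample strictly after it whose
#' brake force reaches `brake_threshold_N` (at least 75 N by default). The
#' search ends at `search_end_ms` — normally the next trigger — so one
#' braking event cannot satisfy two stop signs. A brake already above
#' threshold at the trigger instant is not a response.
#'
#' @param simlog Simulator-log tibble.
#' @param trigger_t_ms Trigger (stop-sign onset) time, ms.
#' @param config A [pipeline_config()].
#' @param search_end_ms End of the search window (exclusive); default `Inf`
#'   (log end).
#' @return PRT in ms, or `NA` when no sample qualifies (a miss).
#' @export
perception_response_time <- function(simlog, trigger_t_ms,
                                     config = pipeline_config(),
                                     search_end_ms = Inf) {
  sl <- as_tibble(simlog)
  hit <- sl$t_ms > trigger_t_ms & sl$t_ms < search_end_ms &
    sl$brake_N >= config$brake_threshold_N
  if (!any(hit)) return(NA_real_)
  sl$t_ms[which(hit)[1]] - trigger_t_ms
}

#' Per-trigger brake response times for a whole session
#'
#' Finds stop-sign triggers (rising edges of the `stop_sign` channel, or an
#' explicit list) and computes one [perception_response_time()] per trigger,
#' each searched up to the next trigger.
#'
#' @param simlog Simulator-log tibble.
#' @param config A [pipeline_config()].
#' @param triggers Optional trigger times (ms); default: rising edges of
#'   `stop_sign`.
#' @return Tibble `trigger_ms, prt_ms` (one row per trigger; `prt_ms` `NA`
#'   for misses).
#' @export
brake_response_times <- function(simlog, config = pipeline_config(),
                                 triggers = NULL) {
  sl <- as_tibble(simlog)
  if (is.null(triggers)) {
    edge <- sl$stop_sign & !dplyr::lag(sl$stop_sign, default = FALSE)
    triggers <- sl$t_ms[edge]
  }
  if (length(triggers) == 0) {
    return(tibble(trigger_ms = double(), prt_ms = double()))
  }
  triggers <- sort(triggers)
  ends <- c(triggers[-1], Inf)
  tibble(
    trigger_ms = triggers,
    prt_ms = purrr::map2_dbl(triggers, ends, function(tr, en) {
      perception_response_time(sl, tr, config, en)
    })
  )
}

#' Average the valid PRT repetitions
#'
#' Per-repetition PRTs outside the validity window (0.5--4 s by default;
#' shorter responses are anticipations, longer ones misses) are discarded;
#' the arithmetic mean of the survivors is returned. With one or two
#' repetitions missing the remaining ones still yield a value; with none,
#' the subject has no PRT.
#'
#' @param prts Numeric vector of candidate PRTs in ms (may contain `NA`).
#' @param config A [pipeline_config()].
#' @return Mean PRT in ms, or `NA` when no repetition survives.
#' @examples
#' average_prt(c(400, 1000))        # 1000: 400 ms is below the 0.5 s floor
#' average_prt(c(1000, 1200, 1400)) # 1200
#' @export
average_prt <- function(prts, config = pipeline_config()) {
  ok <- !is.na(prts) &
    prts >= config$prt_valid_range_ms[1] &
    prts <= config$prt_valid_range_ms[2]
  if (!any(ok)) return(NA_real_)
  mean(prts[ok])
}

#' Type-B timing uncertainty
#'
#' Standard measurement uncertainty of an event timestamp quantised at
#' resolution `r`, under a uniform error distribution over the resolution
#' interval: `u = r / (2 * sqrt(3))`. At the 50 Hz video resolution
#' (r = 20 ms) this is 5.77 ms.
#'
#' @param resolution_ms Timing resolution r in ms (default one 50 Hz frame).
#' @return Standard uncertainty in ms.
#' @examples
#' type_b_uncertainty(20)
#' @export
type_b_uncertainty <- function(resolution_ms = 20) {
  if (any(is.na(resolution_ms)) || any(resolution_ms < 0)) {
    abort("resolution_ms must be non-negative")
  }
  resolution_ms / (2 * sqrt(3))
}
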