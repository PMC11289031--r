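# Compact constructors for hand-built fixtures.

make_gaze <- function(t_ms, x_px, y_px, valid = TRUE) {
  tibble::tibble(t_ms = t_ms, x_px = x_px, y_px = y_px,
                 valid = rep_len(valid, length(t_ms)))
}

make_det <- function(frame, x, y, w = 40, h = 80, track_id = 1L,
                     class = "person", conf = 0.9, source = "detector") {
  tibble::tibble(frame = as.integer(frame), track_id = as.integer(track_id),
                 class = class, conf = conf,
                 x = x, y = y, w = w, h = h, source = source)
}

make_simlog <- function(t_ms, speed_kmh = 20, distance_m = 50,
                        brake_N = 0, stop_sign = FALSE) {
  tibble::tibble(t_ms = t_ms,
                 speed_kmh = rep_len(speed_kmh, length(t_ms)),
                 distance_m = rep_len(distance_m, length(t_ms)),
                 brake_N = rep_len(brake_N, length(t_ms)),
                 stop_sign = rep_len(stop_sign, length(t_ms)))
}

make_session <- function(gaze, detections,
                         simlog = make_simlog(seq(0, 5990, by = 10)),
                         segment = NULL, fitness = "fit", ...) {
  hazard_session("T01", gaze, detections, simlog,
                 segment = segment, fitness = fitness, ...)
}

flat_gaze <- function(n = 200, x = 100, y = 100) {
  make_gaze(seq(0, by = 20, length.out = n), x, y)
}
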