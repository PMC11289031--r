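read_dialect <- function(path, col_types, expected) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, col_types = col_types,
                        na = c("", "NA"), progress = FALSE)
  if (!identical(names(df), expected)) {
    abort(sprintf("unexpected header in %s: expected '%s', found '%s'",
                  path, paste(expected, collapse = ","),
                  paste(names(df), collapse = ",")))
  }
  df
}

#' Read a gaze CSV
#'
#' Dialect: header `t_ms,x_px,y_px,valid` with `valid` in `{0, 1}`,
#' timestamps in milliseconds, coordinates in scene-camera pixels.
#' Invalid samples (tracking loss) are retained and flagged rather than
#' dropped, so quality control can measure the missing-data fraction.
#'
#' @param path CSV file path.
#' @return Tibble `t_ms, x_px, y_px, valid` sorted by strictly increasing
#'   `t_ms`; `valid` is logical.
#' @export
read_gaze_csv <- function(path) {
  df <- read_dialect(path, "dddi", c("t_ms", "x_px", "y_px", "valid"))
  if (any(is.na(df$t_ms)) || any(is.na(df$valid))) {
    abort(sprintf("non-numeric t_ms/valid in %s", path))
  }
  if (!all(df$valid %in% c(0L, 1L))) abort("valid must be 0 or 1")
  df <- dplyr::arrange(df, .data$t_ms)
  dup <- duplicated(df$t_ms)
  if (any(dup)) {
    abort(sprintf("duplicate timestamp %g ms (row %d) in %s",
                  df$t_ms[which(dup)[1]], which(dup)[1], path))
  }
  bad <- df$valid == 1L & (is.na(df$x_px) | is.na(df$y_px))
  if (any(bad)) {
    abort(sprintf("non-numeric coordinate on valid row %d in %s",
                  which(bad)[1], path))
  }
  dplyr::mutate(df, valid = .data$valid == 1L)
}

#' @rdname read_gaze_csv
#' @param gaze Gaze tibble to write.
#' @export
write_gaze_csv <- function(gaze, path) {
  out <- dplyr::mutate(as_tibble(gaze)[c("t_ms", "x_px", "y_px", "valid")],
                       valid = as.integer(.data$valid))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a detections CSV (MOT-like dialect)
#'
#' Dialect: header `frame,track_id,class,conf,x,y,w,h`; `x,y` is the box
#' top-left corner in pixels, origin top-left of the frame. `track_id` may be
#' empty when the detector does not track (tracks are then assembled by
#' [build_tracks()]). Boxes need not lie fully inside the frame; pass a
#' [frame_geometry()] as `clip_to` to clip them, which records a `clipped`
#' flag column. This dialect is also the contract an external detector
#' adapter must emit.
#'
#' @param path CSV file path.
#' @param clip_to Optional [frame_geometry()]; clip boxes to the frame.
#' @return Tibble `frame, track_id, class, conf, x, y, w, h, source`
#'   (plus `clipped` when clipping), `source = "detector"`.
#' @export
read_detections_csv <- function(path, clip_to = NULL) {
  df <- read_dialect(path, "iicddddd",
                     c("frame", "track_id", "class", "conf", "x", "y", "w", "h"))
  if (any(is.na(df$frame)) || any(df$frame < 0)) {
    abort(sprintf("bad frame index in %s", path))
  }
  if (any(is.na(df$conf)) || any(df$conf < 0 | df$conf > 1)) {
    abort(sprintf("confidence outside [0, 1] in %s", path))
  }
  bad <- is.na(df$w) | is.na(df$h) | df$w <= 0 | df$h <= 0
  if (any(bad)) {
    abort(sprintf("non-positive box width/height (row %d) in %s",
                  which(bad)[1], path))
  }
  df$source <- "detector"
  if (!is.null(clip_to)) {
    x2 <- pmin(df$x + df$w, clip_to$width_px)
    y2 <- pmin(df$y + df$h, clip_to$height_px)
    x1 <- pmax(df$x, 0)
    y1 <- pmax(df$y, 0)
    df$clipped <- x1 != df$x | y1 != df$y | x2 != df$x + df$w | y2 != df$y + df$h
    df$x <- x1; df$y <- y1; df$w <- x2 - x1; df$h <- y2 - y1
  }
  as_tibble(df)
}

#' @rdname read_detections_csv
#' @param detections Detection tibble to write.
#' @export
write_detections_csv <- function(detections, path) {
  cols <- c("frame", "track_id", "class", "conf", "x", "y", "w", "h")
  readr::write_csv(as_tibble(detections)[cols], path, na = "")
  invisible(path)
}

#' Read a manual-corrections CSV
#'
#' Same dialect as [read_detections_csv()] plus a trailing `action` column in
#' `{replace, add, delete}`. Corrections are replayed in file order by
#' [apply_corrections()].
#'
#' @param path CSV file path.
#' @return Tibble `frame, track_id, class, conf, x, y, w, h, action`.
#' @export
read_corrections_csv <- function(path) {
  df <- read_dialect(path, "iicdddddc",
                     c("frame", "track_id", "class", "conf",
                       "x", "y", "w", "h", "action"))
  if (!all(df$action %in% c("replace", "add", "delete"))) {
    abort(sprintf("unknown correction action in %s", path))
  }
  as_tibble(df)
}

#' Read a simulator-log CSV
#'
#' Dialect: header `t_ms,speed_kmh,distance_m,brake_N,stop_sign`;
#' `distance_m` is the ego-vehicle-to-pedestrian distance recorded by the
#' simulator, `stop_sign` in `{0, 1}` marks the stop-sign stimulus being on
#' screen.
#'
#' @param path CSV file path.
#' @return Tibble with strictly increasing `t_ms`; `stop_sign` is logical.
#' @export
read_simlog_csv <- function(path) {
  df <- read_dialect(path, "ddddi",
                     c("t_ms", "speed_kmh", "distance_m", "brake_N", "stop_sign"))
  if (any(diff(df$t_ms) <= 0)) {
    abort(sprintf("t_ms not strictly increasing in %s", path))
  }
  if (any(df$speed_kmh < 0, na.rm = TRUE) || any(df$brake_N < 0, na.rm = TRUE) ||
      any(df$distance_m < 0, na.rm = TRUE)) {
    abort(sprintf("negative speed/brake/distance in %s", path))
  }
  dplyr::mutate(df, stop_sign = .data$stop_sign == 1L)
}

#' @rdname read_simlog_csv
#' @param simlog Simulator-log tibble to write.
#' @export
write_simlog_csv <- function(simlog, path) {
  out <- dplyr::mutate(
    as_tibble(simlog)[c("t_ms", "speed_kmh", "distance_m", "brake_N", "stop_sign")],
    stop_sign = as.integer(.data$stop_sign))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read / write a per-subject features CSV
#'
#' Dialect: header `subject_id,fitness,ttf_ms,speed_kmh,igd_deg,ttc_s,prt_ms,flags`,
#' one row per subject; `flags` is a semicolon-separated token list (empty
#' string when clean); absent measurements are empty fields.
#'
#' @param path CSV file path.
#' @return Tibble of feature records.
#' @export
read_features_csv <- function(path) {
  df <- read_dialect(path, "ccdddddc",
                     c("subject_id", "fitness", "ttf_ms", "speed_kmh",
                       "igd_deg", "ttc_s", "prt_ms", "flags"))
  bad <- !is.na(df$fitness) & !df$fitness %in% fitness_levels()
  if (any(bad)) {
    abort(sprintf("unknown fitness label '%s' (row %d) in %s",
                  df$fitness[which(bad)[1]], which(bad)[1], path))
  }
  dplyr::mutate(df, flags = dplyr::coalesce(.data$flags, ""))
}

#' @rdname read_features_csv
#' @param records Feature tibble to write (one row per subject).
#' @export
write_features_csv <- function(records, path) {
  cols <- c("subject_id", "fitness", "ttf_ms", "speed_kmh",
            "igd_deg", "ttc_s", "prt_ms", "flags")
  out <- as_tibble(records)[cols]
  bad <- !is.na(out$fitness) & !out$fitness %in% fitness_levels()
  if (any(bad)) {
    abort(sprintf("unknown fitness label '%s'", out$fitness[which(bad)[1]]))
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}
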