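#' Intersection-over-union of two boxes
#'
#' @param a,b Boxes: named lists / one-row data frames with `x, y, w, h`
#'   (top-left corner plus size, pixels).
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  ix <- max(0, min(a$x + a$w, b$x + b$w) - max(a$x, b$x))
  iy <- max(0, min(a$y + a$h, b$y + b$h) - max(a$y, b$y))
  inter <- ix * iy
  union <- a$w * a$h + b$w * b$h - inter
  if (union <= 0) 0 else inter / union
}

#' Closed-rectangle gaze hit test
#'
#' A gaze point on the box edge counts as inside: the conservative reading
#' of "gaze falls within the detection frame".
#'
#' @param x_px,y_px Gaze point, pixels (vectorised).
#' @param box A box (`x, y, w, h`).
#' @return Logical.
#' @export
point_in_box <- function(x_px, y_px, box) {
  !is.na(x_px) & !is.na(y_px) &
    x_px >= box$x & x_px <= box$x + box$w &
    y_px >= box$y & y_px <= box$y + box$h
}

#' Assemble hazard tracks from detections
#'
#' Keeps detections of the configured person class at or above the
#' confidence floor, then groups them into tracks. When the input provides
#' track ids they are trusted (duplicate detections of one track in one
#' frame are resolved by keeping the highest confidence). Otherwise tracks
#' are built by greedy nearest-box linking: a detection joins the track
#' whose box in the immediately preceding frame overlaps it with the
#' highest IoU at or above `iou_link_threshold`; unmatched detections open
#' new tracks.
#'
#' @param detections Detection tibble (after any corrections).
#' @param config A [pipeline_config()].
#' @return Detection tibble with a complete `track_id` column; zero rows if
#'   nothing survives the filter.
#' @export
build_tracks <- function(detections, config = pipeline_config()) {
  det <- dplyr::filter(as_tibble(detections),
                       .data$class == config$person_class,
                       .data$conf >= config$min_confidence)
  if (nrow(det) == 0) return(det)
  if (!anyNA(det$track_id)) {
    det <- det |>
      dplyr::group_by(.data$track_id, .data$frame) |>
      dplyr::slice_max(.data$conf, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$track_id, .data$frame)
    return(det)
  }
  det <- dplyr::arrange(det, .data$frame)
  det$track_id <- NA_integer_
  next_id <- 1L
  # active tracks: id, frame and box of their latest detection
  active <- tibble(track_id = integer(), frame = integer(),
                   x = double(), y = double(), w = double(), h = double())
  for (f in unique(det$frame)) {
    idx <- which(det$frame == f)
    cand <- active[active$frame == f - 1L, ]
    free_det <- idx
    while (nrow(cand) > 0 && length(free_det) > 0) {
      iou <- outer(seq_len(nrow(cand)), seq_along(free_det),
                   Vectorize(function(i, j) box_iou(cand[i, ], det[free_det[j], ])))
      best <- which(iou == max(iou), arr.ind = TRUE)[1, ]
      if (iou[best[1], best[2]] < config$iou_link_threshold) break
      det$track_id[free_det[best[2]]] <- cand$track_id[best[1]]
      cand <- cand[-best[1], ]
      free_det <- free_det[-best[2]]
    }
    for (j in free_det) {
      det$track_id[j] <- next_id
      next_id <- next_id + 1L
    }
    upd <- det[idx, c("track_id", "frame", "x", "y", "w", "h")]
    active <- dplyr::bind_rows(active[!active$track_id %in% upd$track_id, ], upd)
  }
  dplyr::arrange(det, .data$track_id, .data$frame)
}

#' Bridge short detection gaps by linear box interpolation
#'
#' Detectors intermittently miss the pedestrian for a frame or two. Within
#' each track, gaps of at most `max_gap_frames` missing frames are filled by
#' per-coordinate linear interpolation of `(x, y, w, h)` between the
#' flanking detections; longer gaps are left open. Inserted rows carry
#' `source = "interpolated"` and the smaller flanking confidence.
#'
#' @param tracks Track tibble from [build_tracks()].
#' @param max_gap_frames Longest gap bridged.
#' @return Track tibble with interpolated rows inserted, frame-ordered.
#' @export
interpolate_boxes <- function(tracks, max_gap_frames = 5) {
  tr <- as_tibble(tracks)
  if (nrow(tr) == 0) return(tr)
  fill_one <- function(g) {
    g <- dplyr::arrange(g, .data$frame)
    gaps <- which(diff(g$frame) > 1 & diff(g$frame) <= max_gap_frames + 1)
    if (length(gaps) == 0) return(g)
    new_rows <- purrr::map(gaps, function(i) {
      f0 <- g$frame[i]; f1 <- g$frame[i + 1]
      fr <- seq(f0 + 1L, f1 - 1L)
      a <- (fr - f0) / (f1 - f0)
      tibble(frame = fr,
             track_id = g$track_id[i],
             class = g$class[i],
             conf = min(g$conf[i], g$conf[i + 1]),
             x = g$x[i] + a * (g$x[i + 1] - g$x[i]),
             y = g$y[i] + a * (g$y[i + 1] - g$y[i]),
             w = g$w[i] + a * (g$w[i + 1] - g$w[i]),
             h = g$h[i] + a * (g$h[i + 1] - g$h[i]),
             source = "interpolated")
    })
    dplyr::arrange(dplyr::bind_rows(g, new_rows), .data$frame)
  }
  tr |>
    dplyr::group_split(.data$track_id) |>
    purrr::map(fill_one) |>
    dplyr::bind_rows()
}

#' Derive the analysis window from the hazard tracks
#'
#' When no explicit [scene_segment()] is configured, the window spans the
#' hazard tracks: from the first tracked frame to one frame period past the
#' last.
#'
#' @param tracks Track tibble.
#' @param geometry A [frame_geometry()].
#' @return A [scene_segment()], or `NULL` when there are no tracks.
#' @export
detect_segment <- function(tracks, geometry = frame_geometry()) {
  if (is.null(tracks) || nrow(tracks) == 0) return(NULL)
  scene_segment(frame_to_time(min(tracks$frame), geometry),
                frame_to_time(max(tracks$frame) + 1L, geometry))
}
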