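na_eq <- function(a, b) {
  (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
}

#' Apply manual corrections to a detection table
#'
#' Roughly a third of real hazard segments need manual fixes to the detector
#' output (missed pedestrians, spurious boxes). Corrections are replayed in
#' file order: `replace` swaps the detection at `(frame, track_id)` for the
#' corrected box, `add` inserts a new detection, `delete` removes one
#' (deleting a detection that does not exist raises a warning, not an
#' error). Boxes written by a correction carry `source = "correction"`.
#'
#' @param detections Detection tibble ([read_detections_csv()]).
#' @param corrections Corrections tibble ([read_corrections_csv()]); `NULL`
#'   or zero rows leaves the input unchanged.
#' @return Corrected detection tibble ordered by frame then track id.
#' @export
apply_corrections <- function(detections, corrections) {
  det <- as_tibble(detections)
  if (is.null(corrections) || nrow(corrections) == 0) return(det)
  for (i in seq_len(nrow(corrections))) {
    cr <- corrections[i, ]
    hit <- na_eq(det$frame, cr$frame) & na_eq(det$track_id, cr$track_id)
    if (cr$action == "delete") {
      if (!any(hit)) {
        warn(sprintf("delete: no detection at frame %d track %s",
                     cr$frame, format(cr$track_id)))
      }
      det <- det[!hit, ]
    } else {
      row <- tibble(frame = cr$frame, track_id = cr$track_id,
                    class = cr$class, conf = cr$conf,
                    x = cr$x, y = cr$y, w = cr$w, h = cr$h,
                    source = "correction")
      if (cr$action == "replace") det <- det[!hit, ]
      det <- dplyr::bind_rows(det, row)
    }
  }
  dplyr::arrange(det, .data$frame, .data$track_id)
}
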