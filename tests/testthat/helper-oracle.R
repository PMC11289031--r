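# Brute-force reference for the TTF event chain. Deliberately written as
# plain loops over every (gaze sample x box) pair, with its own gap filling
# and its own closed-rectangle arithmetic, so it shares no code path with
# compute_ttf().
oracle_ttf <- function(session, config = pipeline_config()) {
  geom <- session$geometry
  det <- as.data.frame(session$detections)
  det <- det[det$class == config$person_class &
               det$conf >= config$min_confidence, , drop = FALSE]

  filled <- det
  if (nrow(det) > 0) {
    for (id in unique(det$track_id)) {
      d <- det[det$track_id %in% id, , drop = FALSE]
      d <- d[order(d$frame), , drop = FALSE]
      if (nrow(d) >= 2) {
        for (i in seq_len(nrow(d) - 1)) {
          gap <- d$frame[i + 1] - d$frame[i] - 1
          if (gap >= 1 && gap <= config$max_box_gap_frames) {
            for (f in (d$frame[i] + 1):(d$frame[i + 1] - 1)) {
              a <- (f - d$frame[i]) / (d$frame[i + 1] - d$frame[i])
              row <- d[i, , drop = FALSE]
              row$frame <- f
              row$x <- d$x[i] + a * (d$x[i + 1] - d$x[i])
              row$y <- d$y[i] + a * (d$y[i + 1] - d$y[i])
              row$w <- d$w[i] + a * (d$w[i + 1] - d$w[i])
              row$h <- d$h[i] + a * (d$h[i + 1] - d$h[i])
              filled <- rbind(filled, row)
            }
          }
        }
      }
    }
  }

  segment <- session$segment
  if (is.null(segment)) {
    if (nrow(filled) == 0) {
      return(list(t1_ms = NA_real_, t2_ms = NA_real_, ttf_ms = NA_real_,
                  flags = "no_onset"))
    }
    segment <- list(start_ms = min(filled$frame) * 1000 / geom$fps,
                    end_ms = (max(filled$frame) + 1) * 1000 / geom$fps)
  }

  ft <- filled$frame * 1000 / geom$fps
  in_seg <- ft >= segment$start_ms & ft < segment$end_ms
  if (nrow(filled) == 0 || !any(in_seg)) {
    return(list(t1_ms = NA_real_, t2_ms = NA_real_, ttf_ms = NA_real_,
                flags = "no_onset"))
  }
  t1 <- min(ft[in_seg])

  gaze <- as.data.frame(session$gaze)
  t2 <- NA_real_
  for (i in order(gaze$t_ms)) {
    t <- gaze$t_ms[i]
    if (!gaze$valid[i] || t < t1) next
    if (t >= segment$end_ms) break
    f <- floor(t * geom$fps / 1000)
    boxes <- filled[filled$frame == f, , drop = FALSE]
    hit <- FALSE
    for (j in seq_len(nrow(boxes))) {
      b <- boxes[j, ]
      if (gaze$x_px[i] >= b$x && gaze$x_px[i] <= b$x + b$w &&
          gaze$y_px[i] >= b$y && gaze$y_px[i] <= b$y + b$h) {
        hit <- TRUE
        break
      }
    }
    if (hit) {
      t2 <- t
      break
    }
  }

  ttf <- if (is.na(t2)) NA_real_ else t2 - t1
  flags <- if (is.na(t2)) "miss"
  else if (ttf == 0) "anticipatory"
  else if (ttf < config$ttf_min_saccade_ms) "sub_saccade"
  else character()
  list(t1_ms = t1, t2_ms = t2, ttf_ms = ttf, flags = flags)
}

expect_ttf_matches_oracle <- function(session, config = pipeline_config()) {
  got <- compute_ttf(session, config)
  want <- oracle_ttf(session, config)
  expect_identical(got$t1_ms, want$t1_ms)
  expect_identical(got$t2_ms, want$t2_ms)
  expect_identical(got$ttf_ms, want$ttf_ms)
  expect_identical(sort(got$flags), sort(want$flags))
}
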