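#' Plot one session's gaze trace against the hazard window
#'
#' Horizontal gaze coordinate over time, with invalid samples marked, the
#' hazard box's horizontal extent shaded, and t1/t2 rules when a TTF is
#' available. A quick visual check of why a session produced (or failed to
#' produce) a TTF.
#'
#' @param session A [hazard_session()].
#' @param config A [pipeline_config()].
#' @return A ggplot object.
#' @export
plot_session <- function(session, config = pipeline_config()) {
  rt <- resolve_tracks(session, config)
  ttf <- compute_ttf_resolved(session, rt, config)
  g <- dplyr::mutate(session$gaze,
                     validity = ifelse(.data$valid, "valid", "invalid"))
  p <- ggplot2::ggplot(g, ggplot2::aes(x = .data$t_ms, y = .data$x_px))
  if (nrow(rt$tracks) > 0) {
    band <- dplyr::mutate(rt$tracks,
                          t0 = frame_to_time(.data$frame, session$geometry),
                          t1 = frame_to_time(.data$frame + 1L, session$geometry))
    p <- p + ggplot2::geom_rect(
      data = band,
      ggplot2::aes(xmin = .data$t0, xmax = .data$t1,
                   ymin = .data$x, ymax = .data$x + .data$w),
      inherit.aes = FALSE, fill = "goldenrod", alpha = 0.35)
  }
  p <- p +
    ggplot2::geom_point(ggplot2::aes(shape = .data$validity), size = 0.8) +
    ggplot2::scale_shape_manual(values = c(valid = 16, invalid = 4))
  if (!is.na(ttf$t1_ms)) {
    p <- p + ggplot2::geom_vline(xintercept = ttf$t1_ms, linetype = "dashed")
  }
  if (!is.na(ttf$t2_ms)) {
    p <- p + ggplot2::geom_vline(xintercept = ttf$t2_ms, colour = "red3")
  }
  p + ggplot2::labs(
    x = "time (ms)", y = "horizontal position (px)",
    title = sprintf("subject %s: TTF = %s ms", session$subject_id,
                    format(ttf$ttf_ms)),
    subtitle = "shaded: hazard box horizontal extent; dashed: t1; red: t2"
  )
}

#' Boxplots of a cohort parameter by fitness group
#'
#' @param cohort Feature tibble.
#' @param response Parameter column (tidyselect), e.g. `ttf_ms`.
#' @return A ggplot object.
#' @export
plot_cohort <- function(cohort, response = ttf_ms) {
  lab <- rlang::as_name(rlang::enquo(response))
  ggplot2::ggplot(dplyr::filter(cohort, !is.na({{ response }})),
                  ggplot2::aes(x = .data$fitness, y = {{ response }})) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.5, size = 0.9) +
    ggplot2::labs(x = NULL, y = lab)
}

#' @rdname plot_session
#' @param object A [hazard_session()].
#' @param ... Passed to [plot_session()].
#' @export
autoplot.hazard_session <- function(object, ...) plot_session(object, ...)
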