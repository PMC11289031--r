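utils::globalVariables(c("fitness", "ttf_ms", "prt_ms"))

#' Specification of one synthetic hazard session
#'
#' Emulates the hazard scene: a pedestrian (person-class) track entering the
#' frame at a configured video frame and crossing the road, a gaze trace
#' that holds a road-centre fixation and jumps onto the pedestrian a
#' configured latency after onset (the ground-truth TTF) with Gaussian
#' pixel noise and optional linear slippage drift, optional invalid
#' (tracking-loss) samples, and a simulator log with stop-sign triggers and
#' step brake responses at configured delays. Defaults mirror the study
#' conditions: 960 x 540 at 50 Hz, an onset a few seconds into the segment,
#' a ~240 ms latency, speeds around 20 km/h, three stop-sign repetitions.
#'
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @param geometry A [frame_geometry()].
#' @param duration_ms Session length (ms).
#' @param hazard_entry_frame Video frame at which the pedestrian appears.
#' @param box_entry_px Named vector `c(x, y)`: box top-left at entry.
#' @param box_velocity_px Named vector `c(x, y)`: per-frame box velocity.
#' @param box_size_px Named vector `c(w, h)`: box size.
#' @param detect_conf Detector confidence assigned to every true detection.
#' @param drop_frames Frames (relative to entry, e.g. `c(10, 11)`) whose
#'   detections are withheld, to emulate detector misses.
#' @param gaze_latency_ms Ground-truth TTF: gaze jumps onto the target this
#'   long after onset.
#' @param gaze_noise_px SD of isotropic Gaussian gaze noise.
#' @param slippage_drift_px_per_s Linear horizontal gaze drift (headset
#'   slippage).
#' @param missing_fraction Fraction of gaze samples marked invalid.
#' @param fixation_px Named vector `c(x, y)`: pre-saccade road fixation.
#' @param stop_sign_times_ms Stop-sign trigger times (up to 3 repetitions).
#' @param brake_delay_ms Brake-response delay per trigger (recycled); the
#'   brake is a step to `brake_force_N`, so the pipeline recovers these
#'   exactly when they are multiples of the simulator period.
#' @param brake_hold_ms How long the brake stays pressed.
#' @param brake_force_N Plateau force of the brake step.
#' @param speed_kmh Constant ego speed.
#' @param initial_distance_m Ego-to-pedestrian distance at recording start.
#' @param simlog_rate_hz Simulator log rate.
#' @param subject_id,fitness Subject metadata.
#' @return A `session_spec` object.
#' @export
session_spec <- function(seed = 1,
                         geometry = frame_geometry(),
                         duration_ms = 8000,
                         hazard_entry_frame = 150,
                         box_entry_px = c(x = 640, y = 220),
                         box_velocity_px = c(x = -3, y = 1),
                         box_size_px = c(w = 36, h = 80),
                         detect_conf = 0.9,
                         drop_frames = integer(),
                         gaze_latency_ms = 240,
                         gaze_noise_px = 3,
                         slippage_drift_px_per_s = 0,
                         missing_fraction = 0,
                         fixation_px = c(x = 250, y = 380),
                         stop_sign_times_ms = c(1000, 3500, 6000),
                         brake_delay_ms = 1200,
                         brake_hold_ms = 400,
                         brake_force_N = 120,
                         speed_kmh = 20,
                         initial_distance_m = 60,
                         simlog_rate_hz = 100,
                         subject_id = "synthetic",
                         fitness = "fit") {
  stopifnot(gaze_latency_ms >= 0, gaze_noise_px >= 0,
            missing_fraction >= 0, missing_fraction < 1,
            duration_ms > 0, hazard_entry_frame >= 0,
            length(stop_sign_times_ms) <= 3)
  spec <- as.list(environment())
  structure(spec, class = "session_spec")
}

#' Generate a synthetic session with known ground truth
#'
#' Realises a [session_spec()] into a [hazard_session()] plus the ground
#' truth the generator used, so pipeline output can be checked against
#' construction. The pedestrian box follows its linear trajectory from
#' `hazard_entry_frame` until it leaves the frame or the session ends; the
#' gaze switches from the road fixation to the box centre (plus noise and
#' drift) at `t1 + gaze_latency_ms`; brake force steps above threshold
#' `brake_delay_ms` after each stop-sign trigger.
#'
#' @param spec A [session_spec()].
#' @return List with `session` (a [hazard_session()]) and `truth`
#'   (`t1_ms`, `latency_ms`, `t2_intended_ms`, `prt_ms`).
#' @examples
#' s <- generate_session(session_spec(seed = 7, gaze_latency_ms = 300))
#' tidy(compute_ttf(s$session))
#' @export
generate_session <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  geom <- spec$geometry
  n_frames <- as.integer(floor(spec$duration_ms * geom$fps / 1000))
  if (spec$hazard_entry_frame >= n_frames) {
    abort("hazard_entry_frame lies beyond the session")
  }

  # pedestrian trajectory, truncated when the box centre leaves the frame
  fr <- spec$hazard_entry_frame:(n_frames - 1L)
  k <- seq_along(fr) - 1L
  bx <- spec$box_entry_px[["x"]] + k * spec$box_velocity_px[["x"]]
  by <- spec$box_entry_px[["y"]] + k * spec$box_velocity_px[["y"]]
  cx <- bx + spec$box_size_px[["w"]] / 2
  cy <- by + spec$box_size_px[["h"]] / 2
  inside <- cx >= 0 & cx <= geom$width_px & cy >= 0 & cy <= geom$height_px
  last <- if (all(inside)) length(fr) else which(!inside)[1] - 1L
  if (last < 1) abort("pedestrian trajectory starts outside the frame")
  fr <- fr[seq_len(last)]; bx <- bx[seq_len(last)]; by <- by[seq_len(last)]
  cx <- cx[seq_len(last)]; cy <- cy[seq_len(last)]

  t1 <- frame_to_time(spec$hazard_entry_frame, geom)
  t_switch <- t1 + spec$gaze_latency_ms
  last_box_t <- frame_to_time(fr[last] + 1L, geom)
  if (t_switch >= last_box_t) {
    abort("pedestrian leaves the frame before the gaze arrives; shorten gaze_latency_ms or slow the trajectory")
  }

  det <- tibble(frame = fr, track_id = 1L, class = "person",
                conf = spec$detect_conf,
                x = bx, y = by,
                w = spec$box_size_px[["w"]], h = spec$box_size_px[["h"]],
                source = "detector")
  if (length(spec$drop_frames)) {
    det <- det[!det$frame %in% (spec$hazard_entry_frame + spec$drop_frames), ]
  }

  period <- 1000 / geom$gaze_rate_hz
  n_g <- as.integer(floor(spec$duration_ms / period))
  tg <- (seq_len(n_g) - 1L) * period

  withr::with_seed(spec$seed, {
    # target of each gaze sample: road fixation, then the box centre of the
    # sample's own frame (clamped to the last tracked frame)
    gfr <- time_to_frame(tg, geom)
    idx <- pmin(pmax(gfr - spec$hazard_entry_frame + 1L, 1L), last)
    on_target <- tg >= t_switch
    gx <- ifelse(on_target, cx[idx], spec$fixation_px[["x"]])
    gy <- ifelse(on_target, cy[idx], spec$fixation_px[["y"]])
    gx <- gx + rnorm(n_g, 0, spec$gaze_noise_px) +
      spec$slippage_drift_px_per_s * tg / 1000
    gy <- gy + rnorm(n_g, 0, spec$gaze_noise_px)
    valid <- rep(TRUE, n_g)
    n_bad <- round(spec$missing_fraction * n_g)
    if (n_bad > 0) {
      bad <- sample.int(n_g, n_bad)
      valid[bad] <- FALSE
      gx[bad] <- NA_real_
      gy[bad] <- NA_real_
    }
    gaze <- tibble(t_ms = tg, x_px = gx, y_px = gy, valid = valid)
  })

  sim_period <- 1000 / spec$simlog_rate_hz
  ts <- seq(0, spec$duration_ms - sim_period, by = sim_period)
  delays <- rep_len(spec$brake_delay_ms, length(spec$stop_sign_times_ms))
  brake <- rep(0, length(ts))
  sign_on <- rep(FALSE, length(ts))
  for (i in seq_along(spec$stop_sign_times_ms)) {
    tr <- spec$stop_sign_times_ms[i]
    brake[ts >= tr + delays[i] & ts < tr + delays[i] + spec$brake_hold_ms] <-
      spec$brake_force_N
    sign_on[ts >= tr & ts < tr + 500] <- TRUE
  }
  simlog <- tibble(
    t_ms = ts,
    speed_kmh = spec$speed_kmh,
    distance_m = pmax(0, spec$initial_distance_m -
                        spec$speed_kmh / 3.6 * ts / 1000),
    brake_N = brake,
    stop_sign = sign_on
  )

  session <- hazard_session(
    subject_id = spec$subject_id, gaze = gaze, detections = det,
    simlog = simlog, geometry = geom, fitness = spec$fitness
  )
  t2_intended <- {
    cand <- tg[tg >= t_switch & gaze$valid]
    if (length(cand)) cand[1] else NA_real_
  }
  list(session = session,
       truth = list(t1_ms = t1,
                    latency_ms = spec$gaze_latency_ms,
                    t2_intended_ms = t2_intended,
                    prt_ms = delays))
}

#' Adversarial random session (stress fixture)
#'
#' Draws a session with randomised box trajectories (one or two tracks with
#' random walks and random detector dropouts), uniform-random gaze points
#' over the whole frame and random invalid samples. Unlike
#' [generate_session()] nothing guarantees the gaze reaches the hazard, so
#' anticipatory hits, slow hits and misses all occur — the intended prey for
#' brute-force cross-checks of the event logic.
#'
#' @param seed Integer seed.
#' @param geometry A [frame_geometry()].
#' @param duration_ms Session length (ms).
#' @return List with `session` and its explicit `segment`.
#' @export
random_session <- function(seed, geometry = frame_geometry(),
                           duration_ms = 4000) {
  withr::with_seed(seed, {
    n_frames <- as.integer(duration_ms * geometry$fps / 1000)
    n_tracks <- sample(1:2, 1)
    det <- purrr::map(seq_len(n_tracks), function(id) {
      f0 <- sample.int(max(n_frames - 20, 1), 1) - 1L
      len <- sample(10:60, 1)
      fr <- f0:min(f0 + len, n_frames - 1L)
      n <- length(fr)
      w <- runif(1, 20, 120); h <- runif(1, 30, 160)
      tibble(frame = fr, track_id = id,
             class = sample(c("person", "person", "car"), 1),
             conf = runif(n, 0.1, 1),
             x = cumsum(c(runif(1, 0, geometry$width_px - w), runif(n - 1, -8, 8))),
             y = cumsum(c(runif(1, 0, geometry$height_px - h), runif(n - 1, -5, 5))),
             w = w, h = h, source = "detector")
    }) |> dplyr::bind_rows()
    # random dropouts leave gaps for the interpolation path
    det <- det[runif(nrow(det)) > 0.15, ]

    period <- 1000 / geometry$gaze_rate_hz
    tg <- (seq_len(floor(duration_ms / period)) - 1L) * period
    gaze <- tibble(
      t_ms = tg,
      x_px = runif(length(tg), -50, geometry$width_px + 50),
      y_px = runif(length(tg), -50, geometry$height_px + 50),
      valid = runif(length(tg)) > 0.1
    )
    gaze$x_px[!gaze$valid] <- NA_real_
    gaze$y_px[!gaze$valid] <- NA_real_

    ts <- seq(0, duration_ms - 10, by = 10)
    simlog <- tibble(t_ms = ts, speed_kmh = runif(1, 5, 45),
                     distance_m = pmax(0, 80 - ts / 100),
                     brake_N = 0, stop_sign = FALSE)

    seg_start <- runif(1, 0, duration_ms / 3)
    segment <- scene_segment(seg_start, runif(1, seg_start + 500, duration_ms))
    session <- hazard_session("random", gaze, det, simlog,
                              geometry = geometry, segment = segment)
  })
  list(session = session, segment = segment)
}

#' Specification of a synthetic cohort
#'
#' Per-group feature distributions mirroring the published group summaries:
#' TTF and PRT are truncated normals inside their validity windows (so a
#' generated cohort survives the screens except for injected outliers);
#' speed, IGD and TTC are lognormal with moments matched to the reported
#' mean/SD (their reported ranges are clearly right-skewed). Group sizes
#' default to the analysed cohort: 20 fit, 17 conditionally fit, 19 unfit.
#'
#' @param seed Integer seed.
#' @param n Named integer vector of group sizes (each >= 2).
#' @param ttf_mean,ttf_sd Per-group TTF mean / SD (ms), order
#'   fit, conditionally_fit, unfit.
#' @param ttf_bounds TTF truncation bounds (ms), right-open.
#' @param prt_mean,prt_sd Per-group PRT mean / SD (ms).
#' @param prt_bounds PRT truncation bounds (ms).
#' @param speed_mean,speed_sd Per-group speed moments (km/h).
#' @param igd_mean,igd_sd Per-group IGD moments (degrees).
#' @param ttc_mean,ttc_sd Per-group TTC moments (s).
#' @param n_outliers Number of TTF outliers injected (values above the
#'   validity maximum, replacing random subjects' TTFs).
#' @param outlier_range Uniform range the injected outliers are drawn from.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(seed = 1,
                        n = c(fit = 20, conditionally_fit = 17, unfit = 19),
                        ttf_mean = c(163, 293, 262),
                        ttf_sd = c(47, 95, 99),
                        ttf_bounds = c(100, 500),
                        prt_mean = c(1241, 1215.98, 1696),
                        prt_sd = c(475, 358, 449),
                        prt_bounds = c(500, 4000),
                        speed_mean = c(19.5, 19.1, 20.3),
                        speed_sd = c(10.5, 11.4, 10.9),
                        igd_mean = c(6.67, 3.90, 4.99),
                        igd_sd = c(6.35, 2.20, 4.76),
                        ttc_mean = c(3.3, 3.9, 4.2),
                        ttc_sd = c(2.6, 3.5, 4.7),
                        n_outliers = 0,
                        outlier_range = c(600, 1500)) {
  stopifnot(all(n >= 2), length(n) == 3,
            length(ttf_mean) == 3, length(ttf_sd) == 3,
            n_outliers >= 0, outlier_range[1] > 0,
            outlier_range[1] <= outlier_range[2])
  # truncation must leave usable mass
  mass <- pnorm(ttf_bounds[2], ttf_mean, ttf_sd) -
    pnorm(ttf_bounds[1], ttf_mean, ttf_sd)
  if (any(mass < 0.01)) {
    abort("infeasible TTF truncation: group mean lies far outside the bounds")
  }
  spec <- as.list(environment())
  spec$mass <- NULL
  structure(spec, class = "cohort_spec")
}

# truncated-normal draws by rejection; bounds checked feasible upstream
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= lower & x < upper])
  }
  out[seq_len(n)]
}

rlnorm_moments <- function(n, mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Generate a synthetic per-subject feature cohort
#'
#' Draws one feature table from a [cohort_spec()]: per-group truncated-normal
#' TTFs and PRTs, lognormal covariates, plus optional injected TTF outliers.
#' Bit-reproducible given the seed.
#'
#' @param spec A [cohort_spec()].
#' @return Feature tibble (`subject_id, fitness, ttf_ms, speed_kmh, igd_deg,
#'   ttc_s, prt_ms, flags`); injected-outlier rows carry flag
#'   `injected_outlier` and their indices are in `attr(, "outlier_rows")`.
#' @examples
#' co <- generate_cohort(cohort_spec(seed = 42, n_outliers = 3))
#' sum(screen_ttf(co)$ttf_excluded)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- names(spec$n)
  withr::with_seed(spec$seed, {
    co <- purrr::map(seq_along(groups), function(i) {
      ni <- spec$n[[i]]
      tibble(
        fitness = groups[i],
        ttf_ms = rtrunc_norm(ni, spec$ttf_mean[i], spec$ttf_sd[i],
                             spec$ttf_bounds[1], spec$ttf_bounds[2]),
        speed_kmh = rlnorm_moments(ni, spec$speed_mean[i], spec$speed_sd[i]),
        igd_deg = rlnorm_moments(ni, spec$igd_mean[i], spec$igd_sd[i]),
        ttc_s = rlnorm_moments(ni, spec$ttc_mean[i], spec$ttc_sd[i]),
        prt_ms = rtrunc_norm(ni, spec$prt_mean[i], spec$prt_sd[i],
                             spec$prt_bounds[1], spec$prt_bounds[2])
      )
    }) |> dplyr::bind_rows()
    co <- dplyr::mutate(co,
                        subject_id = sprintf("S%03d", dplyr::row_number()),
                        flags = "", .before = 1)
    out_rows <- integer(0)
    if (spec$n_outliers > 0) {
      out_rows <- sort(sample.int(nrow(co), spec$n_outliers))
      co$ttf_ms[out_rows] <- runif(spec$n_outliers,
                                   spec$outlier_range[1], spec$outlier_range[2])
      co$flags[out_rows] <- "injected_outlier"
    }
  })
  co <- co[, c("subject_id", "fitness", "ttf_ms", "speed_kmh",
               "igd_deg", "ttc_s", "prt_ms", "flags")]
  attr(co, "outlier_rows") <- out_rows
  co
}
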