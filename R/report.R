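try_or_null <- function(expr) {
  tryCatch(expr, error = function(e) {
    warn(paste("stats component skipped:", conditionMessage(e)))
    NULL
  })
}

#' Full group-comparison report for a feature table
#'
#' Runs the whole statistical battery on a per-subject feature table:
#' screening ([screen_ttf()], [screen_prt()]), per-group summaries of every
#' parameter, Welch's ANOVA and Tukey HSD for TTF and PRT, the sequential-SS
#' general linear model with covariates, a Shapiro-Wilk check of its
#' residuals, and Pearson correlations of TTF with speed, IGD, TTC and PRT.
#' PRT analyses use only subjects that also have a TTF. A classical one-way
#' F test for PRT is reported alongside Welch's (PRT conforms to normality,
#' where the published analysis used the plain F test).
#'
#' @param cohort Feature tibble (`subject_id, fitness, ttf_ms, speed_kmh,
#'   igd_deg, ttc_s, prt_ms, flags`), e.g. from [extract_features()] or
#'   [read_features_csv()].
#' @param config A [pipeline_config()].
#' @param include_outliers Re-run with screened TTF outliers kept
#'   (robustness check); screening flags are still reported.
#' @return A `hazard_stats` object. Components: `summaries`, `welch_ttf`,
#'   `welch_prt`, `anova_f_prt`, `tukey_ttf`, `tukey_prt`, `glm_terms`,
#'   `shapiro_residuals`, `correlations`, `screened` (the flagged cohort),
#'   `n`. Methods: [tidy()], [glance()], `print()`.
#' @examples
#' co <- generate_cohort(cohort_spec(seed = 1))
#' hazard_stats(co)
#' @export
hazard_stats <- function(cohort, config = pipeline_config(),
                         include_outliers = FALSE) {
  co <- screen_prt(screen_ttf(as_tibble(cohort), config), config)
  ttf_rows <- if (include_outliers) !is.na(co$ttf_ms) else
    !is.na(co$ttf_ms) & !co$ttf_excluded
  ca <- co[ttf_rows, ]
  prt_rows <- !is.na(ca$prt_ms) & !ca$prt_excluded
  cp <- ca[prt_rows, ]

  summaries <- purrr::map(
    c(ttf_ms = "ttf_ms", speed_kmh = "speed_kmh", igd_deg = "igd_deg",
      ttc_s = "ttc_s", prt_ms = "prt_ms"),
    function(p) {
      dat <- if (p == "prt_ms") cp else ca
      try_or_null(summarize_groups(dat, !!rlang::sym(p)))
    })

  welch_ttf <- try_or_null(welch_anova(ca, ttf_ms))
  welch_prt <- try_or_null(welch_anova(cp, prt_ms))
  anova_f_prt <- try_or_null({
    fit <- aov(prt_ms ~ factor(fitness), data = cp)
    sm <- summary(fit)[[1]]
    tibble(statistic = sm[1, "F value"], df1 = sm[1, "Df"],
           df2 = sm[2, "Df"], p.value = sm[1, "Pr(>F)"])
  })
  tukey_ttf <- try_or_null(tukey_hsd(ca, ttf_ms, conf = config$tukey_conf))
  tukey_prt <- try_or_null(tukey_hsd(cp, prt_ms, conf = config$tukey_conf))
  glm_terms <- try_or_null(ancova_glm(ca, alpha = config$glm_alpha))
  shapiro_res <- if (!is.null(glm_terms)) {
    try_or_null(shapiro_wilk(residuals(attr(glm_terms, "model"))))
  }
  correlations <- try_or_null(
    dplyr::bind_rows(purrr::map(
      c(speed_kmh = "speed_kmh", igd_deg = "igd_deg",
        ttc_s = "ttc_s", prt_ms = "prt_ms"),
      function(p) {
        res <- try_or_null(pearson_correlation(ca$ttf_ms, ca[[p]]))
        if (is.null(res)) tibble(r = NA_real_, p.value = NA_real_, n = NA_integer_)
        else res
      }), .id = "parameter"))

  structure(
    list(summaries = summaries,
         welch_ttf = welch_ttf, welch_prt = welch_prt,
         anova_f_prt = anova_f_prt,
         tukey_ttf = tukey_ttf, tukey_prt = tukey_prt,
         glm_terms = glm_terms,
         shapiro_residuals = shapiro_res,
         correlations = correlations,
         screened = co,
         include_outliers = include_outliers,
         n = c(total = nrow(co), ttf_analysis = nrow(ca),
               prt_analysis = nrow(cp))),
    class = "hazard_stats"
  )
}

#' @export
print.hazard_stats <- function(x, ...) {
  cat(sprintf("<hazard_stats> %d subjects (%d in TTF analysis, %d in PRT analysis)%s\n",
              x$n["total"], x$n["ttf_analysis"], x$n["prt_analysis"],
              if (x$include_outliers) " [outliers included]" else ""))
  if (!is.null(x$welch_ttf)) {
    cat("TTF  "); print(x$welch_ttf)
  }
  if (!is.null(x$welch_prt)) {
    cat("PRT  "); print(x$welch_prt)
  }
  if (!is.null(x$tukey_ttf)) {
    cat("Tukey HSD (TTF):\n")
    print(as.data.frame(tidy(x$tukey_ttf)), digits = 4)
  }
  if (!is.null(x$glm_terms)) {
    cat("GLM terms (sequential SS):\n")
    print(as.data.frame(tidy(x$glm_terms)), digits = 4)
  }
  if (!is.null(x$shapiro_residuals)) {
    cat(sprintf("Shapiro-Wilk on GLM residuals: W = %.4f, p = %.4g\n",
                x$shapiro_residuals$W, x$shapiro_residuals$p.value))
  }
  if (!is.null(x$correlations)) {
    cat("Pearson correlations with TTF:\n")
    print(as.data.frame(x$correlations), digits = 4)
  }
  invisible(x)
}

#' @export
tidy.hazard_stats <- function(x, ...) {
  rows <- list()
  if (!is.null(x$welch_ttf)) {
    rows <- c(rows, list(dplyr::mutate(tidy(x$welch_ttf),
                                       analysis = "welch_ttf", .before = 1)))
  }
  if (!is.null(x$welch_prt)) {
    rows <- c(rows, list(dplyr::mutate(tidy(x$welch_prt),
                                       analysis = "welch_prt", .before = 1)))
  }
  if (!is.null(x$anova_f_prt)) {
    rows <- c(rows, list(dplyr::mutate(x$anova_f_prt,
                                       analysis = "anova_f_prt", .before = 1)))
  }
  if (!is.null(x$tukey_ttf)) {
    rows <- c(rows, list(tidy(x$tukey_ttf) |>
                           dplyr::transmute(analysis = "tukey_ttf",
                                            term = .data$pair,
                                            statistic = .data$diff,
                                            p.value = .data$p_adj)))
  }
  if (!is.null(x$tukey_prt)) {
    rows <- c(rows, list(tidy(x$tukey_prt) |>
                           dplyr::transmute(analysis = "tukey_prt",
                                            term = .data$pair,
                                            statistic = .data$diff,
                                            p.value = .data$p_adj)))
  }
  if (!is.null(x$glm_terms)) {
    rows <- c(rows, list(tidy(x$glm_terms) |>
                           dplyr::transmute(analysis = "glm",
                                            term = .data$term,
                                            statistic = .data$statistic,
                                            p.value = .data$p.value)))
  }
  if (!is.null(x$correlations)) {
    rows <- c(rows, list(x$correlations |>
                           dplyr::transmute(analysis = "pearson_ttf",
                                            term = .data$parameter,
                                            statistic = .data$r,
                                            p.value = .data$p.value)))
  }
  dplyr::bind_rows(rows)
}

#' @export
glance.hazard_stats <- function(x, ...) {
  tibble(
    n_total = unname(x$n["total"]),
    n_ttf = unname(x$n["ttf_analysis"]),
    n_prt = unname(x$n["prt_analysis"]),
    welch_f_ttf = if (is.null(x$welch_ttf)) NA_real_ else x$welch_ttf$statistic,
    welch_p_ttf = if (is.null(x$welch_ttf)) NA_real_ else x$welch_ttf$p.value,
    welch_f_prt = if (is.null(x$welch_prt)) NA_real_ else x$welch_prt$statistic,
    welch_p_prt = if (is.null(x$welch_prt)) NA_real_ else x$welch_prt$p.value,
    shapiro_p = if (is.null(x$shapiro_residuals)) NA_real_ else
      x$shapiro_residuals$p.value
  )
}

#' Serialise a stats report to JSON
#'
#' Numbers are written at full precision.
#'
#' @param x A `hazard_stats` object.
#' @param path Output file.
#' @export
write_stats_json <- function(x, path) {
  payload <- list(
    n = as.list(x$n),
    include_outliers = x$include_outliers,
    summaries = purrr::map(x$summaries, ~ if (is.null(.x)) NULL else as.data.frame(.x)),
    welch = list(ttf = if (is.null(x$welch_ttf)) NULL else
                   as.list(glance(x$welch_ttf)),
                 prt = if (is.null(x$welch_prt)) NULL else
                   as.list(glance(x$welch_prt))),
    anova_f_prt = if (is.null(x$anova_f_prt)) NULL else as.list(x$anova_f_prt),
    tukey = list(ttf = if (is.null(x$tukey_ttf)) NULL else tidy(x$tukey_ttf),
                 prt = if (is.null(x$tukey_prt)) NULL else tidy(x$tukey_prt)),
    glm_terms = if (is.null(x$glm_terms)) NULL else tidy(x$glm_terms),
    shapiro_residuals = x$shapiro_residuals,
    correlations = x$correlations
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}
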