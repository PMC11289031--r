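iqr_upper_fence <- function(values, config) {
  q <- unname(quantile(values, c(0.25, 0.75),
                       type = config$quantile_type, names = FALSE))
  q[2] + config$iqr_multiplier * (q[2] - q[1])
}

#' Cohort-level TTF validity and outlier screening
#'
#' Two pointwise-or-pooled rules, both evaluated in one pass on the original
#' cohort (never on an already-filtered one):
#' * `ttf_over_max` — TTF at or above 500 ms (a glance that slow is a miss,
#'   not a fixation);
#' * `ttf_iqr_outlier` — TTF more than three interquartile ranges above the
#'   third quartile of the pooled TTF sample (quartiles by linear
#'   interpolation between order statistics; one-sided, above Q3 only).
#'
#' The removal set is the union of the two flags. The IQR rule is pooled
#' across groups, not stratified. With fewer than four TTF values the
#' quartiles are unstable and the IQR rule is skipped with a warning.
#'
#' @param cohort Feature tibble with a `ttf_ms` column.
#' @param config A [pipeline_config()].
#' @return `cohort` plus logical columns `ttf_over_max`, `ttf_iqr_outlier`,
#'   `ttf_excluded`.
#' @examples
#' screen_ttf(tibble::tibble(ttf_ms = c(200, 250, 300, 720)))
#' @export
screen_ttf <- function(cohort, config = pipeline_config()) {
  co <- as_tibble(cohort)
  tt <- co$ttf_ms
  present <- !is.na(tt)
  over <- present & tt >= config$ttf_valid_max_ms
  if (sum(present) < 4) {
    warn("fewer than 4 TTF values: IQR outlier rule skipped")
    iqr_flag <- rep(FALSE, length(tt))
  } else {
    fence <- iqr_upper_fence(tt[present], config)
    iqr_flag <- present & tt > fence
  }
  dplyr::mutate(co,
                ttf_over_max = over,
                ttf_iqr_outlier = iqr_flag,
                ttf_excluded = over | iqr_flag)
}

#' Cohort-level PRT screening
#'
#' Per-repetition range validity (0.5--4 s) is enforced upstream by
#' [average_prt()] before averaging; here the averaged PRTs get the same
#' one-sided three-IQR outlier rule as TTF, plus a range flag for averaged
#' values that fall outside the validity window (possible only for
#' externally supplied tables). Subjects without a PRT are absent from PRT
#' analysis (flag columns stay `FALSE`; `prt_ms` is `NA`).
#'
#' @param cohort Feature tibble with a `prt_ms` column (averaged PRTs).
#' @param config A [pipeline_config()].
#' @return `cohort` plus logical columns `prt_out_of_range`,
#'   `prt_iqr_outlier`, `prt_excluded`.
#' @export
screen_prt <- function(cohort, config = pipeline_config()) {
  co <- as_tibble(cohort)
  pr <- co$prt_ms
  present <- !is.na(pr)
  out_of_range <- present & (pr < config$prt_valid_range_ms[1] |
                               pr > config$prt_valid_range_ms[2])
  if (sum(present) < 4) {
    if (sum(present) > 0) warn("fewer than 4 PRT values: IQR outlier rule skipped")
    iqr_flag <- rep(FALSE, length(pr))
  } else {
    fence <- iqr_upper_fence(pr[present], config)
    iqr_flag <- present & pr > fence
  }
  dplyr::mutate(co,
                prt_out_of_range = out_of_range,
                prt_iqr_outlier = iqr_flag,
                prt_excluded = out_of_range | iqr_flag)
}
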