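pull_groups <- function(data, response, group) {
  v <- dplyr::pull(data, {{ response }})
  g <- dplyr::pull(data, {{ group }})
  keep <- !is.na(v) & !is.na(g)
  list(v = v[keep], g = factor(g[keep]))
}

#' Per-group summary statistics
#'
#' Range, mean with standard deviation (Bessel's correction, the n - 1
#' denominator) and median of one parameter per group.
#'
#' @param data Feature tibble.
#' @param response Parameter column (tidyselect).
#' @param group Grouping column; defaults to `fitness`.
#' @return Tibble `group, n, min, max, mean, sd, median`; `sd` is `NA` with a
#'   warning for single-observation groups.
#' @examples
#' co <- generate_cohort(cohort_spec(seed = 1))
#' summarize_groups(co, ttf_ms)
#' @export
summarize_groups <- function(data, response, group = fitness) {
  gv <- pull_groups(data, {{ response }}, {{ group }})
  out <- tibble(group = levels(gv$g)) |>
    dplyr::mutate(
      n = purrr::map_int(.data$group, ~ sum(gv$g == .x)),
      min = purrr::map_dbl(.data$group, ~ min(gv$v[gv$g == .x])),
      max = purrr::map_dbl(.data$group, ~ max(gv$v[gv$g == .x])),
      mean = purrr::map_dbl(.data$group, ~ mean(gv$v[gv$g == .x])),
      sd = purrr::map_dbl(.data$group,
                          ~ if (sum(gv$g == .x) >= 2) sd(gv$v[gv$g == .x]) else NA_real_),
      median = purrr::map_dbl(.data$group, ~ median(gv$v[gv$g == .x]))
    )
  if (any(is.na(out$sd))) {
    warn("standard deviation undefined for single-observation groups")
  }
  out
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Compares k group means without assuming equal variances (Welch 1951):
#' groups are weighted by `n_j / s_j^2` and the denominator degrees of
#' freedom follow the Welch-Satterthwaite approximation (fractional).
#' Appropriate for TTF, whose distribution and spread differ across
#' fitness groups.
#'
#' @param data Feature tibble.
#' @param response Response column (tidyselect).
#' @param group Grouping column; defaults to `fitness`.
#' @return A `welch_anova` object: `statistic` (F), `df1`, `df2`, `p.value`,
#'   `n`, `k`. Methods: [tidy()], [glance()].
#' @examples
#' co <- generate_cohort(cohort_spec(seed = 1))
#' welch_anova(co, ttf_ms)
#' @export
welch_anova <- function(data, response, group = fitness) {
  gv <- pull_groups(data, {{ response }}, {{ group }})
  tab <- table(gv$g)
  if (length(tab) < 2) abort("welch_anova needs at least two groups")
  if (any(tab < 2)) {
    abort(sprintf("group '%s' has fewer than 2 observations",
                  names(tab)[which(tab < 2)[1]]))
  }
  vars <- tapply(gv$v, gv$g, var)
  if (any(vars == 0)) {
    abort(sprintf("zero within-group variance in group '%s'",
                  names(vars)[which(vars == 0)[1]]))
  }
  ow <- oneway.test(v ~ g, data = data.frame(v = gv$v, g = gv$g),
                    var.equal = FALSE)
  structure(
    list(statistic = unname(ow$statistic),
         df1 = unname(ow$parameter[1]),
         df2 = unname(ow$parameter[2]),
         p.value = unname(ow$p.value),
         n = length(gv$v), k = length(tab)),
    class = "welch_anova"
  )
}

#' @export
print.welch_anova <- function(x, ...) {
  cat(sprintf("Welch's ANOVA: F(%g, %.2f) = %.4f, p = %.4g (n = %d, k = %d)\n",
              x$df1, x$df2, x$statistic, x$p.value, x$n, x$k))
  invisible(x)
}

#' @export
tidy.welch_anova <- function(x, ...) {
  tibble(statistic = x$statistic, df1 = x$df1, df2 = x$df2,
         p.value = x$p.value)
}

#' @export
glance.welch_anova <- function(x, ...) {
  tibble(statistic = x$statistic, df1 = x$df1, df2 = x$df2,
         p.value = x$p.value, n = x$n, k = x$k)
}

# Upper tail of the studentized-range distribution by direct numerical
# integration (outer: distribution of the root-mean-square scale; inner:
# CDF of the range of k standard normals). Tighter than the stock ptukey,
# whose absolute error (~1e-8) is visible in identity checks.
ptukey_upper <- function(q, k, df, rel.tol = 1e-11) {
  if (is.na(q)) return(NA_real_)
  if (q <= 0) return(1)
  range_cdf <- function(w) {
    vapply(w, function(wi) {
      if (wi <= 0) return(0)
      stats::integrate(function(z) {
        k * stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - wi))^(k - 1)
      }, -Inf, Inf, rel.tol = rel.tol, abs.tol = 1e-14)$value
    }, numeric(1))
  }
  if (!is.finite(df)) return(max(0, min(1, 1 - range_cdf(q))))
  f_s <- function(s) exp((df / 2) * log(df / 2) - lgamma(df / 2) +
                           (df - 1) * log(s) - df * s^2 / 2 + log(2))
  p <- 1 - stats::integrate(function(s) f_s(s) * range_cdf(q * s), 0, Inf,
                            rel.tol = rel.tol, abs.tol = 1e-14)$value
  max(0, min(1, p))
}

#' Tukey HSD all-pairs comparison
#'
#' Pairwise differences of group means with simultaneous confidence
#' intervals and adjusted p-values from the studentized-range distribution,
#' using the Tukey-Kramer half-width for unequal group sizes. Adjusted
#' p-values are computed by direct numerical integration of the
#' studentized-range upper tail (relative tolerance 1e-11); intervals use
#' the standard quantile function and are symmetric about the observed
#' difference. Deliberately the classical (pooled-variance) HSD, used here
#' alongside Welch's ANOVA exactly as in the published analysis, rather
#' than a Games-Howell variant.
#'
#' @param data Feature tibble.
#' @param response Response column (tidyselect).
#' @param group Grouping column; defaults to `fitness`.
#' @param conf Simultaneous confidence level (default 0.95).
#' @return A `tukey_hsd` tibble: `pair, diff, lwr, upr, p_adj`.
#' @examples
#' co <- generate_cohort(cohort_spec(seed = 1))
#' tukey_hsd(co, ttf_ms)
#' @export
tukey_hsd <- function(data, response, group = fitness, conf = 0.95) {
  gv <- pull_groups(data, {{ response }}, {{ group }})
  if (nlevels(gv$g) < 2) abort("tukey_hsd needs at least two groups")
  fit <- aov(v ~ g, data = data.frame(v = gv$v, g = gv$g))
  mse <- sum(residuals(fit)^2) / fit$df.residual
  tot_var <- var(gv$v)
  if (mse <= 0 || (tot_var > 0 && mse < 1e-10 * tot_var)) {
    abort("zero mean squared error: groups are degenerate")
  }
  tk <- TukeyHSD(fit, conf.level = conf)$g
  # recompute p_adj at high precision from the observed studentized range
  n_g <- table(gv$g)
  k <- nlevels(gv$g)
  cb <- utils::combn(levels(gv$g), 2) # TukeyHSD row i compares cb[2,i]-cb[1,i]
  p_adj <- vapply(seq_len(nrow(tk)), function(i) {
    ni <- n_g[[cb[2, i]]]
    nj <- n_g[[cb[1, i]]]
    se_q <- sqrt(mse / 2 * (1 / ni + 1 / nj))
    ptukey_upper(abs(tk[i, "diff"]) / se_q, k, fit$df.residual)
  }, numeric(1))
  out <- tibble(pair = rownames(tk),
                diff = unname(tk[, "diff"]), lwr = unname(tk[, "lwr"]),
                upr = unname(tk[, "upr"]), p_adj = p_adj)
  class(out) <- c("tukey_hsd", class(out))
  out
}

#' @export
tidy.tukey_hsd <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "tukey_hsd")
  out
}

#' Sequential-SS general linear model for TTF
#'
#' Multi-factor ANOVA testing whether fitness group, speed at onset, initial
#' gaze distance and time-to-collision explain TTF variation, with the
#' three-way fitness x IGD x TTC interaction. Terms enter in that order with
#' sequential (Type I) sums of squares; term significance uses a rigor alpha
#' (0.001 by default) to compensate for TTF variance heterogeneity across
#' groups. Residual normality should be checked with [shapiro_wilk()] on
#' `residuals(attr(result, "model"))`.
#'
#' @param cohort Feature tibble with columns `ttf_ms`, `fitness`,
#'   `speed_kmh`, `igd_deg`, `ttc_s`; only complete cases enter.
#' @param alpha Per-term significance level.
#' @return An `ancova_terms` tibble `term, df, sumsq, statistic, p.value,
#'   significant`, with the fitted model in `attr(, "model")`.
#' @export
ancova_glm <- function(cohort, alpha = 0.001) {
  co <- as_tibble(cohort)
  need <- c("ttf_ms", "fitness", "speed_kmh", "igd_deg", "ttc_s")
  missing_cols <- setdiff(need, names(co))
  if (length(missing_cols)) {
    abort(paste("cohort lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  co <- co[complete.cases(co[need]), need]
  co$fitness <- factor(co$fitness)
  covars <- c("speed_kmh", "igd_deg", "ttc_s")
  dropped <- covars[purrr::map_lgl(covars, ~ var(co[[.x]]) == 0)]
  if (length(dropped)) {
    warn(paste("dropping constant covariate(s):", paste(dropped, collapse = ", ")))
    covars <- setdiff(covars, dropped)
  }
  inter <- if (all(c("igd_deg", "ttc_s") %in% covars)) "fitness:igd_deg:ttc_s"
  form <- stats::reformulate(c("fitness", covars, inter), response = "ttf_ms")
  lfit <- lm(form, data = co)
  if (anyNA(coef(lfit))) {
    abort(paste("rank-deficient model; aliased terms:",
                paste(names(coef(lfit))[is.na(coef(lfit))], collapse = ", ")))
  }
  fit <- aov(form, data = co)
  sm <- summary(fit)[[1]]
  terms <- trimws(rownames(sm))
  keep <- terms != "Residuals"
  out <- tibble(term = terms[keep],
                df = sm[keep, "Df"],
                sumsq = sm[keep, "Sum Sq"],
                statistic = sm[keep, "F value"],
                p.value = sm[keep, "Pr(>F)"]) |>
    dplyr::mutate(significant = .data$p.value < alpha)
  attr(out, "model") <- fit
  class(out) <- c("ancova_terms", class(out))
  out
}

#' @export
tidy.ancova_terms <- function(x, ...) {
  out <- x
  attr(out, "model") <- NULL
  class(out) <- setdiff(class(out), "ancova_terms")
  out
}

#' Shapiro-Wilk normality test
#'
#' W statistic and p-value (AS R94 approximation); used on the residuals of
#' [ancova_glm()] to check the normality assumption behind its F tests.
#'
#' @param x Numeric sample, 3 <= n <= 5000.
#' @return List with `W` and `p.value`.
#' @export
shapiro_wilk <- function(x) {
  st <- shapiro.test(x)
  list(W = unname(st$statistic), p.value = st$p.value)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors; incomplete pairs are dropped; n >= 3 with
#'   nonzero variance in both required.
#' @return Tibble `r, p.value, n` (two-sided p via the t transform with
#'   n - 2 df).
#' @export
pearson_correlation <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("pearson_correlation needs at least 3 complete pairs")
  if (var(x) == 0 || var(y) == 0) abort("zero variance in x or y")
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p.value = ct$p.value, n = length(x))
}
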