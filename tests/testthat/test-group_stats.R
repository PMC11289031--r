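test_that("group summaries match the direct formulas (Bessel sd)", {
  co <- tibble::tibble(fitness = rep("fit", 3), ttf_ms = c(1, 2, 3))
  s <- summarize_groups(co, ttf_ms)
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$median, 2)

  one <- tibble::tibble(fitness = c("fit", "unfit", "unfit"),
                        ttf_ms = c(5, 1, 2))
  expect_warning(s1 <- summarize_groups(one, ttf_ms), "single-observation")
  expect_true(is.na(s1$sd[s1$group == "fit"]))

  # random cohorts against a formula oracle
  set.seed(17)
  for (i in 1:10) {
    co <- tibble::tibble(
      fitness = sample(c("fit", "conditionally_fit", "unfit"), 40, TRUE),
      ttf_ms = runif(40, 100, 500))
    s <- summarize_groups(co, ttf_ms)
    for (g in s$group) {
      v <- co$ttf_ms[co$fitness == g]
      expect_equal(s$mean[s$group == g], sum(v) / length(v), tolerance = 1e-12)
      expect_equal(s$sd[s$group == g],
                   sqrt(sum((v - mean(v))^2) / (length(v) - 1)),
                   tolerance = 1e-12)
      expect_equal(s$min[s$group == g], min(v))
      expect_equal(s$max[s$group == g], max(v))
    }
  }
})

test_that("Welch's ANOVA matches hand computation and the t-squared identity", {
  id <- tibble::tibble(g = rep(c("a", "b"), each = 3), v = rep(c(1, 2, 3), 2))
  w0 <- welch_anova(id, v, g)
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p.value, 1)

  two <- tibble::tibble(g = rep(c("a", "b"), each = 3), v = c(1, 2, 3, 2, 3, 4))
  expect_equal(welch_anova(two, v, g)$statistic, 1.5)

  # F(k = 2) equals the squared Welch two-sample t on random inputs
  set.seed(18)
  for (i in 1:50) {
    n1 <- sample(3:25, 1); n2 <- sample(3:25, 1)
    d <- tibble::tibble(g = rep(c("a", "b"), c(n1, n2)),
                        v = c(rnorm(n1, 0, 1), rnorm(n2, 1, 3)))
    f <- welch_anova(d, v, g)
    tt <- t.test(v ~ g, data = d)
    expect_equal(f$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(f$df2, unname(tt$parameter), tolerance = 1e-10)
    expect_equal(f$p.value, tt$p.value, tolerance = 1e-10)
  }

  const <- tibble::tibble(g = rep(c("a", "b"), each = 3), v = c(1, 1, 1, 1, 2, 3))
  expect_error(welch_anova(const, v, g), "zero within-group variance in group 'a'")
  expect_error(welch_anova(const[const$g == "a", ], v, g), "two groups")
})

test_that("Tukey HSD has symmetric intervals and the k=2 pooled-t identity", {
  id <- tibble::tibble(g = rep(c("a", "b", "c"), each = 4),
                       v = rep(c(1, 2, 3, 4), 3))
  t0 <- tukey_hsd(id, v, g)
  expect_equal(t0$diff, rep(0, 3))
  expect_equal(t0$p_adj, rep(1, 3))

  set.seed(19)
  for (i in 1:30) {
    n <- sample(4:20, 1)
    d <- tibble::tibble(g = rep(c("a", "b"), each = n),
                        v = c(rnorm(n), rnorm(n, 0.8)))
    tk <- tukey_hsd(d, v, g)
    pt <- t.test(v ~ g, data = d, var.equal = TRUE)
    expect_lt(abs(tk$p_adj - pt$p.value), 1e-10)
    expect_equal(tk$upr - tk$diff, tk$diff - tk$lwr, tolerance = 1e-10)
  }

  # enlarging the confidence level widens every interval
  co <- generate_cohort(cohort_spec(seed = 20))
  t95 <- tukey_hsd(co, ttf_ms)
  t99 <- tukey_hsd(co, ttf_ms, conf = 0.99)
  expect_true(all(t99$upr - t99$lwr > t95$upr - t95$lwr))

  expect_error(tukey_hsd(id[id$g != "c", ] |>
                           dplyr::mutate(v = rep(c(1, 1, 1, 1, 2, 2, 2, 2))),
                         v, g), "zero mean squared error")
})

test_that("group tests are invariant under group relabeling", {
  co <- generate_cohort(cohort_spec(seed = 21))
  relab <- dplyr::mutate(co, fitness = dplyr::recode(
    fitness, fit = "zzz_fit", conditionally_fit = "aaa_cond", unfit = "mmm_unfit"))

  expect_equal(welch_anova(co, ttf_ms)$statistic,
               welch_anova(relab, ttf_ms)$statistic, tolerance = 1e-12)
  expect_equal(welch_anova(co, ttf_ms)$p.value,
               welch_anova(relab, ttf_ms)$p.value, tolerance = 1e-12)

  a <- tukey_hsd(co, ttf_ms)
  b <- tukey_hsd(relab, ttf_ms)
  expect_setequal(round(abs(a$diff), 9), round(abs(b$diff), 9))
  expect_setequal(round(a$p_adj, 9), round(b$p_adj, 9))
})

test_that("the sequential-SS model tests the listed terms in order", {
  co <- generate_cohort(cohort_spec(seed = 22))
  gl <- ancova_glm(co)
  expect_equal(gl$term, c("fitness", "speed_kmh", "igd_deg", "ttc_s",
                          "fitness:igd_deg:ttc_s"))
  expect_true(all(gl$statistic >= 0))
  expect_equal(gl$significant, gl$p.value < 0.001)

  const <- dplyr::mutate(co, speed_kmh = 0)
  expect_warning(gl2 <- ancova_glm(const), "constant covariate")
  expect_false("speed_kmh" %in% gl2$term)

  # under a null with no group effect, the 0.001 fitness test rarely fires
  hits <- 0
  for (seed in 1:100) {
    null_co <- generate_cohort(cohort_spec(
      seed = seed, ttf_mean = c(250, 250, 250), ttf_sd = c(80, 80, 80)))
    g <- ancova_glm(null_co)
    hits <- hits + g$significant[g$term == "fitness"]
  }
  expect_lte(hits / 100, 0.01)
})

test_that("Shapiro-Wilk matches an independent reference implementation", {
  x <- c(0.12, 0.25, 0.31, 0.48, 0.5, 0.61, 0.62, 0.77, 0.81, 0.9,
         1.02, 1.15, 1.33, 1.41, 1.6, 1.78, 2.05, 2.33, 2.9, 3.7)
  sw <- shapiro_wilk(x)
  expect_equal(sw$W, 0.8995705676140041, tolerance = 1e-6) # scipy.stats.shapiro
  expect_equal(sw$p.value, 0.04048158781160827, tolerance = 1e-4)
  expect_lte(sw$W, 1)
  expect_lte(shapiro_wilk(rnorm(50))$W, 1)
})

test_that("Pearson correlations behave under affine maps and report t-test p", {
  x <- c(1, 2, 4, 7, 11, 16)
  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_equal(pearson_correlation(x, -2 * x + 7)$r, -1)

  set.seed(23)
  y <- rnorm(20)
  z <- 0.3 * y + rnorm(20)
  pc <- pearson_correlation(y, z)
  r <- pc$r
  tstat <- r * sqrt(18 / (1 - r^2))
  expect_equal(pc$p.value, 2 * pt(-abs(tstat), 18), tolerance = 1e-12)
  expect_error(pearson_correlation(y, rep(1, 20)), "zero variance")
})

test_that("hazard_stats assembles a reproducible full report", {
  co <- generate_cohort(cohort_spec(seed = 24, n_outliers = 2))
  st1 <- hazard_stats(co)
  st2 <- hazard_stats(co)
  expect_identical(tidy(st1), tidy(st2)) # bit-for-bit reproducible
  expect_equal(unname(st1$n["ttf_analysis"]), 54)

  td <- tidy(st1)
  expect_true(all(c("welch_ttf", "welch_prt", "tukey_ttf", "glm", "pearson_ttf")
                  %in% td$analysis))
  gl <- glance(st1)
  expect_true(gl$welch_f_ttf > 0)

  # the outlier-robustness switch keeps flagged TTFs in
  st_in <- hazard_stats(co, include_outliers = TRUE)
  expect_equal(unname(st_in$n["ttf_analysis"]), 56)

  p <- withr::local_tempfile(fileext = ".json")
  write_stats_json(st1, p)
  parsed <- jsonlite::read_json(p)
  expect_equal(parsed$welch$ttf$statistic, st1$welch_ttf$statistic,
               tolerance = 1e-12)
})
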