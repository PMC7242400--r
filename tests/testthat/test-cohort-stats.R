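# Statistics layer: normal ranges, two-way ANOVA, trends, reproducibility

test_that("normal ranges: constant cohort, single stratum, recovery", {
  d <- simulate_cohort(n_per_cell = 5, sd = 0, baseline = 3.14, seed = 1)
  nr <- normal_range_table(d, "value", strata = "both")
  strata <- nr[nr$stratum != "pooled", ]
  expect_true(all(abs(strata$mean - 3.14) < 1e-12))
  expect_true(all(strata$sd == 0))
  # single-stratum cohort: pooled equals the stratum row
  d1 <- d[d$age_category == "<=44" & d$gender == "M", ]
  expect_warning(nr1 <- normal_range_table(d1, "value", strata = "gender"),
                 "empty stratum")
  expect_equal(nr1$mean[nr1$stratum == "M"],
               nr1$mean[nr1$stratum == "pooled"])
  # parameter recovery at n = 50 per stratum
  d2 <- simulate_cohort(n_per_cell = 50, baseline = 10, sd = 2,
                        gender_offset = 1, seed = 42)
  nr2 <- normal_range_table(d2, "value", strata = "both")
  f_rows <- grepl("/F", nr2$stratum)
  m_rows <- grepl("/M", nr2$stratum)
  se <- 2 / sqrt(50)
  expect_true(all(abs(nr2$mean[m_rows] - 10) < 3 * se))
  expect_true(all(abs(nr2$mean[f_rows] - 11) < 3 * se))
})

test_that("two-way ANOVA: identical genders give null gender effect", {
  d <- simulate_cohort(n_per_cell = 30, sd = 1, seed = 5)
  # mirror M values onto F within each cell: genders identical
  dm <- d[d$gender == "M", ]
  df <- dm; df$gender <- "F"; df$subject_id <- paste0(df$subject_id, "F")
  both <- rbind(dm, df)
  r <- two_way_anova_age_gender(both, "value")
  expect_lt(r$anova$F[r$anova$effect == "gender"], 1e-9)
  expect_equal(unname(r$ls_means["M"]), unname(r$ls_means["F"]),
               tolerance = 1e-9)
})

test_that("two-way ANOVA detects a gender offset and keeps size", {
  rej_null <- rej_alt <- int_null <- logical(120)
  for (i in seq_along(rej_null)) {
    d0 <- simulate_cohort(n_per_cell = 40, seed = 5000 + i)
    p0 <- two_way_anova_age_gender(d0, "value")$anova
    rej_null[i] <- p0$p[p0$effect == "gender"] < 0.05
    int_null[i] <- p0$p[p0$effect == "interaction"] < 0.05
    d1 <- simulate_cohort(n_per_cell = 40, gender_offset = 0.5,
                          seed = 6000 + i)
    p1 <- two_way_anova_age_gender(d1, "value")$anova
    rej_alt[i] <- p1$p[p1$effect == "gender"] < 0.05
  }
  expect_gte(mean(rej_alt), 0.9)
  expect_lt(mean(rej_null), 0.12)
  expect_lt(mean(int_null), 0.12)
})

test_that("one-way ANOVA with two groups reproduces the t-test (F = t^2)", {
  d <- simulate_cohort(n_per_cell = 20, gender_offset = 0.4, seed = 9)
  d2 <- d[d$age_category == "<=44", ]
  f <- summary(aov(value ~ gender, data = d2))[[1]][1, "F value"]
  t <- t.test(value ~ gender, data = d2, var.equal = TRUE)$statistic
  expect_equal(f, unname(t^2), tolerance = 1e-9)
})

test_that("Bonferroni-adjusted pairwise p-values never fall below raw", {
  d <- simulate_cohort(n_per_cell = 15, age_slope = 0.01, seed = 10)
  adj <- pairwise.t.test(d$value, d$age_category,
                         p.adjust.method = "bonferroni")$p.value
  raw <- pairwise.t.test(d$value, d$age_category,
                         p.adjust.method = "none")$p.value
  ok <- !is.na(adj)
  expect_true(all(adj[ok] >= raw[ok] - 1e-12))
  r <- two_way_anova_age_gender(d, "value")
  expect_true(all(r$pairwise_p >= 0 & r$pairwise_p <= 1, na.rm = TRUE))
})

test_that("statistics are invariant to subject reordering", {
  d <- simulate_cohort(n_per_cell = 25, gender_offset = 0.3,
                       age_slope = 0.005, seed = 12)
  dp <- d[sample(nrow(d)), ]
  r1 <- two_way_anova_age_gender(d, "value")
  r2 <- two_way_anova_age_gender(dp, "value")
  expect_equal(r1$anova$p, r2$anova$p, tolerance = 1e-9)
  expect_equal(r1$ls_means, r2$ls_means, tolerance = 1e-9)
  t1 <- linear_trend_and_correlation(d, "value")
  t2 <- linear_trend_and_correlation(dp, "value")
  expect_equal(t1$r, t2$r, tolerance = 1e-12)
})

test_that("linear trend: exact line, slope recovery, permutation null", {
  d <- simulate_cohort(n_per_cell = 10, sd = 0, seed = 2)
  d$value <- 2 * d$age
  tr <- suppressWarnings(linear_trend_and_correlation(d, "value"))
  expect_equal(tr$slope[tr$group == "all"], 2, tolerance = 1e-9)
  expect_equal(tr$r[tr$group == "all"], 1, tolerance = 1e-9)
  # recovery of a small age slope under the study design (n = 171)
  slopes <- vapply(1:500, function(i) {
    di <- simulate_cohort(baseline = 0.06, age_slope = 0.00011,
                          sd = 0.011, seed = 20000 + i)
    linear_trend_and_correlation(di, "value", by_gender = FALSE)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) / 0.00011 - 1), 0.05)
  # permutation null: significance rate at most ~5%
  d3 <- simulate_cohort(n_per_cell = 30, sd = 1, seed = 77)
  hits <- vapply(1:400, function(i) {
    dp <- d3
    set.seed(30000 + i)
    dp$age <- sample(dp$age)
    dp$age_category <- age_category(dp$age)
    tr <- linear_trend_and_correlation(dp, "value", by_gender = FALSE)
    tr$r_p < 0.05
  }, logical(1))
  expect_lt(mean(hits), 0.09)
  # zero variance reported as undefined
  d4 <- simulate_cohort(n_per_cell = 5, sd = 0, seed = 3)
  tr4 <- linear_trend_and_correlation(d4, "value", by_gender = FALSE)
  expect_true(is.na(tr4$r))
})

test_that("reproducibility metrics match an independent ICC(A,1) oracle", {
  # fixed dataset; reference values computed once with an independent
  # two-way mixed-effects absolute-agreement implementation
  x <- c(10.0, 12.5, 9.8, 14.2, 11.1, 13.3, 10.7, 12.0, 9.5, 15.0)
  y <- c(10.4, 12.1, 10.1, 14.8, 10.9, 13.0, 11.2, 11.6, 9.9, 14.6)
  r <- reproducibility_metrics(x, y)
  expect_equal(r$icc, 0.975901, tolerance = 1e-5)
  expect_equal(r$bias, 0.05, tolerance = 1e-12)
  expect_equal(r$loa_lower, -0.7776988, tolerance = 1e-6)
  expect_equal(r$loa_upper, 0.8776988, tolerance = 1e-6)
  expect_equal(r$cv, 2.523092, tolerance = 1e-5)
})

test_that("reproducibility edge cases behave as agreement theory says", {
  x <- c(3, 7, 5, 9, 4, 6, 8)
  r <- reproducibility_metrics(x, x)
  expect_equal(c(r$icc, r$bias, r$loa_lower, r$loa_upper, r$cv),
               c(1, 0, 0, 0, 0))
  r2 <- reproducibility_metrics(x, x + 2)
  expect_equal(r2$bias, 2)
  expect_equal(r2$loa_lower, r2$loa_upper)  # SD of differences is zero
  expect_lt(r2$icc, 1)
  expect_error(reproducibility_metrics(1:5, 1:6), "length")
  expect_error(reproducibility_metrics(1:4, 1:4), ">= 5")
})

test_that("cohort validation catches inconsistencies", {
  d <- simulate_cohort(n_per_cell = 5, seed = 1)
  d$age_category[1] <- "75-84"
  expect_error(normal_range_table(d, "value"), "inconsistent")
  d2 <- simulate_cohort(n_per_cell = 5, seed = 1)
  d2$subject_id[2] <- d2$subject_id[1]
  expect_error(normal_range_table(d2, "value"), "duplicated")
})
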