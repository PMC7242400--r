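# Cohort statistics layer: stratified normal ranges, one-way ANOVA with
# Bonferroni pairwise comparisons, two-way age-by-gender ANOVA (type III)
# with least-squares means, linear age trends, Pearson correlation,
# two-sample t tests, and reproducibility metrics (ICC, Bland-Altman, CV).

age_levels <- c("<=44", "45-64", "65-74", "75-84")

check_cohort <- function(cohort) {
  cohort <- as.data.frame(cohort)
  if (anyDuplicated(cohort$subject_id))
    stop_lv("cohort_stats", "duplicated subject_id")
  if (!is.null(cohort$age) && !is.null(cohort$age_category)) {
    implied <- as.character(age_category(cohort$age))
    if (!all(implied == as.character(cohort$age_category)))
      stop_lv("cohort_stats", "age_category inconsistent with age")
  }
  cohort$age_category <- factor(as.character(cohort$age_category),
                                levels = age_levels)
  cohort$gender <- factor(as.character(cohort$gender), levels = c("M", "F"))
  cohort
}

#' Stratified normal-range (mean and SD) table
#'
#' @param cohort one row per subject with `age_category`, `gender` and the
#'   parameter columns.
#' @param parameters character vector of parameter column names.
#' @param strata `"age_category"`, `"gender"` or `"both"`.
#' @return tibble with one row per stratum per parameter (`mean`, `sd`,
#'   `n`) plus a pooled row per parameter (`stratum = "pooled"`).
#' @export
normal_range_table <- function(cohort, parameters,
                               strata = c("both", "age_category",
                                          "gender")) {
  strata <- match.arg(strata)
  cohort <- check_cohort(cohort)
  group_cols <- switch(strata,
                       age_category = "age_category",
                       gender = "gender",
                       both = c("age_category", "gender"))
  out <- list()
  for (p in parameters) {
    y <- cohort[[p]]
    if (is.null(y)) stop_lv("cohort_stats", "unknown parameter ", p)
    key <- interaction(cohort[group_cols], drop = FALSE, sep = "/")
    for (lev in levels(key)) {
      sel <- key == lev & !is.na(y)
      n <- sum(sel)
      if (n == 0L) {
        warning("empty stratum ", lev, " for ", p, call. = FALSE)
        next
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        parameter = p, stratum = lev, n = n, mean = mean(y[sel]),
        sd = if (n > 1L) sd(y[sel]) else 0)
    }
    sel <- !is.na(y)
    out[[length(out) + 1L]] <- tibble::tibble(
      parameter = p, stratum = "pooled", n = sum(sel),
      mean = mean(y[sel]), sd = if (sum(sel) > 1L) sd(y[sel]) else 0)
  }
  do.call(rbind, out)
}

#' Two-way age-by-gender analysis of one parameter
#'
#' Fits parameter ~ age_category * gender with sum-to-zero contrasts and
#' reports type-III F tests for the age and gender main effects and their
#' interaction (the construct matching least-squares means under
#' unbalanced cells), LS means per gender (unweighted over age cells), a
#' one-way age-category ANOVA with Bonferroni-adjusted pairwise
#' comparisons, and the linear trend of the parameter on continuous age.
#'
#' @param cohort subject table with `age`, `age_category`, `gender` and the
#'   parameter.
#' @param parameter column name.
#' @return list of class `lv_group_comparison`: `anova` (tibble of effects
#'   with F and p), `ls_means` (per gender), `oneway` (F, p), `pairwise`
#'   (Bonferroni-adjusted p matrix), `trend` (slope, p), `group_stats`.
#' @export
two_way_anova_age_gender <- function(cohort, parameter) {
  cohort <- check_cohort(cohort)
  y <- cohort[[parameter]]
  if (is.null(y)) stop_lv("cohort_stats", "unknown parameter ", parameter)
  d <- data.frame(y = y, age_category = droplevels(cohort$age_category),
                  gender = cohort$gender, age = cohort$age)
  cells <- table(d$age_category, d$gender)
  with_interaction <- all(cells >= 2L)
  if (!with_interaction)
    warning("empty/singleton age x gender cell: interaction dropped",
            call. = FALSE)
  form <- if (with_interaction) y ~ age_category * gender
          else y ~ age_category + gender
  fit <- lm(form, data = d,
            contrasts = list(age_category = "contr.sum",
                             gender = "contr.sum"))
  a3 <- car::Anova(fit, type = 3)
  pick <- function(term) {
    i <- match(term, rownames(a3))
    if (is.na(i)) c(F = NA_real_, p = NA_real_)
    else c(F = a3[i, "F value"], p = a3[i, "Pr(>F)"])
  }
  eff <- rbind(age = pick("age_category"), gender = pick("gender"),
               interaction = pick("age_category:gender"))
  anova_tbl <- tibble::tibble(effect = rownames(eff),
                              F = eff[, "F"], p = eff[, "p"])
  emm <- suppressMessages(emmeans::emmeans(fit, "gender"))
  emm_df <- as.data.frame(emm)
  ls_means <- setNames(emm_df$emmean, as.character(emm_df$gender))
  ow <- aov(y ~ age_category, data = d)
  ow_s <- summary(ow)[[1]]
  pw <- pairwise.t.test(d$y, d$age_category, p.adjust.method = "bonferroni")
  tr_fit <- lm(y ~ age, data = d)
  tr <- summary(tr_fit)$coefficients
  structure(list(
    parameter = parameter,
    anova = anova_tbl,
    ls_means = ls_means,
    ls_means_p = summary(emmeans::contrast(emm, "pairwise"))$p.value[1],
    oneway = c(F = ow_s[1, "F value"], p = ow_s[1, "Pr(>F)"]),
    pairwise_p = pw$p.value,
    trend = c(slope = tr["age", "Estimate"], p = tr["age", "Pr(>|t|)"]),
    group_stats = normal_range_table(d, "y", strata = "both")),
    class = "lv_group_comparison")
}

#' @export
print.lv_group_comparison <- function(x, ...) {
  cat("<lv_group_comparison>", x$parameter, "\n")
  print(x$anova)
  cat("LS means (gender):", paste(names(x$ls_means),
                                  signif(x$ls_means, 4), collapse = ", "),
      "\nlinear trend slope", signif(x$trend["slope"], 4),
      "(p =", signif(x$trend["p"], 3), ")\n")
  invisible(x)
}

#' Linear age trend, Pearson correlation and gender comparison
#'
#' @param cohort subject table with `age`, `gender` and the parameter.
#' @param parameter column name.
#' @param by_gender also report per-gender slope and correlation.
#' @return tibble with rows `all` (and `M`, `F`): n, OLS slope on age with
#'   its p, Pearson r with its p; attribute `gender_t_test` holds the
#'   two-sample t test comparing genders.
#' @export
linear_trend_and_correlation <- function(cohort, parameter,
                                         by_gender = TRUE) {
  cohort <- check_cohort(cohort)
  y_all <- cohort[[parameter]]
  if (is.null(y_all)) stop_lv("cohort_stats", "unknown parameter ",
                              parameter)
  one <- function(sel, label) {
    a <- cohort$age[sel]; y <- y_all[sel]
    ok <- !is.na(a) & !is.na(y)
    a <- a[ok]; y <- y[ok]
    if (length(y) < 3L)
      stop_lv("cohort_stats", "need >= 3 subjects in group ", label)
    if (var(y) == 0 || var(a) == 0) {
      return(tibble::tibble(group = label, n = length(y),
                            slope = NA_real_, slope_p = NA_real_,
                            r = NA_real_, r_p = NA_real_))
    }
    fit <- summary(lm(y ~ a))$coefficients
    ct <- cor.test(a, y)
    tibble::tibble(group = label, n = length(y),
                   slope = fit["a", "Estimate"],
                   slope_p = fit["a", "Pr(>|t|)"],
                   r = unname(ct$estimate), r_p = ct$p.value)
  }
  out <- one(rep(TRUE, nrow(cohort)), "all")
  if (by_gender) {
    out <- rbind(out, one(cohort$gender == "M", "M"),
                 one(cohort$gender == "F", "F"))
    tt <- t.test(y_all[cohort$gender == "M"], y_all[cohort$gender == "F"])
    attr(out, "gender_t_test") <- c(t = unname(tt$statistic),
                                    p = tt$p.value)
  }
  out
}

# ---- reproducibility ---------------------------------------------------

#' Agreement metrics for paired repeated measurements
#'
#' ICC is the two-way mixed-effects, absolute-agreement, single-measurement
#' form ICC(A,1), computed from the two-way ANOVA mean squares
#' (subjects x raters). Bland-Altman: bias = mean difference, limits of
#' agreement = bias +/- 1.96 SD of differences. CV is the within-subject
#' SD method: 100 * (SD(d)/sqrt(2)) / grand mean.
#'
#' @param measure1,measure2 paired per-subject values, equal length >= 5.
#' @return tibble with `icc`, `bias`, `loa_lower`, `loa_upper`, `cv`, `n`.
#' @export
reproducibility_metrics <- function(measure1, measure2) {
  if (length(measure1) != length(measure2))
    stop_lv("cohort_stats", "paired measurements differ in length")
  ok <- !is.na(measure1) & !is.na(measure2)
  x <- measure1[ok]; y <- measure2[ok]
  n <- length(x)
  if (n < 5L) stop_lv("cohort_stats", "need >= 5 pairs")
  k <- 2
  grand <- mean(c(x, y))
  row_means <- (x + y) / 2
  col_means <- c(mean(x), mean(y))
  msr <- k * var(row_means)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((x - row_means - col_means[1] + grand)^2) +
         sum((y - row_means - col_means[2] + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  icc <- if (denom <= 0) 1 else (msr - mse) / denom
  d <- y - x
  bias <- mean(d)
  sd_d <- sd(d)
  cv <- 100 * (sd_d / sqrt(2)) / grand
  tibble::tibble(n = n, icc = icc, bias = bias,
                 loa_lower = bias - 1.96 * sd_d,
                 loa_upper = bias + 1.96 * sd_d, cv = cv)
}
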