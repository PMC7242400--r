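# Seeded synthetic-cohort generator for exercising the statistics layer.
# Draws a parameter from stratified Gaussians with configurable continuous
# age slope, gender offset and age-by-gender interaction. The default
# design matches the healthy-cohort cell sizes (males/females per age
# category 30/36, 16/22, 30/23, 7/7; 171 subjects).

default_cohort_design <- function() {
  data.frame(age_category = rep(age_levels, each = 2),
             gender = rep(c("M", "F"), 4),
             n = c(30, 36, 16, 22, 30, 23, 7, 7))
}

#' Simulate a single-parameter cohort table
#'
#' Ages are drawn uniformly within each category's range (20-44, 45-64,
#' 65-74, 75-84 years). The parameter is
#' `baseline + age_slope * age + gender_offset * I(F) +
#'  interaction * cell_index * I(F) + N(0, sd)`
#' with `cell_index` the 0-based age-category index, so `interaction = 0`
#' gives parallel gender profiles.
#'
#' @param n_per_cell subjects per age-by-gender cell (balanced design);
#'   ignored when `design` is given.
#' @param design data frame with `age_category`, `gender`, `n` (defaults to
#'   the healthy-cohort cell sizes when both arguments are NULL).
#' @param baseline,sd Gaussian location and scale.
#' @param age_slope units per year of age.
#' @param gender_offset additive offset for females.
#' @param interaction per-category additional female offset.
#' @param parameter name of the generated column.
#' @param seed RNG seed.
#' @return tibble: `subject_id`, `age`, `age_category`, `gender`, parameter.
#' @export
simulate_cohort <- function(n_per_cell = NULL, design = NULL, baseline = 0,
                            sd = 1, age_slope = 0, gender_offset = 0,
                            interaction = 0, parameter = "value",
                            seed = 1L) {
  if (is.null(design)) {
    design <- default_cohort_design()
    if (!is.null(n_per_cell)) design$n <- n_per_cell
  }
  ranges <- list("<=44" = c(20, 44), "45-64" = c(45, 64),
                 "65-74" = c(65, 74), "75-84" = c(75, 84))
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(design)), function(i) {
      cat_i <- as.character(design$age_category[i])
      n <- design$n[i]
      if (n == 0L) return(NULL)
      rng <- ranges[[cat_i]]
      age <- runif(n, rng[1], rng[2])
      fem <- design$gender[i] == "F"
      idx <- match(cat_i, age_levels) - 1L
      val <- baseline + age_slope * age +
        (gender_offset + interaction * idx) * fem + rnorm(n, 0, sd)
      data.frame(age = age, age_category = cat_i,
                 gender = as.character(design$gender[i]), value = val)
    })
    out <- do.call(rbind, rows)
    out$subject_id <- sprintf("S%03d", seq_len(nrow(out)))
    names(out)[names(out) == "value"] <- parameter
    tibble::as_tibble(out[, c("subject_id", "age", "age_category",
                              "gender", parameter)])
  })
}
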