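# Phenotype refinement: questionnaire harmonization into drinks/day and the
# caffeine-weighted daily total.

test_that("closed-format responses recode to the published weekly constants, monotonically", {
  expect_identical(recode_closed_response("never or rarely"), 0)
  expect_identical(recode_closed_response("once in 2 weeks"), 0.5)
  expect_identical(recode_closed_response("once a day or more"), 7)
  recoded <- recode_closed_response(closed_categories())
  expect_identical(recoded, c(0, 0.5, 2, 5.5, 7))
  expect_true(all(diff(recoded) > 0))  # higher-frequency label -> larger value
  expect_true(is.na(recode_closed_response(NA_character_)))
  expect_error(recode_closed_response("sometimes"), "sometimes")
})

test_that("weekday/weekend combination is the day-weighted mean", {
  expect_equal(combine_weekday_weekend(3, 3), 3)
  expect_equal(combine_weekday_weekend(7, 0), 5)
  expect_equal(combine_weekday_weekend(0, 0), 0)
  expect_true(is.na(combine_weekday_weekend(NA, 2)))
  expect_true(is.na(combine_weekday_weekend(1, NA)))
  expect_error(combine_weekday_weekend(-1, 2), "non-negative")
})

test_that("weekly values convert to daily and pass nulls through", {
  expect_equal(weekly_to_daily(7), 1)
  expect_equal(weekly_to_daily(0.5), 0.5 / 7)
  expect_equal(weekly_to_daily(0), 0)
  expect_true(is.na(weekly_to_daily(NA)))
  expect_error(weekly_to_daily(-3), "non-negative")
})

test_that("outlier masking is strict and never increases a value", {
  expect_equal(mask_outliers(10, "coffee"), 10)   # boundary retained
  expect_true(is.na(mask_outliers(16, "tea")))
  expect_equal(mask_outliers(0, "cola"), 0)
  expect_error(mask_outliers(1, "mate"), "mate")
  set.seed(7)
  v <- stats::runif(500, 0, 30)
  bev <- sample(beverages(), 500, replace = TRUE)
  masked <- mask_outliers(v, bev)
  thr <- scoring_constants()$outlier_max_per_day[bev]
  expect_true(all(is.na(masked) | masked <= thr))
  expect_true(all(is.na(masked) | masked == v))
})

test_that("total caffeine is the content-weighted sum with complete-case missingness", {
  expect_equal(total_caffeine(0, 0, 0), 0)
  expect_equal(total_caffeine(1, 1, 1), 149.5)
  expect_true(is.na(total_caffeine(2, 3, NA)))
  expect_equal(total_caffeine(2, 3, NA, impute_zero_cola = TRUE), 270)
  # linearity: f(a + b) = f(a) + f(b)
  set.seed(11)
  for (i in 1:20) {
    a <- stats::runif(3, 0, 5)
    b <- stats::runif(3, 0, 5)
    expect_equal(total_caffeine(a[1] + b[1], a[2] + b[2], a[3] + b[3]),
                 total_caffeine(a[1], a[2], a[3]) +
                   total_caffeine(b[1], b[2], b[3]))
  }
})

make_obs <- function(subject_id, time_point, beverage, caffeinated, format,
                     weekday = NA, weekend = NA, weekly = NA, closed = NA) {
  tibble::tibble(subject_id = subject_id, time_point = time_point,
                 beverage = beverage, caffeinated = caffeinated,
                 format = format, weekday_count = weekday,
                 weekend_count = weekend, weekly_value = weekly,
                 closed_category = as.character(closed))
}

test_that("phenotype table reproduces hand-computed totals through the full chain", {
  obs <- dplyr::bind_rows(
    make_obs("A", "47mo", "coffee", TRUE, "weekday_weekend", weekday = 2, weekend = 2),
    make_obs("A", "47mo", "tea", TRUE, "weekday_weekend", weekday = 3, weekend = 3),
    make_obs("A", "47mo", "cola", TRUE, "weekly_numeric", weekly = 7)
  )
  ph <- build_phenotype_table(obs)
  expect_equal(nrow(ph), 1L)
  expect_equal(ph$coffee_per_day, 2)
  expect_equal(ph$tea_per_day, 3)
  expect_equal(ph$cola_per_day, 1)
  expect_equal(ph$total_caffeine_mg, 75 * 2 + 40 * 3 + 34.5 * 1)  # 304.5

  # closed-format cola goes through the weekly recode first
  obs2 <- dplyr::bind_rows(
    make_obs("B", "85mo", "coffee", TRUE, "weekday_weekend", weekday = 1, weekend = 1),
    make_obs("B", "85mo", "tea", TRUE, "weekday_weekend", weekday = 0, weekend = 0),
    make_obs("B", "85mo", "cola", TRUE, "weekly_closed", closed = "once in 2 weeks")
  )
  ph2 <- build_phenotype_table(obs2)
  expect_equal(ph2$cola_per_day, 0.5 / 7)
  expect_equal(ph2$total_caffeine_mg, 75 + 34.5 * 0.5 / 7)
})

test_that("outliers and missing components propagate to a missing total", {
  obs <- dplyr::bind_rows(
    make_obs("A", "8wk", "coffee", TRUE, "weekday_weekend", weekday = 12, weekend = 12),
    make_obs("A", "8wk", "tea", TRUE, "weekday_weekend", weekday = 1, weekend = 1),
    make_obs("A", "8wk", "cola", TRUE, "weekly_numeric", weekly = 0)
  )
  ph <- build_phenotype_table(obs)
  expect_true(is.na(ph$coffee_per_day))  # 12/day exceeds the coffee threshold
  expect_true(is.na(ph$total_caffeine_mg))
  expect_equal(ph$tea_per_day, 1)
})

test_that("decaffeinated streams stay separate and never enter the total", {
  obs <- dplyr::bind_rows(
    make_obs("A", "18wk", "coffee", TRUE, "weekday_weekend", weekday = 1, weekend = 1),
    make_obs("A", "18wk", "tea", TRUE, "weekday_weekend", weekday = 1, weekend = 1),
    make_obs("A", "18wk", "cola", TRUE, "weekly_numeric", weekly = 0),
    make_obs("A", "18wk", "coffee", FALSE, "weekday_weekend", weekday = 9, weekend = 9)
  )
  ph <- build_phenotype_table(obs)
  expect_equal(ph$decaf_coffee_per_day, 9)
  expect_equal(ph$total_caffeine_mg, 75 + 40)
})

test_that("table construction validates its input", {
  obs <- make_obs("A", "8wk", "coffee", TRUE, "weekday_weekend", weekday = 1, weekend = 1)
  expect_error(build_phenotype_table(dplyr::bind_rows(obs, obs)), "duplicate")
  expect_equal(nrow(build_phenotype_table(obs[0, ])), 0L)
  bad <- obs
  bad$format <- "monthly"
  expect_error(build_phenotype_table(bad), "monthly")
})

test_that("output has one row per distinct subject x time pair", {
  set.seed(3)
  grid <- expand.grid(subject_id = sprintf("S%02d", 1:7),
                      time_point = c("8wk", "47mo", "145mo"),
                      beverage = "tea", stringsAsFactors = FALSE)
  obs <- make_obs(grid$subject_id, grid$time_point, grid$beverage, TRUE,
                  "weekday_weekend",
                  weekday = stats::rpois(nrow(grid), 2),
                  weekend = stats::rpois(nrow(grid), 2))
  ph <- build_phenotype_table(obs)
  expect_equal(nrow(ph), 21L)
  expect_false(any(duplicated(ph[c("subject_id", "time_point")])))
})

test_that("beverage TSV round-trips with empty-string nulls", {
  obs <- dplyr::bind_rows(
    make_obs("A", "8wk", "coffee", TRUE, "weekday_weekend", weekday = 1.5, weekend = NA),
    make_obs("A", "145mo", "cola", TRUE, "weekly_closed", closed = "once a day or more")
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_beverage_tsv(obs, path)
  txt <- readLines(path)
  expect_false(any(grepl("NA", txt)))
  back <- read_beverage_tsv(path)
  expect_equal(back$weekday_count, obs$weekday_count)
  expect_equal(back$closed_category, obs$closed_category)
})
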