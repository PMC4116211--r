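# Phenotype refinement: harmonize raw beverage questionnaire records into
# drinks/day per beverage and a caffeine-content-weighted total (mg/day).
#
# Raw records arrive in one of three formats:
#   weekday_weekend - drinks per weekday and per weekend day (coffee, tea)
#   weekly_numeric  - open-format drinks per week (cola, early waves)
#   weekly_closed   - closed-format frequency category (cola, later waves)

#' Recode a closed-format frequency response to drinks per week
#'
#' The five ordered response categories ("never or rarely" ... "once a day or
#' more") map to 0, 0.5, 2, 5.5 and 7 drinks per week.
#'
#' @param category Character vector of closed-format labels (NA allowed).
#' @return Numeric vector of drinks per week; NA maps to NA.
#' @export
recode_closed_response <- function(category) {
  map <- scoring_constants()$closed_recode
  out <- unname(map[category])
  bad <- !is.na(category) & is.na(out)
  if (any(bad)) {
    stop("unknown closed-format label(s): ",
         paste(sQuote(unique(category[bad])), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Combine weekday and weekend daily counts into drinks per day
#'
#' Day-weighted mean: (5 * weekday + 2 * weekend) / 7. The result is NA when
#' either input is NA.
#'
#' @param weekday_count,weekend_count Drinks per weekday / per weekend day.
#' @return Drinks per day.
#' @export
combine_weekday_weekend <- function(weekday_count, weekend_count) {
  check_nonnegative(weekday_count, "weekday_count")
  check_nonnegative(weekend_count, "weekend_count")
  (5 * weekday_count + 2 * weekend_count) / 7
}

#' Convert drinks per week to drinks per day
#'
#' @param weekly_value Drinks per week (NA allowed).
#' @return Drinks per day.
#' @export
weekly_to_daily <- function(weekly_value) {
  check_nonnegative(weekly_value, "weekly_value")
  weekly_value / 7
}

#' Mask outlying daily consumption values
#'
#' Values strictly above the beverage-specific threshold (coffee 10, tea 15,
#' cola 21 drinks/day) are coded missing; the threshold itself is retained.
#'
#' @param value Drinks per day.
#' @param beverage Beverage label(s), recycled against `value`.
#' @return `value` with outliers set to NA.
#' @export
mask_outliers <- function(value, beverage) {
  check_nonnegative(value, "value")
  thr <- scoring_constants()$outlier_max_per_day
  bad_bev <- !beverage %in% names(thr)
  if (any(bad_bev)) {
    stop("unknown beverage(s): ",
         paste(sQuote(unique(beverage[bad_bev])), collapse = ", "),
         call. = FALSE)
  }
  limit <- unname(thr[beverage])
  ifelse(!is.na(value) & value > limit, NA_real_, value)
}

#' Total daily caffeine (mg) from per-beverage drinks per day
#'
#' Weighted sum at approximate caffeine content per drink: 75 mg (coffee),
#' 40 mg (tea), 34.5 mg (cola). Complete-case: the total is NA when any
#' component is NA, unless `impute_zero_cola = TRUE`, in which case missing
#' cola is treated as zero (sensitivity option).
#'
#' @param coffee_per_day,tea_per_day,cola_per_day Drinks per day.
#' @param impute_zero_cola Treat missing cola as 0 drinks/day.
#' @return Caffeine in mg/day.
#' @export
total_caffeine <- function(coffee_per_day, tea_per_day, cola_per_day,
                           impute_zero_cola = FALSE) {
  check_nonnegative(coffee_per_day, "coffee_per_day")
  check_nonnegative(tea_per_day, "tea_per_day")
  check_nonnegative(cola_per_day, "cola_per_day")
  w <- scoring_constants()$caffeine_mg_per_drink
  if (impute_zero_cola) {
    cola_per_day <- ifelse(is.na(cola_per_day), 0, cola_per_day)
  }
  w[["coffee"]] * coffee_per_day + w[["tea"]] * tea_per_day +
    w[["cola"]] * cola_per_day
}

#' Build the per-subject, per-time-point caffeine phenotype table
#'
#' Converts long-format beverage observations to daily values (weekday/weekend
#' combination for coffee and tea; weekly-to-daily conversion for cola, with
#' closed-format categories recoded to drinks/week first), masks outlying
#' daily values, and assembles one wide row per subject x time point with the
#' caffeinated components, their mg/day total, and decaffeinated components.
#' Decaffeinated values never enter the caffeine total.
#'
#' @param observations Tibble/data frame with columns `subject_id`,
#'   `time_point`, `beverage`, `caffeinated` (logical), `format`,
#'   `weekday_count`, `weekend_count`, `weekly_value`, `closed_category`.
#' @param impute_zero_cola Passed to [total_caffeine()].
#' @return A tibble with one row per subject x time point: `coffee_per_day`,
#'   `tea_per_day`, `cola_per_day`, `total_caffeine_mg`, `decaf_coffee_per_day`,
#'   `decaf_tea_per_day`, `decaf_cola_per_day`.
#' @export
build_phenotype_table <- function(observations, impute_zero_cola = FALSE) {
  obs <- tibble::as_tibble(observations)
  required <- c("subject_id", "time_point", "beverage", "caffeinated",
                "format", "weekday_count", "weekend_count", "weekly_value",
                "closed_category")
  missing_cols <- setdiff(required, names(obs))
  if (length(missing_cols)) {
    stop("observations lack column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  empty_out <- tibble::tibble(
    subject_id = character(), time_point = character(),
    coffee_per_day = double(), tea_per_day = double(),
    cola_per_day = double(), total_caffeine_mg = double(),
    decaf_coffee_per_day = double(), decaf_tea_per_day = double(),
    decaf_cola_per_day = double()
  )
  if (nrow(obs) == 0L) return(empty_out)

  dup <- duplicated(obs[c("subject_id", "time_point", "beverage", "caffeinated")])
  if (any(dup)) {
    keys <- obs[dup, c("subject_id", "time_point", "beverage", "caffeinated")]
    stop("duplicate observation keys: ",
         paste(utils::head(apply(keys, 1, paste, collapse = "/"), 5),
               collapse = "; "),
         call. = FALSE)
  }
  bad_fmt <- !obs$format %in% c("weekday_weekend", "weekly_numeric", "weekly_closed")
  if (any(bad_fmt)) {
    stop("unknown format(s): ",
         paste(sQuote(unique(obs$format[bad_fmt])), collapse = ", "),
         call. = FALSE)
  }

  daily <- rep(NA_real_, nrow(obs))
  is_ww <- obs$format == "weekday_weekend"
  is_wn <- obs$format == "weekly_numeric"
  is_wc <- obs$format == "weekly_closed"
  daily[is_ww] <- combine_weekday_weekend(obs$weekday_count[is_ww],
                                          obs$weekend_count[is_ww])
  daily[is_wn] <- weekly_to_daily(obs$weekly_value[is_wn])
  daily[is_wc] <- weekly_to_daily(recode_closed_response(obs$closed_category[is_wc]))
  obs$per_day <- mask_outliers(daily, obs$beverage)

  obs$stream <- ifelse(obs$caffeinated, obs$beverage,
                       paste0("decaf_", obs$beverage))
  wide <- tidyr::pivot_wider(
    obs[c("subject_id", "time_point", "stream", "per_day")],
    names_from = "stream", values_from = "per_day"
  )
  for (col in c("coffee", "tea", "cola",
                "decaf_coffee", "decaf_tea", "decaf_cola")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  out <- tibble::tibble(
    subject_id = as.character(wide$subject_id),
    time_point = as.character(wide$time_point),
    coffee_per_day = wide$coffee,
    tea_per_day = wide$tea,
    cola_per_day = wide$cola,
    total_caffeine_mg = total_caffeine(wide$coffee, wide$tea, wide$cola,
                                       impute_zero_cola = impute_zero_cola),
    decaf_coffee_per_day = wide$decaf_coffee,
    decaf_tea_per_day = wide$decaf_tea,
    decaf_cola_per_day = wide$decaf_cola
  )
  dplyr::arrange(out, factor(.data$time_point, levels = time_points()),
                 .data$subject_id)
}

#' Read long-format beverage observations from TSV
#'
#' Expects the nine-column long dialect written by [write_beverage_tsv()] and
#' the synthetic generator; empty strings are nulls.
#'
#' @param path TSV file path.
#' @return Tibble of beverage observations.
#' @export
read_beverage_tsv <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      time_point = readr::col_character(),
      beverage = readr::col_character(),
      caffeinated = readr::col_logical(),
      format = readr::col_character(),
      weekday_count = readr::col_double(),
      weekend_count = readr::col_double(),
      weekly_value = readr::col_double(),
      closed_category = readr::col_character()
    ),
    na = c("", "NA"), progress = FALSE
  )
}

#' Write beverage observations / phenotype tables as TSV
#'
#' Nulls are written as empty strings.
#'
#' @param x Tibble to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beverage_tsv <- function(x, path) {
  readr::write_tsv(x, path, na = "")
  invisible(path)
}

check_nonnegative <- function(x, what) {
  if (!is.numeric(x) && !all(is.na(x))) {
    stop(what, " must be numeric", call. = FALSE)
  }
  if (any(!is.na(x) & x < 0)) {
    stop(what, " must be non-negative", call. = FALSE)
  }
  invisible(x)
}
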