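# Package-level constants and fixtures: scoring constants, study time points,
# variant metadata and the published summary-table parameterizations used by
# the synthetic cohort generator.

.caffscore_env <- new.env(parent = emptyenv())

#' Questionnaire time points
#'
#' The eight collection waves of the longitudinal questionnaire: 8, 18 and 32
#' weeks gestation, then 2, 47, 85, 97 and 145 months after delivery.
#'
#' @return Character vector of time-point labels in chronological order.
#' @export
time_points <- function() {
  c("8wk", "18wk", "32wk", "2mo", "47mo", "85mo", "97mo", "145mo")
}

#' Beverage labels
#'
#' @return Character vector `c("coffee", "tea", "cola")`.
#' @export
beverages <- function() c("coffee", "tea", "cola")

#' Phenotype scoring constants
#'
#' Loads the packaged scoring-constant fixture: caffeine content per drink
#' (mg; coffee 75, tea 40, cola 34.5), daily-consumption outlier thresholds
#' (coffee 10, tea 15, cola 21 drinks; values strictly above are masked) and
#' the closed-format frequency recode (drinks per week: 0, 0.5, 2, 5.5, 7).
#'
#' @return A list with elements `caffeine_mg_per_drink`, `outlier_max_per_day`
#'   and `closed_recode`, each a named numeric vector.
#' @export
scoring_constants <- function() {
  if (is.null(.caffscore_env$scoring_constants)) {
    path <- system.file("extdata", "scoring_constants.yaml",
                        package = "caffscore", mustWork = TRUE)
    raw <- yaml::read_yaml(path)
    .caffscore_env$scoring_constants <- lapply(raw, function(x) {
      v <- unlist(x)
      storage.mode(v) <- "double"
      v
    })
  }
  .caffscore_env$scoring_constants
}

#' Closed-format frequency categories
#'
#' @return Character vector of the five closed-format response labels, ordered
#'   from least to most frequent consumption.
#' @export
closed_categories <- function() {
  names(scoring_constants()$closed_recode)
}

#' Variant metadata for the two caffeine-consumption SNPs
#'
#' rs2472297 lies between *CYP1A1* and *CYP1A2*; rs6968865 is upstream of
#' *AHR*. The effect (risk) allele is T at both loci; at rs6968865 T is the
#' major allele, so its T-allele frequency (0.61) exceeds its MAF (0.39).
#' Weights are published per-allele effect sizes (cups/day).
#'
#' @return A tibble with columns `variant_id`, `effect_allele`,
#'   `effect_allele_freq`, `weight` and `imputation_quality`.
#' @export
snp_info <- function() {
  tibble::tibble(
    variant_id         = c("rs2472297", "rs6968865"),
    effect_allele      = c("T", "T"),
    effect_allele_freq = c(0.27, 0.61),
    weight             = c(0.31, 0.26),
    imputation_quality = c(NA_real_, 0.96)
  )
}

#' Genotype quality-control thresholds
#'
#' Standard GWAS-QC cutoffs: variants are kept when MAF >= 1%, call rate
#' >= 95% and the exact Hardy-Weinberg test p-value exceeds 5e-6; subjects
#' with more than 5% missing genotypes are excluded beforehand.
#'
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function() {
  list(
    maf_min = 0.01,
    call_rate_min = 0.95,
    hwe_p_min = 5e-6,
    individual_missingness_max = 0.05
  )
}

#' Published summary-table parameterizations
#'
#' Per phenotype (total caffeine mg/day, coffee and tea drinks/day, cola
#' drinks/week) and time point: sample size, marginal mean and SD, range,
#' and the per-T-allele regression coefficients (with SE and p) for each SNP
#' and for the unweighted combined score. These rows parameterize the
#' synthetic cohort generator.
#'
#' @return A tibble, one row per phenotype x time point.
#' @export
table_scenarios <- function() {
  if (is.null(.caffscore_env$table_scenarios)) {
    path <- system.file("extdata", "table_scenarios.tsv",
                        package = "caffscore", mustWork = TRUE)
    .caffscore_env$table_scenarios <- readr::read_tsv(
      path,
      col_types = readr::cols(
        phenotype = readr::col_character(),
        time_point = readr::col_character(),
        units = readr::col_character(),
        .default = readr::col_double()
      ),
      progress = FALSE
    )
  }
  .caffscore_env$table_scenarios
}

#' Look up one scenario row
#'
#' Returns the generative parameters (n, mean, sd, per-SNP and combined-score
#' betas) for one phenotype at one time point.
#'
#' @param time_point One of [time_points()].
#' @param phenotype One of `"total"`, `"coffee"`, `"tea"`, `"cola"`.
#' @return A one-row tibble from [table_scenarios()].
#' @export
scenario_from_table <- function(time_point, phenotype) {
  stopifnot(length(time_point) == 1, length(phenotype) == 1)
  tab <- table_scenarios()
  row <- tab[tab$time_point == time_point & tab$phenotype == phenotype, ]
  if (nrow(row) != 1L) {
    stop("no scenario for phenotype '", phenotype, "' at time point '",
         time_point, "'", call. = FALSE)
  }
  row
}

# Derive a reproducible sub-seed from a master seed and a stream label, so
# that adding a new stream never perturbs existing ones. Kept below 2^31.
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, length(label) == 1)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483587)
}
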