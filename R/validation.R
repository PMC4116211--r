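# Instrument validation: confounder balance of the genetic score,
# phenotype-confounder associations, and decaffeinated-drink negative
# controls. Confounder regressions are marginal (one confounder at a time),
# with linearity imposed on the ordinal codings (housing tenure 1-3,
# educational level 1-5 treated as numeric).

confounder_cols <- function() {
  c("year_of_birth", "housing_tenure", "crowding_index",
    "education_level", "alcohol", "tobacco")
}

#' Confounder balance of genotypes and the combined score
#'
#' Regresses each confounder on each genetic predictor (both SNPs' T-allele
#' counts and the combined score). A valid genetic instrument should show no
#' association: genotypes are randomly assorted at conception and ought to be
#' independent of lifestyle and socioeconomic factors.
#'
#' @param genotypes Tibble with `subject_id` and rsid call columns.
#' @param confounders Tibble with `subject_id` and the confounder columns
#'   (`year_of_birth`, `housing_tenure`, `crowding_index`, `education_level`,
#'   `alcohol`, `tobacco`); any subset is accepted.
#' @return Tibble of regression rows (one per confounder x predictor) with a
#'   `note` column flagging degenerate cells.
#' @export
confounder_balance <- function(genotypes, confounders) {
  merged <- dplyr::inner_join(genotypes, confounders, by = "subject_id")
  if (nrow(merged) == 0L) {
    stop("no subjects shared between genotype and confounder tables",
         call. = FALSE)
  }
  preds <- predictor_columns(merged)
  cols <- intersect(confounder_cols(), names(confounders))
  rows <- list()
  for (conf in cols) {
    for (pl in names(preds)) {
      res <- tryCatch(
        dplyr::mutate(ols_additive(merged[[conf]], preds[[pl]],
                           phenotype_label = conf, time_point = NA_character_,
                           predictor_label = pl),
              note = ""),
        error = function(e) tibble::tibble(
          phenotype_label = conf, time_point = NA_character_,
          predictor_label = pl, n = NA_integer_, mean = NA_real_,
          sd = NA_real_, beta = NA_real_, se = NA_real_, p_value = NA_real_,
          r_squared = NA_real_, note = conditionMessage(e)
        )
      )
      rows[[length(rows) + 1L]] <- res
    }
  }
  dplyr::bind_rows(rows)
}

#' Association of the caffeine phenotype with confounders
#'
#' Regresses total caffeine consumption (mg/day) on each confounder, per time
#' point. In observational data these associations are typically strong —
#' the contrast with the null confounder balance of the genetic score is the
#' core argument for using the score as an instrument.
#'
#' @param phenotypes Wide phenotype tibble (see [build_phenotype_table()]).
#' @param confounders Confounder tibble.
#' @param time_points_used Time points to analyse (default: all present).
#' @param phenotype_col Phenotype column (default `total_caffeine_mg`).
#' @return Tibble of regression rows (confounder x time point).
#' @export
phenotype_confounding <- function(phenotypes, confounders,
                                  time_points_used = NULL,
                                  phenotype_col = "total_caffeine_mg") {
  merged <- dplyr::inner_join(phenotypes, confounders, by = "subject_id")
  if (nrow(merged) == 0L) {
    stop("no subjects shared between phenotype and confounder tables",
         call. = FALSE)
  }
  tps <- intersect(time_points(), unique(merged$time_point))
  if (!is.null(time_points_used)) tps <- intersect(tps, time_points_used)
  cols <- intersect(confounder_cols(), names(confounders))
  rows <- list()
  for (tp in tps) {
    sub <- merged[merged$time_point == tp, , drop = FALSE]
    for (conf in cols) {
      res <- tryCatch(
        dplyr::mutate(ols_additive(sub[[phenotype_col]], sub[[conf]],
                           phenotype_label = phenotype_col, time_point = tp,
                           predictor_label = conf),
              note = ""),
        error = function(e) tibble::tibble(
          phenotype_label = phenotype_col, time_point = tp,
          predictor_label = conf, n = NA_integer_, mean = NA_real_,
          sd = NA_real_, beta = NA_real_, se = NA_real_, p_value = NA_real_,
          r_squared = NA_real_, note = conditionMessage(e)
        )
      )
      rows[[length(rows) + 1L]] <- res
    }
  }
  dplyr::bind_rows(rows)
}

#' Decaffeinated-drink negative controls
#'
#' Runs the same association machinery as [association_sweep()] on the
#' decaffeinated phenotype columns. If the genetic association with
#' caffeinated drinks acts through caffeine, the decaffeinated counterparts —
#' which share taste, habit and social determinants but not caffeine — should
#' show no association. Each cell is annotated with a `consistent_with_null`
#' flag (two-sided p > 0.05, no correction; a report annotation, not an
#' inferential claim).
#'
#' @param phenotypes Wide phenotype tibble containing the decaf columns.
#' @param genotypes Genotype tibble.
#' @param decaf_cols Decaffeinated phenotype columns.
#' @param weights Optional score weights.
#' @return [association_sweep()] rows plus `consistent_with_null`.
#' @export
negative_control <- function(phenotypes, genotypes,
                             decaf_cols = c("decaf_coffee_per_day",
                                            "decaf_tea_per_day",
                                            "decaf_cola_per_day"),
                             weights = NULL) {
  absent <- setdiff(decaf_cols, names(phenotypes))
  if (length(absent)) {
    stop("decaffeinated column(s) missing: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  res <- association_sweep(phenotypes, genotypes,
                           phenotype_cols = decaf_cols, weights = weights)
  res$consistent_with_null <- !is.na(res$p_value) & res$p_value > 0.05
  res
}

#' Read a confounder TSV
#'
#' @param path TSV with columns `subject_id`, `year_of_birth`,
#'   `housing_tenure`, `crowding_index`, `education_level`, `alcohol`,
#'   `tobacco`.
#' @return Tibble.
#' @export
read_confounder_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    subject_id = readr::col_character(), .default = readr::col_double()
  ), na = c("", "NA"), progress = FALSE)
}
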