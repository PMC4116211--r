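# Additive genetic association: per-SNP and combined-score simple linear
# regressions across time points, variance explained, and within-/between-
# locus non-additivity tests. Regressions use stats::lm, matching common
# practice for these analyses; p-values are two-sided from the t distribution
# with residual df, and no multiple-testing adjustment is applied (raw
# p-values are reported across the eight time points).

#' Univariate additive regression of a phenotype on a genetic predictor
#'
#' Ordinary least squares of phenotype on the per-subject effect-allele count
#' or allelic score. Missing pairs are dropped (complete-case); R^2 is the
#' squared sample correlation.
#'
#' @param phenotype,predictor Aligned numeric vectors.
#' @param phenotype_label,time_point,predictor_label Metadata carried into the
#'   result row.
#' @return One-row tibble: `phenotype_label`, `time_point`, `predictor_label`,
#'   `n`, `mean`, `sd`, `min`, `max`, `beta`, `se`, `p_value`, `r_squared`.
#' @export
ols_additive <- function(phenotype, predictor,
                         phenotype_label = "phenotype",
                         time_point = NA_character_,
                         predictor_label = "predictor") {
  if (length(phenotype) != length(predictor)) {
    stop("phenotype and predictor differ in length", call. = FALSE)
  }
  ok <- !is.na(phenotype) & !is.na(predictor)
  y <- phenotype[ok]
  x <- predictor[ok]
  if (length(y) < 3) {
    stop("fewer than 3 complete pairs", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("predictor has zero variance (monomorphic score)", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- sm$coefficients
  flat <- stats::var(y) == 0  # constant response: slope 0, no explainable variance
  tibble::tibble(
    phenotype_label = phenotype_label,
    time_point = time_point,
    predictor_label = predictor_label,
    n = length(y),
    mean = mean(y),
    sd = stats::sd(y),
    min = min(y),
    max = max(y),
    beta = co["x", "Estimate"],
    se = if (flat) NA_real_ else co["x", "Std. Error"],
    p_value = if (flat) NA_real_ else co["x", "Pr(>|t|)"],
    r_squared = if (flat) 0 else sm$r.squared
  )
}

#' Analytic variance explained by an additive predictor
#'
#' beta^2 * var(score) / var(phenotype). For a single SNP under
#' Hardy-Weinberg equilibrium the score variance is 2q(1-q) (see
#' [hwe_score_variance()]).
#'
#' @param beta Per-unit-score effect in phenotype units.
#' @param score_variance,phenotype_variance Variances (> 0).
#' @return Proportion of variance explained.
#' @export
variance_explained_analytic <- function(beta, score_variance, phenotype_variance) {
  if (any(score_variance <= 0) || any(phenotype_variance <= 0)) {
    stop("variances must be positive", call. = FALSE)
  }
  beta^2 * score_variance / phenotype_variance
}

#' Additive-score variance of one SNP under Hardy-Weinberg proportions
#'
#' @param q Effect-allele frequency.
#' @return 2 q (1 - q).
#' @export
hwe_score_variance <- function(q) {
  stopifnot(all(q > 0 & q < 1))
  2 * q * (1 - q)
}

#' Within-locus non-additivity (dominance) test
#'
#' Fits phenotype ~ additive allele count + heterozygote indicator and tests
#' the heterozygote term: under additivity the heterozygote mean lies midway
#' between the homozygote means and the term is zero.
#'
#' @param phenotype Numeric vector.
#' @param calls Effect-allele counts in \{0, 1, 2\}.
#' @return One-row tibble: `test_kind` ("within_locus"), `term_estimate`,
#'   `term_se`, `p_value`, `n`.
#' @export
dominance_test <- function(phenotype, calls) {
  ok <- !is.na(phenotype) & !is.na(calls)
  y <- phenotype[ok]
  g <- calls[ok]
  present <- sort(unique(g))
  missing_class <- setdiff(0:2, present)
  if (length(missing_class)) {
    stop("genotype class(es) absent: ",
         paste(missing_class, collapse = ", "), call. = FALSE)
  }
  het <- as.numeric(g == 1)
  fit <- stats::lm(y ~ g + het)
  co <- summary(fit)$coefficients
  tibble::tibble(
    test_kind = "within_locus",
    term_estimate = co["het", "Estimate"],
    term_se = co["het", "Std. Error"],
    p_value = co["het", "Pr(>|t|)"],
    n = length(y)
  )
}

#' Between-locus non-additivity (epistasis) test
#'
#' Fits phenotype ~ g1 + g2 + g1:g2 and tests the product term: a joint
#' effect beyond the sum of the two marginal additive effects.
#'
#' @param phenotype Numeric vector.
#' @param calls_snp1,calls_snp2 Effect-allele counts.
#' @return One-row tibble: `test_kind` ("between_locus"), `term_estimate`,
#'   `term_se`, `p_value`, `n`.
#' @export
interaction_test <- function(phenotype, calls_snp1, calls_snp2) {
  ok <- !is.na(phenotype) & !is.na(calls_snp1) & !is.na(calls_snp2)
  y <- phenotype[ok]
  g1 <- calls_snp1[ok]
  g2 <- calls_snp2[ok]
  if (stats::var(g1) == 0 || stats::var(g2) == 0) {
    stop("both SNPs must be polymorphic in the analysed sample", call. = FALSE)
  }
  fit <- stats::lm(y ~ g1 * g2)
  if (fit$rank < 4) {
    stop("degenerate design: interaction column collinear", call. = FALSE)
  }
  co <- summary(fit)$coefficients
  tibble::tibble(
    test_kind = "between_locus",
    term_estimate = co["g1:g2", "Estimate"],
    term_se = co["g1:g2", "Std. Error"],
    p_value = co["g1:g2", "Pr(>|t|)"],
    n = length(y)
  )
}

# Internal: assemble the three default predictors from a genotype tibble.
predictor_columns <- function(genotypes, weights = NULL) {
  info <- snp_info()
  g1 <- genotypes[[info$variant_id[1]]]
  g2 <- genotypes[[info$variant_id[2]]]
  preds <- list(g1, g2, combined_score(g1, g2))
  names(preds) <- c(info$variant_id, "combined")
  if (!is.null(weights)) {
    preds$weighted <- combined_score(g1, g2, weights = weights)
  }
  preds
}

#' Association sweep across time points, phenotypes and predictors
#'
#' Reproduces the published table layout: for each phenotype column, each
#' time point and each predictor (each SNP's T-allele count and the combined
#' score; optionally the weighted score), a complete-case additive regression.
#' Rows are ordered by time point, phenotype, predictor.
#'
#' @param phenotypes Wide phenotype tibble with `subject_id`, `time_point`
#'   and the columns named in `phenotype_cols`.
#' @param genotypes Tibble with `subject_id` and hard-call columns named by
#'   rsid.
#' @param phenotype_cols Character vector of phenotype columns to analyse.
#' @param weights Optional length-2 weights adding a "weighted" predictor.
#' @return Tibble of [ols_additive()] rows; cells whose stratum is empty or
#'   degenerate are flagged in the `note` column with NA estimates.
#' @export
association_sweep <- function(phenotypes, genotypes,
                              phenotype_cols = c("total_caffeine_mg",
                                                 "coffee_per_day",
                                                 "tea_per_day",
                                                 "cola_per_day"),
                              weights = NULL) {
  merged <- dplyr::inner_join(phenotypes, genotypes, by = "subject_id")
  if (nrow(merged) == 0L) {
    stop("no subjects shared between phenotype and genotype tables",
         call. = FALSE)
  }
  tps <- intersect(time_points(), unique(merged$time_point))
  rows <- list()
  for (tp in tps) {
    sub <- merged[merged$time_point == tp, , drop = FALSE]
    preds <- predictor_columns(sub, weights)
    for (ph in phenotype_cols) {
      if (!ph %in% names(sub)) next
      for (pl in names(preds)) {
        res <- tryCatch(
          dplyr::mutate(ols_additive(sub[[ph]], preds[[pl]],
                             phenotype_label = ph, time_point = tp,
                             predictor_label = pl),
                note = ""),
          error = function(e) tibble::tibble(
            phenotype_label = ph, time_point = tp, predictor_label = pl,
            n = NA_integer_, mean = NA_real_, sd = NA_real_,
            beta = NA_real_, se = NA_real_, p_value = NA_real_,
            r_squared = NA_real_, note = conditionMessage(e)
          )
        )
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Sensitivity sweep excluding zero consumers
#'
#' Re-runs [association_sweep()] with each cell restricted to subjects whose
#' analysed phenotype value is strictly positive, checking that associations
#' are not driven by the consumer / non-consumer contrast.
#'
#' @inheritParams association_sweep
#' @return As [association_sweep()]; empty strata are flagged, not fatal.
#' @export
zero_consumer_sensitivity <- function(phenotypes, genotypes,
                                      phenotype_cols = c("total_caffeine_mg",
                                                         "coffee_per_day",
                                                         "tea_per_day",
                                                         "cola_per_day"),
                                      weights = NULL) {
  ph <- phenotypes
  for (col in phenotype_cols) {
    if (col %in% names(ph)) {
      ph[[col]] <- ifelse(!is.na(ph[[col]]) & ph[[col]] > 0, ph[[col]], NA_real_)
    }
  }
  association_sweep(ph, genotypes, phenotype_cols = phenotype_cols,
                    weights = weights)
}
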