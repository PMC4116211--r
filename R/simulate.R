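# Synthetic cohort generator. Emulates the statistical structure the
# analysis assumes: Hardy-Weinberg genotypes at the two loci, longitudinal
# beverage consumption with published per-time-point means/SDs and per-allele
# effects on the caffeinated drinks only, zero genotype effect on
# decaffeinated drinks and on cola, and confounders built from the
# non-genetic phenotype component only (so genotype and confounders are
# independent by construction). Everything is driven by one master seed with
# labelled substreams, so adding a table never perturbs existing ones.

#' Build a simulation configuration
#'
#' Defaults reproduce the study conditions: the published per-time-point
#' means, SDs and per-allele effects parameterize consumption; cola and all
#' decaffeinated drinks get zero genotype effect; cola switches from open to
#' closed format after the 2-month wave; confounder effect sizes follow the
#' published phenotype-confounder pattern.
#'
#' @param n Cohort size.
#' @param seed Master seed (integer).
#' @param time_points_used Subset of [time_points()] to simulate.
#' @param missingness Per-observation missingness probability.
#' @param outlier_rate Probability of replacing an observation with an
#'   implausibly large value (exercises the outlier mask).
#' @param censor_at_zero Left-censor latent phenotype values at zero
#'   (realism option; off by default so OLS recovery targets are unbiased).
#' @param truncate_confounders Clamp continuous confounders at zero
#'   (realism option, off by default for the same reason).
#' @return A list of class `caffscore_config`.
#' @export
simulation_config <- function(n = 5000, seed = 1,
                              time_points_used = time_points(),
                              missingness = 0.03,
                              outlier_rate = 0.002,
                              censor_at_zero = FALSE,
                              truncate_confounders = FALSE) {
  stopifnot(n >= 10, all(time_points_used %in% time_points()))
  cfg <- list(
    n = as.integer(n),
    seed = as.integer(seed),
    variants = snp_info(),
    time_points = time_points_used,
    scenarios = table_scenarios(),
    cola_genotype_effect = 0,
    closed_format_time_points = c("47mo", "85mo", "97mo", "145mo"),
    reference_time_point = "18wk",
    # Decaffeinated consumption: no published summary rows exist, so modest
    # realistic levels are fixed here (daily for coffee/tea, weekly for cola).
    decaf = tibble::tibble(
      beverage = c("coffee", "tea", "cola"),
      mean = c(0.4, 0.5, 0.8),
      sd = c(0.9, 1.1, 1.8)
    ),
    # Confounders: target slope of total caffeine (mg/day) regressed on the
    # confounder at the reference time point, following the published sign
    # pattern; ordinals are generated from a latent continuous scale and cut
    # into levels, which attenuates the realized slope.
    confounders = tibble::tibble(
      name = c("year_of_birth", "housing_tenure", "crowding_index",
               "education_level", "alcohol", "tobacco"),
      type = c("integer", "ordinal", "continuous", "ordinal",
               "continuous", "continuous"),
      mean = c(1962, 2, 0.7, 3, 3, 1.5),
      sd = c(4.5, 0.7, 0.35, 1.1, 4, 4),
      beta = c(0.78, 26.6, 29.6, -15.0, 3.96, 7.91),
      n_levels = c(NA, 3, NA, 5, NA, NA)
    ),
    missingness = missingness,
    outlier_rate = outlier_rate,
    censor_at_zero = censor_at_zero,
    truncate_confounders = truncate_confounders
  )
  class(cfg) <- "caffscore_config"
  cfg
}

#' Simulate genotypes at one variant under Hardy-Weinberg proportions
#'
#' Hard calls are drawn with genotype probabilities (1-q)^2, 2q(1-q), q^2 for
#' 0, 1, 2 copies of the effect allele. When an imputation quality r^2 < 1 is
#' given, dosages are the hard call plus Gaussian noise scaled so that the
#' squared correlation between dosage and call is approximately r^2, clipped
#' to \[0, 2\]; otherwise dosage equals the call.
#'
#' @param n Number of subjects.
#' @param effect_allele_freq Effect-allele frequency q in (0, 1).
#' @param imputation_quality r^2 in (0, 1\], or NULL/NA for a directly
#'   genotyped variant.
#' @param seed Integer seed.
#' @return Tibble with `hard_call` and `dosage`.
#' @export
simulate_genotypes <- function(n, effect_allele_freq,
                               imputation_quality = NULL, seed = 1) {
  q <- effect_allele_freq
  if (!is.numeric(q) || q <= 0 || q >= 1) {
    stop("effect_allele_freq must lie in (0, 1)", call. = FALSE)
  }
  set.seed(seed)
  calls <- stats::rbinom(n, 2, q)
  r2 <- imputation_quality
  if (is.null(r2) || is.na(r2) || r2 >= 1) {
    dosage <- as.numeric(calls)
  } else {
    stopifnot(r2 > 0)
    var_g <- 2 * q * (1 - q)
    noise_sd <- sqrt(var_g * (1 - r2) / r2)
    dosage <- pmin(2, pmax(0, calls + stats::rnorm(n, 0, noise_sd)))
  }
  tibble::tibble(hard_call = as.integer(calls), dosage = dosage)
}

#' Simulate genotypes for the configured variants as a cohort table
#'
#' @param config A [simulation_config()].
#' @return Tibble with `subject_id`, one hard-call column per rsid and one
#'   `<rsid>_dosage` column per rsid.
#' @export
simulate_cohort_genotypes <- function(config) {
  v <- config$variants
  out <- tibble::tibble(subject_id = sprintf("S%05d", seq_len(config$n)))
  for (i in seq_len(nrow(v))) {
    g <- simulate_genotypes(config$n, v$effect_allele_freq[i],
                            v$imputation_quality[i],
                            seed = substream_seed(config$seed,
                                                  paste0("geno_", v$variant_id[i])))
    out[[v$variant_id[i]]] <- g$hard_call
    out[[paste0(v$variant_id[i], "_dosage")]] <- g$dosage
  }
  out
}

#' Simulate a phenotype with additive two-SNP effects and calibrated marginals
#'
#' latent = mu_adj + beta1 g1 + beta2 g2 + eps, with eps normal and sigma
#' chosen so the marginal SD equals `sd` (the genetic variance implied by the
#' configured allele frequencies is subtracted) and mu_adj chosen so the
#' marginal mean equals `mean`.
#'
#' @param g1,g2 Effect-allele counts.
#' @param mean,sd Target marginal mean and SD.
#' @param beta1,beta2 Per-allele effects in phenotype units.
#' @param q1,q2 Effect-allele frequencies used for the calibration.
#' @param seed Integer seed.
#' @param censor_at_zero Left-censor at zero (attenuates recovery; off by
#'   default).
#' @return Numeric vector of phenotype values.
#' @export
simulate_phenotype <- function(g1, g2, mean, sd, beta1, beta2,
                               q1 = snp_info()$effect_allele_freq[1],
                               q2 = snp_info()$effect_allele_freq[2],
                               seed = 1, censor_at_zero = FALSE) {
  var_g <- beta1^2 * hwe_score_variance(q1) + beta2^2 * hwe_score_variance(q2)
  if (sd^2 <= var_g) {
    stop("infeasible SD: genetic variance (", signif(var_g, 4),
         ") is not below the target total variance (", signif(sd^2, 4), ")",
         call. = FALSE)
  }
  mu_adj <- mean - beta1 * 2 * q1 - beta2 * 2 * q2
  set.seed(seed)
  y <- mu_adj + beta1 * g1 + beta2 * g2 +
    stats::rnorm(length(g1), 0, sqrt(sd^2 - var_g))
  if (censor_at_zero) y <- pmax(y, 0)
  y
}

# Map a nonnegative weekly cola value to the nearest closed-format recode
# value; ties go to the smaller category.
closed_category_from_weekly <- function(weekly) {
  recode <- scoring_constants()$closed_recode
  labels <- names(recode)
  idx <- vapply(weekly, function(w) {
    if (is.na(w)) return(NA_integer_)
    which.min(abs(recode - w))
  }, integer(1))
  labels[idx]
}

#' Simulate the beverage observation tables
#'
#' For each configured time point and beverage, draws a latent daily (cola:
#' weekly) value with the published marginal mean/SD and the per-SNP
#' per-allele effects (zero for cola and for all decaffeinated drinks), then
#' renders questionnaire observations: coffee and tea as weekday/weekend
#' splits with equal values, cola as open weekly counts at the early waves
#' and closed categories later. Rendered counts are censored at zero (a
#' questionnaire count cannot be negative). Configured missingness and
#' outlier injections are applied last.
#'
#' @param genotypes Tibble from [simulate_cohort_genotypes()].
#' @param config A [simulation_config()].
#' @return List with `observations` (long questionnaire table including
#'   decaffeinated records), `truth` (per record: uncensored latent daily
#'   value and `expected_per_day`, the value phenotype refinement should
#'   recover, NA where masked or missing) and `resid_reference` (per-subject
#'   non-genetic total-caffeine component at the reference time point, for
#'   confounder generation).
#' @export
simulate_consumption <- function(genotypes, config) {
  v <- config$variants
  g1 <- genotypes[[v$variant_id[1]]]
  g2 <- genotypes[[v$variant_id[2]]]
  q1 <- v$effect_allele_freq[1]
  q2 <- v$effect_allele_freq[2]
  n <- nrow(genotypes)
  weights <- scoring_constants()$caffeine_mg_per_drink
  obs_rows <- list()
  truth_rows <- list()
  resid_ref <- rep(0, n)
  ref_tp <- if (config$reference_time_point %in% config$time_points) {
    config$reference_time_point
  } else {
    config$time_points[1]
  }

  for (tp in config$time_points) {
    for (bev in beverages()) {
      for (caff in c(TRUE, FALSE)) {
        stream <- paste("consume", tp, bev, caff, sep = "_")
        if (caff) {
          sc <- scenario_from_table(tp, bev)
          b1 <- sc$beta_rs2472297
          b2 <- sc$beta_rs6968865
          if (bev == "cola") {
            b1 <- config$cola_genotype_effect
            b2 <- config$cola_genotype_effect
          }
          mu <- sc$mean
          sdv <- sc$sd
        } else {
          d <- config$decaf[config$decaf$beverage == bev, ]
          b1 <- 0; b2 <- 0; mu <- d$mean; sdv <- d$sd
        }
        latent <- simulate_phenotype(g1, g2, mu, sdv, b1, b2, q1, q2,
                                     seed = substream_seed(config$seed, stream))
        # accumulate the non-genetic total-caffeine component (mg/day scale)
        if (caff && tp == ref_tp) {
          nongenetic <- latent - b1 * g1 - b2 * g2
          daily_scale <- if (bev == "cola") 1 / 7 else 1
          resid_ref <- resid_ref + weights[[bev]] * nongenetic * daily_scale
        }
        rendered <- pmax(latent, 0)

        set.seed(substream_seed(config$seed, paste0(stream, "_noise")))
        miss <- stats::runif(n) < config$missingness
        outl <- !miss & stats::runif(n) < config$outlier_rate

        if (bev == "cola") {
          closed <- tp %in% config$closed_format_time_points
          weekly <- rendered
          if (closed) {
            cat_lab <- closed_category_from_weekly(weekly)
            expected_day <- recode_closed_response(cat_lab) / 7
            fmt <- "weekly_closed"
          } else {
            if (any(outl)) weekly[outl] <- 200
            expected_day <- weekly / 7
            fmt <- "weekly_numeric"
            cat_lab <- rep(NA_character_, n)
          }
          expected_day <- mask_outliers(expected_day, bev)
          expected_day[miss] <- NA_real_
          obs_rows[[length(obs_rows) + 1L]] <- tibble::tibble(
            subject_id = genotypes$subject_id, time_point = tp,
            beverage = bev, caffeinated = caff, format = fmt,
            weekday_count = NA_real_, weekend_count = NA_real_,
            weekly_value = if (fmt == "weekly_numeric")
              ifelse(miss, NA_real_, weekly) else NA_real_,
            closed_category = if (fmt == "weekly_closed")
              ifelse(miss, NA_character_, cat_lab) else NA_character_
          )
          latent_daily <- latent / 7
        } else {
          daily <- rendered
          if (any(outl)) {
            daily[outl] <- scoring_constants()$outlier_max_per_day[[bev]] + 5
          }
          expected_day <- mask_outliers(daily, bev)
          expected_day[miss] <- NA_real_
          obs_rows[[length(obs_rows) + 1L]] <- tibble::tibble(
            subject_id = genotypes$subject_id, time_point = tp,
            beverage = bev, caffeinated = caff, format = "weekday_weekend",
            weekday_count = ifelse(miss, NA_real_, daily),
            weekend_count = ifelse(miss, NA_real_, daily),
            weekly_value = NA_real_, closed_category = NA_character_
          )
          latent_daily <- latent
        }
        truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
          subject_id = genotypes$subject_id, time_point = tp,
          beverage = bev, caffeinated = caff,
          latent_daily = latent_daily,
          expected_per_day = expected_day,
          beta_rs2472297 = b1, beta_rs6968865 = b2
        )
      }
    }
  }
  list(
    observations = dplyr::bind_rows(obs_rows),
    truth = dplyr::bind_rows(truth_rows),
    resid_reference = unname(resid_ref)
  )
}

#' Simulate the confounder table
#'
#' Each confounder is built from the *non-genetic* component of the reference
#' time point's total caffeine consumption: latent = mean + lambda * centred
#' residual + noise, with lambda chosen so that regressing the phenotype on
#' the confounder recovers the configured slope and the confounder's marginal
#' SD matches its configuration. Because only the non-genetic residual is
#' used, confounders are independent of genotype by construction, whatever
#' the configured effects. Ordinal confounders are cut from the latent scale
#' into equal-probability levels (which attenuates their realized slope).
#'
#' @param resid_reference Per-subject non-genetic phenotype component (mg/day).
#' @param config A [simulation_config()].
#' @return Tibble with `subject_id` and the six confounder columns.
#' @export
simulate_confounders <- function(resid_reference, config) {
  n <- length(resid_reference)
  r <- resid_reference - mean(resid_reference)
  var_r <- stats::var(resid_reference)
  out <- tibble::tibble(subject_id = sprintf("S%05d", seq_len(n)))
  spec <- config$confounders
  for (i in seq_len(nrow(spec))) {
    nm <- spec$name[i]
    s2 <- spec$sd[i]^2
    lambda <- spec$beta[i] * s2 / var_r
    var_e <- s2 - lambda^2 * var_r
    if (var_e < 0) {
      stop("confounder ", nm, ": configured slope too large for its SD",
           call. = FALSE)
    }
    set.seed(substream_seed(config$seed, paste0("conf_", nm)))
    latent <- spec$mean[i] + lambda * r + stats::rnorm(n, 0, sqrt(var_e))
    val <- switch(
      spec$type[i],
      ordinal = {
        k <- spec$n_levels[i]
        cuts <- stats::quantile(latent, probs = seq(0, 1, length.out = k + 1))
        cuts[1] <- -Inf; cuts[k + 1] <- Inf
        as.numeric(cut(latent, breaks = cuts, labels = FALSE,
                       include.lowest = TRUE))
      },
      integer = round(latent),
      continuous = if (config$truncate_confounders) pmax(latent, 0) else latent
    )
    out[[nm]] <- val
  }
  out
}

#' Simulate a full synthetic cohort
#'
#' Genotypes, raw questionnaire observations (caffeinated and decaffeinated),
#' confounders and a latent-truth table, all keyed by subject id and driven
#' by the single master seed in `config`.
#'
#' @param config A [simulation_config()].
#' @return List of class `caffscore_cohort` with elements `genotypes`,
#'   `observations`, `confounders`, `truth` and `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  genotypes <- simulate_cohort_genotypes(config)
  cons <- simulate_consumption(genotypes, config)
  confounders <- simulate_confounders(cons$resid_reference, config)
  structure(
    list(
      genotypes = genotypes,
      observations = cons$observations,
      confounders = confounders,
      truth = cons$truth,
      config = config
    ),
    class = "caffscore_cohort"
  )
}

#' Write a synthetic cohort's tables to a directory
#'
#' Emits `genotypes.tsv` (dosage dialect: `subject_id`, `<rsid>_T` columns),
#' `observations.tsv`, `confounders.tsv` and `truth.tsv`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- cohort$config$variants
  geno_out <- tibble::tibble(subject_id = cohort$genotypes$subject_id)
  for (i in seq_len(nrow(v))) {
    geno_out[[paste0(v$variant_id[i], "_", v$effect_allele[i])]] <-
      cohort$genotypes[[paste0(v$variant_id[i], "_dosage")]]
  }
  readr::write_tsv(geno_out, file.path(dir, "genotypes.tsv"), na = "")
  write_beverage_tsv(cohort$observations, file.path(dir, "observations.tsv"))
  readr::write_tsv(cohort$confounders, file.path(dir, "confounders.tsv"), na = "")
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"), na = "")
  invisible(dir)
}
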