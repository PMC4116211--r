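# Simulation-based parameter recovery at a published table row: the study
# protocol used to check the pipeline end to end when the real cohort data
# are not accessible. Each replicate draws a fresh HWE cohort at the row's
# sample size, injects the row's per-allele effects, and refits the additive
# regression.

#' Replicate a table-row scenario and refit the association
#'
#' For each replicate: simulate hard calls for the two SNPs at their
#' configured T-allele frequencies and the scenario's sample size, draw the
#' phenotype with the scenario's marginal mean/SD and per-allele effects, and
#' fit the additive regression of phenotype on the chosen predictor.
#'
#' @param time_point,phenotype Scenario row key (see [scenario_from_table()]).
#' @param predictor `"combined"` for the unweighted two-SNP score, or an rsid
#'   for a univariate per-SNP regression.
#' @param effects `"equal_combined"` injects the row's combined-score
#'   coefficient as an equal per-SNP effect at both loci (the additive
#'   generating model whose score regression recovers that coefficient);
#'   `"per_snp"` injects each SNP's own univariate coefficient.
#' @param n_reps Number of replicate cohorts.
#' @param seed Master seed; each replicate uses a labelled substream.
#' @return Tibble with one row per replicate: `rep`, `n`, `beta`, `se`,
#'   `r_squared`, plus the generating effect sizes as attributes
#'   `"beta1"`/`"beta2"`.
#' @export
scenario_recovery <- function(time_point, phenotype,
                              predictor = "combined",
                              effects = c("equal_combined", "per_snp"),
                              n_reps = 200, seed = 1) {
  effects <- match.arg(effects)
  sc <- scenario_from_table(time_point, phenotype)
  info <- snp_info()
  q1 <- info$effect_allele_freq[1]
  q2 <- info$effect_allele_freq[2]
  if (effects == "equal_combined") {
    b1 <- sc$beta_combined
    b2 <- sc$beta_combined
  } else {
    b1 <- sc$beta_rs2472297
    b2 <- sc$beta_rs6968865
  }
  stopifnot(predictor %in% c("combined", info$variant_id))
  out <- vector("list", n_reps)
  label <- paste(time_point, phenotype, effects, sep = "_")
  for (r in seq_len(n_reps)) {
    g1 <- simulate_genotypes(sc$n, q1,
                             seed = substream_seed(seed, paste0(label, "_g1_", r)))$hard_call
    g2 <- simulate_genotypes(sc$n, q2,
                             seed = substream_seed(seed, paste0(label, "_g2_", r)))$hard_call
    y <- simulate_phenotype(g1, g2, sc$mean, sc$sd, b1, b2, q1, q2,
                            seed = substream_seed(seed, paste0(label, "_y_", r)))
    x <- switch(predictor,
                combined = combined_score(g1, g2),
                rs2472297 = g1,
                rs6968865 = g2)
    fit <- ols_additive(y, x, phenotype_label = phenotype,
                        time_point = time_point, predictor_label = predictor)
    out[[r]] <- tibble::tibble(rep = r, n = fit$n, beta = fit$beta,
                               se = fit$se, r_squared = fit$r_squared)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "beta1") <- b1
  attr(res, "beta2") <- b2
  res
}
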