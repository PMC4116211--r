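# Table rendering and pipeline orchestration. Layouts mirror the published
# summary tables: per-phenotype association tables (time point rows, Beta/SE/P
# per predictor), the confounder-balance table (confounder rows) and the
# phenotype-confounder table (confounder rows x time-point column blocks).

#' Format a p-value in compact scientific notation
#'
#' @param p Numeric vector.
#' @return Character vector like `"3.74e-14"` (two significant digits in the
#'   mantissa); NA renders as `"NA"`.
#' @export
format_p <- function(p) {
  ifelse(is.na(p), "NA", sprintf("%.2e", p))
}

format_est <- function(x, digits) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"), x))
}

#' Render association results in a published-table layout
#'
#' @param results Tibble of association rows (from [association_sweep()],
#'   [confounder_balance()] or [phenotype_confounding()]).
#' @param layout `"association"` (time-point rows; for the per-phenotype
#'   tables and the decaffeinated negative controls), `"confounder_balance"`
#'   (confounder rows x predictor blocks) or `"phenotype_confounding"`
#'   (confounder rows x time-point blocks).
#' @param digits Decimal places for betas and SEs (1 for mg-scale phenotypes,
#'   3 for drinks-scale).
#' @return A tibble of formatted character columns, ready for
#'   [readr::write_tsv()].
#' @export
render_table <- function(results, layout = c("association",
                                             "confounder_balance",
                                             "phenotype_confounding"),
                         digits = 3) {
  layout <- match.arg(layout)
  if (nrow(results) == 0L) {
    warning("no result rows; rendering header only")
  }
  if (any(is.na(results$beta))) {
    warning("missing cells rendered as NA")
  }
  if (layout == "association") {
    key <- "time_point"
    row_levels <- intersect(time_points(), unique(results$time_point))
    block_col <- "predictor_label"
    blocks <- unique(results$predictor_label)
  } else if (layout == "confounder_balance") {
    key <- "phenotype_label"
    row_levels <- intersect(confounder_cols(), unique(results$phenotype_label))
    block_col <- "predictor_label"
    blocks <- unique(results$predictor_label)
  } else {
    key <- "predictor_label"
    row_levels <- intersect(confounder_cols(), unique(results$predictor_label))
    block_col <- "time_point"
    blocks <- intersect(time_points(), unique(results$time_point))
  }
  out <- tibble::tibble(!!key := row_levels)
  first_block <- TRUE
  for (b in blocks) {
    sub <- results[results[[block_col]] == b, , drop = FALSE]
    sub <- sub[match(row_levels, sub[[key]]), , drop = FALSE]
    if (first_block && layout == "association") {
      out$N <- sub$n
      out$Mean <- format_est(sub$mean, digits)
      out$SD <- format_est(sub$sd, digits)
      out$Min <- format_est(sub$min, digits)
      out$Max <- format_est(sub$max, digits)
    }
    if (first_block && layout != "association") out$N <- sub$n
    out[[paste0(b, "_Beta")]] <- format_est(sub$beta, digits)
    out[[paste0(b, "_SE")]] <- format_est(sub$se, digits)
    out[[paste0(b, "_P")]] <- format_p(sub$p_value)
    first_block <- FALSE
  }
  out
}

#' Run the full analysis pipeline on a directory of input tables
#'
#' Orchestrates phenotype refinement, genotype QC and scoring, the
#' association sweep, confounder balance, phenotype-confounder regressions
#' and the decaffeinated negative controls, and writes rendered tables plus a
#' run log. Inputs are the TSV dialects written by [write_cohort()]:
#' `observations.tsv`, `genotypes.tsv`, `confounders.tsv`.
#'
#' @param input_dir Directory holding the input TSVs.
#' @param output_dir Directory for rendered tables and the run log.
#' @param weights Use the published per-allele weights as an additional
#'   predictor.
#' @param zero_sensitivity Also run the zero-consumer sensitivity sweep.
#' @param impute_zero_cola Treat missing cola as zero in the caffeine total.
#' @param seed Seed recorded in the log (the analysis itself is
#'   deterministic).
#' @param verbose Print stage progress to stderr.
#' @return Invisibly, a list with all result tibbles and the QC table.
#' @export
run_pipeline <- function(input_dir, output_dir,
                         weights = FALSE, zero_sensitivity = FALSE,
                         impute_zero_cola = FALSE, seed = 1,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message("[caffscore] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    paste0("caffscore ", as.character(utils::packageVersion("caffscore"))),
    paste0("R ", R.version.string),
    paste0("seed ", seed),
    paste0("options weights=", weights, " zero_sensitivity=", zero_sensitivity,
           " impute_zero_cola=", impute_zero_cola)
  )

  say("reading inputs from ", input_dir)
  obs <- stage("read_observations",
               read_beverage_tsv(file.path(input_dir, "observations.tsv")))
  dosages <- stage("read_genotypes",
                   read_dosage_tsv(file.path(input_dir, "genotypes.tsv")))
  confounders <- stage("read_confounders",
                       read_confounder_tsv(file.path(input_dir, "confounders.tsv")))

  say("refining phenotypes (", nrow(obs), " observations)")
  phenotypes <- stage("phenotype_refinement",
                      build_phenotype_table(obs, impute_zero_cola = impute_zero_cola))
  log_lines <- c(log_lines, paste0("observations ", nrow(obs)),
                 paste0("phenotype_rows ", nrow(phenotypes)))

  say("genotype QC and scoring")
  # individual-level missingness filter precedes variant metrics
  dosages <- stage("individual_missingness",
                   filter_individual_missingness(dosages))
  log_lines <- c(log_lines,
                 paste0("subjects_dropped_missingness ",
                        length(attr(dosages, "dropped"))))
  info <- snp_info()
  genotypes <- tibble::tibble(subject_id = dosages$subject_id)
  qc_rows <- list()
  for (i in seq_len(nrow(info))) {
    rsid <- info$variant_id[i]
    calls <- best_guess(dosages[[rsid]])
    genotypes[[rsid]] <- calls
    qc_rows[[i]] <- variant_qc(calls, rsid, info$effect_allele[i])
  }
  qc <- stage("qc_filter", qc_filter(dplyr::bind_rows(qc_rows)))
  for (i in seq_len(nrow(qc))) {
    log_lines <- c(log_lines, paste0(
      "variant ", qc$variant_id[i], " maf=", signif(qc$maf[i], 3),
      " call_rate=", signif(qc$call_rate[i], 4),
      " hwe_p=", signif(qc$hwe_p[i], 3),
      " kept=", qc$kept[i],
      if (!qc$kept[i]) paste0(" reasons=", qc$fail_reasons[i]) else ""))
  }
  if (!all(qc$kept)) {
    stop("stage 'qc_filter' failed: variant(s) failed QC: ",
         paste(qc$variant_id[!qc$kept], collapse = ", "), call. = FALSE)
  }

  w <- if (weights) info$weight else NULL
  say("association sweep")
  sweep <- stage("association_sweep",
                 association_sweep(phenotypes, genotypes, weights = w))
  say("validation")
  balance <- stage("confounder_balance",
                   confounder_balance(genotypes, confounders))
  confounding <- stage("phenotype_confounding",
                       phenotype_confounding(phenotypes, confounders))
  decaf <- stage("negative_control",
                 negative_control(phenotypes, genotypes, weights = w))
  sensitivity <- NULL
  if (zero_sensitivity) {
    sensitivity <- stage("zero_consumer_sensitivity",
                         zero_consumer_sensitivity(phenotypes, genotypes,
                                                   weights = w))
  }

  say("rendering tables to ", output_dir)
  pheno_digits <- c(total_caffeine_mg = 1, coffee_per_day = 3,
                    tea_per_day = 3, cola_per_day = 3)
  table_files <- c(total_caffeine_mg = "table1_total_caffeine.tsv",
                   coffee_per_day = "table2_coffee.tsv",
                   tea_per_day = "table3_tea.tsv",
                   cola_per_day = "table4_cola.tsv")
  for (ph in names(table_files)) {
    sub <- sweep[sweep$phenotype_label == ph, , drop = FALSE]
    readr::write_tsv(render_table(sub, "association", pheno_digits[[ph]]),
                     file.path(output_dir, table_files[[ph]]))
  }
  readr::write_tsv(render_table(balance, "confounder_balance", 3),
                   file.path(output_dir, "table5_confounder_balance.tsv"))
  readr::write_tsv(render_table(confounding, "phenotype_confounding", 3),
                   file.path(output_dir, "table6_phenotype_confounders.tsv"))
  decaf_files <- c(decaf_coffee_per_day = "decaf_coffee.tsv",
                   decaf_tea_per_day = "decaf_tea.tsv",
                   decaf_cola_per_day = "decaf_cola.tsv")
  for (ph in names(decaf_files)) {
    sub <- decaf[decaf$phenotype_label == ph, , drop = FALSE]
    readr::write_tsv(render_table(sub, "association", 3),
                     file.path(output_dir, decaf_files[[ph]]))
  }
  if (!is.null(sensitivity)) {
    readr::write_tsv(sensitivity, file.path(output_dir,
                                            "zero_consumer_sensitivity.tsv"))
  }
  log_lines <- c(log_lines,
                 paste0("association_rows ", nrow(sweep)),
                 paste0("balance_rows ", nrow(balance)),
                 paste0("confounding_rows ", nrow(confounding)),
                 paste0("decaf_rows ", nrow(decaf)))
  writeLines(log_lines, file.path(output_dir, "run_log.txt"))
  say("done")
  invisible(list(phenotypes = phenotypes, genotypes = genotypes, qc = qc,
                 sweep = sweep, balance = balance, confounding = confounding,
                 decaf = decaf, sensitivity = sensitivity))
}
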