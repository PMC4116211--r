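# Genotype ingestion, QC and allelic-score construction for the two-SNP
# caffeine instrument (rs2472297, rs6968865; effect allele T at both).

#' Effect-allele frequency from hard calls
#'
#' @param calls Integer vector of per-subject effect-allele counts in
#'   \{0, 1, 2\}; NA allowed.
#' @return Frequency in \[0, 1\].
#' @export
effect_allele_frequency <- function(calls) {
  ok <- !is.na(calls)
  if (!any(ok)) stop("all genotype calls are missing", call. = FALSE)
  if (any(!calls[ok] %in% 0:2)) {
    stop("genotype calls must be 0, 1 or 2", call. = FALSE)
  }
  sum(calls[ok]) / (2 * sum(ok))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: all
#' heterozygote counts compatible with the allele counts are enumerated, each
#' configuration's conditional probability is computed in closed form, and the
#' p-value is the sum of probabilities no greater than that of the observed
#' configuration. No mid-p correction is applied.
#'
#' @param n_ref_hom,n_het,n_alt_hom Genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return Exact p-value in (0, 1\].
#' @export
hwe_exact_test <- function(n_ref_hom, n_het, n_alt_hom) {
  counts <- c(n_ref_hom, n_het, n_alt_hom)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0) stop("no genotypes supplied", call. = FALSE)
  n1 <- 2 * n_alt_hom + n_het   # alternate allele count
  n2 <- 2 * n_ref_hom + n_het   # reference allele count
  if (n1 == 0 || n2 == 0) return(1)

  hets <- seq(n1 %% 2, min(n1, n2), by = 2)
  log_prob <- vapply(hets, function(h) {
    a <- (n1 - h) / 2
    r <- (n2 - h) / 2
    lfactorial(n) - lfactorial(a) - lfactorial(h) - lfactorial(r) +
      h * log(2) + lfactorial(n1) + lfactorial(n2) - lfactorial(2 * n)
  }, numeric(1))
  prob <- exp(log_prob - max(log_prob))
  prob <- prob / sum(prob)
  p_obs <- prob[hets == n_het]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-9)]))
}

#' Best-guess genotype from imputed dosage
#'
#' Rounds an effect-allele dosage in \[0, 2\] to a hard call with half-open
#' bins: \[0, 0.5) -> 0, \[0.5, 1.5) -> 1, \[1.5, 2\] -> 2.
#'
#' @param dosage Numeric vector in \[0, 2\]; NA allowed.
#' @return Integer vector of hard calls.
#' @export
best_guess <- function(dosage) {
  ok <- !is.na(dosage)
  if (any(dosage[ok] < 0 | dosage[ok] > 2)) {
    stop("dosage must lie in [0, 2]", call. = FALSE)
  }
  out <- rep(NA_integer_, length(dosage))
  out[ok] <- ifelse(dosage[ok] < 0.5, 0L, ifelse(dosage[ok] < 1.5, 1L, 2L))
  out
}

#' Per-variant QC metrics
#'
#' Computes effect-allele frequency, MAF, call rate and the exact HWE p-value
#' from hard calls.
#'
#' @param calls Integer vector of effect-allele counts (NA = missing).
#' @param variant_id Variant label.
#' @param effect_allele Effect-allele symbol (default "T").
#' @return One-row tibble with columns `variant_id`, `effect_allele`,
#'   `effect_allele_freq`, `maf`, `call_rate`, `hwe_p`, `n_called`.
#' @export
variant_qc <- function(calls, variant_id, effect_allele = "T") {
  eaf <- effect_allele_frequency(calls)
  ok <- !is.na(calls)
  tibble::tibble(
    variant_id = variant_id,
    effect_allele = effect_allele,
    effect_allele_freq = eaf,
    maf = min(eaf, 1 - eaf),
    call_rate = mean(ok),
    hwe_p = hwe_exact_test(sum(calls[ok] == 0), sum(calls[ok] == 1),
                           sum(calls[ok] == 2)),
    n_called = sum(ok)
  )
}

#' Variant-level QC filter
#'
#' A variant is kept iff MAF >= `maf_min`, call rate >= `call_rate_min` and
#' HWE p > `hwe_p_min`. All failing criteria are reported, not just the first.
#'
#' @param qc Tibble of per-variant metrics as produced by [variant_qc()].
#' @param thresholds List as returned by [qc_thresholds()].
#' @return `qc` with logical `kept` and character `fail_reasons`
#'   (comma-separated; empty when kept).
#' @export
qc_filter <- function(qc, thresholds = qc_thresholds()) {
  reasons <- mapply(function(maf, cr, hwe) {
    r <- c(
      if (maf < thresholds$maf_min) "maf",
      if (cr < thresholds$call_rate_min) "call_rate",
      if (hwe <= thresholds$hwe_p_min) "hwe"
    )
    paste(r, collapse = ",")
  }, qc$maf, qc$call_rate, qc$hwe_p)
  qc$kept <- reasons == ""
  qc$fail_reasons <- reasons
  qc
}

#' Exclude subjects with excessive genotype missingness
#'
#' @param genotypes Tibble with `subject_id` and one call column per variant.
#' @param max_missing Maximum tolerated fraction of missing calls (default
#'   0.05; subjects strictly above are dropped).
#' @return Filtered tibble; dropped subject ids in attribute `"dropped"`.
#' @export
filter_individual_missingness <- function(genotypes,
                                          max_missing = qc_thresholds()$individual_missingness_max) {
  geno_cols <- setdiff(names(genotypes), "subject_id")
  miss <- rowMeans(is.na(genotypes[geno_cols]))
  out <- genotypes[miss <= max_missing, , drop = FALSE]
  attr(out, "dropped") <- genotypes$subject_id[miss > max_missing]
  out
}

#' Combined two-SNP allelic score
#'
#' Sums effect-allele counts across the two SNPs (unweighted score in
#' \{0..4\}), or a weighted sum when per-variant weights are supplied
#' (published weights: rs2472297 0.31, rs6968865 0.26). The score is missing
#' when either genotype is missing.
#'
#' @param calls_snp1,calls_snp2 Effect-allele counts, aligned by subject.
#' @param weights NULL for the unweighted score, or numeric length-2 vector
#'   of per-variant weights.
#' @return Numeric vector of per-subject scores.
#' @export
combined_score <- function(calls_snp1, calls_snp2, weights = NULL) {
  if (length(calls_snp1) != length(calls_snp2)) {
    stop("genotype vectors differ in length (", length(calls_snp1), " vs ",
         length(calls_snp2), "); subjects are misaligned", call. = FALSE)
  }
  for (g in list(calls_snp1, calls_snp2)) {
    if (any(!is.na(g) & !g %in% 0:2)) {
      stop("genotype calls must be 0, 1 or 2", call. = FALSE)
    }
  }
  if (is.null(weights)) weights <- c(1, 1)
  stopifnot(length(weights) == 2, all(weights > 0))
  weights[1] * calls_snp1 + weights[2] * calls_snp2
}

#' Read an additive-dosage TSV
#'
#' Header: `subject_id`, then one column per variant named
#' `<rsid>_<effect_allele>` with dosages in \[0, 2\] (empty = missing) — the
#' PLINK `.raw` dialect for the dosage columns. The declared effect allele of
#' each requested variant is checked against the column suffix; a mismatch is
#' an error rather than a silent allele flip.
#'
#' @param path TSV path.
#' @param variants Tibble with `variant_id` and `effect_allele`
#'   (default [snp_info()]).
#' @return Tibble with `subject_id` and one dosage column per variant
#'   (named by rsid).
#' @export
read_dosage_tsv <- function(path, variants = snp_info()) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    subject_id = readr::col_character(), .default = readr::col_double()
  ), na = c("", "NA"), progress = FALSE)
  out <- tibble::tibble(subject_id = raw$subject_id)
  for (i in seq_len(nrow(variants))) {
    rsid <- variants$variant_id[i]
    expected <- paste0(rsid, "_", variants$effect_allele[i])
    hit <- grep(paste0("^", rsid, "_"), names(raw), value = TRUE)
    if (length(hit) == 0L) {
      stop("no dosage column for variant ", rsid, call. = FALSE)
    }
    if (!expected %in% hit) {
      stop("column ", hit[1], " does not count the declared effect allele ",
           variants$effect_allele[i], " for ", rsid,
           "; refusing to flip alleles silently", call. = FALSE)
    }
    dos <- raw[[expected]]
    if (any(!is.na(dos) & (dos < 0 | dos > 2))) {
      stop("dosages for ", rsid, " outside [0, 2]", call. = FALSE)
    }
    out[[rsid]] <- dos
  }
  out
}

#' Read hard calls or dosages for configured variants from a VCF
#'
#' Extracts GT (preferred DS when `field = "DS"`) for the requested rsids and
#' counts copies of the declared effect allele, checking it against REF/ALT.
#' When the effect allele is the REF allele the ALT count is flipped
#' explicitly. Requires the vcfR package.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param variants Tibble with `variant_id` and `effect_allele`.
#' @param field "GT" for hard calls (default) or "DS" for dosages.
#' @return Tibble with `subject_id` and one column per variant.
#' @export
read_genotype_vcf <- function(path, variants = snp_info(), field = c("GT", "DS")) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_genotype_vcf requires the vcfR package", call. = FALSE)
  }
  field <- match.arg(field)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(vcf)
  if (is.null(dim(fixm))) {  # single-variant VCF collapses to a vector
    fixm <- matrix(fixm, nrow = 1, dimnames = list(NULL, names(fixm)))
  }
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  mat <- vcfR::extract.gt(vcf, element = field,
                          as.numeric = identical(field, "DS"))
  out <- tibble::tibble(subject_id = colnames(mat))
  for (i in seq_len(nrow(variants))) {
    rsid <- variants$variant_id[i]
    ea <- variants$effect_allele[i]
    j <- which(fix$ID == rsid)
    if (length(j) != 1L) {
      stop("variant ", rsid, " not found exactly once in ", path, call. = FALSE)
    }
    if (!ea %in% c(fix$REF[j], fix$ALT[j])) {
      stop("effect allele ", ea, " matches neither REF nor ALT for ", rsid,
           call. = FALSE)
    }
    flip <- identical(ea, fix$REF[j]) && !identical(fix$REF[j], fix$ALT[j])
    if (field == "GT") {
      gt <- unname(mat[j, ])
      alt_count <- ifelse(is.na(gt), NA_integer_,
                          vapply(strsplit(gt, "[/|]"),
                                 function(a) sum(a == "1"), integer(1)))
    } else {
      alt_count <- unname(mat[j, ])
    }
    out[[rsid]] <- if (flip) 2 - alt_count else alt_count
  }
  out
}
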