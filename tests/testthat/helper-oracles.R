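# Independent oracles used across test files. These deliberately take
# different computational routes from the package implementations.

# Exact HWE p-value via the conditional multinomial route: compute each
# compatible configuration's probability as a multinomial density under HWE
# proportions at the allele-frequency MLE, normalize over configurations with
# the same allele counts, and sum probabilities <= the observed one.
hwe_oracle_multinom <- function(n_ref_hom, n_het, n_alt_hom) {
  n <- n_ref_hom + n_het + n_alt_hom
  n1 <- 2 * n_alt_hom + n_het
  if (n1 == 0 || 2 * n - n1 == 0) return(1)
  q <- n1 / (2 * n)
  hets <- seq(n1 %% 2, min(n1, 2 * n - n1), by = 2)
  dens <- vapply(hets, function(h) {
    stats::dmultinom(c((2 * n - n1 - h) / 2, h, (n1 - h) / 2),
                     prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
  }, numeric(1))
  prob <- dens / sum(dens)
  p_obs <- prob[hets == n_het]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-9)]))
}

# Ground-truth oracle for very small samples: enumerate every placement of
# the rare alleles over the 2N ordered allele slots (slots (1,2), (3,4), ...
# form the diploids), tally the heterozygote-count distribution, and sum the
# tail. Feasible for 2N <= 12.
hwe_oracle_pairing <- function(n_ref_hom, n_het, n_alt_hom) {
  n <- n_ref_hom + n_het + n_alt_hom
  stopifnot(2 * n <= 12)
  n1 <- 2 * n_alt_hom + n_het
  if (n1 == 0 || n1 == 2 * n) return(1)
  slots <- utils::combn(2 * n, n1)
  het_of_placement <- apply(slots, 2, function(pos) {
    carrier <- tabulate(ceiling(pos / 2), nbins = n)
    sum(carrier == 1)
  })
  counts <- table(het_of_placement)
  prob <- as.numeric(counts) / sum(counts)
  obs <- prob[names(counts) == as.character(n_het)]
  min(1, sum(prob[prob <= obs * (1 + 1e-9)]))
}

# Chi-square goodness-of-fit p for HWE (1 df), expected counts from the
# observed allele frequency.
hwe_chisq_p <- function(n_ref_hom, n_het, n_alt_hom) {
  n <- n_ref_hom + n_het + n_alt_hom
  q <- (2 * n_alt_hom + n_het) / (2 * n)
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  stat <- sum((c(n_ref_hom, n_het, n_alt_hom) - expected)^2 / expected)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# Closed-form simple-regression slope, SE, p and R^2.
ols_closed_form <- function(x, y) {
  n <- length(x)
  beta <- stats::cov(x, y) / stats::var(x)
  alpha <- mean(y) - beta * mean(x)
  resid <- y - alpha - beta * x
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 / ((n - 1) * stats::var(x)))
  tstat <- beta / se
  list(beta = beta, se = se,
       p = 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE),
       r_squared = stats::cor(x, y)^2)
}

# Small genotype tibble for sweep-level tests.
toy_genotypes <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    subject_id = sprintf("S%05d", seq_len(n)),
    rs2472297 = stats::rbinom(n, 2, 0.27),
    rs6968865 = stats::rbinom(n, 2, 0.61)
  )
}
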