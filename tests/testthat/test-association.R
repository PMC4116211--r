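# Additive association machinery: simple regression, variance explained,
# non-additivity tests and the table-shaped sweep.

test_that("additive regression matches the closed-form slope, SE, p and R^2", {
  res <- ols_additive(c(1, 2, 4), c(0, 1, 2))
  expect_equal(res$beta, 1.5)
  set.seed(21)
  for (i in 1:10) {
    n <- sample(10:200, 1)
    x <- stats::rnorm(n)
    y <- 0.5 * x + stats::rnorm(n)
    fit <- ols_additive(y, x)
    oracle <- ols_closed_form(x, y)
    expect_equal(fit$beta, oracle$beta, tolerance = 1e-10)
    expect_equal(fit$se, oracle$se, tolerance = 1e-10)
    expect_equal(fit$p_value, oracle$p, tolerance = 1e-10)
    expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-10)
  }
})

test_that("perfect, flat and degenerate fits behave as contracted", {
  x <- c(0, 1, 2, 1, 0)
  perfect <- suppressWarnings(ols_additive(2 * x, x))
  expect_equal(perfect$beta, 2)
  expect_equal(perfect$r_squared, 1)
  flat <- suppressWarnings(ols_additive(rep(3, 5), x))
  expect_equal(flat$beta, 0)
  expect_equal(flat$r_squared, 0)
  expect_error(ols_additive(c(1, 2, 3), rep(1, 3)), "zero variance")
  expect_error(ols_additive(c(1, NA), c(1, 2, 3)), "length")
  expect_error(ols_additive(c(1, 2, NA), c(1, 2, 3)), "fewer than 3")
})

test_that("regression is equivariant under phenotype shift and scale", {
  set.seed(4)
  x <- stats::rbinom(100, 4, 0.4)
  y <- 2 + 0.3 * x + stats::rnorm(100)
  base <- ols_additive(y, x)
  shifted <- ols_additive(y + 11, x)
  expect_equal(shifted$beta, base$beta)
  expect_equal(shifted$se, base$se)
  scaled <- ols_additive(3 * y, x)
  expect_equal(scaled$beta, 3 * base$beta)
  expect_equal(scaled$se, 3 * base$se)
  expect_equal(scaled$r_squared, base$r_squared)
})

test_that("fitted R^2 equals the analytic variance explained at the fitted beta", {
  set.seed(9)
  x <- stats::rbinom(500, 4, 0.4)
  y <- 10 * x + stats::rnorm(500, 0, 30)
  fit <- ols_additive(y, x)
  expect_equal(fit$r_squared,
               variance_explained_analytic(fit$beta, stats::var(x), stats::var(y)),
               tolerance = 1e-10)
})

test_that("analytic variance explained behaves at its edges and matches simulation", {
  expect_equal(variance_explained_analytic(0, 1, 1), 0)
  expect_equal(variance_explained_analytic(1, 4, 4), 1)
  expect_error(variance_explained_analytic(1, 0, 1), "positive")
  # single-SNP case: analytic value vs empirical R^2 of a large simulation
  q <- 0.27; beta <- 21.4; sd_y <- 144.9
  analytic <- variance_explained_analytic(beta, hwe_score_variance(q), sd_y^2)
  set.seed(123)
  g <- stats::rbinom(200000, 2, q)
  y <- beta * g + stats::rnorm(200000, 0, sqrt(sd_y^2 - beta^2 * hwe_score_variance(q)))
  expect_equal(ols_additive(y, g)$r_squared, analytic, tolerance = 0.05)
})

test_that("dominance test flags pure dominance and not additive truth", {
  set.seed(31)
  g <- stats::rbinom(2000, 2, 0.4)
  additive <- dominance_test(3 + 2 * g + stats::rnorm(2000), g)
  expect_lt(abs(additive$term_estimate), 0.2)
  pure <- suppressWarnings(dominance_test(as.numeric(g == 1), g))
  expect_gt(abs(pure$term_estimate), 0.9)
  expect_lt(pure$p_value, 1e-10)
  expect_error(dominance_test(stats::rnorm(5), c(0, 0, 1, 1, 1)), "class")
})

test_that("interaction test flags epistasis and not additive truth", {
  set.seed(32)
  g1 <- stats::rbinom(2000, 2, 0.3)
  g2 <- stats::rbinom(2000, 2, 0.6)
  additive <- interaction_test(2 * g1 + 3 * g2 + stats::rnorm(2000), g1, g2)
  expect_lt(abs(additive$term_estimate), 0.2)
  epi <- interaction_test(g1 * g2 + stats::rnorm(2000, 0, 0.01), g1, g2)
  expect_equal(epi$term_estimate, 1, tolerance = 0.01)
  expect_error(interaction_test(stats::rnorm(10), rep(1, 10), stats::rbinom(10, 2, 0.5)),
               "polymorphic")
})

sim_sweep_inputs <- function(n = 400, seed = 2,
                             tps = c("8wk", "47mo", "145mo")) {
  geno <- toy_genotypes(n, seed)
  set.seed(seed + 1)
  ph <- dplyr::bind_rows(lapply(tps, function(tp) tibble::tibble(
    subject_id = geno$subject_id, time_point = tp,
    total_caffeine_mg = 200 + 10 * geno$rs2472297 + stats::rnorm(n, 0, 100),
    coffee_per_day = stats::rexp(n), tea_per_day = stats::rexp(n),
    cola_per_day = stats::rexp(n)
  )))
  list(genotypes = geno, phenotypes = ph)
}

test_that("association sweep has the contracted row structure and ordering", {
  inp <- sim_sweep_inputs()
  sw <- association_sweep(inp$phenotypes, inp$genotypes,
                          phenotype_cols = "total_caffeine_mg")
  expect_equal(nrow(sw), 3 * 3)  # 3 time points x 3 predictors
  expect_identical(unique(sw$time_point), c("8wk", "47mo", "145mo"))
  full <- association_sweep(inp$phenotypes, inp$genotypes)
  expect_equal(nrow(full), 3 * 4 * 3)
  weighted <- association_sweep(inp$phenotypes, inp$genotypes,
                                weights = snp_info()$weight)
  expect_equal(nrow(weighted), 3 * 4 * 4)
  expect_true("weighted" %in% weighted$predictor_label)
})

test_that("sweep cells are independent and deterministic", {
  inp <- sim_sweep_inputs()
  full <- association_sweep(inp$phenotypes, inp$genotypes)
  no_cola <- association_sweep(inp$phenotypes[setdiff(names(inp$phenotypes), "cola_per_day")],
                               inp$genotypes)
  expect_false(any(no_cola$phenotype_label == "cola_per_day"))
  expect_equal(no_cola, full[full$phenotype_label != "cola_per_day", ],
               ignore_attr = TRUE)
  expect_identical(full, association_sweep(inp$phenotypes, inp$genotypes))
  expect_error(association_sweep(inp$phenotypes[0, ], inp$genotypes),
               "no subjects")
})

test_that("zero-consumer sensitivity drops only zero values", {
  inp <- sim_sweep_inputs()
  # strictly positive data: sensitivity sweep equals the plain sweep
  pos <- inp$phenotypes
  pos$total_caffeine_mg <- abs(pos$total_caffeine_mg) + 1
  expect_equal(zero_consumer_sensitivity(pos, inp$genotypes,
                                         phenotype_cols = "total_caffeine_mg"),
               association_sweep(pos, inp$genotypes,
                                 phenotype_cols = "total_caffeine_mg"))
  # an all-zero beverage is flagged, not fatal
  zero <- inp$phenotypes
  zero$cola_per_day <- 0
  sens <- zero_consumer_sensitivity(zero, inp$genotypes)
  cola_rows <- sens[sens$phenotype_label == "cola_per_day", ]
  expect_true(all(is.na(cola_rows$beta)))
  expect_true(all(cola_rows$note != ""))
})

test_that("genotype-independent zeros do not shift null betas beyond MC noise", {
  set.seed(77)
  reps <- 40
  diffs <- replicate(reps, {
    g <- stats::rbinom(800, 2, 0.4)
    y <- stats::rnorm(800, 30, 20)          # no genetic effect
    y0 <- ifelse(stats::runif(800) > 0.3, y, 0)
    ols_additive(y0, g)$beta -
      ols_additive(ifelse(y0 > 0, y0, NA), g)$beta
  })
  expect_lt(abs(mean(diffs)), 2 * stats::sd(diffs) / sqrt(reps))
})
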