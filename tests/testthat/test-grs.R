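make_toy_cohort_matrix <- function(n, inst, seed = 1, case = NULL) {
  set.seed(seed)
  dos <- vapply(inst$maf, function(p) rbinom(n, 2, p), numeric(n))
  colnames(dos) <- inst$snp_id
  rownames(dos) <- sprintf("id%04d", seq_len(n))
  if (is.null(case)) case <- rep(0:1, length.out = n)
  ph <- data.frame(sample_id = rownames(dos), case = case,
                   age = rnorm(n, 60, 8), sex = rbinom(n, 1, 0.5),
                   stringsAsFactors = FALSE)
  mr_cohort(dos, ph)
}

test_that("compute_grs equals the elementwise double-loop oracle", {
  inst <- toy_instruments(9, seed = 4)
  co <- make_toy_cohort_matrix(5, inst, seed = 4)
  grs <- compute_grs(co, inst)
  oracle <- numeric(5)
  for (i in 1:5)
    for (j in 1:9)
      oracle[i] <- oracle[i] + inst$beta_x[j] * co$dosages[i, j]
  expect_equal(grs$grs, oracle, tolerance = 1e-12)
})

test_that("compute_grs handles degenerate weights and single terms", {
  inst <- toy_instruments(3, seed = 1)
  co <- make_toy_cohort_matrix(4, inst, seed = 2)
  zero <- inst; zero$beta_x <- 0
  expect_identical(compute_grs(co, zero)$grs, rep(0, 4))
  one <- inst[1, ]; one$beta_x <- 0.1
  co$dosages[, 1] <- 2
  expect_equal(compute_grs(co, one)$grs, rep(0.2, 4))
})

test_that("missing-dosage policies drop or impute at 2*maf", {
  inst <- toy_instruments(3, seed = 6)
  co <- make_toy_cohort_matrix(6, inst, seed = 6)
  co$dosages[2, 1] <- NA
  dropped <- compute_grs(co, inst, missing_policy = "drop")
  expect_identical(attr(dropped, "dropped"), rownames(co$dosages)[2])
  expect_identical(nrow(dropped), 5L)
  imputed <- compute_grs(co, inst, missing_policy = "mean_impute")
  expect_identical(nrow(imputed), 6L)
  manual <- sum(c(2 * inst$maf[1], co$dosages[2, 2:3]) * inst$beta_x)
  expect_equal(imputed$grs[2], manual)
  expect_error(compute_grs(co, transform(inst, unit = "bp")), "kb")
})

test_that("fit_grs_logistic matches the IRLS oracle on a 300-row fixture", {
  co <- toy_cohort(150, 150, seed = 33)
  inst <- co$config$instruments
  grs <- compute_grs(co, inst)
  covs <- c("age", "sex", "pack_years", "pc1", "study")
  fit <- fit_grs_logistic(grs, co, covs)
  d <- data.frame(case = co$phenotype$case, grs = grs$grs,
                  co$phenotype[covs])
  X <- design_matrix(d, "grs", covs)
  o <- irls_logistic(X, d$case)
  expect_equal(log(fit$or_value), o$coef[["grs"]], tolerance = 1e-6)
  expect_equal(fit$se, sqrt(o$vcov["grs", "grs"]), tolerance = 1e-6)
  expect_equal(fit$pval, 2 * pnorm(-abs(o$coef[["grs"]] /
                                          sqrt(o$vcov["grs", "grs"]))),
               tolerance = 1e-6)
})

test_that("rescaling weights by c divides the GRS log-OR by exactly 1/c", {
  co <- toy_cohort(200, 200, seed = 9)
  inst <- co$config$instruments
  fit1 <- fit_grs_logistic(compute_grs(co, inst), co)
  scaled <- inst; scaled$beta_x <- scaled$beta_x * 3
  fit3 <- fit_grs_logistic(compute_grs(co, scaled), co)
  expect_equal(log(fit3$or_value), log(fit1$or_value) / 3, tolerance = 1e-6)
  expect_equal(fit3$pval, fit1$pval, tolerance = 1e-6)
})

test_that("adding a constant to every GRS leaves the estimate unchanged", {
  co <- toy_cohort(200, 200, seed = 10)
  grs <- compute_grs(co, co$config$instruments)
  fit1 <- fit_grs_logistic(grs, co)
  grs$grs <- grs$grs + 5
  fit2 <- fit_grs_logistic(grs, co)
  expect_equal(fit2$or_value, fit1$or_value, tolerance = 1e-6)
  expect_equal(fit2$ci_low, fit1$ci_low, tolerance = 1e-6)
  expect_equal(fit2$pval, fit1$pval, tolerance = 1e-6)
})

test_that("degenerate GRS inputs are rejected", {
  inst <- toy_instruments(2, seed = 2)
  co <- make_toy_cohort_matrix(30, inst, seed = 3)
  zero <- inst; zero$beta_x <- 0
  expect_error(fit_grs_logistic(compute_grs(co, zero), co,
                                covariates = character(0)),
               "constant")
  co1 <- make_toy_cohort_matrix(30, inst, seed = 3, case = rep(1, 30))
  expect_error(fit_grs_logistic(compute_grs(co1, inst), co1,
                                covariates = character(0)),
               "both outcome classes")
})

test_that("aggregate test reduces to the null on zero SNPs and is order-invariant", {
  co <- toy_cohort(150, 150, seed = 19)
  inst <- co$config$instruments
  none <- aggregate_test(co, inst[0, ], covariates = c("age", "sex"))
  expect_identical(none$statistic, 0)
  expect_identical(none$pval, 1)
  a <- aggregate_test(co, inst, covariates = c("age", "sex"))
  b <- aggregate_test(co, inst[rev(seq_len(nrow(inst))), ],
                      covariates = c("age", "sex"))
  expect_equal(a$statistic, b$statistic, tolerance = 1e-8)
  expect_identical(a$df, 9L)
  # cross-check against direct log-likelihoods
  d <- data.frame(case = co$phenotype$case, co$phenotype[c("age", "sex")],
                  co$dosages)
  ll0 <- as.numeric(logLik(glm(case ~ age + sex, binomial, d)))
  ll1 <- as.numeric(logLik(glm(case ~ ., binomial, d[, c("case", "age", "sex",
                                                         inst$snp_id)])))
  expect_equal(a$statistic, 2 * (ll1 - ll0), tolerance = 1e-8)
  expect_equal(a$pval, pchisq(a$statistic, 9, lower.tail = FALSE))
})

test_that("aggregate-test statistic is null-calibrated", {
  reps <- 120
  pvals <- vapply(seq_len(reps), function(r) {
    co <- simulate_cohort(sim_config(250, 250, causal_log_or_per_kb = 0,
                                     seed = 5000 + r))
    aggregate_test(co, co$config$instruments,
                   covariates = c("age", "sex"))$pval
  }, numeric(1))
  rej <- sum(pvals < 0.05)
  band <- qbinom(c(0.025, 0.975), reps, 0.05)
  expect_gte(rej, band[1])
  expect_lte(rej, band[2])
})

test_that("decile analysis partitions 1..100 into ten groups of ten", {
  inst <- toy_instruments(1, seed = 1)
  set.seed(44)
  n <- 100
  dos <- matrix(rbinom(n, 2, 0.3), ncol = 1,
                dimnames = list(sprintf("i%03d", 1:n), inst$snp_id))
  ph <- data.frame(sample_id = rownames(dos), case = rep(0:1, 50))
  co <- mr_cohort(dos, ph)
  grs <- compute_grs(co, inst)
  grs$grs <- as.numeric(1:100)          # exact no-tie ladder
  res <- decile_analysis(grs, co, covariates = character(0))
  expect_identical(res$per_decile$n, rep(10L, 10))
  expect_identical(res$per_decile$or_value[1], 1)   # reference decile
  expect_true(is.na(res$per_decile$pval[1]))
})

test_that("decile trend OR equals the IRLS oracle with the index covariate", {
  co <- toy_cohort(250, 250, seed = 23)
  grs <- compute_grs(co, co$config$instruments)
  covs <- c("age", "sex")
  res <- decile_analysis(grs, co, covariates = covs)
  breaks <- quantile(grs$grs, probs = seq(0, 1, 0.1), names = FALSE)
  decile <- .bincode(grs$grs, breaks, right = TRUE, include.lowest = TRUE)
  d <- data.frame(case = co$phenotype$case, decile = decile,
                  co$phenotype[covs])
  X <- design_matrix(d, "decile", covs)
  o <- irls_logistic(X, d$case)
  expect_equal(log(res$trend$or_value), o$coef[["decile"]], tolerance = 1e-6)
})

test_that("heavy boundary ties raise a decile error naming the boundary", {
  inst <- toy_instruments(1, seed = 2)
  dos <- matrix(rbinom(100, 2, 0.3), ncol = 1,
                dimnames = list(sprintf("i%03d", 1:100), inst$snp_id))
  ph <- data.frame(sample_id = rownames(dos), case = rep(0:1, 50))
  co <- mr_cohort(dos, ph)
  grs <- compute_grs(co, inst)
  grs$grs <- c(rep(1, 50), seq(2, length.out = 50))  # half the mass tied at 1
  expect_error(decile_analysis(grs, co, covariates = character(0)),
               "ties at boundary 1")
})
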