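test_that("wald_ratio divides outcome by exposure effects with linear SE", {
  inst <- toy_instruments(1, seed = 1)
  inst$beta_x <- 0.1
  assoc <- data.frame(snp_id = inst$snp_id, beta_y = 0.05, se_y = 0.02)
  wr <- wald_ratio(inst, assoc)
  expect_equal(wr$beta, 0.5)
  expect_equal(wr$se, 0.2)
  assoc$beta_y <- 0
  expect_equal(wald_ratio(inst, assoc)$beta, 0)
  assoc$se_y <- 0.04                      # doubling se_y doubles se exactly
  expect_equal(wald_ratio(inst, assoc)$se, 0.4)
  inst0 <- inst; inst0$beta_x <- 0
  expect_error(wald_ratio(inst0, assoc), "beta_x is zero")
  assoc$snp_id <- "rsX"
  expect_error(wald_ratio(inst, assoc), "mismatch")
})

test_that("single-SNP IVW reduces to the Wald ratio with zero Q", {
  inst <- toy_instruments(1, seed = 3)
  assoc <- toy_assocs(inst, seed = 3)
  res <- ivw_estimate(inst, assoc)
  wr <- wald_ratio(inst, assoc)
  expect_equal(res$beta, wr$beta, tolerance = 1e-12)
  expect_equal(res$se, wr$se, tolerance = 1e-12)
  expect_identical(res$q_stat, 0)
  expect_identical(res$q_df, 0L)
  expect_identical(res$q_pval, 1)
})

test_that("IVW equals origin-constrained weighted least squares to 1e-10", {
  for (seed in 1:5) {
    inst <- toy_instruments(9, seed = seed)
    assoc <- toy_assocs(inst, seed = seed + 50)
    res <- ivw_estimate(inst, assoc)
    w <- 1 / assoc$se_y^2
    slope <- wls_origin_slope(inst$beta_x, assoc$beta_y, w)
    expect_equal(res$beta, slope, tolerance = 1e-10)
    expect_equal(res$se, 1 / sqrt(sum(w * inst$beta_x^2)), tolerance = 1e-10)
    q <- sum(w * (assoc$beta_y - slope * inst$beta_x)^2)
    expect_equal(res$q_stat, q, tolerance = 1e-10)
    expect_equal(res$q_pval, pchisq(q, 8, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("IVW validates its inputs", {
  inst <- toy_instruments(3, seed = 2)
  assoc <- toy_assocs(inst, seed = 2)
  expect_error(ivw_estimate(inst, assoc[c(1, 1, 2), ]), "duplicated")
  expect_error(ivw_estimate(inst, transform(assoc, snp_id = paste0(snp_id, "x"))),
               "no SNPs shared")
  bad <- assoc; bad$se_y[2] <- 0
  expect_error(ivw_estimate(inst, bad), "se_y")
})

test_that("exposure rescaling equivariance: beta scales as 1/c, Q invariant", {
  inst <- toy_instruments(9, seed = 8)
  assoc <- toy_assocs(inst, seed = 9)
  res <- ivw_estimate(inst, assoc)
  scaled <- inst; scaled$beta_x <- scaled$beta_x * 4
  res4 <- ivw_estimate(scaled, assoc)
  expect_equal(res4$beta, res$beta / 4, tolerance = 1e-12)
  expect_equal(res4$q_stat, res$q_stat, tolerance = 1e-12)
  expect_equal(res4$q_pval, res$q_pval, tolerance = 1e-12)
  expect_equal(res4$per_snp_residual, res$per_snp_residual, tolerance = 1e-12)
})

test_that("Q is invariant under joint allele flips after re-harmonization", {
  inst <- toy_instruments(9, seed = 12)
  assoc <- toy_assocs(inst, seed = 13)
  res <- ivw_estimate(inst, assoc)
  flip <- c(2, 5)
  flipped <- inst
  flipped$beta_x[flip] <- -flipped$beta_x[flip]
  ea <- flipped$effect_allele[flip]
  flipped$effect_allele[flip] <- flipped$other_allele[flip]
  flipped$other_allele[flip] <- ea
  assoc2 <- assoc
  assoc2$beta_y[flip] <- -assoc2$beta_y[flip]   # outcome follows the flip
  reharm <- harmonize_orientation(flipped)
  assoc2$beta_y[flip] <- -assoc2$beta_y[flip]   # back to the long allele
  res2 <- ivw_estimate(reharm, assoc2)
  expect_equal(res2$beta, res$beta, tolerance = 1e-12)
  expect_equal(res2$q_stat, res$q_stat, tolerance = 1e-12)
})

test_that("perfect proportionality yields no pleiotropy flags", {
  inst <- toy_instruments(5, seed = 21)
  assoc <- toy_assocs(inst, seed = 1, slope = 0.7, noise = 0)
  res <- ivw_estimate(inst, assoc)
  expect_equal(max(abs(res$per_snp_residual)), 0, tolerance = 1e-12)
  expect_identical(flag_pleiotropic_snps(res), character(0))
})

test_that("flagging is invariant to SNP input order", {
  inst <- toy_instruments(9, seed = 31)
  assoc <- toy_assocs(inst, seed = 32, noise = 0.02)
  assoc$beta_y[4] <- assoc$beta_y[4] + 0.5    # gross outlier
  f1 <- flag_pleiotropic_snps(ivw_estimate(inst, assoc))
  perm <- sample(seq_len(9))
  f2 <- flag_pleiotropic_snps(ivw_estimate(inst[perm, ], assoc[rev(perm), ]))
  expect_identical(f1, f2)
  expect_true("rs004" %in% f1)
})

test_that("exclusion refit equals IVW on the reduced set", {
  inst <- toy_instruments(9, seed = 41)
  assoc <- toy_assocs(inst, seed = 42)
  # empty exclusion is the identity
  expect_equal(exclude_and_refit(inst, assoc, character(0)),
               ivw_estimate(inst, assoc))
  res8 <- exclude_and_refit(inst, assoc, "rs003")
  direct <- ivw_estimate(inst[inst$snp_id != "rs003", ],
                         assoc[assoc$snp_id != "rs003", ])
  expect_equal(res8, direct)
  expect_identical(res8$q_df, 7L)
  expect_error(exclude_and_refit(inst, assoc, inst$snp_id), "every instrument")
})

test_that("excluding a zero-residual SNP from an exact fit leaves beta unchanged", {
  inst <- toy_instruments(4, seed = 51)
  assoc <- toy_assocs(inst, seed = 1, slope = 1.2, noise = 0)
  res <- ivw_estimate(inst, assoc)
  res3 <- exclude_and_refit(inst, assoc, "rs002")
  expect_equal(res3$beta, res$beta, tolerance = 1e-12)
})

test_that("between-study Q matches the hand-computed meta-analysis oracle", {
  # trivial cases
  h <- between_study_q(c(0.4, 0.4), c(0.1, 0.1))
  expect_equal(h$q, 0)
  expect_equal(h$pval, 1)
  expect_equal(between_study_q(c(0.2, 0.6), c(0.1, 0.1))$pooled_beta, 0.4)
  # 3-study fixture, worked by hand: w = 1/se^2 = (100, 25, 4)
  b <- c(0.50, 0.30, -0.20); se <- c(0.10, 0.20, 0.50)
  pooled <- (100 * 0.5 + 25 * 0.3 + 4 * -0.2) / 129        # = 0.4426357
  q <- 100 * (0.5 - pooled)^2 + 25 * (0.3 - pooled)^2 + 4 * (-0.2 - pooled)^2
  res <- between_study_q(b, se)
  expect_equal(res$pooled_beta, pooled, tolerance = 1e-12)
  expect_equal(res$q, q, tolerance = 1e-12)
  expect_identical(res$df, 2L)
  expect_equal(res$pval, pchisq(q, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(between_study_q(0.3, 0.1), "two studies")
})

test_that("se_from_ci inverts the symmetric Wald interval", {
  expect_equal(se_from_ci(exp(1), exp(1 - 1.96 * 0.5), exp(1 + 1.96 * 0.5)),
               0.5, tolerance = 1e-12)
  # published-style row: OR 1.33 (1.26, 1.39)
  expect_equal(se_from_ci(1.33, 1.26, 1.39),
               (log(1.39) - log(1.26)) / 3.92, tolerance = 1e-12)
  expect_identical(se_from_ci(1.2, 1.2, 1.2), 0)
  expect_error(assoc_from_or_ci("rs1", 1.2, 1.2, 1.2), "degenerate")
  expect_error(se_from_ci(-1, 0.5, 2), "positive")
  expect_error(se_from_ci(1.0, 1.1, 1.2), "ci_low <= or_value")
})

test_that("Q p-values are uniform without pleiotropy (summary-level null)", {
  reps <- 400
  set.seed(202)
  inst <- toy_instruments(9, seed = 77)
  gamma <- 0.4
  pvals <- vapply(seq_len(reps), function(r) {
    se <- runif(9, 0.03, 0.08)
    assoc <- data.frame(snp_id = inst$snp_id,
                        beta_y = rnorm(9, gamma * inst$beta_x, se),
                        se_y = se)
    ivw_estimate(inst, assoc)$q_pval
  }, numeric(1))
  rej <- sum(pvals < 0.05)
  band <- qbinom(c(0.025, 0.975), reps, 0.05)
  expect_gte(rej, band[1])
  expect_lte(rej, band[2])
})
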