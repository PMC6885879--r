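#' Wald ratio for a single instrument
#'
#' The per-SNP causal estimate `beta_y / beta_x` with first-order standard
#' error `se_y / |beta_x|` (exposure-side uncertainty ignored, as in the
#' standard summary-data estimator).
#'
#' @param inst single-row instrument table (exposure side).
#' @param assoc single-row summary association (outcome side) with the
#'   same `snp_id`.
#' @return list with `beta` and `se`, log-OR per kb of TL.
#' @export
wald_ratio <- function(inst, assoc) {
  inst <- instruments(inst)
  if (nrow(inst) != 1L || NROW(assoc) != 1L)
    abort("wald_ratio takes exactly one instrument and one association")
  if (inst$snp_id != assoc$snp_id)
    abort("snp_id mismatch: ", inst$snp_id, " vs ", assoc$snp_id)
  if (inst$beta_x == 0) abort("beta_x is zero for ", inst$snp_id)
  if (assoc$se_y <= 0) abort("se_y must be positive for ", inst$snp_id)
  list(beta = assoc$beta_y / inst$beta_x,
       se = assoc$se_y / abs(inst$beta_x))
}

# join instrument and association tables by snp_id with error checks
join_snp <- function(instruments, assocs) {
  inst <- instruments(instruments)
  if (anyDuplicated(assocs$snp_id))
    abort("duplicated snp_id in associations: ",
          paste(unique(assocs$snp_id[duplicated(assocs$snp_id)]),
                collapse = ", "))
  common <- intersect(inst$snp_id, assocs$snp_id)
  if (length(common) == 0) abort("no SNPs shared between instruments and associations")
  i <- inst[match(common, inst$snp_id), , drop = FALSE]
  a <- assocs[match(common, assocs$snp_id), , drop = FALSE]
  if (any(a$se_y <= 0))
    abort("non-positive se_y for: ",
          paste(common[a$se_y <= 0], collapse = ", "))
  if (any(i$unit != "kb")) abort("instruments must be in kb")
  list(inst = i, assoc = a, snp_id = common)
}

#' Inverse-variance-weighted MR estimate
#'
#' Fixed-effect IVW combination of per-SNP Wald ratios; algebraically the
#' weighted least-squares slope of outcome effects `beta_y` on exposure
#' effects `beta_x` through the origin with weights `1 / se_y^2`:
#' \deqn{\hat\beta = \frac{\sum_j \beta_{Xj}\beta_{Yj}\sigma_{Yj}^{-2}}
#'                        {\sum_j \beta_{Xj}^2\sigma_{Yj}^{-2}},\qquad
#'       \mathrm{se} = \Big(\sum_j \beta_{Xj}^2\sigma_{Yj}^{-2}\Big)^{-1/2}.}
#' Cochran's Q over the instruments,
#' `q = sum_j (beta_y_j - beta * beta_x_j)^2 / se_y_j^2` on `J - 1` df,
#' tests proportionality of SNP-exposure and SNP-outcome effects — the
#' pleiotropy (exclusion-restriction) diagnostic. Standardized per-SNP
#' residuals `(beta_y_j - beta * beta_x_j) / se_y_j` localize violations.
#'
#' @param instruments harmonized kb-scale instrument table.
#' @param assocs `mr_summary_assoc` table (one row per SNP).
#' @return An object of class `ivw_result`: `beta`, `se`, `or_value`,
#'   `ci_low`, `ci_high`, `pval` (two-sided normal), `q_stat`, `q_df`,
#'   `q_pval`, `per_snp_residual` (named), `snp_id`. OR is per 1-kb TL.
#'   With a single SNP `q_stat = 0`, `q_df = 0` and `q_pval = 1`.
#' @export
ivw_estimate <- function(instruments, assocs) {
  j <- join_snp(instruments, assocs)
  bx <- j$inst$beta_x; by <- j$assoc$beta_y; w <- 1 / j$assoc$se_y^2
  denom <- sum(bx^2 * w)
  if (denom == 0) abort("all beta_x are zero; no identifying variation")
  beta <- sum(bx * by * w) / denom
  se <- 1 / sqrt(denom)
  resid <- (by - beta * bx) / j$assoc$se_y
  q <- sum(resid^2)
  J <- length(bx)
  q_df <- J - 1L
  z <- qnorm(0.975)
  structure(list(
    beta = beta, se = se, or_value = exp(beta),
    ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
    pval = 2 * pnorm(-abs(beta / se)),
    q_stat = if (J == 1L) 0 else q, q_df = q_df,
    q_pval = if (q_df == 0L) 1 else pchisq(q, q_df, lower.tail = FALSE),
    per_snp_residual = setNames(resid, j$snp_id),
    snp_id = j$snp_id, n_snps = J),
    class = "ivw_result")
}

#' @export
print.ivw_result <- function(x, ...) {
  cat(sprintf("<ivw_result> %d SNP(s): OR per kb = %.3f [95%% CI %.3f, %.3f], p = %.3g\n",
              x$n_snps, x$or_value, x$ci_low, x$ci_high, x$pval))
  cat(sprintf("  pleiotropy/heterogeneity: Q = %.3f on %d df, p = %.3g\n",
              x$q_stat, x$q_df, x$q_pval))
  invisible(x)
}

#' Flag instruments with pleiotropic outcome effects
#'
#' A SNP whose outcome effect is disproportionate to its exposure effect
#' shows a large standardized IVW residual. Each residual is referred to
#' the standard normal two-sided tail and flagged when below
#' `alpha / J` (Bonferroni over the J instruments). Result is ordered by
#' decreasing residual magnitude and independent of input order.
#'
#' @param result an `ivw_result` with at least two SNPs.
#' @param alpha familywise significance level, default 0.05.
#' @return character vector of flagged snp_ids (possibly empty).
#' @export
flag_pleiotropic_snps <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "ivw_result"))
  if (result$n_snps < 2L) abort("pleiotropy flagging needs at least 2 SNPs")
  r <- result$per_snp_residual
  p <- 2 * pnorm(-abs(r))
  flagged <- names(r)[p < alpha / length(r)]
  flagged[order(-abs(r[flagged]))]
}

#' Refit the IVW estimate excluding named SNPs
#'
#' Sensitivity analysis: rerun [ivw_estimate()] on the instrument set
#' minus `exclude` (for example a SNP failing the pleiotropy test), with
#' the Q degrees of freedom reduced accordingly.
#'
#' @inheritParams ivw_estimate
#' @param exclude character vector of snp_ids to drop (may be empty).
#' @return An `ivw_result` on the reduced set.
#' @export
exclude_and_refit <- function(instruments, assocs, exclude = character(0)) {
  inst <- instruments(instruments)
  keep <- !inst$snp_id %in% exclude
  if (!any(keep)) abort("exclusion removes every instrument")
  ivw_estimate(inst[keep, , drop = FALSE],
               assocs[!assocs$snp_id %in% exclude, , drop = FALSE])
}

#' Between-study heterogeneity of MR estimates
#'
#' Fixed-effect inverse-variance pooling of per-study estimates with
#' Cochran's Q: `q = sum_s (beta_s - pooled)^2 / se_s^2` on `S - 1` df.
#'
#' @param betas per-study estimates (log-OR per kb).
#' @param ses matching standard errors, all positive.
#' @return list with `pooled_beta`, `pooled_se`, `q`, `df`, `pval`.
#' @export
between_study_q <- function(betas, ses) {
  if (length(betas) < 2L) abort("need at least two studies")
  if (length(betas) != length(ses)) abort("betas and ses differ in length")
  if (any(ses <= 0)) abort("standard errors must be positive")
  w <- 1 / ses^2
  pooled <- sum(w * betas) / sum(w)
  q <- sum(w * (betas - pooled)^2)
  df <- length(betas) - 1L
  list(pooled_beta = pooled, pooled_se = 1 / sqrt(sum(w)),
       q = q, df = df, pval = pchisq(q, df, lower.tail = FALSE))
}

#' Standard error from a symmetric-Wald 95% confidence interval
#'
#' Recovers the log-scale standard error of a published odds ratio from
#' its 95% CI under the symmetric-Wald assumption:
#' `se = (log(ci_high) - log(ci_low)) / (2 * 1.96)`. A zero-width CI
#' yields `se = 0`, which downstream constructors reject as degenerate.
#'
#' @param or_value,ci_low,ci_high odds ratio and CI bounds, all positive,
#'   with `ci_low <= or_value <= ci_high`.
#' @return the standard error (log-OR scale).
#' @export
se_from_ci <- function(or_value, ci_low, ci_high) {
  if (any(c(or_value, ci_low, ci_high) <= 0))
    abort("odds ratio and CI bounds must be positive")
  if (ci_low > or_value || or_value > ci_high)
    abort("require ci_low <= or_value <= ci_high")
  (log(ci_high) - log(ci_low)) / (2 * 1.96)
}
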