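#' Weighted genetic risk score for telomere length
#'
#' Computes `GRS_i = sum_j beta_x_j * x_ij`, the genetically predicted TL
#' of individual i (kb, up to an additive constant), from harmonized
#' kb-scale instrument weights and effect-allele dosage counts.
#'
#' @param cohort an `mr_cohort`.
#' @param instruments harmonized instrument table (unit kb, `beta_x >= 0`);
#'   every snp_id must be a dosage column.
#' @param missing_policy `"drop"` (default): individuals with any missing
#'   dosage are omitted and their ids recorded in the `dropped` attribute;
#'   `"mean_impute"`: a missing dosage is replaced by its Hardy-Weinberg
#'   expectation `2 * maf_j`.
#' @return data.frame of class `grs_vector` with columns `sample_id`,
#'   `grs`.
#' @export
compute_grs <- function(cohort, instruments,
                        missing_policy = c("drop", "mean_impute")) {
  stopifnot(inherits(cohort, "mr_cohort"))
  missing_policy <- match.arg(missing_policy)
  inst <- instruments(instruments)
  if (any(inst$unit != "kb")) abort("instrument weights must be in kb")
  absent <- setdiff(inst$snp_id, colnames(cohort$dosages))
  if (length(absent))
    abort("instrument(s) absent from dosage columns: ",
          paste(absent, collapse = ", "))
  x <- cohort$dosages[, inst$snp_id, drop = FALSE]
  dropped <- character(0)
  if (anyNA(x)) {
    if (missing_policy == "drop") {
      bad <- rowSums(is.na(x)) > 0
      dropped <- rownames(x)[bad]
      x <- x[!bad, , drop = FALSE]
    } else {
      for (j in seq_len(ncol(x))) {
        mis <- is.na(x[, j])
        if (any(mis)) x[mis, j] <- 2 * inst$maf[j]
      }
    }
  }
  res <- data.frame(sample_id = rownames(x),
                    grs = as.vector(x %*% inst$beta_x),
                    stringsAsFactors = FALSE)
  attr(res, "dropped") <- dropped
  class(res) <- c("grs_vector", "data.frame")
  res
}

# align a grs_vector with a cohort's phenotype rows, with covariates
grs_frame <- function(grs, cohort, covariates) {
  ph <- cohort$phenotype
  m <- match(grs$sample_id, ph$sample_id)
  if (anyNA(m)) abort("GRS sample ids not found in cohort phenotype")
  missing_cov <- setdiff(covariates, names(ph))
  if (length(missing_cov))
    abort("covariate(s) absent from phenotype: ",
          paste(missing_cov, collapse = ", "))
  d <- data.frame(case = ph$case[m], grs = grs$grs,
                  ph[m, covariates, drop = FALSE],
                  check.names = FALSE)
  d[complete.cases(d), , drop = FALSE]
}

mr_estimate <- function(scale, est, se, pval = NULL, n_cases, n_controls,
                        covariates) {
  z <- qnorm(0.975)
  structure(list(scale = scale, or_value = exp(est),
                 ci_low = exp(est - z * se), ci_high = exp(est + z * se),
                 log_or = est, se = se,
                 pval = if (is.null(pval)) 2 * pnorm(-abs(est / se)) else pval,
                 n_cases = n_cases, n_controls = n_controls,
                 covariates = covariates),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> OR (%s) = %.3f [95%% CI %.3f, %.3f], p = %.3g (%d cases / %d controls)\n",
              x$scale, x$or_value, x$ci_low, x$ci_high, x$pval,
              x$n_cases, x$n_controls))
  invisible(x)
}

#' Logistic MR estimate from the weighted GRS
#'
#' Maximum-likelihood logistic regression of case status on the GRS plus
#' covariates (a `study` covariate enters as indicator variables). The
#' exponentiated GRS coefficient is the odds ratio per 1-kb increase in
#' genetically predicted TL, with Wald 95% CI and two-sided Wald p.
#'
#' @param grs a [compute_grs()] result.
#' @param cohort the matching `mr_cohort`.
#' @param covariates phenotype columns to adjust for.
#' @param stratum optional histology stratum (cases of that stratum vs all
#'   controls).
#' @return An `mr_estimate` with scale `"per-kb"`.
#' @export
fit_grs_logistic <- function(grs, cohort,
                             covariates = c("age", "sex", "pack_years",
                                            "pc1", "study"),
                             stratum = NULL) {
  cohort <- stratum_subset(cohort, stratum)
  grs <- grs[grs$sample_id %in% cohort$phenotype$sample_id, , drop = FALSE]
  d <- grs_frame(grs, cohort, covariates)
  if (length(unique(d$case)) < 2L) abort("both outcome classes required")
  if (length(unique(d$grs)) < 2L) abort("GRS is constant; cannot fit")
  fit <- fit_logistic(case ~ grs, d, covariates, label = "GRS model")
  co <- summary_coef(fit, "grs")
  mr_estimate("per-kb", co[["est"]], co[["se"]],
              n_cases = sum(d$case == 1), n_controls = sum(d$case == 0),
              covariates = covariates)
}

#' Aggregate likelihood-ratio test of all instruments
#'
#' Log-likelihood-ratio test comparing the covariates-only logistic model
#' with the model adding every TL-associated SNP dosage, measuring the
#' total outcome association of the instrument set.
#'
#' @inheritParams per_snp_outcome_stats
#' @param covariates phenotype columns present in both models.
#' @return list with `statistic` (`2 * (ll_full - ll_null)`), `df`
#'   (number of SNP terms) and `pval` (upper chi-square tail).
#' @export
aggregate_test <- function(cohort, instruments,
                           covariates = c("age", "sex", "pack_years",
                                          "pc1", "study"),
                           stratum = NULL) {
  stopifnot(inherits(cohort, "mr_cohort"))
  inst <- instruments(instruments)
  cohort <- stratum_subset(cohort, stratum)
  absent <- setdiff(inst$snp_id, colnames(cohort$dosages))
  if (length(absent))
    abort("instrument(s) absent from dosage columns: ",
          paste(absent, collapse = ", "))
  ph <- cohort$phenotype
  snp_cols <- inst$snp_id
  d <- data.frame(case = ph$case, ph[covariates],
                  check.names = FALSE)
  if (length(snp_cols))
    d <- cbind(d, as.data.frame(cohort$dosages[, snp_cols, drop = FALSE]))
  d <- d[complete.cases(d), , drop = FALSE]
  null_fit <- fit_logistic(case ~ 1, d, covariates, label = "null model")
  if (length(snp_cols) == 0L)
    return(list(statistic = 0, df = 0L, pval = 1))
  full_fit <- fit_logistic(stats::reformulate(sprintf("`%s`", snp_cols),
                                              response = "case"),
                           d, covariates, label = "full model")
  if (stats::nobs(null_fit) != stats::nobs(full_fit))
    abort("null and full models fitted on different sample sets")
  stat <- max(0, 2 * (as.numeric(logLik(full_fit)) - as.numeric(logLik(null_fit))))
  df <- length(snp_cols)
  list(statistic = stat, df = df, pval = pchisq(stat, df, lower.tail = FALSE))
}

#' GRS decile analysis
#'
#' Categorizes the weighted GRS into `n_groups` groups by its decile
#' distribution in all participants (cases and controls pooled), fits
#' per-group ORs against the lowest decile, and a trend OR treating the
#' decile index 1..10 as a continuous covariate.
#'
#' Boundaries are left-open/right-closed, so a value tied with a cut point
#' falls in the lower decile; group sizes then differ only by boundary
#' ties.
#'
#' @param grs a [compute_grs()] result.
#' @param cohort the matching `mr_cohort`.
#' @param covariates phenotype columns to adjust for.
#' @param n_groups number of quantile groups, default 10.
#' @param stratum optional histology stratum.
#' @return list with `per_decile` (data.frame: decile, or_value, ci_low,
#'   ci_high, pval, n; decile 1 is the reference with OR 1) and `trend`
#'   (an `mr_estimate` with scale `"per-decile"`).
#' @export
decile_analysis <- function(grs, cohort,
                            covariates = c("age", "sex", "pack_years",
                                           "pc1", "study"),
                            n_groups = 10, stratum = NULL) {
  if (length(unique(grs$grs)) < n_groups)
    abort("need at least ", n_groups, " distinct GRS values")
  # cut points from the pooled distribution, before any stratum subsetting
  breaks <- quantile(grs$grs, probs = seq(0, 1, length.out = n_groups + 1),
                     names = FALSE, type = 7)
  if (anyDuplicated(breaks))
    abort("decile group(s) empty due to ties at boundary ",
          paste(unique(signif(breaks[duplicated(breaks)], 6)),
                collapse = ", "))
  grs$decile <- .bincode(grs$grs, breaks, right = TRUE, include.lowest = TRUE)
  empty <- setdiff(seq_len(n_groups), unique(grs$decile))
  if (length(empty))
    abort("decile group(s) empty due to ties at boundary ",
          paste(signif(breaks[empty], 6), collapse = ", "))
  cohort <- stratum_subset(cohort, stratum)
  keep <- grs$sample_id %in% cohort$phenotype$sample_id
  g <- grs[keep, , drop = FALSE]
  missing_cov <- setdiff(covariates, names(cohort$phenotype))
  if (length(missing_cov))
    abort("covariate(s) absent from phenotype: ",
          paste(missing_cov, collapse = ", "))
  m <- match(g$sample_id, cohort$phenotype$sample_id)
  dd <- data.frame(case = cohort$phenotype$case[m], decile = g$decile,
                   cohort$phenotype[m, covariates, drop = FALSE],
                   check.names = FALSE)
  dd <- dd[complete.cases(dd), , drop = FALSE]
  n_cases <- sum(dd$case == 1); n_controls <- sum(dd$case == 0)

  fit_ind <- fit_logistic(case ~ factor(decile), dd, covariates,
                          label = "decile model")
  z <- qnorm(0.975)
  per <- data.frame(decile = seq_len(n_groups), or_value = 1,
                    ci_low = NA_real_, ci_high = NA_real_, pval = NA_real_,
                    n = as.integer(table(factor(dd$decile,
                                                levels = seq_len(n_groups)))))
  cn <- sprintf("factor(decile)%d", 2:n_groups)
  est <- coef(fit_ind)[cn]
  se <- sqrt(diag(vcov(fit_ind))[cn])
  per$or_value[-1] <- exp(est)
  per$ci_low[-1] <- exp(est - z * se)
  per$ci_high[-1] <- exp(est + z * se)
  per$pval[-1] <- 2 * pnorm(-abs(est / se))

  fit_trend <- fit_logistic(case ~ decile, dd, covariates,
                            label = "decile trend model")
  co <- summary_coef(fit_trend, "decile")
  trend <- mr_estimate("per-decile", co[["est"]], co[["se"]],
                       n_cases = n_cases, n_controls = n_controls,
                       covariates = covariates)
  list(per_decile = per, trend = trend, breaks = breaks)
}
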