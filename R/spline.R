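#' Restricted cubic spline basis
#'
#' Truncated-power restricted cubic spline basis with k knots: column 1 is
#' the identity and, for m = 1..k-2,
#' \deqn{B_{m+1}(x) = \big[(x-t_m)_+^3
#'   - (x-t_{k-1})_+^3 \tfrac{t_k - t_m}{t_k - t_{k-1}}
#'   + (x-t_k)_+^3 \tfrac{t_{k-1} - t_m}{t_k - t_{k-1}}\big] / (t_k - t_1)^2,}
#' which is linear beyond the boundary knots. The `(t_k - t_1)^2`
#' normalization is for numerical conditioning only; any consistent
#' scaling gives identical model fits and p-values.
#'
#' @param x numeric vector of evaluation points.
#' @param knots strictly increasing knot locations, at least 3.
#' @return numeric matrix with `length(x)` rows and `length(knots) - 1`
#'   columns, named `linear`, `nl1`, `nl2`, ...
#' @export
rcs_basis <- function(x, knots) {
  knots <- as.numeric(knots)
  if (length(knots) < 3L) abort("need at least 3 knots")
  if (any(diff(knots) <= 0)) abort("knots must be strictly increasing")
  k <- length(knots)
  tk <- knots[k]; tk1 <- knots[k - 1L]
  norm <- (knots[k] - knots[1L])^2
  pos3 <- function(u) pmax(u, 0)^3
  b <- matrix(0, nrow = length(x), ncol = k - 1L,
              dimnames = list(NULL, c("linear", paste0("nl", seq_len(k - 2L)))))
  b[, 1L] <- x
  for (m in seq_len(k - 2L)) {
    tm <- knots[m]
    b[, m + 1L] <- (pos3(x - tm) -
                      pos3(x - tk1) * (tk - tm) / (tk - tk1) +
                      pos3(x - tk) * (tk1 - tm) / (tk - tk1)) / norm
  }
  b
}

# default knot placement quantiles (standard recommendations)
default_knot_quantiles <- function(n_knots) {
  switch(as.character(n_knots),
         "3" = c(0.10, 0.50, 0.90),
         "4" = c(0.05, 0.35, 0.65, 0.95),
         "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
         abort("n_knots must be 3, 4 or 5"))
}

#' Restricted-cubic-spline tests of the GRS dose-response
#'
#' Fits three nested covariate-adjusted logistic models of case status:
#' covariates only, covariates + linear GRS, covariates + full restricted
#' cubic spline of the GRS. Likelihood-ratio tests give
#' `p_linear` (linear vs null, 1 df — is there a log-linear dose-response
#' at all?) and `p_nonlinear` (spline vs linear, k-2 df — does the
#' dose-response depart from log-linearity?).
#'
#' @param grs a [compute_grs()] result.
#' @param cohort the matching `mr_cohort`.
#' @param covariates phenotype columns to adjust for.
#' @param n_knots number of knots (3, 4 or 5; default 4 at the 5th, 35th,
#'   65th and 95th percentiles of the pooled GRS).
#' @param knot_quantiles optional explicit quantiles overriding the
#'   default placement.
#' @param stratum optional histology stratum.
#' @return An object of class `spline_fit`: `knots`, `coefficients`
#'   (spline terms of the full model), `loglik` (named: null, linear,
#'   full), `p_linear`, `p_nonlinear`, plus the fitted full model's
#'   spline coefficient covariance for curve construction.
#' @export
spline_tests <- function(grs, cohort,
                         covariates = c("age", "sex", "pack_years",
                                        "pc1", "study"),
                         n_knots = 4, knot_quantiles = NULL,
                         stratum = NULL) {
  if (is.null(knot_quantiles)) knot_quantiles <- default_knot_quantiles(n_knots)
  if (length(knot_quantiles) != n_knots)
    abort("knot_quantiles must have length n_knots")
  # knots from the pooled GRS distribution, before stratum subsetting
  knots <- as.numeric(quantile(grs$grs, probs = knot_quantiles, names = FALSE))
  if (any(diff(knots) <= 0))
    abort("knots collapse due to ties in the GRS distribution")
  cohort <- stratum_subset(cohort, stratum)
  g <- grs[grs$sample_id %in% cohort$phenotype$sample_id, , drop = FALSE]
  d <- grs_frame(g, cohort, covariates)
  if (length(unique(d$grs)) < n_knots + 2L)
    abort("too few distinct GRS values for a ", n_knots, "-knot spline")
  basis <- rcs_basis(d$grs, knots)
  dd <- cbind(d, as.data.frame(basis))
  spline_terms <- colnames(basis)

  fit_null <- fit_logistic(case ~ 1, dd, covariates, label = "null model")
  fit_lin <- fit_logistic(case ~ linear, dd, covariates, label = "linear model")
  fit_full <- fit_logistic(stats::reformulate(spline_terms, response = "case"),
                           dd, covariates, label = "spline model")
  ll <- c(null = as.numeric(logLik(fit_null)),
          linear = as.numeric(logLik(fit_lin)),
          full = as.numeric(logLik(fit_full)))
  lrt <- function(l1, l0, df) {
    stat <- max(0, 2 * (l1 - l0))
    pchisq(stat, df, lower.tail = FALSE)
  }
  structure(list(
    knots = knots,
    coefficients = coef(fit_full)[spline_terms],
    vcov = vcov(fit_full)[spline_terms, spline_terms, drop = FALSE],
    loglik = ll,
    p_linear = lrt(ll[["linear"]], ll[["null"]], 1L),
    p_nonlinear = lrt(ll[["full"]], ll[["linear"]], n_knots - 2L),
    n_knots = n_knots,
    grs_range = range(d$grs)),
    class = "spline_fit")
}

#' @export
print.spline_fit <- function(x, ...) {
  cat(sprintf("<spline_fit> %d knots at %s (kb)\n", x$n_knots,
              paste(signif(x$knots, 4), collapse = ", ")))
  cat(sprintf("  p-linear = %.3g, p-nonlinear = %.3g\n",
              x$p_linear, x$p_nonlinear))
  invisible(x)
}

#' Fitted spline dose-response curve
#'
#' Evaluates the fitted spline's log-OR relative to a reference GRS value
#' over a grid, with delta-method pointwise 95% CIs.
#'
#' @param fit a [spline_tests()] result.
#' @param grid evaluation points; default 100 points across the observed
#'   GRS range.
#' @param reference reference GRS (log-OR 0); default the first knot.
#' @return data.frame with columns `grs`, `log_or`, `ci_low`, `ci_high`.
#' @export
spline_curve <- function(fit, grid = NULL, reference = NULL) {
  stopifnot(inherits(fit, "spline_fit"))
  if (is.null(grid))
    grid <- seq(fit$grs_range[1], fit$grs_range[2], length.out = 100)
  if (is.null(reference)) reference <- fit$knots[1]
  b <- rcs_basis(grid, fit$knots)
  b0 <- rcs_basis(reference, fit$knots)
  d <- sweep(b, 2, as.vector(b0))
  log_or <- as.vector(d %*% fit$coefficients)
  se <- sqrt(pmax(0, rowSums((d %*% fit$vcov) * d)))
  z <- qnorm(0.975)
  data.frame(grs = grid, log_or = log_or,
             ci_low = log_or - z * se, ci_high = log_or + z * se)
}
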