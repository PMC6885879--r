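#' Configuration for the synthetic case-control cohort generator
#'
#' Defines the generative model the MR analysis assumes: independent
#' Hardy-Weinberg biallelic SNPs raise latent leukocyte telomere length
#' (TL, kb), TL raises disease risk on the log-odds scale, measured
#' confounders (age, sex, pack-years, first genetic principal component,
#' study membership) act directly on risk, and - optionally - individual
#' SNPs get a direct (horizontally pleiotropic) path to disease that
#' violates the exclusion restriction.
#'
#' Histology strata: `causal_log_or_per_kb` may be a single value or a
#' named vector over `names(histology_props)`; each stratum then has its
#' own disease logit (sharing `baseline_log_odds` offsets and confounder
#' effects), an individual is a control iff no stratum fires, and a case's
#' stratum is drawn proportionally to the per-stratum odds.
#'
#' @param n_cases,n_controls target sample sizes (cases of any stratum).
#' @param instruments harmonized instrument table in kb (see
#'   [harmonize_orientation()], [scale_to_kb()]); dosages are drawn as
#'   Binomial(2, maf) per SNP, independently across SNPs.
#' @param tl_mean mean TL in kb (default 6.5, a typical adult leukocyte
#'   value).
#' @param tl_sd residual TL standard deviation in kb. The default `NULL`
#'   derives it so the instruments explain `tl_variance_share` of TL
#'   variance.
#' @param tl_variance_share fraction of TL variance explained by the SNPs
#'   when `tl_sd` is derived (default 0.01, the share typically reported
#'   for these loci).
#' @param causal_log_or_per_kb causal effect gamma: log-odds of disease per
#'   kb of TL (default `log(2.25)`, the magnitude of the association this
#'   design is powered around). Scalar or named per-stratum vector.
#' @param confounder_effects named log-OR vector for `age` (per year,
#'   centered), `sex` (female vs male), `pack_years` (per pack-year),
#'   `pc1` (per unit) and `study` (per study index step). All are config
#'   values, never hidden constants.
#' @param pleiotropy named vector of direct per-allele log-ORs keyed by
#'   snp_id; every key must be an instrument. Default none.
#' @param baseline_log_odds intercept alpha0 of the disease logit at
#'   covariate means (default `qlogis(0.25)`; with rejection sampling it
#'   governs sampler efficiency, not the case:control ratio).
#' @param n_studies number of constituent studies (default 2); individuals
#'   are assigned uniformly.
#' @param histology_props named case-stratum proportions; default
#'   adenocarcinoma/squamous/other at 0.67/0.21/0.12, the composition of a
#'   large pooled East Asian lung cancer sample.
#' @param p_female,age_mean,age_sd,p_never_smoker,pack_years_shape,pack_years_scale
#'   covariate distribution parameters: sex ~ Bernoulli(p_female),
#'   age ~ Normal(age_mean, age_sd), pack-years is zero for never-smokers
#'   and Gamma(shape, scale) otherwise, pc1 ~ Normal(0, 1).
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @param max_draw_factor sampler cap: at most
#'   `max_draw_factor * (n_cases + n_controls)` individuals are drawn
#'   before the generator aborts with an error (guards against a disease
#'   model whose case probability is numerically 0 or 1).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cases, n_controls,
                       instruments = default_instruments(),
                       tl_mean = 6.5, tl_sd = NULL,
                       tl_variance_share = 0.01,
                       causal_log_or_per_kb = log(2.25),
                       confounder_effects = c(age = 0.02, sex = -0.25,
                                              pack_years = 0.025,
                                              pc1 = 0.15, study = 0.1),
                       pleiotropy = NULL,
                       baseline_log_odds = qlogis(0.25),
                       n_studies = 2,
                       histology_props = c(adenocarcinoma = 0.67,
                                           squamous = 0.21, other = 0.12),
                       p_female = 0.6, age_mean = 60, age_sd = 10,
                       p_never_smoker = 0.6,
                       pack_years_shape = 2, pack_years_scale = 15,
                       seed = 1L,
                       max_draw_factor = 500) {
  stopifnot(n_cases > 0, n_controls > 0, n_studies >= 1, tl_variance_share > 0,
            tl_variance_share < 1, max_draw_factor >= 1)
  inst <- instruments(instruments)
  if (any(inst$unit != "kb")) abort("simulator requires instruments in kb")
  if (any(inst$beta_x < 0)) abort("simulator requires harmonized instruments (beta_x >= 0)")
  if (!is.null(pleiotropy)) {
    bad <- setdiff(names(pleiotropy), inst$snp_id)
    if (length(bad) || is.null(names(pleiotropy)))
      abort("pleiotropy keys must be instrument snp_ids; offending: ",
            paste(bad, collapse = ", "))
  }
  var_g <- sum(inst$beta_x^2 * 2 * inst$maf * (1 - inst$maf))
  if (is.null(tl_sd)) {
    # residual SD giving the requested genetic variance share
    tl_sd <- sqrt(var_g * (1 - tl_variance_share) / tl_variance_share)
  }
  stopifnot(tl_sd > 0)
  hp <- histology_props / sum(histology_props)
  gam <- causal_log_or_per_kb
  if (length(gam) > 1) {
    if (!setequal(names(gam), names(hp)))
      abort("per-stratum causal_log_or_per_kb must be named over histology_props")
    gam <- gam[names(hp)]
  }
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    instruments = inst, tl_mean = tl_mean, tl_sd = tl_sd,
    tl_variance_share_requested = tl_variance_share,
    tl_variance_share = var_g / (var_g + tl_sd^2),
    causal_log_or_per_kb = gam,
    confounder_effects = confounder_effects,
    pleiotropy = pleiotropy, baseline_log_odds = baseline_log_odds,
    n_studies = as.integer(n_studies), histology_props = hp,
    p_female = p_female, age_mean = age_mean, age_sd = age_sd,
    p_never_smoker = p_never_smoker,
    pack_years_shape = pack_years_shape, pack_years_scale = pack_years_scale,
    seed = as.integer(seed), max_draw_factor = max_draw_factor),
    class = "sim_config")
}

#' Simulate a case-control cohort under the MR causal model
#'
#' Draws individuals from the generative model in [sim_config()] and
#' retains them by rejection sampling until exactly `n_cases` cases and
#' `n_controls` controls are collected. Dosages are counts of the effect
#' (long-TL) allele, Binomial(2, maf) per SNP; latent TL is
#' `tl_mean + sum_j beta_x_j * x_ij + eps`, `eps ~ N(0, tl_sd^2)`; the
#' disease logit is `alpha0 + gamma_s * (TL - tl_mean) + confounders +
#' direct pleiotropic terms` (age and TL enter centered so `alpha0` is the
#' risk at covariate means).
#'
#' @param config a [sim_config()].
#' @return An object of class `mr_cohort`: list with `dosages`
#'   (individuals x SNPs integer matrix, sample ids as rownames) and
#'   `phenotype` (data.frame: sample_id, case, histology, age, sex,
#'   pack_years, pc1, study), plus the latent `tl` vector (kb) kept for
#'   diagnostics.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  inst <- cfg$instruments
  J <- nrow(inst)
  strata <- names(cfg$histology_props)
  gam <- cfg$causal_log_or_per_kb
  if (length(gam) == 1) gam <- setNames(rep(gam, length(strata)), strata)
  # per-stratum intercepts: overall baseline split by histology mix
  alpha <- cfg$baseline_log_odds + log(cfg$histology_props)

  with_seed(cfg$seed, {
    need_case <- cfg$n_cases; need_ctrl <- cfg$n_controls
    cap <- ceiling(cfg$max_draw_factor * (need_case + need_ctrl))
    drawn <- 0L
    acc <- list()
    while (need_case > 0 || need_ctrl > 0) {
      b <- min(max(2000L, 2L * (need_case + need_ctrl)), cap - drawn)
      if (b <= 0L)
        abort("case/control quota unreachable within ", cap,
              " draws; disease probabilities may be numerically 0 or 1")
      drawn <- drawn + b
      dos <- vapply(inst$maf, function(p) rbinom(b, 2L, p), integer(b))
      if (b == 1L) dos <- matrix(dos, nrow = 1L)
      colnames(dos) <- inst$snp_id
      tl <- cfg$tl_mean + as.vector(dos %*% inst$beta_x) +
        rnorm(b, 0, cfg$tl_sd)
      age <- rnorm(b, cfg$age_mean, cfg$age_sd)
      sex <- rbinom(b, 1L, cfg$p_female)
      smoker <- rbinom(b, 1L, 1 - cfg$p_never_smoker)
      pack_years <- smoker * rgamma(b, shape = cfg$pack_years_shape,
                                    scale = cfg$pack_years_scale)
      pc1 <- rnorm(b)
      study <- sample.int(cfg$n_studies, b, replace = TRUE)
      ce <- cfg$confounder_effects
      conf <- ce[["age"]] * (age - cfg$age_mean) + ce[["sex"]] * sex +
        ce[["pack_years"]] * pack_years + ce[["pc1"]] * pc1 +
        ce[["study"]] * (study - 1L)
      direct <- 0
      if (!is.null(cfg$pleiotropy))
        direct <- as.vector(dos[, names(cfg$pleiotropy), drop = FALSE] %*%
                              cfg$pleiotropy)
      # per-stratum odds; control iff no stratum fires
      odds <- vapply(strata, function(s)
        exp(alpha[[s]] + gam[[s]] * (tl - cfg$tl_mean) + conf + direct),
        numeric(b))
      if (b == 1L) odds <- matrix(odds, nrow = 1L)
      p_case <- 1 - 1 / (1 + rowSums(odds))
      is_case <- runif(b) < p_case
      histology <- rep(NA_character_, b)
      if (any(is_case)) {
        idx <- which(is_case)
        histology[idx] <- vapply(idx, function(i)
          sample(strata, 1L, prob = odds[i, ]), character(1))
      }
      take_case <- which(is_case)[seq_len(min(need_case, sum(is_case)))]
      take_ctrl <- which(!is_case)[seq_len(min(need_ctrl, sum(!is_case)))]
      take <- sort(c(take_case, take_ctrl))
      if (length(take)) {
        acc[[length(acc) + 1L]] <- list(
          dos = dos[take, , drop = FALSE], tl = tl[take],
          case = as.integer(is_case[take]), histology = histology[take],
          age = age[take], sex = sex[take], pack_years = pack_years[take],
          pc1 = pc1[take], study = study[take])
        need_case <- need_case - length(take_case)
        need_ctrl <- need_ctrl - length(take_ctrl)
      }
    }
    dosages <- do.call(rbind, lapply(acc, `[[`, "dos"))
    n <- nrow(dosages)
    ids <- sprintf("S%05d", seq_len(n))
    rownames(dosages) <- ids
    phenotype <- data.frame(
      sample_id = ids,
      case = unlist(lapply(acc, `[[`, "case")),
      histology = unlist(lapply(acc, `[[`, "histology")),
      age = unlist(lapply(acc, `[[`, "age")),
      sex = unlist(lapply(acc, `[[`, "sex")),
      pack_years = unlist(lapply(acc, `[[`, "pack_years")),
      pc1 = unlist(lapply(acc, `[[`, "pc1")),
      study = unlist(lapply(acc, `[[`, "study")),
      stringsAsFactors = FALSE)
    rownames(phenotype) <- NULL
    structure(list(dosages = dosages, phenotype = phenotype,
                   tl = unlist(lapply(acc, `[[`, "tl")),
                   config = cfg),
              class = "mr_cohort")
  })
}

#' Assemble a cohort from external dosage and phenotype tables
#'
#' @param dosages numeric matrix (individuals x SNPs) of 0/1/2 effect-allele
#'   counts, `NA` allowed; rownames are sample ids.
#' @param phenotype data.frame with columns `sample_id`, `case` (0/1) and
#'   any covariates; row order must match `dosages`.
#' @return An `mr_cohort`.
#' @export
mr_cohort <- function(dosages, phenotype) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != nrow(phenotype))
    abort("dosages and phenotype must have the same number of rows")
  ok <- is.na(dosages) | dosages %in% c(0, 1, 2)
  if (!all(ok)) abort("dosage values must be 0, 1, 2 or missing")
  if (!all(c("sample_id", "case") %in% names(phenotype)))
    abort("phenotype needs sample_id and case columns")
  if (!all(phenotype$case %in% c(0, 1)))
    abort("case column must be binary 0/1")
  if (is.null(rownames(dosages))) rownames(dosages) <- phenotype$sample_id
  structure(list(dosages = dosages, phenotype = phenotype),
            class = "mr_cohort")
}

#' @export
print.mr_cohort <- function(x, ...) {
  cat(sprintf("<mr_cohort> %d individuals (%d cases / %d controls), %d SNP(s)\n",
              nrow(x$dosages), sum(x$phenotype$case == 1),
              sum(x$phenotype$case == 0), ncol(x$dosages)))
  invisible(x)
}

# subset a cohort to one histology stratum's cases plus all controls
stratum_subset <- function(cohort, stratum) {
  if (is.null(stratum)) return(cohort)
  ph <- cohort$phenotype
  if (!"histology" %in% names(ph)) abort("cohort has no histology column")
  keep <- ph$case == 0 | (ph$case == 1 & ph$histology == stratum)
  keep[is.na(keep)] <- FALSE
  out <- cohort
  out$dosages <- cohort$dosages[keep, , drop = FALSE]
  out$phenotype <- ph[keep, , drop = FALSE]
  if (!is.null(cohort$tl)) out$tl <- cohort$tl[keep]
  out
}

#' Per-SNP outcome association statistics
#'
#' One covariate-adjusted logistic regression of case status per SNP, with
#' dosage entered as a continuous 0/1/2 term. This is the outcome side of
#' the summary-data MR arm: each fit yields the per-effect-allele log-OR
#' `beta_y`, its standard error and the two-sided Wald p-value.
#'
#' @param cohort an `mr_cohort`.
#' @param instruments instrument table; every snp_id must be a dosage
#'   column.
#' @param adjust character vector of phenotype covariate columns (a
#'   `study` column enters as indicator variables).
#' @param stratum optional histology stratum: cases restricted to that
#'   stratum, all controls kept.
#' @return data.frame of class `mr_summary_assoc` with columns `snp_id`,
#'   `beta_y`, `se_y`, `pval_y`, `n`.
#' @export
per_snp_outcome_stats <- function(cohort, instruments,
                                  adjust = c("age", "sex", "pack_years",
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
  missing_cov <- setdiff(adjust, names(ph))
  if (length(missing_cov))
    abort("covariate(s) absent from phenotype: ",
          paste(missing_cov, collapse = ", "))
  out <- lapply(inst$snp_id, function(id) {
    d <- data.frame(case = ph$case, dosage = cohort$dosages[, id],
                    ph[adjust], check.names = FALSE)
    d <- d[complete.cases(d), , drop = FALSE]
    if (length(unique(d$dosage)) < 2L)
      abort("no dosage variation for SNP ", id)
    fit <- fit_logistic(case ~ dosage, d, covariates = adjust,
                        label = paste("SNP", id))
    co <- summary_coef(fit, "dosage")
    data.frame(snp_id = id, beta_y = co[["est"]], se_y = co[["se"]],
               pval_y = co[["p"]], n = nrow(d), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("mr_summary_assoc", "data.frame")
  res
}

# shared logistic fitting with convergence / separation guards.
# `formula` carries the focal terms; covariates are appended, with a
# multi-level `study` column coerced to factor indicators.
fit_logistic <- function(formula, data, covariates = character(0),
                         label = "model") {
  if ("study" %in% names(data) && "study" %in% covariates)
    data$study <- factor(data$study)
  rhs <- attr(terms(formula), "term.labels")
  all_terms <- c(rhs, covariates)
  if (length(all_terms) == 0) all_terms <- "1"
  f <- stats::reformulate(all_terms, response = all.vars(formula)[1])
  fit <- suppressWarnings(glm(f, data = data, family = binomial()))
  if (!fit$converged)
    abort(label, ": logistic regression did not converge")
  # separation: degenerate fitted probabilities together with a coefficient
  # whose swing across one predictor SD exceeds any plausible log-odds range
  mu <- fit$fitted.values
  if (any(mu < 1e-8 | mu > 1 - 1e-8)) {
    mm <- stats::model.matrix(fit)
    swing <- abs(coef(fit)) * apply(mm, 2, stats::sd)
    swing[1] <- 0
    if (any(swing > 20, na.rm = TRUE))
      abort(label, ": separation suspected (diverging coefficient)")
  }
  fit
}

summary_coef <- function(fit, term) {
  est <- coef(fit)[[term]]
  se <- sqrt(diag(vcov(fit))[[term]])
  c(est = est, se = se, p = 2 * pnorm(-abs(est / se)))
}

#' Build a summary-association table from odds ratios and 95% CIs
#'
#' Converts published per-SNP outcome rows (OR with symmetric-Wald 95% CI)
#' into the log-OR/SE form consumed by [ivw_estimate()], using
#' [se_from_ci()].
#'
#' @param snp_id character vector.
#' @param or_value,ci_low,ci_high odds ratio and 95% CI bounds.
#' @param n sample size(s), optional.
#' @return An `mr_summary_assoc` data.frame.
#' @export
assoc_from_or_ci <- function(snp_id, or_value, ci_low, ci_high, n = NA_integer_) {
  se <- mapply(se_from_ci, or_value, ci_low, ci_high)
  if (any(se <= 0))
    abort("degenerate confidence interval (zero width) for: ",
          paste(snp_id[se <= 0], collapse = ", "))
  beta <- log(or_value)
  res <- data.frame(snp_id = as.character(snp_id), beta_y = beta, se_y = se,
                    pval_y = 2 * pnorm(-abs(beta / se)), n = n,
                    stringsAsFactors = FALSE)
  class(res) <- c("mr_summary_assoc", "data.frame")
  res
}
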