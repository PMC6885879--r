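#' Validate a pipeline configuration
#'
#' Checks the configuration (YAML file or list) for the end-to-end
#' analysis before any computation: required fields, types and ranges.
#'
#' @param config path to a YAML file or an equivalent named list with
#'   entries `seed`, `cohort` (arguments of [sim_config()], requiring
#'   `n_cases` and `n_controls`) and optionally `instruments` (TSV path;
#'   default the bundled catalog) and `analysis` (`covariates`, `n_knots`,
#'   `missing_policy`, `alpha_pleiotropy`, `strata`).
#' @return The normalized configuration list, invisibly.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or YAML path")
  if (is.null(config$cohort)) abort("config lacks a 'cohort' section")
  for (f in c("n_cases", "n_controls")) {
    v <- config$cohort[[f]]
    if (is.null(v) || !is.numeric(v) || v < 1)
      abort("cohort.", f, " must be a positive count")
  }
  if (is.null(config$seed)) config$seed <- 1L
  if (!is.numeric(config$seed)) abort("seed must be an integer")
  a <- config$analysis
  if (is.null(a)) a <- list()
  if (is.null(a$covariates))
    a$covariates <- c("age", "sex", "pack_years", "pc1", "study")
  if (is.null(a$n_knots)) a$n_knots <- 4L
  if (!a$n_knots %in% 3:5) abort("analysis.n_knots must be 3, 4 or 5")
  if (is.null(a$missing_policy)) a$missing_policy <- "drop"
  if (!a$missing_policy %in% c("drop", "mean_impute"))
    abort("analysis.missing_policy must be 'drop' or 'mean_impute'")
  if (is.null(a$alpha_pleiotropy)) a$alpha_pleiotropy <- 0.05
  if (a$alpha_pleiotropy <= 0 || a$alpha_pleiotropy >= 1)
    abort("analysis.alpha_pleiotropy must lie in (0, 1)")
  if (is.null(a$strata)) a$strata <- c("adenocarcinoma", "squamous")
  if (is.null(a$exclude)) a$exclude <- character(0)
  config$analysis <- a
  invisible(config)
}

sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7 + k) %% (.Machine$integer.max - 1) + 1)
}

estimate_row <- function(e) {
  list(or = e$or_value, ci_low = e$ci_low, ci_high = e$ci_high,
       pval = e$pval, n_cases = e$n_cases, n_controls = e$n_controls)
}

ivw_row <- function(e) {
  list(or = e$or_value, ci_low = e$ci_low, ci_high = e$ci_high,
       pval = e$pval, beta = e$beta, se = e$se, n_snps = e$n_snps,
       q_stat = e$q_stat, q_df = e$q_df, q_pval = e$q_pval,
       per_snp_residual = as.list(e$per_snp_residual))
}

log_step <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[telomr] ", fmt), ...))
}

#' Run the full MR analysis pipeline
#'
#' Simulates a cohort from the configuration, runs the individual-level
#' (GRS) and summary-level (IVW) MR arms on it - overall and per histology
#' stratum - together with the aggregate instrument test, decile and trend
#' analysis, pleiotropy flagging with automatic exclusion refits of both
#' arms, between-study heterogeneity and the restricted-cubic-spline
#' nonlinearity tests. Fully deterministic for a given seed. Failures in
#' one arm are recorded in the report without aborting the others.
#'
#' @param config YAML path or list; see [validate_config()].
#' @param out_dir optional directory: the report is written as
#'   `report.json` plus TSV tables (`decile.tsv`, `per_snp_overall.tsv`).
#' @param seed optional override of the config seed.
#' @param verbose emit one log line per pipeline step (default TRUE).
#' @return The report, an object of class `mr_report` (a nested list).
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL, verbose = TRUE) {
  config <- validate_config(config)
  if (!is.null(seed)) config$seed <- seed
  a <- config$analysis
  t0 <- Sys.time()

  inst <- if (!is.null(config$instruments))
    read_instruments(config$instruments) else default_instruments()
  inst <- harmonize_orientation(scale_to_kb(inst))
  if (length(a$exclude)) inst <- inst[!inst$snp_id %in% a$exclude, , drop = FALSE]

  cohort_args <- config$cohort
  cohort_args$instruments <- inst
  cohort_args$seed <- sub_seed(config$seed, 1)
  if (!is.null(cohort_args$pleiotropy))
    cohort_args$pleiotropy <- unlist(cohort_args$pleiotropy)
  if (!is.null(cohort_args$causal_log_or_per_kb) &&
      is.list(cohort_args$causal_log_or_per_kb))
    cohort_args$causal_log_or_per_kb <- unlist(cohort_args$causal_log_or_per_kb)
  cfg <- do.call(sim_config, cohort_args)
  log_step(verbose, "simulating cohort: %d cases / %d controls, %d SNPs",
           cfg$n_cases, cfg$n_controls, nrow(inst))
  cohort <- simulate_cohort(cfg)

  strata <- c(list(overall = NULL), setNames(as.list(a$strata), a$strata))
  arm <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      log_step(verbose, "arm '%s' failed: %s", label, conditionMessage(e))
      list(error = conditionMessage(e))
    })
  }

  log_step(verbose, "GRS arm")
  grs <- compute_grs(cohort, inst, missing_policy = a$missing_policy)
  grs_arm <- arm("grs", {
    fits <- lapply(strata, function(s)
      estimate_row(fit_grs_logistic(grs, cohort, a$covariates, stratum = s)))
    agg <- aggregate_test(cohort, inst, a$covariates)
    dec <- decile_analysis(grs, cohort, a$covariates)
    list(per_kb = fits, aggregate_test = agg,
         decile = list(per_decile = dec$per_decile,
                       trend = estimate_row(dec$trend)))
  })

  log_step(verbose, "summary (IVW) arm")
  assoc_overall <- NULL
  summary_arm <- arm("ivw", {
    res <- lapply(names(strata), function(nm) {
      assoc <- per_snp_outcome_stats(cohort, inst, a$covariates,
                                     stratum = strata[[nm]])
      if (nm == "overall") assoc_overall <<- assoc
      list(assoc = assoc, ivw = ivw_estimate(inst, assoc))
    })
    names(res) <- names(strata)
    list(per_snp = lapply(res, function(r) r$assoc),
         ivw = lapply(res, function(r) ivw_row(r$ivw)))
  })

  log_step(verbose, "sensitivity: pleiotropy flagging and exclusion refits")
  sensitivity <- arm("sensitivity", {
    ivw_all <- ivw_estimate(inst, assoc_overall)
    flagged <- flag_pleiotropic_snps(ivw_all, alpha = a$alpha_pleiotropy)
    excl <- NULL
    if (length(flagged)) {
      inst_x <- inst[!inst$snp_id %in% flagged, , drop = FALSE]
      grs_x <- compute_grs(cohort, inst_x, missing_policy = a$missing_policy)
      excl <- list(
        ivw = lapply(strata, function(s) {
          assoc <- per_snp_outcome_stats(cohort, inst_x, a$covariates,
                                         stratum = s)
          ivw_row(ivw_estimate(inst_x, assoc))
        }),
        grs = lapply(strata, function(s)
          estimate_row(fit_grs_logistic(grs_x, cohort, a$covariates,
                                        stratum = s))))
    }
    studies <- sort(unique(cohort$phenotype$study))
    between_study <- NULL
    if (length(studies) >= 2) {
      per_study <- lapply(studies, function(s) {
        sub <- cohort
        keep <- cohort$phenotype$study == s
        sub$dosages <- cohort$dosages[keep, , drop = FALSE]
        sub$phenotype <- cohort$phenotype[keep, , drop = FALSE]
        cov <- setdiff(a$covariates, "study")
        ivw_estimate(inst, per_snp_outcome_stats(sub, inst, cov))
      })
      bq <- between_study_q(vapply(per_study, `[[`, 0, "beta"),
                            vapply(per_study, `[[`, 0, "se"))
      between_study <- c(bq, list(per_study = lapply(per_study, ivw_row)))
    }
    list(flagged = as.list(flagged), excluding_flagged = excl,
         between_study = between_study)
  })

  log_step(verbose, "spline nonlinearity arm")
  spline_arm <- arm("spline", {
    lapply(strata, function(s) {
      f <- spline_tests(grs, cohort, a$covariates, n_knots = a$n_knots,
                        stratum = s)
      list(knots = f$knots, p_linear = f$p_linear,
           p_nonlinear = f$p_nonlinear, loglik = as.list(f$loglik))
    })
  })

  report <- structure(list(
    software = list(package = "telomr",
                    version = as.character(packageVersion("telomr"))),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = config[setdiff(names(config), "instruments_table")],
    cohort = list(n_cases = sum(cohort$phenotype$case == 1),
                  n_controls = sum(cohort$phenotype$case == 0),
                  n_snps = nrow(inst),
                  tl_variance_share = cfg$tl_variance_share),
    grs_arm = grs_arm,
    summary_arm = summary_arm,
    sensitivity = sensitivity,
    spline = spline_arm),
    class = "mr_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, file.path(out_dir, "report.json"))
    if (is.null(grs_arm$error))
      write.table(grs_arm$decile$per_decile,
                  file.path(out_dir, "decile.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    if (is.null(summary_arm$error))
      write_summary_tsv(summary_arm$per_snp$overall, inst,
                        file.path(out_dir, "per_snp_overall.tsv"))
    log_step(verbose, "report written to %s", out_dir)
  }
  report
}

#' Write / read a pipeline report as JSON
#'
#' @param report an `mr_report`.
#' @param path JSON file path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = FALSE),
            class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("<mr_report> telomr %s, seed %s: %s cases / %s controls\n",
              x$software$version, x$seed, x$cohort$n_cases,
              x$cohort$n_controls))
  if (is.null(x$grs_arm$error))
    cat(sprintf("  GRS OR per kb (overall): %.3f\n",
                x$grs_arm$per_kb$overall$or))
  if (is.null(x$summary_arm$error))
    cat(sprintf("  IVW OR per kb (overall): %.3f (Q p = %.3g)\n",
                x$summary_arm$ivw$overall$or,
                x$summary_arm$ivw$overall$q_pval))
  invisible(x)
}
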