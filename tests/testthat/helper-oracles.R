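# Independent oracles and small fixture builders shared across tests.

# From-scratch iteratively reweighted least squares for logistic regression.
# Deliberately independent of stats::glm: plain Newton-Raphson on the
# log-likelihood with a dense design matrix.
irls_logistic <- function(X, y, tol = 1e-12, maxit = 100) {
  X <- as.matrix(X)
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    score <- crossprod(X, y - mu)
    info <- crossprod(X, w * X)
    step <- solve(info, score)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  eta <- as.vector(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  list(coef = setNames(as.vector(beta), colnames(X)),
       vcov = solve(crossprod(X, (mu * (1 - mu)) * X)),
       loglik = ll)
}

# weighted least squares through the origin: slope of by on bx, weights w
wls_origin_slope <- function(bx, by, w) {
  sum(w * bx * by) / sum(w * bx^2)
}

# design matrix matching fit_logistic's covariate handling
design_matrix <- function(d, focal, covariates) {
  covs <- d[, covariates, drop = FALSE]
  if ("study" %in% covariates) covs$study <- factor(covs$study)
  mm <- stats::model.matrix(~ ., data = cbind(d[, focal, drop = FALSE], covs))
  mm
}

# random valid instrument table of J SNPs (kb, harmonized)
toy_instruments <- function(J, seed = 1) {
  set.seed(seed)
  instruments(data.frame(
    snp_id = sprintf("rs%03d", seq_len(J)),
    effect_allele = sample(c("A", "C", "G", "T"), J, replace = TRUE),
    other_allele = sample(c("A", "C", "G", "T"), J, replace = TRUE),
    maf = runif(J, 0.08, 0.45),
    beta_x = runif(J, 0.03, 0.13),
    se_x = runif(J, 0.005, 0.02),
    pval_x = 10^runif(J, -30, -9),
    unit = "kb", stringsAsFactors = FALSE))
}

# random summary associations matched to an instrument table
toy_assocs <- function(inst, seed = 2, slope = 0.5, noise = 0.05) {
  set.seed(seed)
  se <- runif(nrow(inst), 0.02, 0.08)
  beta <- slope * inst$beta_x + rnorm(nrow(inst), 0, noise)
  data.frame(snp_id = inst$snp_id, beta_y = beta, se_y = se,
             pval_y = 2 * pnorm(-abs(beta / se)), n = 10000L,
             stringsAsFactors = FALSE)
}

# small simulated cohort with package defaults
toy_cohort <- function(n_cases = 500, n_controls = 500, seed = 11, ...) {
  simulate_cohort(sim_config(n_cases, n_controls, seed = seed, ...))
}

# declarative characterization of greedy-by-p LD pruning: a subset S of the
# (p/maf-filtered) pool is greedy-consistent iff, taking candidates in
# ascending p order, each is in S exactly when compatible (r2 < r2_max)
# with every earlier member of S. Enumerates all subsets; exactly one is
# consistent.
prune_oracle <- function(pool, ld, r2_max) {
  ord <- order(pool$pval_x)
  ids <- pool$snp_id[ord]
  n <- length(ids)
  consistent <- list()
  for (mask in 0:(2^n - 1)) {
    s <- ids[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    ok <- TRUE
    for (k in seq_len(n)) {
      id <- ids[k]
      earlier <- intersect(ids[seq_len(k - 1)], s)
      compatible <- all(ld[id, earlier] < r2_max)
      if ((id %in% s) != compatible) { ok <- FALSE; break }
    }
    if (ok) consistent[[length(consistent) + 1]] <- s
  }
  stopifnot(length(consistent) == 1)
  consistent[[1]]
}
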