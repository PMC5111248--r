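# Independent oracles and fixture builders. Everything here is coded
# against the documented contracts, not against the package internals,
# so tests compare two independent routes to the same numbers.

# Hand-coded Newton-Raphson (IRLS) logistic regression with explicit
# matrix algebra. Columns that are constant or all-zero in the sample
# are dropped before fitting (the aliased-term convention: such terms
# are never significant). Separation is flagged when a boundary fitted
# probability co-occurs with an exploding coefficient or standard error.
oracle_irls <- function(X, y, maxit = 100L, tol = 1e-8) {
  keep <- apply(X, 2L, function(col) length(unique(col)) > 1L)
  Xf <- cbind(1, X[, keep, drop = FALSE])
  beta <- rep(0, ncol(Xf))
  dev_old <- Inf
  converged <- FALSE
  boundary <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(Xf %*% beta)
    mu <- 1 / (1 + exp(-eta))
    eps <- 10 * .Machine$double.eps
    if (any(mu < eps | mu > 1 - eps)) boundary <- TRUE
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-10)
    z <- eta + (y - mu) / w
    beta <- solve(crossprod(Xf, w * Xf), crossprod(Xf, w * z))
    mu2 <- 1 / (1 + exp(-drop(Xf %*% beta)))
    dev <- -2 * sum(y * log(pmax(mu2, 1e-300)) +
                      (1 - y) * log(pmax(1 - mu2, 1e-300)))
    if (abs(dev - dev_old) / (abs(dev) + 0.1) < tol) { converged <- TRUE; break }
    dev_old <- dev
  }
  se_f <- sqrt(diag(solve(crossprod(Xf, pmax(mu2 * (1 - mu2), 1e-10) * Xf))))
  est <- rep(NA_real_, ncol(X) + 1L)
  se <- rep(NA_real_, ncol(X) + 1L)
  est[c(TRUE, keep)] <- drop(beta)
  se[c(TRUE, keep)] <- se_f
  names(est) <- names(se) <- c("(Intercept)", colnames(X))
  separated <- boundary &&
    (max(abs(est), na.rm = TRUE) > 10 || max(se, na.rm = TRUE) > 100)
  p <- 2 * pnorm(-abs(est / se))
  list(estimate = est, se = se, p = p,
       converged = converged && !separated, terms = names(est))
}

# Significance decision and repetition weight, re-derived from the
# documented tally rules (independent of evaluate_repetition()).
oracle_var_significant <- function(fit, cols, alpha, direction, expect) {
  if (!fit$converged) return(FALSE)
  any(vapply(cols, function(cl) {
    p <- fit$p[[cl]]; est <- fit$estimate[[cl]]
    ok <- !is.na(p) && p < alpha
    if (ok && direction) ok <- sign(est) == expect[[cl]]
    isTRUE(ok)
  }, logical(1)))
}

oracle_rep_weight <- function(fit, spec) {
  vc <- list(age = "age_lt75",
             location = c("loc_residential_institution", "loc_home",
                          "loc_other"),
             deprivation = "deprivation", density = "density_q",
             ndvi = "ndvi")
  expect <- c(age_lt75 = 1, loc_residential_institution = 1, loc_home = 1,
              loc_other = 1, deprivation = 1, density_q = 1, ndvi = -1)
  sig <- vapply(names(vc), function(v) {
    cols <- intersect(vc[[v]], fit$terms)
    if (length(cols) == 0L) return(NA)
    oracle_var_significant(fit, cols, spec$alpha, spec$direction_required,
                           expect)
  }, logical(1))
  sig <- sig[!is.na(sig)]
  if (spec$tally_rule == "count_significant") sum(sig) else as.integer(any(sig))
}

# Build a small, well-behaved cohort directly from records (two location
# levels only, so tiny fits stay full-rank on the observed categories).
make_tiny_cohort <- function(n_cases = 6L, n_controls = 24L, seed = 42L) {
  set.seed(seed)
  event <- as.Date("2009-07-27") + 0:2
  mk <- function(n, prefix, dates) {
    data.frame(
      record_id = sprintf("%s%02d", prefix, seq_len(n)),
      death_date = sample(dates, n, replace = TRUE),
      age_years = sample(c(60:74, 75:95), n, replace = TRUE),
      location_of_death = sample(c("hospital", "home"), n, replace = TRUE),
      deprivation_quintile = sample.int(5L, n, replace = TRUE),
      density_quintile = sample.int(5L, n, replace = TRUE),
      ndvi = round(runif(n, 0.1, 0.6), 3),
      stringsAsFactors = FALSE)
  }
  cases <- mk(n_cases, "case", event)
  controls <- mk(n_controls, "ctl", as.Date("2010-07-01") + 0:20)
  cases$group <- "case"; controls$group <- "control"
  cohort(cases, controls, event, provenance = "tiny fixture")
}

# Independent replay of a trial's A/B tallies: reproduces the documented
# RNG consumption order (per repetition: case draw then control draw,
# univariate models in the order age, location, deprivation, density,
# ndvi), refits every repetition with oracle_irls, and re-derives the
# weights from the tally rules.
oracle_trial_tallies <- function(cohort, spec, n_reps, n_case_draw,
                                 control_ratio, seed) {
  all_rec <- rbind(cohort$cases, cohort$controls)
  des <- encode_design(all_rec)
  X <- as.matrix(des[, setdiff(names(des), "outcome")])
  y <- des$outcome
  n_cases <- nrow(cohort$cases)
  n_controls <- nrow(cohort$controls)
  vc <- list(age = "age_lt75",
             location = c("loc_residential_institution", "loc_home",
                          "loc_other"),
             deprivation = "deprivation", density = "density_q",
             ndvi = "ndvi")
  A <- integer(n_cases); B <- numeric(n_cases)
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    if (spec$model_type == "univariate") {
      for (v in names(vc)) {
        ci <- sample.int(n_cases, n_case_draw)
        ki <- sample.int(n_controls, control_ratio * n_case_draw)
        idx <- c(ci, n_cases + ki)
        f <- oracle_irls(X[idx, vc[[v]], drop = FALSE], y[idx])
        w <- as.integer(oracle_var_significant(
          f, intersect(vc[[v]], f$terms), spec$alpha,
          spec$direction_required,
          c(age_lt75 = 1, loc_residential_institution = 1, loc_home = 1,
            loc_other = 1, deprivation = 1, density_q = 1, ndvi = -1)))
        A[ci] <- A[ci] + 1L
        B[ci] <- B[ci] + w
      }
    } else {
      ci <- sample.int(n_cases, n_case_draw)
      ki <- sample.int(n_controls, control_ratio * n_case_draw)
      idx <- c(ci, n_cases + ki)
      f <- oracle_irls(X[idx, , drop = FALSE], y[idx])
      w <- oracle_rep_weight(f, spec)
      A[ci] <- A[ci] + 1L
      B[ci] <- B[ci] + w
    }
  }
  list(A = A, B = B)
}

# Reduced-size scenario used by fast tests: same structure as the study
# scale but smaller pools.
small_scenario <- function(seed, strong = TRUE, n_controls = 1200L,
                           n_expected_cases = 80L, n_excess_cases = 30L) {
  ctor <- if (strong) scenario_strong else scenario_null
  ctor(seed = seed, n_controls = n_controls,
       n_expected_cases = n_expected_cases, n_excess_cases = n_excess_cases)
}

small_sim <- function(...) simulate_cohort(small_scenario(...))
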