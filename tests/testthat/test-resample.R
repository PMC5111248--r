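# Build a logit_fit-shaped object from variable-level p-values and signs.
fake_fit <- function(p, est, converged = TRUE) {
  terms <- c("(Intercept)", names(p))
  structure(list(
    coefficients = data.frame(term = terms, estimate = c(0, est),
                              se = 1, p_value = c(1, p),
                              stringsAsFactors = FALSE),
    converged = converged, terms = names(p)), class = "logit_fit")
}

test_that("fit_logit agrees with an independent IRLS fit and recovers truth", {
  set.seed(1234)
  n <- 5000L
  X <- cbind(age_lt75 = rbinom(n, 1, .4), deprivation = sample(1:5, n, TRUE),
             ndvi = rnorm(n, .33, .1))
  beta <- c(-1.2, 0.8, 0.15, -1.5)
  pr <- plogis(cbind(1, X) %*% beta)
  y <- rbinom(n, 1L, pr)
  fit <- fit_logit(cbind(as.data.frame(X), outcome = y))
  orc <- oracle_irls(X, y)

  expect_true(fit$converged)
  expect_equal(fit$coefficients$estimate, unname(orc$estimate),
               tolerance = 1e-6)
  expect_equal(fit$coefficients$se, unname(orc$se), tolerance = 1e-6)
  expect_equal(fit$coefficients$p_value, unname(orc$p), tolerance = 1e-5)
  # both routes within 3 SE of the generating coefficients
  expect_true(all(abs(fit$coefficients$estimate - beta) <
                    3 * fit$coefficients$se))
})

test_that("a covariate unrelated to the outcome is not significant", {
  set.seed(77)
  n <- 4000L
  d <- data.frame(age_lt75 = rbinom(n, 1, .5), outcome = rbinom(n, 1, .3))
  fit <- fit_logit(d)
  co <- fit$coefficients[fit$coefficients$term == "age_lt75", ]
  expect_gt(co$p_value, 0.01)
  expect_lt(abs(co$estimate), 0.3)
})

test_that("degenerate designs are rejected or reported, never mis-fitted", {
  expect_error(fit_logit(data.frame(x = 1:5, outcome = rep(1L, 5))),
               "degenerate")
  expect_error(fit_logit(data.frame(outcome = rep(0:1, 5))), "no covariate")
  # perfect separation: converged = FALSE and zero downstream weight
  d <- data.frame(ndvi = c(sort(runif(20, .5, .9)), sort(runif(20, 0, .45))),
                  outcome = rep(1:0, each = 20L))
  fit <- fit_logit(d)
  expect_false(fit$converged)
  # even a wildly sub-alpha p-value in a non-converged fit carries no weight
  null_fit <- function(cols) fake_fit(p = setNames(rep(.5, length(cols)),
                                                   cols),
                                      est = rep(1, length(cols)))
  fit5 <- list(age = null_fit("age_lt75"),
               location = null_fit(c("loc_residential_institution",
                                     "loc_home", "loc_other")),
               deprivation = null_fit("deprivation"),
               density = null_fit("density_q"),
               ndvi = fit)
  spec <- combination_spec("u", "univariate", "per_model", FALSE, 0.10)
  expect_equal(unname(evaluate_repetition(fit5, spec)), rep(0L, 5L))
})

test_that("draw_sample enforces exact sizes without replacement", {
  ch <- make_tiny_cohort(20, 100, seed = 15)
  set.seed(1)
  s <- draw_sample(ch, 10, 4)
  expect_length(s$case_ids, 10L)
  expect_length(s$control_ids, 40L)
  expect_false(anyDuplicated(s$case_ids) > 0)
  expect_false(anyDuplicated(s$control_ids) > 0)
  expect_true(all(s$case_ids %in% ch$cases$record_id))
  expect_true(all(s$control_ids %in% ch$controls$record_id))

  # exhaustive case draw selects the whole pool
  s2 <- draw_sample(ch, 20, 4)
  expect_setequal(s2$case_ids, ch$cases$record_id)
  expect_error(draw_sample(ch, 30, 4), "sampling error")
  expect_error(draw_sample(ch, 20, 6), "sampling error")
})

multi_fit <- fake_fit(
  p = c(age_lt75 = .04, loc_residential_institution = .20, loc_home = .20,
        loc_other = .20, deprivation = .50, density_q = .30, ndvi = .09),
  est = c(1, 1, 1, 1, 1, 1, -1))

test_that("tally rules reproduce the worked significance examples", {
  count_spec <- combination_spec("m1", "multivariate", "count_significant",
                                 TRUE, 0.10)
  any_spec <- combination_spec("m5", "multivariate", "any_significant",
                               TRUE, 0.10)
  # age .04 (+) and ndvi .09 (-) are the two sub-alpha, right-signed terms
  expect_identical(evaluate_repetition(multi_fit, count_spec), 2L)
  expect_identical(evaluate_repetition(multi_fit, any_spec), 1L)

  # direction gate: the only sub-alpha coefficient has the wrong sign
  wrong <- fake_fit(p = c(age_lt75 = .04, loc_residential_institution = .5,
                          loc_home = .5, loc_other = .5, deprivation = .5,
                          density_q = .5, ndvi = .5),
                    est = c(-1, 1, 1, 1, 1, 1, -1))
  expect_identical(evaluate_repetition(wrong, count_spec), 0L)
  nodir <- combination_spec("m2", "multivariate", "count_significant",
                            FALSE, 0.10)
  expect_identical(evaluate_repetition(wrong, nodir), 1L)

  # the location factor counts once even with several significant dummies
  loc2 <- fake_fit(p = c(age_lt75 = .5, loc_residential_institution = .01,
                         loc_home = .02, loc_other = .5, deprivation = .5,
                         density_q = .5, ndvi = .5),
                   est = c(1, 1, 1, 1, 1, 1, -1))
  expect_identical(evaluate_repetition(loc2, nodir), 1L)

  # contract errors
  uni_spec <- combination_spec("u", "univariate", "per_model", FALSE, 0.10)
  expect_error(evaluate_repetition(multi_fit, uni_spec), "contract error")
})

test_that("weights are bounded and monotone in alpha and direction", {
  vars <- c("age_lt75", "loc_residential_institution", "loc_home",
            "loc_other", "deprivation", "density_q", "ndvi")
  specs <- expand.grid(rule = c("count_significant", "any_significant"),
                       dir = c(TRUE, FALSE), stringsAsFactors = FALSE)
  set.seed(8)
  for (i in 1:40) {
    f <- fake_fit(p = setNames(runif(7), vars),
                  est = setNames(sample(c(-1, 1), 7, TRUE), vars))
    for (j in seq_len(nrow(specs))) {
      w10 <- evaluate_repetition(f, combination_spec(
        "a", "multivariate", specs$rule[j], specs$dir[j], 0.10))
      w05 <- evaluate_repetition(f, combination_spec(
        "b", "multivariate", specs$rule[j], specs$dir[j], 0.05))
      expect_lte(w05, w10)   # stricter alpha never increases the weight
      expect_lte(w10, if (specs$rule[j] == "count_significant") 5L else 1L)
      expect_gte(w05, 0L)
    }
    # removing the direction requirement never decreases the weight
    for (al in c(0.05, 0.10)) for (rule in unique(specs$rule)) {
      wd <- evaluate_repetition(f, combination_spec(
        "c", "multivariate", rule, TRUE, al))
      wf <- evaluate_repetition(f, combination_spec(
        "d", "multivariate", rule, FALSE, al))
      expect_lte(wd, wf)
    }
  }
})

test_that("the twelve standard combinations form the documented cross", {
  specs <- standard_combinations()
  expect_length(specs, 12L)
  expect_identical(names(specs), unname(vapply(specs, `[[`, "", "label")))
  uni <- Filter(function(s) s$model_type == "univariate", specs)
  multi <- Filter(function(s) s$model_type == "multivariate", specs)
  expect_length(uni, 4L)
  expect_length(multi, 8L)
  expect_true(all(vapply(uni, `[[`, "", "tally_rule") == "per_model"))
  expect_setequal(vapply(multi, `[[`, "", "tally_rule"),
                  c("count_significant", "any_significant"))
  grid <- t(vapply(specs, function(s)
    c(s$model_type, s$tally_rule, s$direction_required, s$alpha), character(4)))
  expect_false(anyDuplicated(as.data.frame(grid)) > 0)
  expect_true(all(vapply(specs, `[[`, 0, "alpha") %in% c(0.05, 0.10)))
  # the invalid corners of the cross are rejected
  expect_error(combination_spec("x", "univariate", "any_significant"),
               "per model")
  expect_error(combination_spec("x", "multivariate", "per_model"),
               "any_significant or count_significant")
})
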