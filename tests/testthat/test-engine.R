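test_that("trial tallies match independent brute-force replay exactly", {
  # univariate tallies on a 6-case / 24-control instance, recorded seed
  ch <- make_tiny_cohort(6, 24, seed = 42)
  spec <- standard_combinations()$uni2
  tr <- suppressWarnings(run_trial(ch, spec, n_reps = 2, expected_count = 3,
                                   control_ratio = 2, seed = 1))
  orc <- oracle_trial_tallies(ch, spec, 2, 3, 2, seed = 1)
  expect_identical(as.integer(tr$tally$A), orc$A)
  expect_equal(tr$tally$B, orc$B)

  # multivariate tallies across several recorded seeds
  ch2 <- make_tiny_cohort(10, 60, seed = 7)
  for (s in c(2, 9, 23)) {
    for (lab in c("multi1", "multi6")) {
      spec2 <- standard_combinations()[[lab]]
      tr2 <- suppressWarnings(run_trial(ch2, spec2, n_reps = 3,
                                        expected_count = 6,
                                        control_ratio = 3, seed = s))
      orc2 <- oracle_trial_tallies(ch2, spec2, 3, 6, 3, seed = s)
      expect_identical(as.integer(tr2$tally$A), orc2$A)
      expect_equal(tr2$tally$B, orc2$B)
    }
  }
})

test_that("trials conserve selections and flag the enforced split", {
  ch <- make_tiny_cohort(20, 120, seed = 4)
  for (lab in c("multi1", "uni2")) {
    spec <- standard_combinations()[[lab]]
    tr <- suppressWarnings(run_trial(ch, spec, n_reps = 8,
                                     expected_count = 12, control_ratio = 4,
                                     seed = 31))
    mult <- if (spec$model_type == "univariate") 5L else 1L
    expect_identical(tr$n_draws, 8L * mult)
    expect_identical(sum(tr$tally$A), 12L * tr$n_draws)
    expect_identical(sum(tr$control_selections), 48L * tr$n_draws)
    expect_identical(sort(tr$tally$rank), 1:20)
    expect_identical(sum(tr$tally$flag_excess), 8L)
    expect_true(all(tr$tally$B <= tr$tally$A *
                      (if (spec$tally_rule == "count_significant") 5L else 1L)))
    expect_true(all(tr$tally$ratio[tr$tally$A == 0] == 0))
  }
})

test_that("identical seeds reproduce runs; never-selected cases warn", {
  ch <- make_tiny_cohort(12, 60, seed = 6)
  spec <- standard_combinations()$multi2
  a <- run_combination(ch, spec, n_trials = 3, n_reps = 10,
                       expected_count = 8, control_ratio = 4, seed = 17)
  b <- run_combination(ch, spec, n_trials = 3, n_reps = 10,
                       expected_count = 8, control_ratio = 4, seed = 17)
  expect_identical(a$per_case, b$per_case)
  expect_identical(a$ranks, b$ranks)

  # a single 1-rep trial leaves most cases unselected
  expect_warning(run_trial(ch, spec, n_reps = 1, expected_count = 3,
                           control_ratio = 2, seed = 1),
                 "never selected")
})

test_that("alpha = 1 saturates every converged repetition", {
  ch <- make_tiny_cohort(20, 120, seed = 10)
  spec <- combination_spec("sat", "multivariate", "any_significant",
                           FALSE, 1.0)
  tr <- run_trial(ch, spec, n_reps = 12, expected_count = 12,
                  control_ratio = 4, seed = 5)
  expect_identical(tr$n_nonconverged, 0L)
  expect_true(all(tr$tally$ratio[tr$tally$A > 0] == 1))
  # flags are then decided purely by tie-breaking, but the count holds
  expect_identical(sum(tr$tally$flag_excess), 8L)
})

test_that("combination results keep the label contract and rank summaries", {
  sim <- small_sim(seed = 3)
  res <- run_combination(sim$cohort, standard_combinations()$multi1,
                         n_trials = 4, n_reps = 40, expected_count = 80,
                         control_ratio = 4, seed = 23)
  pc <- res$per_case
  expect_identical(sum(pc$final_label == "probable_excess"), 30L)
  expect_identical(sum(pc$final_label == "probable_expected"), 80L)
  expect_true(all(pc$pct_trials_excess >= 0 & pc$pct_trials_excess <= 100))
  expect_equal(pc$mean_rank, rowMeans(res$ranks))
  expect_equal(pc$rank_sd, apply(res$ranks, 1, sd))
  # every trial column is a permutation
  for (t in 1:4) expect_identical(sort(res$ranks[, t]), 1:110)

  # selection frequency converges to the draw fraction (conservation)
  expect_equal(res$case_selection_rate, 80 / 110, tolerance = 1e-12)
  expect_equal(res$control_selection_rate, 320 / 1200, tolerance = 1e-12)

  # a single trial: labels computed, rank_sd undefined
  r1 <- run_combination(sim$cohort, standard_combinations()$multi1,
                        n_trials = 1, n_reps = 20, expected_count = 80,
                        control_ratio = 4, seed = 29)
  expect_true(all(is.na(r1$per_case$rank_sd)))
  expect_identical(sum(r1$per_case$final_label == "probable_excess"), 30L)
  expect_error(stability_summary(r1), "at least 2 trials")

  expect_error(run_combination(sim$cohort, standard_combinations()$multi1,
                               2, 10, expected_count = 110, seed = 1),
               "run rejected")
})

test_that("per-case selection frequencies match the binomial expectation", {
  ch <- make_tiny_cohort(15, 80, seed = 44)
  spec <- standard_combinations()$multi6
  n_reps <- 150L
  tr <- run_trial(ch, spec, n_reps = n_reps, expected_count = 9,
                  control_ratio = 4, seed = 91)
  p <- 9 / 15
  se <- sqrt(p * (1 - p) / n_reps)
  expect_true(all(abs(tr$tally$A / n_reps - p) < 4 * se))
})

# fake combination_result carrying given rank SDs
fake_result <- function(label, model_type, rank_sd,
                        tally_rule = "count_significant") {
  list(per_case = data.frame(record_id = seq_along(rank_sd),
                             rank_sd = rank_sd),
       spec = list(label = label, model_type = model_type,
                   tally_rule = tally_rule))
}

test_that("stability summaries reduce rank SDs as documented", {
  s1 <- stability_summary(list(fake_result("a", "univariate", rep(3.5, 8))))
  expect_equal(s1$mean_of_rank_sd, 3.5)
  expect_equal(s1$median_of_rank_sd, 3.5)
  expect_equal(s1$sd_of_rank_sd, 0)
  expect_equal(s1$iqr_of_rank_sd, 0)

  s2 <- stability_summary(list(fake_result("b", "univariate", c(1, 2, 3, 4))))
  expect_equal(s2$mean_of_rank_sd, 2.5)
  expect_equal(s2$median_of_rank_sd, 2.5)
})

test_that("the most consistent combinations are selected by rank-SD spread", {
  # ordering and tie rules
  s <- data.frame(label = c("u_a", "u_b"), model_type = "univariate",
                  mean_of_rank_sd = c(10, 20), median_of_rank_sd = c(9, 19))
  expect_identical(select_most_consistent(s)$univariate, "u_a")
  s2 <- data.frame(label = c("u_a", "u_b"), model_type = "univariate",
                   mean_of_rank_sd = c(10, 10), median_of_rank_sd = c(5, 4))
  expect_identical(select_most_consistent(s2)$univariate, "u_b")
  expect_error(select_most_consistent(s[0, ]), "no stability summaries")

  # the published rank-SD table singles out uni #2 and multi #1
  tab1 <- data.frame(
    label = c("uni1", "uni2", "uni3", "uni4", "multi1", "multi2", "multi3",
              "multi4", "multi5", "multi6", "multi7", "multi8"),
    model_type = rep(c("univariate", "multivariate"), c(4, 8)),
    mean_of_rank_sd = c(36.94, 36.61, 41.12, 41.05, 50.56, 50.56, 60.07,
                        60.31, 89.74, 89.83, 66.83, 67.07),
    median_of_rank_sd = c(40.37, 40.10, 44.44, 44.40, 54.23, 54.43, 64.25,
                          63.89, 93.17, 94.09, 74.09, 74.75))
  pick <- select_most_consistent(tab1)
  expect_identical(pick$univariate, "uni2")
  # multi1 and multi2 tie on the mean; the median breaks the tie
  expect_identical(pick$multivariate, "multi1")
})
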