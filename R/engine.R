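# Fast per-repetition weight from an internal core fit.
.rep_weight <- function(fitcore, spec, expectations) {
  sig <- .variable_significance(fitcore, .analysis_variables, spec,
                                expectations)
  if (spec$tally_rule == "any_significant") as.integer(any(sig))
  else sum(as.integer(sig))
}

#' Run one trial of resampling repetitions
#'
#' A trial executes `n_reps` repetitions. Each repetition draws
#' `expected_count` cases and `control_ratio * expected_count` controls
#' (without replacement, fresh each repetition), fits the combination's
#' logit model(s), and converts the fit into a significance weight. Two
#' tallies accumulate per case: A, the number of draws containing the
#' case, and B, the sum of repetition weights over those draws. For
#' univariate combinations each repetition comprises five independent
#' draw-and-fit steps (one per variable, in the order age, location,
#' deprivation, density, ndvi) and tallies are summed across variables.
#'
#' After all repetitions, each case gets a probability ratio B/A (cases
#' never selected get ratio 0 with a warning), cases are ranked by
#' descending ratio (ties broken by a random permutation drawn once per
#' trial), and the top `n_cases - expected_count` are flagged as the more
#' probable excess deaths of the trial.
#'
#' Within a repetition the RNG is consumed in a fixed order (case draw,
#' then control draw, per model), so a recorded seed fully determines
#' every draw.
#'
#' @param cohort A [cohort()] object.
#' @param spec A [combination_spec()].
#' @param n_reps Repetitions in the trial (study scale: 10,000).
#' @param expected_count Baseline expected deaths for a window of the
#'   event's length; both the per-repetition case draw size and the count
#'   of cases classified as probable expected (study scale: 297).
#' @param control_ratio Controls per case (default 4).
#' @param seed Optional integer seed for the trial's RNG stream.
#' @return An object of class `trial_result`: list with `tally` (data
#'   frame: `record_id`, `A`, `B`, `ratio`, `rank`, `flag_excess`),
#'   `control_selections`, `n_draws` (case draws performed),
#'   `n_nonconverged`, and the configuration.
#' @export
run_trial <- function(cohort, spec, n_reps, expected_count,
                      control_ratio = 4L, seed = NULL, .design = NULL) {
  stopifnot(inherits(spec, "combination_spec"), n_reps >= 1L)
  n_reps <- as.integer(n_reps)
  expected_count <- as.integer(expected_count)
  control_ratio <- as.integer(control_ratio)
  if (!is.null(seed)) set.seed(seed)
  dm <- if (is.null(.design)) .design_matrix(cohort) else .design
  n_cases <- dm$n_cases
  if (expected_count >= n_cases)
    stop("run rejected: case pool (", n_cases,
         ") must exceed expected_count (", expected_count, ")")
  expectations <- direction_expectations()
  univariate <- spec$model_type == "univariate"
  var_cols <- dm$var_cols

  A <- integer(n_cases)
  B <- numeric(n_cases)
  ctl_A <- integer(dm$n_controls)
  n_nonconv <- 0L

  for (r in seq_len(n_reps)) {
    if (univariate) {
      for (v in .analysis_variables) {
        d <- .draw_indices(n_cases, dm$n_controls, expected_count,
                           control_ratio)
        idx <- c(d$case_idx, n_cases + d$control_idx)
        f <- .fit_logit_core(dm$X[idx, var_cols[[v]], drop = FALSE],
                             dm$y[idx])
        if (!f$converged) n_nonconv <- n_nonconv + 1L
        w <- as.integer(.variable_significance(f, v, spec, expectations))
        A[d$case_idx] <- A[d$case_idx] + 1L
        if (w > 0L) B[d$case_idx] <- B[d$case_idx] + w
        ctl_A[d$control_idx] <- ctl_A[d$control_idx] + 1L
      }
    } else {
      d <- .draw_indices(n_cases, dm$n_controls, expected_count,
                         control_ratio)
      idx <- c(d$case_idx, n_cases + d$control_idx)
      f <- .fit_logit_core(dm$X[idx, , drop = FALSE], dm$y[idx])
      if (!f$converged) n_nonconv <- n_nonconv + 1L
      w <- .rep_weight(f, spec, expectations)
      A[d$case_idx] <- A[d$case_idx] + 1L
      if (w > 0L) B[d$case_idx] <- B[d$case_idx] + w
      ctl_A[d$control_idx] <- ctl_A[d$control_idx] + 1L
    }
  }

  never <- A == 0L
  if (any(never))
    warning(sum(never), " case(s) never selected in this trial; ",
            "probability ratio set to 0")
  ratio <- ifelse(never, 0, B / pmax(A, 1L))
  tie_perm <- sample.int(n_cases)
  rank <- integer(n_cases)
  rank[order(-ratio, tie_perm)] <- seq_len(n_cases)
  flag <- rank <= (n_cases - expected_count)

  structure(list(
    tally = data.frame(record_id = dm$case_ids, A = A, B = B, ratio = ratio,
                       rank = rank, flag_excess = flag,
                       stringsAsFactors = FALSE),
    control_selections = ctl_A,
    n_draws = n_reps * (if (univariate) 5L else 1L),
    n_nonconverged = n_nonconv,
    spec = spec, n_reps = n_reps, expected_count = expected_count,
    control_ratio = control_ratio, seed = seed), class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("trial_result (%s): %d reps, %d cases, %d flagged excess\n",
              x$spec$label, x$n_reps, nrow(x$tally), sum(x$tally$flag_excess)))
  invisible(x)
}

#' Run a full combination: many trials, cross-trial aggregation
#'
#' Runs `n_trials` independent trials (each on its own RNG substream
#' derived from the master seed, so trials are reproducible in isolation)
#' and aggregates: per case, the percentage of trials flagging it as a
#' more probable excess death, its mean rank, and the standard deviation
#' of its rank across trials (sample SD, n-1). The
#' `n_cases - expected_count` cases with the highest flag percentages are
#' labeled `probable_excess`, the remainder `probable_expected`; ties at
#' the boundary are broken by a random permutation drawn once per
#' combination from the master stream.
#'
#' @inheritParams run_trial
#' @param n_trials Number of trials (study scale: 100). With fewer than 2
#'   trials `rank_sd` is undefined (NA) but labels are still computed.
#' @param seed Master seed for the combination.
#' @return Object of class `combination_result`: list with `per_case`
#'   (data frame: `record_id`, `A`, `B`, `pct_trials_excess`, `mean_rank`,
#'   `rank_sd`, `final_label`), `ranks` (cases x trials matrix),
#'   `control_selection_rate`, `n_draws_total`, `n_nonconverged`, and the
#'   run configuration.
#' @export
run_combination <- function(cohort, spec, n_trials, n_reps, expected_count,
                            control_ratio = 4L, seed = 1L) {
  stopifnot(n_trials >= 1L)
  n_trials <- as.integer(n_trials)
  expected_count <- as.integer(expected_count)
  dm <- .design_matrix(cohort)
  n_cases <- dm$n_cases
  n_excess <- n_cases - expected_count
  set.seed(seed)
  seeds <- sample.int(2147483646L, n_trials + 1L)

  ranks <- matrix(NA_integer_, n_cases, n_trials)
  flags <- matrix(FALSE, n_cases, n_trials)
  A <- integer(n_cases); B <- numeric(n_cases)
  ctl_sel <- 0; n_nonconv <- 0L; n_draws <- 0L
  for (t in seq_len(n_trials)) {
    tr <- run_trial(cohort, spec, n_reps, expected_count, control_ratio,
                    seed = seeds[t], .design = dm)
    ranks[, t] <- tr$tally$rank
    flags[, t] <- tr$tally$flag_excess
    A <- A + tr$tally$A; B <- B + tr$tally$B
    ctl_sel <- ctl_sel + sum(tr$control_selections)
    n_nonconv <- n_nonconv + tr$n_nonconverged
    n_draws <- n_draws + tr$n_draws
  }

  pct <- 100 * rowMeans(flags)
  mean_rank <- rowMeans(ranks)
  rank_sd <- if (n_trials >= 2L) apply(ranks, 1L, stats::sd)
             else rep(NA_real_, n_cases)
  # Final labels: highest flag percentage wins; cases with equal flag
  # percentages are ordered by mean rank (the trials' own evidence), and
  # only residual ties fall to a seeded random permutation. With few
  # trials the flag percentage takes few distinct values, so the
  # secondary key matters; at study scale (100 trials) it rarely does.
  set.seed(seeds[n_trials + 1L])
  tie_perm <- sample.int(n_cases)
  final_label <- rep("probable_expected", n_cases)
  final_label[order(-pct, mean_rank, tie_perm)[seq_len(n_excess)]] <-
    "probable_excess"

  structure(list(
    per_case = data.frame(record_id = dm$case_ids, A = A, B = B,
                          pct_trials_excess = pct, mean_rank = mean_rank,
                          rank_sd = rank_sd, final_label = final_label,
                          stringsAsFactors = FALSE),
    ranks = ranks,
    control_selection_rate = ctl_sel / (dm$n_controls * n_draws),
    case_selection_rate = sum(A) / (n_cases * n_draws),
    n_draws_total = n_draws, n_nonconverged = n_nonconv,
    spec = spec, n_trials = n_trials, n_reps = n_reps,
    expected_count = expected_count, control_ratio = control_ratio,
    seed = seed), class = "combination_result")
}

#' @export
print.combination_result <- function(x, ...) {
  cat(sprintf(
    "combination_result %s: %d trials x %d reps; %d cases (%d excess / %d expected)\n",
    x$spec$label, x$n_trials, x$n_reps, nrow(x$per_case),
    sum(x$per_case$final_label == "probable_excess"),
    sum(x$per_case$final_label == "probable_expected")))
  if (x$n_trials >= 2L)
    cat(sprintf("  mean rank SD across cases: %.2f\n",
                mean(x$per_case$rank_sd)))
  invisible(x)
}

#' Summarize rank stability for one or more combinations
#'
#' The spread of per-case rank standard deviations across trials is the
#' framework's consistency diagnostic: combinations whose case rankings
#' are reproducible across trials have low rank SDs.
#'
#' @param results A `combination_result` or list of them.
#' @return Data frame with one row per combination: `label`, `model_type`,
#'   `tally_rule`, `mean_of_rank_sd`, `sd_of_rank_sd`, `median_of_rank_sd`,
#'   `iqr_of_rank_sd`.
#' @export
stability_summary <- function(results) {
  if (inherits(results, "combination_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    if (anyNA(r$per_case$rank_sd))
      stop("rank_sd undefined (need at least 2 trials) for ", r$spec$label)
    s <- r$per_case$rank_sd
    data.frame(label = r$spec$label, model_type = r$spec$model_type,
               tally_rule = r$spec$tally_rule,
               mean_of_rank_sd = mean(s), sd_of_rank_sd = stats::sd(s),
               median_of_rank_sd = stats::median(s),
               iqr_of_rank_sd = stats::IQR(s), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select the most consistent univariate and multivariate combinations
#'
#' Within each model type, picks the combination minimizing the mean of
#' the per-case rank SDs; ties are broken by the median of the rank SDs,
#' then by input order.
#'
#' @param summaries Data frame as returned by [stability_summary()]
#'   (columns `label`, `model_type`, `mean_of_rank_sd`,
#'   `median_of_rank_sd`).
#' @return Named list with the winning `label` per model type present.
#' @export
select_most_consistent <- function(summaries) {
  if (is.null(summaries) || nrow(summaries) == 0L)
    stop("no stability summaries supplied")
  out <- list()
  for (mt in intersect(c("univariate", "multivariate"),
                       unique(summaries$model_type))) {
    sub <- summaries[summaries$model_type == mt, , drop = FALSE]
    ord <- order(sub$mean_of_rank_sd, sub$median_of_rank_sd,
                 seq_len(nrow(sub)))
    out[[mt]] <- sub$label[ord[1L]]
  }
  out
}
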