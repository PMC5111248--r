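#' Compare a group of deaths with the control pool on the five variables
#'
#' Variable-by-variable comparison of a labeled group (e.g. the probable
#' excess deaths) against controls: a Welch two-sample t-test for NDVI,
#' chi-square tests for the categorical age (<75 / >=75) and location of
#' death variables, and Wilcoxon rank-sum tests for the ordinal
#' deprivation and density quintiles. The probable excess deaths are
#' expected to differ from controls on each variable; the probable
#' expected deaths are not.
#'
#' The age (2x2) chi-square uses the Yates continuity correction by
#' default; the 4-category location table never does. Location categories
#' empty in both groups are dropped with a message. The Wilcoxon test
#' uses the normal approximation with tie correction, switching to exact
#' enumeration only for tie-free samples with a group of 25 or fewer.
#'
#' @param group Data frame of records (e.g. a subset of cases).
#' @param controls Data frame of control records.
#' @param yates Logical, continuity correction for 2x2 tables.
#' @return Data frame of class `group_comparison`: one row per variable
#'   with `variable`, `test`, `statistic`, `p_value`.
#' @export
compare_to_controls <- function(group, controls, yates = TRUE) {
  if (nrow(group) == 0L) stop("group must be non-empty")
  row <- function(variable, test, ht)
    data.frame(variable = variable, test = test,
               statistic = unname(ht$statistic), p_value = ht$p.value,
               stringsAsFactors = FALSE)

  age_tab <- rbind(group = table(factor(group$age_years < 75, c(TRUE, FALSE))),
                   control = table(factor(controls$age_years < 75,
                                          c(TRUE, FALSE))))
  age_ht <- suppressWarnings(stats::chisq.test(age_tab, correct = yates))

  loc_tab <- rbind(group = table(factor(group$location_of_death,
                                        .location_levels)),
                   control = table(factor(controls$location_of_death,
                                          .location_levels)))
  empty <- colSums(loc_tab) == 0L
  if (any(empty)) {
    message("dropping location categor", if (sum(empty) > 1L) "ies" else "y",
            " empty in both groups: ",
            paste(colnames(loc_tab)[empty], collapse = ", "))
    loc_tab <- loc_tab[, !empty, drop = FALSE]
  }
  loc_ht <- suppressWarnings(stats::chisq.test(loc_tab, correct = FALSE))

  wilcox <- function(x, y) {
    exact <- min(length(x), length(y)) <= 25L && !anyDuplicated(c(x, y))
    suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  }
  dep_ht <- wilcox(group$deprivation_quintile, controls$deprivation_quintile)
  den_ht <- wilcox(group$density_quintile, controls$density_quintile)
  ndvi_ht <- stats::t.test(group$ndvi, controls$ndvi, var.equal = FALSE)

  out <- rbind(row("age", "chi_square", age_ht),
               row("location", "chi_square", loc_ht),
               row("deprivation", "wilcoxon_rank_sum", dep_ht),
               row("density", "wilcoxon_rank_sum", den_ht),
               row("ndvi", "welch_t", ndvi_ht))
  class(out) <- c("group_comparison", class(out))
  out
}

#' Significance band of a p-value
#'
#' The four reporting bands used for group-comparison heat maps:
#' `<0.001`, `0.001-0.01`, `0.01-0.05`, `>=0.05`.
#'
#' @param p Numeric vector of p-values.
#' @return Ordered factor of bands.
#' @export
significance_band <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("<0.001", "0.001-0.01", "0.01-0.05", ">=0.05"),
      right = FALSE, ordered_result = TRUE)
}

#' Pairwise overlap of probable excess sets between combinations
#'
#' Entry (i, j) is `100 * |excess_i intersect excess_j| / set size`. The
#' framework guarantees equal set sizes (`n_cases - expected_count`); if
#' sizes differ the smaller is used as the denominator with a warning.
#'
#' @param sets Named list of record-id vectors, one per combination.
#' @return Square numeric matrix of percentages (diagonal 100).
#' @export
overlap_percent <- function(sets) {
  if (length(sets) < 1L) stop("no sets supplied")
  sizes <- lengths(sets)
  if (length(unique(sizes)) > 1L)
    warning("sets differ in size; overlap computed against the smaller set")
  k <- length(sets)
  m <- matrix(0, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k))
    m[i, j] <- 100 * length(intersect(sets[[i]], sets[[j]])) /
      min(sizes[i], sizes[j])
  m
}

#' Consensus probable excess deaths across combinations
#'
#' The cases identified as probable excess deaths by every combination,
#' with the consensus size as a percentage of the (common) excess-set
#' size.
#'
#' @param sets Named list of at least two record-id vectors.
#' @return List with `ids` (intersection) and `pct_of_set` (percentage).
#' @export
consensus_set <- function(sets) {
  if (length(sets) < 2L) stop("need at least 2 sets")
  ids <- Reduce(intersect, sets)
  list(ids = ids, pct_of_set = 100 * length(ids) / length(sets[[1L]]))
}

#' Daily distribution of a group of deaths over the event window
#'
#' Proportion of the group's deaths on each event day, plus whether every
#' event day is represented. Probable excess deaths are expected to shift
#' towards the hottest days while still appearing on every day.
#'
#' @param group Data frame of case records (subset of the cohort's cases).
#' @param cohort A [cohort()] object supplying the event window.
#' @return Data frame with `date`, `n`, `proportion`; attribute
#'   `every_day_represented`.
#' @export
daily_distribution <- function(group, cohort) {
  if (!all(group$record_id %in% cohort$cases$record_id))
    stop("group must be a subset of the cohort's cases")
  tab <- table(factor(format(group$death_date, "%Y-%m-%d"),
                      levels = format(cohort$event_dates, "%Y-%m-%d")))
  out <- data.frame(date = cohort$event_dates, n = as.integer(tab),
                    proportion = as.numeric(tab) / nrow(group))
  attr(out, "every_day_represented") <- all(out$n > 0L)
  out
}

#' Score recovery of synthetic ground truth
#'
#' Standard 2x2 classification metrics of the `probable_excess` labels
#' against a scenario's known excess deaths. Under the enforced label
#' count (`n_cases - expected_count` positives) and an uninformative
#' classifier, expected sensitivity equals the excess fraction of the
#' case pool (114/411 = 0.277 at study scale).
#'
#' @param result A `combination_result` (or a data frame with
#'   `record_id`, `final_label`).
#' @param truth Data frame `record_id`, `truth_label` from
#'   [simulate_cohort()].
#' @return List with `sensitivity`, `specificity`, `ppv` and the 2x2
#'   counts `tp`, `fp`, `fn`, `tn`.
#' @export
recovery_metrics <- function(result, truth) {
  labels <- if (inherits(result, "combination_result")) result$per_case
            else result
  m <- match(labels$record_id, truth$record_id)
  if (anyNA(m))
    stop("truth labels missing for ",
         paste(utils::head(labels$record_id[is.na(m)], 5L), collapse = ", "))
  is_pos <- labels$final_label == "probable_excess"
  is_exc <- truth$truth_label[m] == "excess"
  tp <- sum(is_pos & is_exc);  fp <- sum(is_pos & !is_exc)
  fn <- sum(!is_pos & is_exc); tn <- sum(!is_pos & !is_exc)
  list(sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0L) tn / (tn + fp) else NA_real_,
       ppv = if (tp + fp > 0L) tp / (tp + fp) else NA_real_,
       tp = tp, fp = fp, fn = fn, tn = tn)
}
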