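# Index-level sampling primitive shared by draw_sample() and the trial
# engine. RNG consumption order is part of the contract: case indices are
# drawn first, then control indices, each as a uniform simple random
# sample without replacement.
.draw_indices <- function(n_cases, n_controls, n_case_draw, control_ratio) {
  n_ctl_draw <- control_ratio * n_case_draw
  if (n_case_draw > n_cases)
    stop("sampling error: n_case_draw (", n_case_draw,
         ") exceeds case pool size (", n_cases, ")")
  if (n_ctl_draw > n_controls)
    stop("sampling error: control draw (", n_ctl_draw,
         ") exceeds control pool size (", n_controls, ")")
  list(case_idx = sample.int(n_cases, n_case_draw),
       control_idx = sample.int(n_controls, n_ctl_draw))
}

#' Draw one case-control repetition sample
#'
#' Selects `n_case_draw` cases and `control_ratio * n_case_draw` controls,
#' each by uniform simple random sampling without replacement from its
#' pool. At the study's scale this draws 297 of the 411 cases (the
#' expected count) and 1188 of the 11,632 controls, a 4:1 control:case
#' ratio.
#'
#' @param cohort A [cohort()] object.
#' @param n_case_draw Number of cases per repetition (the expected count).
#' @param control_ratio Controls drawn per case (default 4).
#' @return List with `case_ids` and `control_ids` (record id vectors).
#' @export
draw_sample <- function(cohort, n_case_draw, control_ratio = 4L) {
  d <- .draw_indices(nrow(cohort$cases), nrow(cohort$controls),
                     n_case_draw, control_ratio)
  list(case_ids = cohort$cases$record_id[d$case_idx],
       control_ids = cohort$controls$record_id[d$control_idx])
}

# Normalize a public logit_fit to the internal core-fit view.
.core_view <- function(fit) {
  if (inherits(fit, "logit_fit")) {
    cf <- fit$coefficients
    list(estimate = stats::setNames(cf$estimate, cf$term),
         se = stats::setNames(cf$se, cf$term),
         p = stats::setNames(cf$p_value, cf$term),
         converged = fit$converged, terms = cf$term)
  } else fit
}

# Variable-level significance for one fit: the location factor counts as
# a single variable, significant when any of its indicators is (direction
# applied per indicator).
.variable_significance <- function(fit, variables, spec, expectations) {
  vc <- variable_columns()
  out <- logical(length(variables))
  names(out) <- variables
  for (v in variables) {
    cols <- intersect(vc[[v]], fit$terms)
    if (length(cols) == 0L)
      stop("contract error: fit has no terms for variable '", v, "'")
    out[v] <- any(.significant_terms(fit, cols, spec$alpha,
                                     spec$direction_required, expectations))
  }
  out
}

#' Convert fits from one repetition into a significance weight
#'
#' Applies a combination's tally rule. A term is significant when its fit
#' converged, its Wald p-value is below the combination's alpha, and (if
#' the combination requires it) the coefficient sign matches the expected
#' direction. The location-of-death factor counts as one variable,
#' significant when any of its three indicators is.
#'
#' For univariate combinations, supply the five single-variable fits as a
#' list named by variable; each model contributes weight 1 when its
#' variable is significant. For multivariate combinations, supply the
#' single five-variable fit; `any_significant` gives weight 1 when at
#' least one variable is significant, `count_significant` gives the
#' number of significant variables (0-5).
#'
#' @param fits A [fit_logit()] result (multivariate) or a named list of
#'   five of them (univariate, names = variable names).
#' @param spec A [combination_spec()].
#' @param expectations Named sign vector, see [direction_expectations()].
#' @return Integer weight per fit: a named length-5 vector of 0/1 for
#'   univariate specs, a single integer for multivariate specs.
#' @export
evaluate_repetition <- function(fits, spec,
                                expectations = direction_expectations()) {
  stopifnot(inherits(spec, "combination_spec"))
  if (spec$model_type == "univariate") {
    if (!is.list(fits) || inherits(fits, "logit_fit") || length(fits) != 5L)
      stop("contract error: univariate spec needs a list of five fits")
    if (is.null(names(fits)) || !setequal(names(fits), .analysis_variables))
      stop("contract error: univariate fits must be named by variable")
    fits <- lapply(fits, .core_view)
    w <- vapply(.analysis_variables, function(v)
      as.integer(.variable_significance(fits[[v]], v, spec, expectations)),
      integer(1))
    return(w)
  }
  if (is.list(fits) && !inherits(fits, "logit_fit") &&
      is.null(fits$terms) && length(fits) == 1L)
    fits <- fits[[1L]]
  fit <- .core_view(fits)
  sig <- .variable_significance(fit, .analysis_variables, spec, expectations)
  if (spec$tally_rule == "any_significant") as.integer(any(sig))
  else sum(as.integer(sig))
}
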