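#' Define a modeling combination
#'
#' A combination fixes the four modeling choices varied in the sensitivity
#' analysis: model type (five univariate logit models versus one
#' multivariate model), how per-repetition significance is tallied,
#' whether a coefficient must have the a-priori expected sign to count,
#' and the significance threshold.
#'
#' Univariate combinations always tally per model (`per_model`): each of
#' the five variable models contributes weight 1 when it has a significant
#' term, and selection/significance tallies are summed across variables.
#' Multivariate combinations tally either `any_significant` (weight 1 when
#' at least one variable is significant) or `count_significant` (weight =
#' number of significant variables, 0-5).
#'
#' @param label Short identifier, e.g. `"uni2"` or `"multi1"`.
#' @param model_type `"univariate"` or `"multivariate"`.
#' @param tally_rule `"per_model"`, `"any_significant"`, or
#'   `"count_significant"`.
#' @param direction_required Logical; when `TRUE` a term only counts as
#'   significant if its coefficient sign matches [direction_expectations()].
#' @param alpha Significance threshold in (0, 1).
#' @return An object of class `combination_spec`.
#' @export
combination_spec <- function(label, model_type = c("univariate", "multivariate"),
                             tally_rule = c("per_model", "any_significant",
                                            "count_significant"),
                             direction_required = FALSE, alpha = 0.10) {
  model_type <- match.arg(model_type)
  tally_rule <- match.arg(tally_rule)
  if (model_type == "univariate" && tally_rule != "per_model")
    stop("univariate combinations tally per model")
  if (model_type == "multivariate" && tally_rule == "per_model")
    stop("multivariate combinations tally any_significant or count_significant")
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]")
  structure(list(label = label, model_type = model_type,
                 tally_rule = tally_rule,
                 direction_required = isTRUE(direction_required),
                 alpha = alpha),
            class = "combination_spec")
}

#' @export
print.combination_spec <- function(x, ...) {
  cat(sprintf("combination %s: %s, %s, direction %s, alpha %.2f\n",
              x$label, x$model_type, x$tally_rule,
              if (x$direction_required) "required" else "ignored", x$alpha))
  invisible(x)
}

#' The twelve standard modeling combinations
#'
#' The cross of: univariate x direction \{required, ignored\} x alpha
#' \{0.10, 0.05\} (four combinations, `uni1`-`uni4`) and multivariate x
#' tally \{count_significant, any_significant\} x direction x alpha (eight
#' combinations, `multi1`-`multi8`). `multi1`-`multi4` count significant
#' variables; `multi5`-`multi8` tally at least one significant variable.
#' Odd numbers require the expected coefficient direction, and alpha 0.10
#' precedes 0.05 within each block.
#'
#' @return Named list of twelve [combination_spec()] objects.
#' @export
standard_combinations <- function() {
  specs <- list(
    combination_spec("uni1", "univariate", "per_model", TRUE,  0.10),
    combination_spec("uni2", "univariate", "per_model", FALSE, 0.10),
    combination_spec("uni3", "univariate", "per_model", TRUE,  0.05),
    combination_spec("uni4", "univariate", "per_model", FALSE, 0.05),
    combination_spec("multi1", "multivariate", "count_significant", TRUE,  0.10),
    combination_spec("multi2", "multivariate", "count_significant", FALSE, 0.10),
    combination_spec("multi3", "multivariate", "count_significant", TRUE,  0.05),
    combination_spec("multi4", "multivariate", "count_significant", FALSE, 0.05),
    combination_spec("multi5", "multivariate", "any_significant", TRUE,  0.10),
    combination_spec("multi6", "multivariate", "any_significant", FALSE, 0.10),
    combination_spec("multi7", "multivariate", "any_significant", TRUE,  0.05),
    combination_spec("multi8", "multivariate", "any_significant", FALSE, 0.05))
  names(specs) <- vapply(specs, `[[`, "", "label")
  specs
}

#' Expected coefficient directions for the five heat-vulnerability variables
#'
#' Signs established by prior hot-weather mortality work: risk is higher
#' for the younger (<75) age category, for any location of death compared
#' with death in hospital, for increasing deprivation, and for increasing
#' population density; risk decreases with increasing greenness (NDVI).
#'
#' @return Named numeric vector over design columns with entries +1 / -1.
#' @export
direction_expectations <- function() {
  c(age_lt75 = 1,
    loc_residential_institution = 1, loc_home = 1, loc_other = 1,
    deprivation = 1, density_q = 1, ndvi = -1)
}

# Maximum per-repetition weight attainable under a spec.
.max_weight <- function(spec) {
  if (spec$tally_rule == "count_significant") 5L else 1L
}
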