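#' @keywords internal
"_PACKAGE"

# Canonical analysis variables and their design-matrix columns.
.analysis_variables <- c("age", "location", "deprivation", "density", "ndvi")

.location_levels <- c("hospital", "residential_institution", "home", "other")

#' Design-matrix columns for each analysis variable
#'
#' The five analysis variables are encoded as seven design columns: a binary
#' indicator for age below 75, three indicators for location of death
#' (hospital is the reference), ordered deprivation and population-density
#' quintiles treated as continuous scores, and continuous NDVI greenness.
#'
#' @return Named list mapping each variable name to its design column names.
#' @export
variable_columns <- function() {
  list(
    age         = "age_lt75",
    location    = c("loc_residential_institution", "loc_home", "loc_other"),
    deprivation = "deprivation",
    density     = "density_q",
    ndvi        = "ndvi"
  )
}

.required_columns <- c("record_id", "death_date", "age_years",
                       "location_of_death", "deprivation_quintile", "ndvi")

#' Read a pool of death records from a delimited text file
#'
#' Reads and validates one pool (cases or controls) of decedent records.
#' The file must have a header naming at least `record_id`, `death_date`
#' (ISO-8601), `age_years`, `location_of_death` (one of `hospital`,
#' `residential_institution`, `home`, `other`), `deprivation_quintile`
#' (1-5, 1 = least deprived), `ndvi` (in \[-1, 1\]), and either
#' `population_density` (persons/km^2) or `density_quintile` (1-5).
#' An optional `sex` column is carried through but never used analytically.
#'
#' Rows with a missing value in any analysis field are dropped with a
#' message reporting the count; rows with an out-of-range or unparseable
#' value raise a validation error naming the offending `record_id`s.
#'
#' @param path Path to a CSV file.
#' @param group Either `"case"` or `"control"`; recorded on every row.
#' @return A `data.frame` of validated records with a `group` column.
#' @export
read_pool <- function(path, group = c("case", "control")) {
  group <- match.arg(group)
  if (!file.exists(path)) stop("pool file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.required_columns, names(raw))
  if (length(missing_cols) > 0L)
    stop("schema error in ", path, ": missing required column(s) ",
         paste(missing_cols, collapse = ", "))
  if (!any(c("population_density", "density_quintile") %in% names(raw)))
    stop("schema error in ", path,
         ": need population_density or density_quintile")
  validate_pool(raw, group = group, source = path)
}

#' Validate a data frame of death records
#'
#' The validation applied by [read_pool()], exposed for records built in
#' memory (e.g. by the synthetic-cohort generator).
#'
#' @param records Data frame with the columns described in [read_pool()].
#' @param group `"case"` or `"control"`.
#' @param source Label used in diagnostics.
#' @return Validated `data.frame` with typed columns and a `group` column.
#' @export
validate_pool <- function(records, group = c("case", "control"),
                          source = "records") {
  group <- match.arg(group)
  df <- records
  df$record_id <- as.character(df$record_id)

  has_density <- "population_density" %in% names(df)
  has_dq <- "density_quintile" %in% names(df)

  # death_date: parse first so NA-from-parse counts as invalid, not missing
  was_na <- is.na(df$death_date)
  dd <- as.Date(as.character(df$death_date), format = "%Y-%m-%d")
  bad_date <- !was_na & is.na(dd)
  df$death_date <- dd

  # drop rows missing any analysis value (the data sources are administrative
  # and incompleteness is expected; dropped counts are reported)
  dens_missing <- if (has_dq) is.na(df$density_quintile)
                  else is.na(df$population_density)
  incomplete <- was_na | is.na(df$age_years) | is.na(df$location_of_death) |
    df$location_of_death == "" | is.na(df$deprivation_quintile) |
    is.na(df$ndvi) | dens_missing
  if (any(incomplete)) {
    message("dropping ", sum(incomplete), " of ", nrow(df),
            " records from ", source, " with missing analysis values")
    df <- df[!incomplete, , drop = FALSE]
    bad_date <- bad_date[!incomplete]
  }
  if (nrow(df) == 0L) stop("no complete records in ", source)

  bad <- function(cond, what) {
    if (any(cond))
      stop("validation error in ", source, " (", what, "): record_id ",
           paste(utils::head(df$record_id[cond], 10L), collapse = ", "),
           if (sum(cond) > 10L) " ..." else "")
  }
  bad(bad_date, "death_date not ISO-8601 YYYY-MM-DD")
  bad(duplicated(df$record_id), "duplicate record_id")
  bad(df$age_years < 0 | df$age_years != round(df$age_years),
      "age_years must be a non-negative integer")
  bad(!(df$location_of_death %in% .location_levels),
      "location_of_death outside the 4-level set")
  bad(!(df$deprivation_quintile %in% 1:5), "deprivation_quintile not in 1..5")
  if (has_dq) bad(!(df$density_quintile %in% 1:5),
                  "density_quintile not in 1..5")
  if (has_density) bad(df$population_density < 0,
                       "population_density negative")
  bad(df$ndvi < -1 | df$ndvi > 1, "ndvi outside [-1, 1]")

  df$age_years <- as.integer(df$age_years)
  df$deprivation_quintile <- as.integer(df$deprivation_quintile)
  if (has_dq) df$density_quintile <- as.integer(df$density_quintile)
  df$ndvi <- as.numeric(df$ndvi)
  df$group <- group
  rownames(df) <- NULL
  df
}

#' Write a pool of death records to CSV
#'
#' Inverse of [read_pool()]: all analysis fields round-trip exactly.
#'
#' @param pool Data frame of records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pool <- function(pool, path) {
  out <- pool
  out$death_date <- format(out$death_date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bin values into sample quintiles
#'
#' Assigns quintile 1-5 membership so that bin k holds values between the
#' (k-1)/5 and k/5 sample quantiles (type 7). Values tied with a boundary
#' all receive the lower bin, so the assignment is deterministic and
#' order-independent; degenerate input (all values equal) maps to bin 1.
#' Alternatively, explicit upper boundaries for bins 1-4 may be supplied,
#' e.g. published quintile cut points.
#'
#' @param values Numeric vector, length at least 5 (unless `breaks` given).
#' @param breaks Optional numeric vector of 4 increasing upper boundaries
#'   for bins 1-4; values greater than all boundaries fall in bin 5.
#' @return Integer vector of bins in 1..5.
#' @export
quintile_bin <- function(values, breaks = NULL) {
  if (anyNA(values)) stop("quintile_bin: missing values not allowed")
  if (is.null(breaks)) {
    if (length(values) < 5L)
      stop("quintile_bin: need at least 5 values, got ", length(values))
    breaks <- stats::quantile(values, probs = c(.2, .4, .6, .8),
                              names = FALSE, type = 7)
  } else {
    if (length(breaks) != 4L || is.unsorted(breaks))
      stop("quintile_bin: breaks must be 4 increasing boundaries")
  }
  # ties at a boundary go to the lower bin: count boundaries strictly below
  bins <- rowSums(outer(values, breaks, ">")) + 1L
  as.integer(bins)
}

#' Assemble a case-control cohort
#'
#' Combines a case pool (deaths during the event window) and a control pool
#' (deaths during comparison-period typical weather) into a validated
#' cohort. Every case death date must lie within `event_dates` and no
#' control date may. If any record lacks a `density_quintile`, quintiles
#' are derived once from `population_density` pooled over both groups (a
#' decedent's neighborhood quintile is a fixed attribute, so binning is
#' never repeated downstream).
#'
#' @param cases,controls Validated record data frames (see [read_pool()]).
#' @param event_dates Vector of `Date`s defining the event window (a closed
#'   set of calendar dates).
#' @param provenance Free-text metadata carried on the object.
#' @return An object of class `heat_cohort`: a list with elements `cases`,
#'   `controls`, `event_dates`, `provenance`.
#' @export
cohort <- function(cases, controls, event_dates, provenance = "") {
  event_dates <- sort(as.Date(event_dates))
  if (nrow(cases) == 0L || nrow(controls) == 0L)
    stop("both pools must be non-empty")
  if (any(duplicated(c(cases$record_id, controls$record_id))))
    stop("record_id values must be unique across both pools")
  if (!all(cases$death_date %in% event_dates))
    stop("case death dates outside the event window: ",
         paste(utils::head(cases$record_id[!(cases$death_date %in% event_dates)], 5L),
               collapse = ", "))
  if (any(controls$death_date %in% event_dates))
    stop("control death dates inside the event window: ",
         paste(utils::head(controls$record_id[controls$death_date %in% event_dates], 5L),
               collapse = ", "))

  need_dq <- function(df) !("density_quintile" %in% names(df)) ||
    anyNA(df$density_quintile)
  if (need_dq(cases) || need_dq(controls)) {
    if (!("population_density" %in% names(cases)) ||
        !("population_density" %in% names(controls)))
      stop("population_density required in both pools to derive density quintiles")
    pooled <- c(cases$population_density, controls$population_density)
    bins <- quintile_bin(pooled)
    cases$density_quintile <- bins[seq_len(nrow(cases))]
    controls$density_quintile <- bins[nrow(cases) + seq_len(nrow(controls))]
  }
  structure(list(cases = cases, controls = controls,
                 event_dates = event_dates, provenance = provenance),
            class = "heat_cohort")
}

#' @export
print.heat_cohort <- function(x, ...) {
  cat("heat_cohort:", nrow(x$cases), "cases /", nrow(x$controls),
      "controls; event window", format(min(x$event_dates)), "to",
      format(max(x$event_dates)),
      sprintf("(%d days)\n", length(x$event_dates)))
  if (nzchar(x$provenance)) cat("  ", x$provenance, "\n")
  invisible(x)
}

#' Encode death records as a logistic-regression design table
#'
#' Produces one design row per record: `age_lt75` (1 if age < 75),
#' location-of-death indicators with hospital as reference, deprivation
#' and density quintiles as continuous scores, continuous NDVI, and the
#' case/control `outcome` indicator.
#'
#' @param records Data frame of validated records with a `group` column;
#'   `density_quintile` must be present (see [cohort()]).
#' @param variables Subset of
#'   `c("age", "location", "deprivation", "density", "ndvi")`.
#' @return Data frame with the design columns for the requested variables
#'   plus `outcome` (1 = case); row order follows `records`.
#' @export
encode_design <- function(records, variables = .analysis_variables) {
  if (length(variables) == 0L) stop("no variables requested")
  unknown <- setdiff(variables, .analysis_variables)
  if (length(unknown) > 0L)
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  if ("density" %in% variables && !("density_quintile" %in% names(records)))
    stop("density requested but density_quintile absent; build a cohort() first")
  out <- list()
  for (v in variables) {
    out <- c(out, switch(v,
      age = list(age_lt75 = as.integer(records$age_years < 75)),
      location = {
        loc <- records$location_of_death
        list(loc_residential_institution =
               as.integer(loc == "residential_institution"),
             loc_home  = as.integer(loc == "home"),
             loc_other = as.integer(loc == "other"))
      },
      deprivation = list(deprivation = as.numeric(records$deprivation_quintile)),
      density = list(density_q = as.numeric(records$density_quintile)),
      ndvi = list(ndvi = records$ndvi)))
  }
  out$outcome <- as.integer(records$group == "case")
  as.data.frame(out)
}

# Precompute the full design matrix for a cohort: cases occupy rows
# 1..n_cases, controls follow. Reused across all repetitions of a run.
.design_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "heat_cohort"))
  all_rec <- rbind(cohort$cases[intersect(names(cohort$cases), names(cohort$controls))],
                   cohort$controls[intersect(names(cohort$cases), names(cohort$controls))])
  des <- encode_design(all_rec)
  X <- as.matrix(des[, setdiff(names(des), "outcome")])
  list(X = X, y = des$outcome,
       n_cases = nrow(cohort$cases), n_controls = nrow(cohort$controls),
       case_ids = cohort$cases$record_id,
       control_ids = cohort$controls$record_id,
       var_cols = variable_columns())
}
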