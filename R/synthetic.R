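#' Default control-pool marginal distributions
#'
#' Marginals of the five analysis variables in a typical-summer-weather
#' control population: 37.4% aged under 75; location of death 51.9%
#' hospital, 30.9% residential institution, 14.5% home, 2.7% other;
#' deprivation quintiles 20.7/20.7/19.2/19.1/20.2% (renormalized to sum
#' to one); population-density quintiles 20.1/19.5/19.9/19.8/20.7%; NDVI
#' normal with mean 0.329. The NDVI spread is not a published quantity;
#' the default 0.1 makes the documented excess/control greenness gap
#' (0.254 vs 0.329) a moderate ~0.75 SD separation.
#'
#' @param ndvi_sd Standard deviation of the NDVI distribution.
#' @return Named list of marginals, see [scenario_params()].
#' @export
default_control_marginals <- function(ndvi_sd = 0.1) {
  norm1 <- function(x) x / sum(x)
  list(age_lt75 = 0.374,
       location = norm1(c(hospital = .519, residential_institution = .309,
                          home = .145, other = .027)),
       deprivation = norm1(c(.207, .207, .192, .191, .202)),
       density = norm1(c(.201, .195, .199, .198, .207)),
       ndvi_mean = 0.329, ndvi_sd = ndvi_sd)
}

#' A zero (null) excess shift
#'
#' Under the null shift, excess-type cases are drawn from the control
#' marginals and are exchangeable with expected-type cases.
#'
#' @return Named list of zero shifts, see [scenario_params()].
#' @export
zero_shift <- function() {
  list(age_lt75 = 0, location = rep(0, 4L), deprivation = rep(0, 5L),
       density = rep(0, 5L), ndvi = 0)
}

#' Log-odds shift reproducing a target categorical profile
#'
#' Computes the additive log-odds shift `d` such that
#' `softmax(log(p) + d) = q`; categories absent from the target receive
#' `-Inf`.
#'
#' @param p Source category probabilities (positive, sum 1).
#' @param q Target category probabilities (sum 1).
#' @return Shift vector of the same length.
#' @export
shift_for_target <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  d <- log(q / p)
  fin <- is.finite(d)
  if (!any(fin)) stop("target has no overlap with source support")
  d[fin] <- d[fin] - mean(d[fin])
  d
}

#' Strong excess shift targeting the consensus excess-death profile
#'
#' The excess-type marginals implied by the profile of the decedents
#' identified as probable excess deaths by all twelve modeling
#' combinations: 96.7% aged under 75; 80% home and 20% other location
#' deaths; deprivation quintiles 0/0/20/13.3/66.7%; density quintiles
#' 0/3.3/16.7/20/60%; mean NDVI 0.254.
#'
#' @param marginals Control marginals the shift applies to.
#' @return Named shift list, see [scenario_params()].
#' @export
consensus_excess_shift <- function(marginals = default_control_marginals()) {
  norm1 <- function(x) x / sum(x)
  target_loc <- norm1(c(hospital = 0, residential_institution = 0,
                        home = .80, other = .20))
  target_dep <- norm1(c(0, 0, .200, .133, .667))
  target_den <- norm1(c(0, .033, .167, .200, .600))
  list(age_lt75 = stats::qlogis(0.967) - stats::qlogis(marginals$age_lt75),
       location = shift_for_target(marginals$location, target_loc),
       deprivation = shift_for_target(marginals$deprivation, target_dep),
       density = shift_for_target(marginals$density, target_den),
       ndvi = 0.254 - marginals$ndvi_mean)
}

#' Apply an excess shift to control marginals
#'
#' Categorical probabilities are perturbed on the log-odds scale and
#' renormalized (softmax); the NDVI mean is shifted additively. The
#' transformation is transparent and invertible for finite shifts.
#'
#' @param marginals Marginals as in [default_control_marginals()].
#' @param shift Shift list as in [zero_shift()].
#' @return Shifted marginals.
#' @export
apply_excess_shift <- function(marginals, shift) {
  softmax_shift <- function(p, d) {
    w <- exp(log(p) + d)
    w / sum(w)
  }
  out <- marginals
  out$age_lt75 <- stats::plogis(stats::qlogis(marginals$age_lt75) +
                                  shift$age_lt75)
  out$location <- softmax_shift(marginals$location, shift$location)
  out$deprivation <- softmax_shift(marginals$deprivation, shift$deprivation)
  out$density <- softmax_shift(marginals$density, shift$density)
  out$ndvi_mean <- marginals$ndvi_mean + shift$ndvi
  out
}

.check_probs <- function(x, what, n = NULL, tol = 1e-8) {
  if (!is.null(n) && length(x) != n)
    stop("parameter error: ", what, " must have length ", n)
  if (any(x < 0) || abs(sum(x) - 1) > tol)
    stop("parameter error: ", what,
         " must be non-negative and sum to 1 (got sum ",
         format(sum(x), digits = 12), ")")
  invisible(x)
}

#' Define a synthetic-cohort scenario
#'
#' A scenario fixes everything needed to generate case and control pools
#' with known excess/expected ground truth: pool sizes, control-pool
#' marginals for the five analysis variables, the excess-type effect
#' shifts, the event window, and per-type daily death weights over the
#' event days. Expected-type cases are drawn from the control marginals —
#' the framework's core assumption that expected deaths are exchangeable
#' with typical-summer-weather deaths — while excess-type cases are drawn
#' from the shifted marginals.
#'
#' @param n_controls,n_expected_cases,n_excess_cases Pool sizes. The
#'   generated case pool has `n_expected_cases + n_excess_cases` records.
#' @param control_marginals See [default_control_marginals()].
#' @param excess_shift See [zero_shift()], [consensus_excess_shift()].
#' @param event_dates `Date` vector of event days.
#' @param event_day_weights_expected,event_day_weights_excess Probability
#'   vectors over `event_dates` for each case type.
#' @param control_dates `Date` vector from which control death dates are
#'   drawn uniformly; must not intersect `event_dates`.
#' @param seed Integer seed; [simulate_cohort()] is a deterministic
#'   function of the full parameter set.
#' @return Object of class `scenario_params`.
#' @export
scenario_params <- function(n_controls = 11632L,
                            n_expected_cases = 297L,
                            n_excess_cases = 114L,
                            control_marginals = default_control_marginals(),
                            excess_shift = zero_shift(),
                            event_dates = as.Date("2009-07-27") + 0:6,
                            event_day_weights_expected = NULL,
                            event_day_weights_excess = NULL,
                            control_dates = NULL,
                            seed = 1L) {
  n_days <- length(event_dates)
  if (is.null(event_day_weights_expected))
    event_day_weights_expected <- rep(1 / n_days, n_days)
  if (is.null(event_day_weights_excess))
    event_day_weights_excess <- rep(1 / n_days, n_days)
  if (is.null(control_dates)) {
    yrs <- 2010:2012
    control_dates <- do.call(c, lapply(yrs, function(y)
      seq(as.Date(sprintf("%d-06-01", y)), as.Date(sprintf("%d-08-31", y)),
          by = "day")))
  }
  stopifnot(n_controls >= 1L, n_expected_cases >= 1L, n_excess_cases >= 0L)
  m <- control_marginals
  .check_probs(c(m$age_lt75, 1 - m$age_lt75), "age_lt75")
  .check_probs(m$location, "location probabilities", 4L)
  .check_probs(m$deprivation, "deprivation probabilities", 5L)
  .check_probs(m$density, "density probabilities", 5L)
  stopifnot(m$ndvi_sd > 0, abs(m$ndvi_mean) <= 1)
  .check_probs(event_day_weights_expected, "expected day weights", n_days)
  .check_probs(event_day_weights_excess, "excess day weights", n_days)
  if (any(as.Date(control_dates) %in% as.Date(event_dates)))
    stop("parameter error: control_dates intersect event_dates")
  lengths_ok <- lengths(excess_shift[c("location", "deprivation",
                                       "density")]) == c(4L, 5L, 5L)
  if (!all(lengths_ok))
    stop("parameter error: excess_shift category lengths must be 4/5/5")
  structure(list(n_controls = as.integer(n_controls),
                 n_expected_cases = as.integer(n_expected_cases),
                 n_excess_cases = as.integer(n_excess_cases),
                 control_marginals = m, excess_shift = excess_shift,
                 event_dates = as.Date(event_dates),
                 event_day_weights_expected = event_day_weights_expected,
                 event_day_weights_excess = event_day_weights_excess,
                 control_dates = as.Date(control_dates),
                 seed = as.integer(seed)),
            class = "scenario_params")
}

#' Null scenario: no excess effect
#'
#' Study-scale pools in which excess-type cases are exchangeable with
#' expected-type cases and controls; the classifier has no information
#' and recovers ground truth only at the chance rate.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [scenario_params()].
#' @return `scenario_params` object.
#' @export
scenario_null <- function(seed = 1L, ...) {
  scenario_params(excess_shift = zero_shift(), seed = seed, ...)
}

#' Strong-effect scenario: consensus excess profile
#'
#' Study-scale pools in which the 114 excess-type cases follow the
#' consensus excess-death profile ([consensus_excess_shift()]) and their
#' death dates concentrate on the hottest event days (6.7, 10, 20, 23.3,
#' 20, 10, 10% across the seven days), while expected-type cases follow
#' the control marginals with uniform day weights.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [scenario_params()].
#' @return `scenario_params` object.
#' @export
scenario_strong <- function(seed = 1L, ...) {
  w <- c(.067, .100, .200, .233, .200, .100, .100)
  scenario_params(excess_shift = consensus_excess_shift(),
                  event_day_weights_excess = w / sum(w), seed = seed, ...)
}

# truncated-normal NDVI draw (truncation to [-1, 1] is essentially
# inactive at the default mean/sd but guarantees the record invariant)
.rndvi <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < -1 | x > 1))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

# Draw covariates (no dates) for n records from a marginal set. The five
# variables are generated independently; only marginal structure is
# emulated.
.draw_records <- function(n, marg, ids) {
  lt75 <- stats::rbinom(n, 1L, marg$age_lt75) == 1L
  age <- integer(n)
  age[lt75] <- sample(30:74, sum(lt75), replace = TRUE)
  age[!lt75] <- sample(75:99, sum(!lt75), replace = TRUE)
  data.frame(
    record_id = ids,
    death_date = as.Date(NA),
    age_years = age,
    location_of_death = sample(.location_levels, n, replace = TRUE,
                               prob = marg$location),
    deprivation_quintile = sample.int(5L, n, replace = TRUE,
                                      prob = marg$deprivation),
    density_quintile = sample.int(5L, n, replace = TRUE,
                                  prob = marg$density),
    ndvi = .rndvi(n, marg$ndvi_mean, marg$ndvi_sd),
    stringsAsFactors = FALSE)
}

#' Generate the control pool of a scenario
#'
#' Draws `n_controls` records with covariates from the control marginals
#' (independently per record) and death dates uniform over the scenario's
#' control dates, all outside the event window.
#'
#' @param params A [scenario_params()] object.
#' @return Data frame of control records (uses the caller's RNG state;
#'   see [simulate_cohort()] for the seeded entry point).
#' @export
generate_controls <- function(params) {
  n <- params$n_controls
  df <- .draw_records(n, params$control_marginals,
                      sprintf("ctl_%06d", seq_len(n)))
  df$death_date <- sample(params$control_dates, n, replace = TRUE)
  df$group <- "control"
  df
}

#' Generate the case pool of a scenario with ground truth
#'
#' Expected-type cases are drawn from the control marginals; excess-type
#' cases from the marginals perturbed by the scenario's excess shift.
#' Records are shuffled so file order carries no information about the
#' truth labels. Death dates are unset until [assign_event_dates()].
#'
#' @param params A [scenario_params()] object.
#' @return List with `records` (case data frame) and `truth` (data frame
#'   `record_id`, `truth_label` in `{excess, expected}`).
#' @export
generate_cases <- function(params) {
  n_exp <- params$n_expected_cases
  n_exc <- params$n_excess_cases
  excess_marg <- apply_excess_shift(params$control_marginals,
                                    params$excess_shift)
  ids <- sprintf("case_%04d", seq_len(n_exp + n_exc))
  expected <- .draw_records(n_exp, params$control_marginals,
                            ids[seq_len(n_exp)])
  records <- expected
  truth_label <- rep("expected", n_exp)
  if (n_exc > 0L) {
    excess <- .draw_records(n_exc, excess_marg, ids[n_exp + seq_len(n_exc)])
    records <- rbind(expected, excess)
    truth_label <- c(truth_label, rep("excess", n_exc))
  }
  perm <- sample.int(nrow(records))
  records <- records[perm, , drop = FALSE]
  rownames(records) <- NULL
  records$group <- "case"
  list(records = records,
       truth = data.frame(record_id = records$record_id,
                          truth_label = truth_label[perm],
                          stringsAsFactors = FALSE))
}

#' Assign event-window death dates to generated cases
#'
#' Expected-type cases receive dates drawn from the scenario's expected
#' day weights, excess-type cases from the excess day weights; all dates
#' lie within the event window.
#'
#' @param cases Case records from [generate_cases()].
#' @param truth Matching truth data frame.
#' @param params A [scenario_params()] object.
#' @return `cases` with `death_date` filled in.
#' @export
assign_event_dates <- function(cases, truth, params) {
  stopifnot(identical(cases$record_id, truth$record_id))
  is_exc <- truth$truth_label == "excess"
  dates <- rep(params$event_dates[1L], nrow(cases))
  if (any(!is_exc))
    dates[!is_exc] <- sample(params$event_dates, sum(!is_exc), replace = TRUE,
                             prob = params$event_day_weights_expected)
  if (any(is_exc))
    dates[is_exc] <- sample(params$event_dates, sum(is_exc), replace = TRUE,
                            prob = params$event_day_weights_excess)
  cases$death_date <- dates
  cases
}

#' Simulate a full case-control cohort with known ground truth
#'
#' Seeds the RNG from the scenario and generates controls, cases, and
#' event dates; identical parameters and seed give bit-identical pools.
#'
#' @param params A [scenario_params()] object.
#' @return List with `cohort` (a [cohort()] object), `truth` (data frame
#'   `record_id`, `truth_label`), and `params`.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "scenario_params"))
  set.seed(params$seed)
  controls <- generate_controls(params)
  cg <- generate_cases(params)
  cases <- assign_event_dates(cg$records, cg$truth, params)
  ch <- cohort(cases, controls, params$event_dates,
               provenance = sprintf("synthetic scenario (seed %d)",
                                    params$seed))
  list(cohort = ch, truth = cg$truth, params = params)
}

#' Write scenario pools and ground truth to CSV
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly; writes `cases.csv`, `controls.csv`,
#'   `truth.csv` and a JSON `manifest.json`.
#' @export
write_scenario <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pool(sim$cohort$cases, file.path(dir, "cases.csv"))
  write_pool(sim$cohort$controls, file.path(dir, "controls.csv"))
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  manifest <- list(
    tool = "heatexcess", version = as.character(utils::packageVersion("heatexcess")),
    seed = sim$params$seed,
    n_controls = sim$params$n_controls,
    n_expected_cases = sim$params$n_expected_cases,
    n_excess_cases = sim$params$n_excess_cases,
    event_dates = format(sim$params$event_dates))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
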