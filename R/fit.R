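# Internal maximum-likelihood logit fit on a numeric design matrix.
# Returns estimates, standard errors and two-sided Wald p-values.
# Non-convergence and (quasi-)complete separation are reported through
# converged = FALSE rather than raising; separation is flagged when a
# fitted probability reaches the IRLS boundary (within 10 * machine
# epsilon of 0 or 1) together with an exploding coefficient or standard
# error. Rank-deficient columns get NA estimates and are never
# counted as significant.
.fit_logit_core <- function(X, y, maxit = 100L, epsilon = 1e-8) {
  Xi <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xi)
  warned <- FALSE
  fit <- withCallingHandlers(
    glm.fit(Xi, y, family = stats::binomial(),
            control = list(epsilon = epsilon, maxit = maxit)),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  coefs <- fit$coefficients
  se <- rep(NA_real_, p)
  rank <- fit$qr$rank
  if (rank > 0L) {
    R <- fit$qr$qr[seq_len(rank), seq_len(rank), drop = FALSE]
    R[lower.tri(R)] <- 0
    cov_ok <- tryCatch({
      covmat <- chol2inv(R)
      TRUE
    }, error = function(e) FALSE)
    if (cov_ok) {
      piv <- fit$qr$pivot[seq_len(rank)]
      se[piv] <- sqrt(diag(covmat))
    }
  }
  names(se) <- colnames(Xi)
  z <- coefs / se
  pval <- 2 * stats::pnorm(-abs(z))
  separated <- warned &&
    (max(abs(coefs), na.rm = TRUE) > 10 || max(se, na.rm = TRUE) > 100)
  converged <- isTRUE(fit$converged) && !separated
  list(estimate = coefs, se = se, p = pval,
       converged = converged, terms = colnames(Xi))
}

#' Fit a logistic regression to a design table
#'
#' Maximum-likelihood logit fit with intercept, the basic model of the
#' resampling framework. Per-term two-sided Wald p-values are computed
#' from coefficient / standard error against the standard normal.
#' Non-convergence and (quasi-)complete separation are reported via
#' `converged = FALSE`; a non-converged fit contributes no significant
#' terms downstream.
#'
#' @param design Data frame with an `outcome` column (0/1, both classes
#'   present) and at least one covariate column, as produced by
#'   [encode_design()].
#' @return An object of class `logit_fit`: list with a `coefficients`
#'   data frame (`term`, `estimate`, `se`, `p_value`), `converged`, and
#'   `terms` (covariate columns fitted).
#' @export
fit_logit <- function(design) {
  if (!("outcome" %in% names(design)))
    stop("design must contain an outcome column")
  y <- design$outcome
  if (length(unique(y[!is.na(y)])) < 2L)
    stop("degenerate input: outcome must contain both classes")
  covars <- setdiff(names(design), "outcome")
  if (length(covars) == 0L) stop("no covariate columns in design")
  X <- as.matrix(design[, covars, drop = FALSE])
  f <- .fit_logit_core(X, y)
  structure(list(
    coefficients = data.frame(term = f$terms, estimate = unname(f$estimate),
                              se = unname(f$se), p_value = unname(f$p),
                              stringsAsFactors = FALSE),
    converged = f$converged, terms = covars), class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat("logit_fit (", if (x$converged) "converged" else "NOT converged",
      "):\n", sep = "")
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

# Significance indicator per design column under a combination spec.
.significant_terms <- function(fit, cols, alpha, direction_required,
                               expectations) {
  if (!fit$converged) return(stats::setNames(rep(FALSE, length(cols)), cols))
  p <- fit$p[cols]
  est <- fit$estimate[cols]
  sig <- !is.na(p) & p < alpha
  if (direction_required)
    sig <- sig & !is.na(est) & sign(est) == expectations[cols]
  stats::setNames(sig, cols)
}
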