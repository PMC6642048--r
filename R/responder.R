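#' Simple linear regression summary
#'
#' Ordinary least squares of y on x with intercept, reporting slope,
#' intercept, Pearson r, R-squared, and per-sample squared residuals. For
#' this model R-squared equals r-squared exactly and residuals sum to zero.
#'
#' @param x predictor values (marker expression, e.g. CD3E TPM).
#' @param y response values (checkpoint expression, e.g. PDCD1 TPM).
#' @return list of class \code{"regression_summary"}: \code{slope},
#'   \code{intercept}, \code{r}, \code{r_squared}, \code{residuals},
#'   \code{squared_residuals}, \code{n}.
#' @export
fit_ols <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("x has zero variance")
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  r2 <- if (stats::sd(y) == 0) 0 else
    1 - sum(res^2) / sum((y - mean(y))^2)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r = if (stats::sd(y) == 0) 0 else stats::cor(x, y),
                 r_squared = r2,
                 residuals = unname(res),
                 squared_residuals = unname(res^2),
                 n = length(x)),
            class = "regression_summary")
}

#' @export
print.regression_summary <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d): slope %.4g, intercept %.4g, r %.4f, R^2 %.4f\n",
              x$n, x$slope, x$intercept, x$r, x$r_squared))
  invisible(x)
}

#' Mann-Whitney U test (two-sided)
#'
#' U from rank sums with midranks for ties. The p-value is exact (full
#' enumeration of label assignments) when both groups have at most
#' \code{exact_limit} observations and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used. The method actually applied is reported.
#'
#' @param a,b numeric samples.
#' @param exact_limit largest group size for the exact path (default 8).
#' @return list of class \code{"mwu_result"}: \code{u} (U of the first
#'   sample), \code{p} (two-sided), \code{method}.
#' @export
mann_whitney_u <- function(a, b, exact_limit = 8L) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- !ties && length(a) <= exact_limit && length(b) <= exact_limit
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE,
                       alternative = "two.sided"))
  structure(list(u = unname(ht$statistic),
                 p = min(1, ht$p.value),
                 method = if (use_exact) "exact" else "normal-approximation"),
            class = "mwu_result")
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f, two-sided p = %.4g (%s)\n",
              x$u, x$p, x$method))
  invisible(x)
}

#' Compare marker-checkpoint coupling between response groups
#'
#' Fits one regression of PDCD1 on CD3E expression per response group,
#' reports each group's Pearson r and R-squared, and tests whether the
#' squared residuals of one group are systematically smaller than the
#' other's with a two-sided Mann-Whitney U test. Tight coupling in
#' responders — higher r and R-squared, smaller squared residuals — is the
#' signature of a cohort in which PD-1-axis expression tracks T-cell
#' infiltration.
#'
#' @param cohort a \code{responder_cohort} data.frame (columns
#'   \code{sample_id}, \code{response}, \code{CD3E_TPM}, \code{PDCD1_TPM}).
#' @param predictor,response columns used as regression x and y; the default
#'   regresses PDCD1 on CD3E.
#' @return list of class \code{"responder_comparison"}: per-group
#'   \code{regression} summaries and \code{n}, the \code{test}
#'   (\code{mwu_result} on squared residuals, responders vs non-responders),
#'   and the direction of the comparison.
#' @export
compare_response_groups <- function(cohort, predictor = "CD3E_TPM",
                                    response = "PDCD1_TPM") {
  stopifnot(is.data.frame(cohort),
            all(c("sample_id", "response", predictor, response) %in%
                  names(cohort)))
  groups <- split(cohort, cohort$response)
  if (!setequal(names(groups), c("responder", "nonresponder")))
    stop("cohort must contain both responder and nonresponder samples")
  small <- names(groups)[vapply(groups, nrow, 0L) < 3L]
  if (length(small)) stop("group with <3 samples: ", small[1L])
  fits <- lapply(groups, function(g) fit_ols(g[[predictor]], g[[response]]))
  test <- mann_whitney_u(fits$responder$squared_residuals,
                         fits$nonresponder$squared_residuals)
  structure(list(
    responder = fits$responder, nonresponder = fits$nonresponder,
    n_responders = nrow(groups$responder),
    n_nonresponders = nrow(groups$nonresponder),
    test = test,
    direction = if (mean(fits$responder$squared_residuals) <
                    mean(fits$nonresponder$squared_residuals))
      "responders have smaller squared residuals"
    else "nonresponders have smaller squared residuals"),
    class = "responder_comparison")
}

#' @export
print.responder_comparison <- function(x, ...) {
  cat("CD3E-PDCD1 coupling by response group\n")
  cat(sprintf("  responders    (n = %2d): r = %.3f, R^2 = %.3f\n",
              x$n_responders, x$responder$r, x$responder$r_squared))
  cat(sprintf("  nonresponders (n = %2d): r = %.3f, R^2 = %.3f\n",
              x$n_nonresponders, x$nonresponder$r,
              x$nonresponder$r_squared))
  cat(sprintf("  squared residuals: U = %.1f, two-sided p = %.4g (%s)\n",
              x$test$u, x$test$p, x$test$method))
  cat(" ", x$direction, "\n")
  invisible(x)
}

#' @export
summary.responder_comparison <- function(object, ...) {
  data.frame(group = c("responder", "nonresponder"),
             n = c(object$n_responders, object$n_nonresponders),
             r = c(object$responder$r, object$nonresponder$r),
             r_squared = c(object$responder$r_squared,
                           object$nonresponder$r_squared),
             slope = c(object$responder$slope, object$nonresponder$slope),
             intercept = c(object$responder$intercept,
                           object$nonresponder$intercept),
             u = object$test$u, p = object$test$p,
             method = object$test$method,
             stringsAsFactors = FALSE)
}

#' Outlier-exclusion rerun of the response-group comparison
#'
#' Repeats [compare_response_groups()] on the cohort with the named samples
#' removed, returning the full and reduced comparisons side by side — the
#' standard robustness check when a single very-high-expression patient
#' dominates the regression.
#'
#' @param cohort a responder cohort.
#' @param excluded_sample_ids sample IDs to drop (may be empty).
#' @param ... passed to [compare_response_groups()].
#' @return list of class \code{"exclusion_rerun"} with elements \code{full},
#'   \code{reduced}, \code{excluded}.
#' @export
exclude_and_rerun <- function(cohort, excluded_sample_ids, ...) {
  unknown <- setdiff(excluded_sample_ids, cohort$sample_id)
  if (length(unknown)) stop("unknown sample ID: ", unknown[1L])
  reduced <- cohort[!cohort$sample_id %in% excluded_sample_ids, , drop = FALSE]
  structure(list(full = compare_response_groups(cohort, ...),
                 reduced = compare_response_groups(reduced, ...),
                 excluded = excluded_sample_ids),
            class = "exclusion_rerun")
}

#' @export
print.exclusion_rerun <- function(x, ...) {
  cat("== full cohort ==\n"); print(x$full)
  cat(sprintf("== excluding %s ==\n",
              if (length(x$excluded)) paste(x$excluded, collapse = ", ")
              else "nothing"))
  print(x$reduced)
  invisible(x)
}

#' Flag very-high-expression samples
#'
#' Convenience heuristic: flags samples whose marker expression exceeds the
#' within-group 75th percentile by more than 3 interquartile ranges.
#' Intended to suggest candidates for [exclude_and_rerun()]; exclusion
#' itself is always by explicit sample ID.
#'
#' @param cohort a responder cohort.
#' @param column expression column inspected (default \code{CD3E_TPM}).
#' @return character vector of flagged sample IDs.
#' @export
flag_outliers <- function(cohort, column = "CD3E_TPM") {
  flags <- unlist(lapply(split(cohort, cohort$response), function(g) {
    qs <- stats::quantile(g[[column]], c(0.25, 0.75), names = FALSE)
    g$sample_id[g[[column]] > qs[2L] + 3 * (qs[2L] - qs[1L])]
  }), use.names = FALSE)
  sort(flags)
}
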