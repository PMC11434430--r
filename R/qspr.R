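## QSPR statistics: pairwise Pearson correlations, simple-regression
## summaries with full inferential statistics, and descriptor-vs-activity
## correlations.

#' Pearson correlation with strict validation
#'
#' Thin wrapper around [stats::cor()] that enforces the preconditions of a
#' meaningful product-moment correlation: equal lengths, at least three
#' observations, and non-zero variance in both vectors.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return the Pearson correlation coefficient in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) {
    stop("'x' and 'y' must have equal length", call. = FALSE)
  }
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values in input", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined for a constant vector",
         call. = FALSE)
  }
  stats::cor(x, y)
}

#' Pairwise Pearson correlation matrix of a descriptor table
#'
#' @param table a descriptor table (see [as_descriptor_table()]).
#' @return symmetric matrix of Pearson correlations with unit diagonal,
#'   dimnames the descriptor names.
#' @examples
#' tab <- cbind(logP_TLC = load_fixture("table3_retention")$logp_tlc,
#'              load_fixture("table4_theoretical_logp"))
#' correlation_matrix(tab)["logP_TLC", "iLOGP"]
#' @export
correlation_matrix <- function(table) {
  table <- as_descriptor_table(table)
  sds <- apply(table, 2L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("constant descriptor column(s): %s",
                 paste(colnames(table)[sds == 0], collapse = ", ")),
         call. = FALSE)
  }
  r <- stats::cor(table)
  diag(r) <- 1
  r
}

#' Simple linear regression with full inferential summary
#'
#' Ordinary least squares of `y` on `x` reporting the complete set of
#' statistics conventionally printed for a QSPR correlation equation:
#' slope and intercept with their standard errors, the Pearson correlation
#' `r` (carrying the sign of the slope), the residual standard error
#' \eqn{s = \sqrt{SSE/(n-2)}}, the F statistic for zero slope
#' \eqn{F = MSR/MSE}, and its upper-tail p value on (1, n-2) degrees of
#' freedom.
#'
#' A perfect fit (zero residual) reports `s = 0` with `F` and `p` set to
#' `NA` and `perfect_fit = TRUE` rather than an infinite statistic.
#'
#' @param x predictor vector (non-constant).
#' @param y response vector, same length as `x`, n >= 3.
#' @param xname,yname labels carried into the summary.
#' @return an object of class `"regression_summary"`: list with
#'   `predictor`, `response`, `slope`, `slope_se`, `intercept`,
#'   `intercept_se`, `r`, `s`, `F`, `p`, `n`, `perfect_fit`.
#' @examples
#' t3 <- load_fixture("table3_retention")
#' t4 <- load_fixture("table4_theoretical_logp")
#' regress(t4[, "iLOGP"], t3$logp_tlc, "iLOGP", "logP_TLC")
#' @export
regress <- function(x, y, xname = "x", yname = "y") {
  if (length(x) != length(y)) {
    stop("'x' and 'y' must have equal length", call. = FALSE)
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values in input", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop(sprintf("predictor '%s' is constant: degenerate design", xname),
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  ## a zero-residual fit is handled explicitly below; silence lm's own
  ## "essentially perfect fit" caution
  cf <- suppressWarnings(summary(fit))$coefficients
  sse <- sum(stats::residuals(fit)^2)
  ssyy <- sum((y - mean(y))^2)
  s <- sqrt(sse / (n - 2L))
  r <- stats::cor(x, y)
  perfect <- isTRUE(all.equal(sse, 0)) || sse < 1e-24 * max(ssyy, 1)
  if (perfect) {
    Fstat <- NA_real_
    p <- NA_real_
  } else {
    msr <- ssyy - sse           # regression SS on 1 df
    Fstat <- msr / (sse / (n - 2L))
    p <- stats::pf(Fstat, 1L, n - 2L, lower.tail = FALSE)
  }
  structure(list(predictor = xname, response = yname,
                 slope = unname(cf["x", "Estimate"]),
                 slope_se = unname(cf["x", "Std. Error"]),
                 intercept = unname(cf["(Intercept)", "Estimate"]),
                 intercept_se = unname(cf["(Intercept)", "Std. Error"]),
                 r = r, s = s, F = Fstat, p = p, n = n,
                 perfect_fit = perfect),
            class = "regression_summary")
}

#' @export
print.regression_summary <- function(x, ...) {
  cat(sprintf("%s = %.3f (+/-%.3f) %s %s %.3f (+/-%.3f)\n",
              x$response, x$slope, x$slope_se, x$predictor,
              ifelse(x$intercept < 0, "-", "+"), abs(x$intercept),
              x$intercept_se))
  if (x$perfect_fit) {
    cat(sprintf("  r = %.3f  s = 0  (perfect fit; F, p undefined)  n = %d\n",
                x$r, x$n))
  } else {
    cat(sprintf("  r = %.3f  s = %.3f  F = %.0f  p = %.2f  n = %d\n",
                x$r, x$s, x$F, x$p, x$n))
  }
  invisible(x)
}

#' Regress one response descriptor on every other column
#'
#' Produces the conventional table of simple correlation equations: one
#' [regress()] summary per non-response column, each flagged significant
#' or not at `alpha`. All rows are returned; deciding which rows to print
#' is a presentation choice, not a computation filter.
#'
#' @param table a descriptor table.
#' @param response name of the response column.
#' @param alpha significance level for the flag (default 0.05).
#' @return data frame with one row per predictor: `predictor`, `slope`,
#'   `slope_se`, `intercept`, `intercept_se`, `r`, `s`, `F`, `p`, `n`,
#'   `significant`.
#' @export
regression_table <- function(table, response, alpha = 0.05) {
  table <- as_descriptor_table(table)
  if (!response %in% colnames(table)) {
    stop(sprintf("unknown response column '%s'", response), call. = FALSE)
  }
  predictors <- setdiff(colnames(table), response)
  rows <- lapply(predictors, function(p) {
    fit <- regress(table[, p], table[, response], xname = p,
                   yname = response)
    data.frame(predictor = p, slope = fit$slope, slope_se = fit$slope_se,
               intercept = fit$intercept, intercept_se = fit$intercept_se,
               r = fit$r, s = fit$s, F = fit$F, p = fit$p, n = fit$n,
               significant = !is.na(fit$p) && fit$p <= alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(predictor = character(), slope = numeric(),
                      slope_se = numeric(), intercept = numeric(),
                      intercept_se = numeric(), r = numeric(), s = numeric(),
                      F = numeric(), p = numeric(), n = integer(),
                      significant = logical(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Correlate every descriptor with a biological activity
#'
#' Aligns a descriptor table with per-compound activity records (IC50
#' values) on compound id, complete cases only, and returns the Pearson
#' correlation of each descriptor with the activity over the shared
#' compounds. Correlations over exactly three compounds are statistically
#' weak; they are flagged via the `low_power` attribute and a message.
#'
#' @param table a descriptor table with compound ids as row names.
#' @param activities data frame with columns `compound` and `ic50_uM`
#'   (positive); an optional `assay` column is carried through.
#' @return named numeric vector of correlations (one per descriptor), with
#'   attributes `n` (shared compounds), `compounds` (their ids),
#'   `dropped` (ids present in only one input) and `low_power`.
#' @export
activity_correlation <- function(table, activities) {
  table <- as_descriptor_table(table)
  if (!is.data.frame(activities) ||
      !all(c("compound", "ic50_uM") %in% names(activities))) {
    stop("activities must have columns 'compound' and 'ic50_uM'",
         call. = FALSE)
  }
  if (any(activities$ic50_uM <= 0)) {
    stop("ic50_uM values must be positive", call. = FALSE)
  }
  shared <- intersect(rownames(table), activities$compound)
  dropped <- union(setdiff(rownames(table), shared),
                   setdiff(activities$compound, shared))
  if (length(dropped)) {
    message("dropped (no match across inputs): ",
            paste(dropped, collapse = ", "))
  }
  if (length(shared) < 3L) {
    stop(sprintf("need >= 3 shared compounds, got %d", length(shared)),
         call. = FALSE)
  }
  ic50 <- activities$ic50_uM[match(shared, activities$compound)]
  if (stats::sd(ic50) == 0) {
    stop("activity values are constant: correlation undefined", call. = FALSE)
  }
  sub <- table[shared, , drop = FALSE]
  r <- vapply(colnames(sub), function(d) pearson(sub[, d], ic50), numeric(1))
  structure(r, n = length(shared), compounds = shared, dropped = dropped,
            low_power = length(shared) == 3L)
}
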