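#' Convert a retardation factor to the R_M retention parameter
#'
#' The chromatographic retention parameter is defined as
#' \eqn{R_M = \log_{10}(1/R_F - 1)}. It is zero at \eqn{R_F = 0.5},
#' strictly decreasing in \eqn{R_F}, and antisymmetric about 0.5:
#' `rf_to_rm(1 - x) == -rf_to_rm(x)`.
#'
#' @param rf numeric vector of retardation factors, strictly inside (0, 1).
#' @return numeric vector of R_M values (dimensionless, base-10 log scale).
#' @seealso [rm_to_rf()] for the inverse map.
#' @examples
#' rf_to_rm(0.5)   # 0
#' rf_to_rm(0.25)  # log10(3)
#' @export
rf_to_rm <- function(rf) {
  if (!is.numeric(rf) || length(rf) == 0) {
    stop("'rf' must be a non-empty numeric vector", call. = FALSE)
  }
  bad <- !is.finite(rf) | rf <= 0 | rf >= 1
  if (any(bad)) {
    stop(sprintf("retardation factors must lie strictly in (0, 1); offending value(s): %s",
                 paste(format(rf[bad]), collapse = ", ")), call. = FALSE)
  }
  log10(1 / rf - 1)
}

#' Convert R_M back to a retardation factor
#'
#' Inverse of [rf_to_rm()]: \eqn{R_F = 1 / (1 + 10^{R_M})}. Any finite R_M
#' maps strictly inside (0, 1).
#'
#' @param rm numeric vector of R_M values.
#' @return numeric vector of retardation factors in (0, 1).
#' @export
rm_to_rf <- function(rm) {
  if (!is.numeric(rm) || length(rm) == 0 || any(!is.finite(rm))) {
    stop("'rm' must be a finite numeric vector", call. = FALSE)
  }
  1 / (1 + 10 ^ rm)
}

## shared OLS backend: y on x through stats::lm, returning the quantities
## both fitted stages report. r_abs is |Pearson r|; the slope keeps its sign.
.ols_fit <- function(x, y) {
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  n <- length(x)
  list(intercept = unname(cf[1L]),
       slope = unname(cf[2L]),
       r = stats::cor(x, y),
       residual_se = sqrt(sum(stats::residuals(fit)^2) / (n - 2L)),
       n = n,
       fit = fit)
}

#' Fit the linear retention model for one compound
#'
#' Fits \eqn{R_M = R_{M0} + bC} by ordinary least squares, where C is the
#' organic-modifier concentration (% v/v) and R_M is computed from the
#' measured retardation factors via [rf_to_rm()]. The intercept R_M0 is the
#' retention parameter extrapolated to 0% modifier and is the compound's
#' chromatographic lipophilicity index.
#'
#' Replicate spots at the same concentration are averaged into a mean R_F
#' before the R_M transform (the conventional treatment of replicate
#' plates). A warning is issued when the absolute correlation of the fit
#' drops below `r_warn`, the practical quality floor for this experiment.
#'
#' @param measurements data frame with columns `compound`, `acetone_pct`
#'   and `rf`, all rows belonging to a single compound.
#' @param average_replicates average replicate `rf` values observed at the
#'   same concentration before transforming (default `TRUE`). When `FALSE`,
#'   replicate rows enter the regression individually.
#' @param r_warn warn when the fit's absolute Pearson correlation falls
#'   below this value (default 0.98).
#' @return an object of class `"retention_fit"`: a list with elements
#'   `compound_id`, `rm0`, `b`, `r_abs`, `residual_se`, `n_points`,
#'   `c_range` (measured concentration range) and `extrapolation_distance`
#'   (distance from C = 0 to the nearest measured concentration; the
#'   intercept is always an extrapolation in this assay).
#' @examples
#' m <- data.frame(compound = "X", acetone_pct = seq(65, 90, 5),
#'                 rf = rm_to_rf(6.05 - 0.07 * seq(65, 90, 5)))
#' fit_retention(m)
#' @export
fit_retention <- function(measurements, average_replicates = TRUE,
                          r_warn = 0.98) {
  measurements <- validate_measurements(measurements)
  ids <- unique(measurements$compound)
  if (length(ids) != 1L) {
    stop(sprintf("fit_retention() expects a single compound, got: %s",
                 paste(ids, collapse = ", ")), call. = FALSE)
  }
  if (average_replicates) {
    rf <- tapply(measurements$rf, measurements$acetone_pct, mean)
    cc <- as.numeric(names(rf))
    rf <- as.numeric(rf)
  } else {
    cc <- measurements$acetone_pct
    rf <- measurements$rf
  }
  if (length(unique(cc)) < 3L) {
    stop(sprintf("compound '%s': need >= 3 distinct modifier concentrations, got %d",
                 ids, length(unique(cc))), call. = FALSE)
  }
  rm_vals <- rf_to_rm(rf)
  if (stats::sd(rm_vals) == 0) {
    stop(sprintf("compound '%s': all R_M values identical; retention model is degenerate",
                 ids), call. = FALSE)
  }
  ols <- .ols_fit(cc, rm_vals)
  if (abs(ols$r) < r_warn) {
    warning(sprintf("compound '%s': |r| = %.3f below quality floor %.2f",
                    ids, abs(ols$r), r_warn), call. = FALSE)
  }
  structure(list(compound_id = ids,
                 rm0 = ols$intercept,
                 b = ols$slope,
                 r_abs = abs(ols$r),
                 residual_se = ols$residual_se,
                 n_points = ols$n,
                 c_range = range(cc),
                 extrapolation_distance = min(cc)),
            class = "retention_fit")
}

#' @export
print.retention_fit <- function(x, ...) {
  cat(sprintf("Retention model (R_M = R_M0 + b C) for '%s'\n", x$compound_id))
  cat(sprintf("  R_M0 = %.4f  b = %.4f  |r| = %.4f  s = %.4f  (n = %d)\n",
              x$rm0, x$b, x$r_abs, x$residual_se, x$n_points))
  cat(sprintf("  measured C in [%g, %g]%% v/v; intercept extrapolated %g%% beyond range\n",
              x$c_range[1], x$c_range[2], x$extrapolation_distance))
  invisible(x)
}

#' Construct a calibration curve from known coefficients
#'
#' Wraps externally obtained calibration coefficients (for instance a
#' published standard-curve equation) in the object [predict_logp()]
#' expects. Use [fit_calibration()] to fit the curve from standards.
#'
#' @param slope logP per unit R_M0.
#' @param intercept logP at R_M0 = 0.
#' @param r_abs,residual_se,n optional fit diagnostics when known.
#' @return an object of class `"calibration_curve"`.
#' @export
calibration_curve <- function(slope, intercept, r_abs = NA_real_,
                              residual_se = NA_real_, n = NA_integer_) {
  stopifnot(is.numeric(slope), is.numeric(intercept),
            is.finite(slope), is.finite(intercept))
  structure(list(slope = slope, intercept = intercept,
                 r_abs = r_abs, residual_se = residual_se, n = n),
            class = "calibration_curve")
}

#' Fit the standards calibration curve
#'
#' Ordinary least squares of literature logP on extrapolated R_M0 over the
#' reference standards, yielding the linear map used to convert a
#' compound's R_M0 into its chromatographic lipophilicity
#' \eqn{logP_{TLC} = slope \cdot R_{M0} + intercept}.
#'
#' @param standards data frame with columns `name`, `rm0` and `logp_lit`.
#' @return an object of class `"calibration_curve"` with elements `slope`,
#'   `intercept`, `r_abs`, `residual_se` and `n`.
#' @examples
#' fit_calibration(load_fixture("table2_standards"))
#' @export
fit_calibration <- function(standards) {
  standards <- validate_standards(standards)
  if (nrow(standards) < 3L) {
    stop("need >= 3 calibration standards", call. = FALSE)
  }
  if (stats::sd(standards$rm0) == 0) {
    stop("calibration standards have zero variance in rm0; cannot fit a line",
         call. = FALSE)
  }
  ols <- .ols_fit(standards$rm0, standards$logp_lit)
  structure(list(slope = ols$slope, intercept = ols$intercept,
                 r_abs = abs(ols$r), residual_se = ols$residual_se,
                 n = ols$n),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration: logP_TLC = %.4f R_M0 + %.4f", x$slope, x$intercept))
  if (is.finite(x$r_abs)) cat(sprintf("  (|r| = %.3f, n = %s)", x$r_abs, x$n))
  cat("\n")
  invisible(x)
}

#' Predict chromatographic lipophilicity from R_M0
#'
#' @param curve a `"calibration_curve"` from [fit_calibration()] or
#'   [calibration_curve()].
#' @param rm0 numeric vector of extrapolated R_M0 values.
#' @return numeric vector of logP_TLC predictions.
#' @export
predict_logp <- function(curve, rm0) {
  if (!inherits(curve, "calibration_curve")) {
    stop("'curve' must be a calibration_curve object", call. = FALSE)
  }
  if (!is.numeric(rm0) || any(!is.finite(rm0))) {
    stop("'rm0' must be finite numeric", call. = FALSE)
  }
  curve$slope * rm0 + curve$intercept
}

#' Run the full lipophilicity pipeline
#'
#' Chains the three stages of the chromatographic lipophilicity
#' determination: the R_F to R_M transform, the per-compound retention fit
#' extrapolating R_M0, the standards calibration, and the final logP_TLC
#' prediction.
#'
#' @param measurements data frame with columns `compound`, `acetone_pct`,
#'   `rf` covering one or more compounds.
#' @param standards either a standards data frame (`name`, `rm0`,
#'   `logp_lit`) or an already fitted `"calibration_curve"`.
#' @param round round reported `rm0`/`logp_tlc` to 2 decimals, `b` to 2 and
#'   `r_abs` to 3, mirroring the conventional reporting precision
#'   (default `FALSE`: full precision).
#' @inheritParams fit_retention
#' @return an object of class `"tlc_pipeline"`: list with `records` (data
#'   frame with one row per compound: `compound`, `rm0`, `b`, `r_abs`,
#'   `residual_se`, `n_points`, `logp_tlc`, `extrapolation_distance`),
#'   `curve`, and `warnings` (character vector of per-stage warnings).
#' @examples
#' std <- load_fixture("table2_standards")
#' m <- data.frame(compound = "X", acetone_pct = seq(65, 90, 5),
#'                 rf = rm_to_rf(6.05 - 0.07 * seq(65, 90, 5)))
#' run_tlc_pipeline(m, std)
#' @export
run_tlc_pipeline <- function(measurements, standards, round = FALSE,
                             average_replicates = TRUE) {
  measurements <- validate_measurements(measurements)
  if (nrow(measurements) == 0L) {
    stop("no measurements supplied", call. = FALSE)
  }
  curve <- if (inherits(standards, "calibration_curve")) standards
           else fit_calibration(standards)
  warnings_log <- character(0)
  ids <- unique(measurements$compound)
  fits <- lapply(ids, function(id) {
    rows <- measurements[measurements$compound == id, , drop = FALSE]
    withCallingHandlers(
      tryCatch(fit_retention(rows, average_replicates = average_replicates),
               error = function(e) {
                 stop(sprintf("compound '%s': %s", id, conditionMessage(e)),
                      call. = FALSE)
               }),
      warning = function(w) {
        warnings_log <<- c(warnings_log, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  })
  records <- do.call(rbind, lapply(fits, function(f) {
    data.frame(compound = f$compound_id, rm0 = f$rm0, b = f$b,
               r_abs = f$r_abs, residual_se = f$residual_se,
               n_points = f$n_points,
               logp_tlc = predict_logp(curve, f$rm0),
               extrapolation_distance = f$extrapolation_distance,
               stringsAsFactors = FALSE)
  }))
  rownames(records) <- NULL
  if (round) records <- round_records(records)
  structure(list(records = records, curve = curve, warnings = warnings_log),
            class = "tlc_pipeline")
}

## reporting precision: R_M0 and logP to 2 dp, b to 2 dp, r to 3 dp
round_records <- function(records) {
  records$rm0 <- round(records$rm0, 2)
  records$b <- round(records$b, 2)
  records$r_abs <- round(records$r_abs, 3)
  records$logp_tlc <- round(records$logp_tlc, 2)
  records
}

#' @export
print.tlc_pipeline <- function(x, ...) {
  print(x$curve)
  cat(sprintf("%d compound(s):\n", nrow(x$records)))
  print(x$records, digits = 4)
  if (length(x$warnings)) {
    cat("Warnings:\n"); for (w in x$warnings) cat(" -", w, "\n")
  }
  invisible(x)
}
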