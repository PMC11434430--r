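## CSV readers/writers and the JSON run report. All tabular I/O is plain
## UTF-8 CSV with dot decimals; the Unicode minus sign occasionally found
## in published tables is normalized to ASCII hyphen-minus on ingestion.

.normalize_minus <- function(df) {
  chr <- vapply(df, is.character, logical(1))
  df[chr] <- lapply(df[chr], function(x) gsub("−", "-", x))
  df
}

.read_csv <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                  fileEncoding = "UTF-8")
}

#' Read retardation-factor measurements from CSV
#'
#' Expects columns `compound`, `acetone_pct`, `rf`. Validation errors cite
#' offending (1-based, header-excluded) row numbers. Duplicate
#' compound/concentration pairs are an error unless `replicates` allows
#' them: `"keep"` passes them through (they are averaged inside
#' [fit_retention()]), `"average"` collapses them to the mean `rf` on read.
#'
#' @param path CSV file path.
#' @param replicates one of `"error"` (default), `"keep"`, `"average"`.
#' @return validated measurements data frame.
#' @export
read_measurements <- function(path,
                              replicates = c("error", "keep", "average")) {
  replicates <- match.arg(replicates)
  df <- .normalize_minus(.read_csv(path))
  for (col in c("acetone_pct", "rf")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  df <- validate_measurements(df)
  key <- paste(df$compound, df$acetone_pct, sep = "\1")
  if (anyDuplicated(key)) {
    if (replicates == "error") {
      stop_invalid("duplicate compound/concentration pairs in row(s): %s (use replicates = 'keep' or 'average')",
                   paste(which(duplicated(key)), collapse = ", "))
    }
    if (replicates == "average") {
      agg <- stats::aggregate(rf ~ compound + acetone_pct, df, mean)
      df <- agg[order(agg$compound, agg$acetone_pct), ]
      rownames(df) <- NULL
    }
  }
  df
}

#' Write measurements to CSV
#' @param path output path.
#' @param measurements measurements data frame.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(path, measurements) {
  measurements <- validate_measurements(measurements)
  utils::write.csv(measurements, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read calibration standards from CSV
#'
#' Two layouts are accepted. Fitted mode: columns `name`, `rm0`,
#' `logp_lit`. Raw mode: columns `name`, `acetone_pct`, `rf`, `logp_lit`
#' with one row per spot — each standard's retention model is then fitted
#' with [fit_retention()] and its extrapolated R_M0 used.
#'
#' @param path CSV file path.
#' @return standards data frame with columns `name`, `rm0`, `logp_lit`.
#' @export
read_standards <- function(path) {
  df <- .normalize_minus(.read_csv(path))
  num_cols <- intersect(c("rm0", "logp_lit", "acetone_pct", "rf"), names(df))
  df[num_cols] <- lapply(df[num_cols], as.numeric)
  if (all(c("name", "acetone_pct", "rf", "logp_lit") %in% names(df))) {
    per <- lapply(split(df, df$name), function(rows) {
      m <- data.frame(compound = rows$name, acetone_pct = rows$acetone_pct,
                      rf = rows$rf, stringsAsFactors = FALSE)
      data.frame(name = rows$name[1], rm0 = fit_retention(m)$rm0,
                 logp_lit = rows$logp_lit[1], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, per)
    rownames(out) <- NULL
    return(validate_standards(out))
  }
  validate_standards(df)
}

#' Write lipophilicity records to CSV
#' @param path output path.
#' @param records the `records` data frame of a `"tlc_pipeline"` (or the
#'   object itself).
#' @return `path`, invisibly.
#' @export
write_records <- function(path, records) {
  if (inherits(records, "tlc_pipeline")) records <- records$records
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read lipophilicity records back from CSV
#' @param path CSV written by [write_records()].
#' @return records data frame.
#' @export
read_records <- function(path) {
  df <- .read_csv(path)
  need <- c("compound", "rm0", "b", "r_abs", "logp_tlc")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_invalid("records missing column(s): %s", paste(miss, collapse = ", "))
  }
  df
}

#' Assemble a run report
#'
#' Bundles the pipeline outputs with provenance (inputs used, seed,
#' package version, calibration coefficients, warnings) into a list whose
#' JSON serialization is deterministic: two identical runs produce
#' byte-identical reports.
#'
#' @param pipeline a `"tlc_pipeline"` object.
#' @param inputs named list or character vector describing input
#'   provenance (paths or fixture ids).
#' @param seed seed used for any randomness, `NULL` if none.
#' @param extras optional named list of additional tables (e.g. a
#'   correlation matrix or regression table) to embed.
#' @return an object of class `"run_report"` (a list).
#' @export
run_report <- function(pipeline, inputs = list(), seed = NULL,
                       extras = list()) {
  if (!inherits(pipeline, "tlc_pipeline")) {
    stop_invalid("'pipeline' must be a tlc_pipeline object")
  }
  structure(list(
    schema = "tlclipo-run-report/1",
    version = as.character(utils::packageVersion("tlclipo")),
    inputs = inputs,
    seed = seed,
    calibration = list(slope = pipeline$curve$slope,
                       intercept = pipeline$curve$intercept,
                       r_abs = pipeline$curve$r_abs,
                       residual_se = pipeline$curve$residual_se,
                       n = pipeline$curve$n),
    records = pipeline$records,
    warnings = pipeline$warnings,
    extras = extras), class = "run_report")
}

#' Write a run report to JSON
#' @param report a `"run_report"`.
#' @param path output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "run_report")) {
    stop_invalid("'report' must be a run_report object")
  }
  json <- jsonlite::toJSON(unclass(report), dataframe = "rows",
                           auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Check a run report against the packaged schema
#'
#' The schema (a JSON list of required top-level fields, shipped under
#' `extdata/`) pins the report contract consumed by downstream tooling.
#'
#' @param report a `"run_report"` or a path to a report JSON file.
#' @return `TRUE` invisibly; errors describe missing fields.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema_path <- system.file("extdata", "report_schema.json",
                             package = "tlclipo", mustWork = TRUE)
  required <- unlist(jsonlite::read_json(schema_path)$required)
  miss <- setdiff(required, names(report))
  if (length(miss)) {
    stop_invalid("report missing required field(s): %s",
                 paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}
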