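## Input validation and the descriptor-table container.
##
## A descriptor table is a plain numeric matrix: rows = compounds (rownames
## carry the ids), columns = named numeric descriptors. No missing values.

## precondition violations carry a dedicated condition class so callers
## (notably the CLI) can separate bad input (exit 2) from internal faults
stop_invalid <- function(fmt, ...) {
  msg <- if (...length()) sprintf(fmt, ...) else fmt
  stop(errorCondition(msg, class = c("tlclipo_invalid", "error")))
}

#' Coerce a data frame or matrix to a descriptor table
#'
#' A descriptor table is a numeric matrix with unique compound ids as row
#' names and unique descriptor names as column names, with no missing
#' values. Data frames may carry the compound ids either as row names or in
#' a character column named by `compound_col`.
#'
#' @param x data frame or matrix of numeric descriptors.
#' @param compound_col name of the id column when `x` is a data frame with
#'   ids in a column (default `"compound"`; ignored when absent).
#' @return a numeric matrix with row and column names.
#' @export
as_descriptor_table <- function(x, compound_col = "compound") {
  if (is.data.frame(x)) {
    if (compound_col %in% names(x)) {
      ids <- as.character(x[[compound_col]])
      x <- x[, setdiff(names(x), compound_col), drop = FALSE]
      rownames(x) <- ids
    }
    x <- as.matrix(x)
  }
  if (!is.matrix(x)) stop_invalid("cannot coerce to a descriptor table")
  storage.mode(x) <- "double"
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  if (is.null(colnames(x))) {
    stop_invalid("descriptor table needs named columns")
  }
  if (anyDuplicated(colnames(x))) {
    stop_invalid("descriptor names must be unique")
  }
  if (anyDuplicated(rownames(x))) {
    stop_invalid("compound ids must be unique")
  }
  if (nrow(x) < 2L) stop_invalid("descriptor table needs >= 2 compounds")
  if (ncol(x) < 1L) stop_invalid("descriptor table needs >= 1 descriptor")
  if (any(!is.finite(x))) {
    stop_invalid("descriptor table contains missing or non-finite values")
  }
  x
}

## measurements: compound, acetone_pct, rf. Errors cite 1-based row numbers.
validate_measurements <- function(measurements) {
  if (!is.data.frame(measurements)) {
    stop_invalid("measurements must be a data frame")
  }
  need <- c("compound", "acetone_pct", "rf")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) {
    stop_invalid("measurements missing column(s): %s",
                 paste(miss, collapse = ", "))
  }
  measurements$compound <- as.character(measurements$compound)
  for (col in c("acetone_pct", "rf")) {
    v <- measurements[[col]]
    if (!is.numeric(v)) {
      stop_invalid("column '%s' must be numeric", col)
    }
  }
  bad <- which(!is.finite(measurements$acetone_pct) |
               measurements$acetone_pct < 0 | measurements$acetone_pct >= 100)
  if (length(bad)) {
    stop_invalid("acetone_pct out of [0, 100) in row(s): %s",
                 paste(bad, collapse = ", "))
  }
  bad <- which(!is.finite(measurements$rf) |
               measurements$rf <= 0 | measurements$rf >= 1)
  if (length(bad)) {
    stop_invalid("rf outside (0, 1) in row(s): %s",
                 paste(bad, collapse = ", "))
  }
  measurements
}

validate_standards <- function(standards) {
  if (!is.data.frame(standards)) {
    stop_invalid("standards must be a data frame")
  }
  need <- c("name", "rm0", "logp_lit")
  miss <- setdiff(need, names(standards))
  if (length(miss)) {
    stop_invalid("standards missing column(s): %s",
                 paste(miss, collapse = ", "))
  }
  standards$name <- as.character(standards$name)
  bad <- which(!is.finite(standards$rm0) | !is.finite(standards$logp_lit))
  if (length(bad)) {
    stop_invalid("non-finite standard values in row(s): %s",
                 paste(bad, collapse = ", "))
  }
  standards
}
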