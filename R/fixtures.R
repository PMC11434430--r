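## Packaged fixtures: the published reference-standard, retention,
## theoretical-logP, physicochemical/ADME, activity and toxicity tables,
## shipped as plain-text CSVs under inst/extdata/fixtures.

.fixture_names <- c("table2_standards", "table3_retention",
                    "table4_theoretical_logp", "table6_properties",
                    "mcf7_ic50", "table9_toxicity_labels")

#' Names of the packaged fixtures
#' @return character vector of fixture names accepted by [load_fixture()].
#' @export
fixture_names <- function() .fixture_names

#' Load a packaged fixture table
#'
#' Returns the published input tables the analyses consume, typed and
#' validated:
#' \describe{
#'   \item{`table2_standards`}{seven reference standards: `name`, `rm0`,
#'     `logp_lit`, plus the published fit diagnostics `b`, `r` and the
#'     derived `logp_tlc` (data frame).}
#'   \item{`table3_retention`}{retention results for betulin and its four
#'     indole derivatives: `compound`, `rm0`, `b`, `r`, `logp_tlc`
#'     (data frame).}
#'   \item{`table4_theoretical_logp`}{5 x 10 descriptor matrix of
#'     calculator-based logP values (iLOGP ... ALOGPs).}
#'   \item{`table6_properties`}{5 x 8 descriptor matrix of physicochemical
#'     and ADME properties (M, TPSA, nROTB, nHBD, nHBA, MR, logPapp,
#'     logKp).}
#'   \item{`mcf7_ic50`}{IC50 values (micromolar) of the three active
#'     derivatives against the MCF-7 cell line (data frame).}
#'   \item{`table9_toxicity_labels`}{published binary organ-toxicity
#'     labels; shipped for completeness, nothing in the package computes
#'     from them (data frame).}
#' }
#'
#' @param name one of [fixture_names()].
#' @return a data frame or descriptor matrix, depending on the fixture.
#' @examples
#' load_fixture("table2_standards")
#' @export
load_fixture <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% .fixture_names) {
    stop(sprintf("unknown fixture '%s'; available: %s",
                 paste(name, collapse = ","),
                 paste(.fixture_names, collapse = ", ")), call. = FALSE)
  }
  path <- system.file("extdata", "fixtures", paste0(name, ".csv"),
                      package = "tlclipo", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  switch(name,
    table2_standards = validate_standards(df),
    table3_retention = {
      stopifnot(all(c("compound", "rm0", "b", "r", "logp_tlc") %in% names(df)))
      df
    },
    table4_theoretical_logp = as_descriptor_table(df),
    table6_properties = as_descriptor_table(df),
    mcf7_ic50 = {
      stopifnot(all(c("compound", "assay", "ic50_uM") %in% names(df)),
                all(df$ic50_uM > 0))
      df
    },
    table9_toxicity_labels = df)
}

#' Assemble the published lipophilicity descriptor block
#'
#' Convenience builder for the compound-by-descriptor matrices the
#' chemometric analyses run on, assembled from the packaged fixtures:
#' experimental `R_M0` and `logP_TLC` joined with the ten theoretical logP
#' columns, and optionally the physicochemical/ADME block.
#'
#' @param include character vector among `"experimental"` (R_M0 and
#'   logP_TLC), `"theoretical"` (the ten calculator columns) and
#'   `"properties"` (the physicochemical/ADME columns).
#' @return a descriptor matrix with the five compounds as rows.
#' @examples
#' lipophilicity_table()                    # the 12 lipophilicity columns
#' lipophilicity_table(c("experimental", "theoretical", "properties"))
#' @export
lipophilicity_table <- function(include = c("experimental", "theoretical")) {
  include <- match.arg(include,
                       c("experimental", "theoretical", "properties"),
                       several.ok = TRUE)
  t3 <- load_fixture("table3_retention")
  blocks <- list()
  if ("experimental" %in% include) {
    blocks$exp <- matrix(c(t3$rm0, t3$logp_tlc), ncol = 2,
                         dimnames = list(t3$compound,
                                         c("R_M0", "logP_TLC")))
  }
  if ("theoretical" %in% include) {
    blocks$theo <- load_fixture("table4_theoretical_logp")[t3$compound, ,
                                                           drop = FALSE]
  }
  if ("properties" %in% include) {
    blocks$prop <- load_fixture("table6_properties")[t3$compound, ,
                                                     drop = FALSE]
  }
  do.call(cbind, unname(blocks))
}
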