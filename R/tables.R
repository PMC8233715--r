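#' Packaged study tables
#'
#' @description
#' Three reference tables from the freeze-dried beef fatty-acid NIRS study
#' ship with the package as plain CSV:
#'
#' * `fa_reference_stats()` - descriptive statistics (mean, min, max, SD,
#'   CV%) of 20 fatty acids and 4 group sums, per lipid fraction
#'   (`phospholipid`, `total`) and per set (`calibration`, `validation`),
#'   in mg FA per 100 g meat.
#' * `model_configs()` - the 48 published model configurations: pre-treatment
#'   columns (baseline, normalization, scatter, smooth, mathematical
#'   treatment) and the number of PLS factors per fraction/analyte. The
#'   derived column `chain` holds the [parse_chain()] specification string
#'   assembled from the five pre-treatment columns in application order.
#' * `reported_performance()` - the published per-model statistics
#'   (n, SEC, R2c, SEP, R2p, RPD, Consistency).
#'
#' These tables are inputs: the descriptive statistics parameterize the
#' synthetic-data generator, the configurations drive [run_suite()], and the
#' reported performance supports the arithmetic-identity checks (RPD =
#' SD/SEP, Consistency = SEC*100/SEP, CV = SD/mean*100).
#'
#' @return A `data.frame`.
#' @name study_tables
NULL

read_extdata <- function(file) {
  path <- system.file("extdata", file, package = "nirsfa", mustWork = TRUE)
  as.data.frame(data.table::fread(path))
}

#' @rdname study_tables
#' @export
fa_reference_stats <- function() read_extdata("fa_reference_stats.csv")

#' @rdname study_tables
#' @export
model_configs <- function() {
  cfg <- read_extdata("model_configs.csv")
  cfg$chain <- apply(cfg[, c("baseline", "normalization", "scatter",
                             "smooth", "math")], 1,
                     paste, collapse = "|")
  cfg
}

#' @rdname study_tables
#' @export
reported_performance <- function() read_extdata("reported_performance.csv")

#' Names of the modelled analytes
#'
#' The 20 individual fatty acids followed by the 4 group sums
#' (`TotalFA`, `SFA`, `MUFA`, `PUFA`).
#'
#' @return Character vector of length 24.
#' @export
analyte_names <- function() {
  c("12:0", "14:0", "16:0", "16:0ald", "16:1", "18:0", "18:0ald",
    "18:1t9", "18:1c9", "18:1c11", "18:2n-6", "20:1", "18:3n-3",
    "CLA9c11t", "20:3n-6", "20:4n-6", "20:5n-3", "22:4n-6", "22:5n-3",
    "22:6n-3", "TotalFA", "SFA", "MUFA", "PUFA")
}

# group membership used for group sums; SFA includes the two aldehydes,
# PUFA includes CLA (a conjugated diene)
fa_groups <- function() {
  list(SFA  = c("12:0", "14:0", "16:0", "18:0", "16:0ald", "18:0ald"),
       MUFA = c("16:1", "18:1t9", "18:1c9", "18:1c11", "20:1"),
       PUFA = c("18:2n-6", "18:3n-3", "CLA9c11t", "20:3n-6", "20:4n-6",
                "20:5n-3", "22:4n-6", "22:5n-3", "22:6n-3"))
}
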