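#' Descriptive statistics of a concentration vector
#'
#' Mean, min, max, sample (n-1) standard deviation, and coefficient of
#' variation CV% = SD/mean*100. CV is `NA` when the mean is zero.
#'
#' @param values numeric vector, length >= 2.
#' @return A one-row `data.frame` with columns `n, mean, min, max, sd, cv`.
#' @export
descriptive_stats <- function(values) {
  values <- as.numeric(values)
  stopifnot(length(values) >= 2, all(is.finite(values)))
  m <- mean(values)
  s <- stats::sd(values)
  data.frame(n = length(values), mean = m, min = min(values),
             max = max(values), sd = s,
             cv = if (m != 0) s / m * 100 else NA_real_)
}

#' Coefficient of variation (percent)
#'
#' @param sd standard deviation.
#' @param mean mean (non-zero).
#' @return `sd / mean * 100`.
#' @export
cv_percent <- function(sd, mean) {
  if (any(mean == 0)) stop("CV undefined for zero mean")
  sd / mean * 100
}

#' Standard error of calibration (SEC)
#'
#' Root of the calibration residual sum of squares over `n - F - 1` degrees
#' of freedom, F the number of PLS factors.
#'
#' @param y_true,y_pred calibration reference values and model predictions.
#' @param n_factors F, the number of factors consumed by the model.
#' @return SEC, in the units of `y`.
#' @export
sec <- function(y_true, y_pred, n_factors) {
  r <- y_true - y_pred
  n <- length(r)
  stopifnot(length(y_pred) == n)
  if (n <= n_factors + 1)
    stop("SEC undefined: need n > n_factors + 1")
  sqrt(sum(r^2) / (n - n_factors - 1))
}

#' Standard error of prediction (SEP)
#'
#' Bias-corrected standard deviation of the validation residuals,
#' `sqrt(sum((r - mean(r))^2) / (n - 1))`. A systematic bias therefore does
#' not inflate SEP; see [rmsep()] for the uncorrected error.
#'
#' @param y_true,y_pred validation reference values and predictions (n >= 2).
#' @return SEP, in the units of `y`.
#' @export
sep <- function(y_true, y_pred) {
  r <- y_true - y_pred
  stopifnot(length(y_pred) == length(y_true), length(r) >= 2)
  stats::sd(r)
}

#' Root mean squared error of prediction
#'
#' @inheritParams sep
#' @return `sqrt(mean((y_true - y_pred)^2))`.
#' @export
rmsep <- function(y_true, y_pred) {
  sqrt(mean((y_true - y_pred)^2))
}

#' Coefficient of determination as squared Pearson correlation
#'
#' The R2 reported for calibration (R2c) and validation (R2p) scatter:
#' `cor(y_true, y_pred)^2`. Note that this definition is insensitive to
#' scale and sign of the predictions (a perfectly anti-correlated predictor
#' also scores 1); it reflects the tightness of the scatter plot, not
#' prediction bias.
#'
#' @inheritParams sep
#' @return R2 in `[0, 1]`.
#' @export
r_squared <- function(y_true, y_pred) {
  if (stats::var(y_true) <= 0) stop("R2 undefined: y_true has zero variance")
  if (stats::var(y_pred) <= 0) return(0)
  stats::cor(y_true, y_pred)^2
}

#' Ratio of performance to deviation (RPD)
#'
#' `RPD = SD / SEP`, with SD the standard deviation of the reference values
#' of the validation set. RPD below 2 is conventionally regarded as adequate
#' only for screening.
#'
#' @param sd_validation standard deviation of the validation reference values.
#' @param sep standard error of prediction (> 0).
#' @return RPD (dimensionless).
#' @export
rpd <- function(sd_validation, sep) {
  if (any(sep <= 0)) stop("RPD undefined for SEP <= 0")
  sd_validation / sep
}

#' Consistency (percent)
#'
#' `Consistency = SEC * 100 / SEP`. Values near 100% indicate that the model
#' performs comparably on calibration and validation data; values well below
#' 100% indicate over-fitting to the calibration set.
#'
#' @param sec standard error of calibration.
#' @param sep standard error of prediction (> 0).
#' @return Consistency in percent.
#' @export
consistency <- function(sec, sep) {
  if (any(sep <= 0)) stop("Consistency undefined for SEP <= 0")
  sec * 100 / sep
}

#' Classify a model by its RPD
#'
#' @param rpd RPD value (>= 0).
#' @return `"screening"` if `rpd < 2`, `"analytical"` if `rpd >= 2`
#'   (the boundary value 2 counts as analytical).
#' @export
classify_rpd <- function(rpd) {
  stopifnot(all(rpd >= 0))
  ifelse(rpd < 2, "screening", "analytical")
}

#' Write a validation report as delimited text
#'
#' Emits the standard report column order:
#' `analyte, n, SEC, R2c, SEP, R2p, RPD, Consistency` (plus any extra
#' columns present, appended after these).
#'
#' @param report a `data.frame` with (at least) the columns above, lowercase
#'   or as produced by [run_suite()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  lead <- c("analyte", "n", "SEC", "R2c", "SEP", "R2p", "RPD", "Consistency")
  missing <- setdiff(lead, names(report))
  if (length(missing))
    stop("report lacks columns: ", paste(missing, collapse = ", "))
  report <- report[, c(lead, setdiff(names(report), lead)), drop = FALSE]
  data.table::fwrite(report, path)
  invisible(path)
}
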