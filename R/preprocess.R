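#' @name pretreatments
#' @title Spectral pre-treatment operators
#'
#' @description
#' The operator catalog used in meat NIRS calibration work. All operators act
#' row-wise on a scans x wavelengths matrix and preserve the grid length:
#'
#' * `offset_baseline()` subtracts each spectrum's minimum.
#' * `area_normalize()` divides each spectrum by its L1 norm (sum of absolute
#'   values), so the normalized spectrum has unit total area.
#' * `snv()` is the standard normal variate: per-spectrum centering and
#'   scaling to unit sample (n-1) standard deviation.
#' * `detrend()` removes a least-squares quadratic polynomial in wavelength
#'   from each spectrum (the "D" of SNVD).
#' * `msc()` is multiplicative scatter correction: each spectrum is regressed
#'   on a reference spectrum, `x = a + b * ref`, and corrected to
#'   `(x - a) / b`.
#' * `emsc()` extends MSC with linear and quadratic wavelength terms,
#'   `x = a + b * ref + c1 * l + c2 * l^2` with `l` the wavelength mapped to
#'   `[-1, 1]`; the polynomial baseline is removed along with the offset.
#' * `savgol_derivative()` is the Savitzky-Golay smoothing differentiator,
#'   parameterized by derivative order, polynomial order and (odd) window
#'   size in grid points. Derivatives are scaled by the grid step so units
#'   are absorbance per nm^deriv; edge points come from one-sided fits of the
#'   local polynomial.
#' * `norris_gap_derivative()` is the Norris gap first derivative
#'   `(x[i+g] - x[i-g]) / (2 g step)`; edge points take the nearest interior
#'   value.
#'
#' @param X numeric matrix (or vector, treated as one spectrum),
#'   scans x wavelengths.
#' @param grid the [wl_grid()] the columns of `X` are aligned to.
#' @param reference reference spectrum (numeric vector) for MSC/EMSC,
#'   typically the mean calibration spectrum.
#' @return A matrix of the same dimension as `X` (a vector in gives a
#'   1-row matrix back via `as_spec_matrix`, returned as a vector).
NULL

as_spec_matrix <- function(X) {
  if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
}

restore_shape <- function(out, X) {
  if (is.null(dim(X))) drop(out) else out
}

#' @rdname pretreatments
#' @export
offset_baseline <- function(X) {
  M <- as_spec_matrix(X)
  restore_shape(M - apply(M, 1, min), X)
}

#' @rdname pretreatments
#' @export
area_normalize <- function(X) {
  M <- as_spec_matrix(X)
  area <- rowSums(abs(M))
  if (any(area <= 0))
    stop("degenerate input: all-zero spectrum cannot be area-normalized")
  restore_shape(M / area, X)
}

#' @rdname pretreatments
#' @export
snv <- function(X) {
  M <- as_spec_matrix(X)
  mu <- rowMeans(M)
  sdv <- apply(M, 1, stats::sd)
  if (any(sdv <= 0))
    stop("degenerate input: constant spectrum has zero variance under SNV")
  restore_shape((M - mu) / sdv, X)
}

#' @rdname pretreatments
#' @export
detrend <- function(X, grid) {
  M <- as_spec_matrix(X)
  if (grid$n_points <= 3) stop("detrend needs more than 3 grid points")
  l <- scaled_lambda(grid)
  D <- cbind(1, l, l^2)
  # residual of per-row quadratic fit; B = M D (D'D)^-1 are the coefficients
  B <- M %*% D %*% solve(crossprod(D))
  restore_shape(M - B %*% t(D), X)
}

#' @rdname pretreatments
#' @export
msc <- function(X, reference) {
  M <- as_spec_matrix(X)
  stopifnot(length(reference) == ncol(M))
  vr <- stats::var(reference)
  if (vr <= 0) stop("MSC reference spectrum has zero variance")
  rc <- reference - mean(reference)
  # least-squares slope of x ~ a + b*ref; sums cancel the n-1 factors
  b <- as.vector(M %*% rc) / sum(rc^2)
  a <- rowMeans(M) - b * mean(reference)
  if (any(abs(b) < 1e-12)) stop("scatter fit degenerate: slope ~ 0")
  restore_shape((M - a) / b, X)
}

#' @rdname pretreatments
#' @export
emsc <- function(X, reference, grid) {
  M <- as_spec_matrix(X)
  stopifnot(length(reference) == ncol(M), grid$n_points == ncol(M))
  if (stats::var(reference) <= 0) stop("EMSC reference spectrum has zero variance")
  l <- scaled_lambda(grid)
  E <- cbind(1, reference, l, l^2)
  B <- M %*% E %*% solve(crossprod(E))  # rows: (a, b, c1, c2)
  b <- B[, 2]
  if (any(abs(b) < 1e-12)) stop("scatter fit degenerate: slope ~ 0")
  corrected <- (M - B[, c(1, 3, 4), drop = FALSE] %*% t(E[, c(1, 3, 4)])) / b
  restore_shape(corrected, X)
}

#' @rdname pretreatments
#' @param deriv_order derivative order (0 = smoothing only for SG; NG only
#'   supports 1).
#' @param poly_order polynomial order of the SG local fit (> deriv_order
#'   required... precisely: >= deriv_order and < window_points).
#' @param window_points odd SG window length in grid points.
#' @export
savgol_derivative <- function(X, deriv_order, poly_order, window_points, grid) {
  if (window_points %% 2 != 1 || window_points <= poly_order ||
      deriv_order > poly_order || deriv_order < 0)
    stop(sprintf(
      "invalid Savitzky-Golay parameters: deriv %d, poly %d, window %d",
      deriv_order, poly_order, window_points))
  M <- as_spec_matrix(X)
  if (window_points > ncol(M)) stop("SG window larger than spectrum")
  out <- t(apply(M, 1, function(x)
    signal::sgolayfilt(x, p = poly_order, n = window_points,
                       m = deriv_order, ts = grid$step_nm)))
  restore_shape(out, X)
}

#' @rdname pretreatments
#' @param gap_points Norris gap size g in grid points.
#' @export
norris_gap_derivative <- function(X, deriv_order, gap_points, grid) {
  if (deriv_order != 1)
    stop("Norris gap derivative: only first order is supported")
  M <- as_spec_matrix(X)
  p <- ncol(M)
  g <- as.integer(gap_points)
  if (g < 1 || p <= 2 * g)
    stop(sprintf("Norris gap %d too large for %d grid points", g, p))
  idx <- (g + 1):(p - g)
  D <- matrix(0, nrow(M), p)
  D[, idx] <- (M[, idx + g, drop = FALSE] - M[, idx - g, drop = FALSE]) /
    (2 * g * grid$step_nm)
  # edges replicate the nearest interior derivative
  D[, seq_len(g)] <- D[, g + 1]
  D[, (p - g + 1):p] <- D[, p - g]
  restore_shape(D, X)
}

# ---- chain grammar ----------------------------------------------------------

#' Parse a pre-treatment chain specification
#'
#' Chains are written as `|`-separated tokens in application order, mirroring
#' the Baseline / Normalization / Scatter / Smooth / Mathematical-treatment
#' columns of the model-configuration tables:
#' `Offset`, `Area`, `SNV`, `SNV+D`, `MSC`, `EMSC`, `EMSC+D`,
#' `SG-<deriv>-<poly>-<window>`, `NG-<deriv>-<gap>`, `None`.
#' `SNV+D`/`EMSC+D` expand to the scatter step followed by detrending.
#' Irregular smoothing tokens of the form `SG1-<poly>-<window>` (a
#' zeroth-derivative smoothing pass, as they appear in some published model
#' tables) are accepted with the window normalized up to the smallest valid
#' odd value; such steps are flagged `low_confidence`.
#'
#' @param spec_string chain specification, e.g. `"Offset|Area|SNV+D|SG-1-2-3"`.
#' @return An object of class `pretreat_chain`: a list of steps, each a list
#'   with `type` and parameters. `"None"` tokens contribute no step.
#' @export
parse_chain <- function(spec_string) {
  stopifnot(is.character(spec_string), length(spec_string) == 1)
  tokens <- trimws(strsplit(spec_string, "|", fixed = TRUE)[[1]])
  steps <- list()
  add <- function(...) steps[[length(steps) + 1]] <<- list(...)
  for (tok in tokens) {
    if (tok == "" || tok == "None") next
    if (tok == "Offset") add(type = "offset")
    else if (tok == "Area") add(type = "area")
    else if (tok == "SNV") add(type = "snv")
    else if (tok == "SNV+D") { add(type = "snv"); add(type = "detrend") }
    else if (tok == "D" || tok == "Detrend") add(type = "detrend")
    else if (tok == "MSC") add(type = "msc")
    else if (tok == "EMSC") add(type = "emsc")
    else if (tok == "EMSC+D") { add(type = "emsc"); add(type = "detrend") }
    else if (grepl("^SG-[0-9]+-[0-9]+-[0-9]+$", tok)) {
      v <- as.integer(strsplit(tok, "-")[[1]][-1])
      add(type = "sg", deriv = v[1], poly = v[2], window = v[3])
    } else if (grepl("^NG-[0-9]+-[0-9]+$", tok)) {
      v <- as.integer(strsplit(tok, "-")[[1]][-1])
      add(type = "ng", deriv = v[1], gap = v[2])
    } else if (grepl("^SG1-[0-9]+-[0-9]+$", tok)) {
      v <- as.integer(strsplit(tok, "-")[[1]][-1])
      w <- v[2]
      if (w %% 2 == 0 || w <= v[1]) {  # normalize to smallest valid odd window
        w <- v[1] + 1 + (v[1] %% 2)
        w <- max(w, 3)
      }
      add(type = "sg", deriv = 0L, poly = v[1], window = w,
          low_confidence = TRUE)
    } else stop("unknown pre-treatment token: '", tok, "'")
  }
  structure(list(steps = steps, spec = spec_string, fitted = FALSE),
            class = "pretreat_chain")
}

#' @export
print.pretreat_chain <- function(x, ...) {
  cat(sprintf("Pre-treatment chain \"%s\": %d step(s)%s\n", x$spec,
              length(x$steps), if (x$fitted) " [fitted]" else ""))
  invisible(x)
}

needs_reference <- function(step) step$type %in% c("msc", "emsc")

apply_step <- function(step, X, grid) {
  switch(step$type,
         offset  = offset_baseline(X),
         area    = area_normalize(X),
         snv     = snv(X),
         detrend = detrend(X, grid),
         msc     = msc(X, step$reference),
         emsc    = emsc(X, step$reference, grid),
         sg      = savgol_derivative(X, step$deriv, step$poly, step$window, grid),
         ng      = norris_gap_derivative(X, step$deriv, step$gap, grid),
         stop("unknown step type: ", step$type))
}

#' Fit a pre-treatment chain on calibration spectra
#'
#' Reference-dependent steps (MSC, EMSC) take as reference the mean of the
#' calibration spectra pre-treated by the preceding steps of the chain; only
#' calibration data contribute to any fitted state, so applying the fitted
#' chain to new spectra uses no statistic of those spectra.
#'
#' @param chain a [parse_chain()] result.
#' @param X_cal calibration spectra matrix (samples x wavelengths).
#' @param grid the [wl_grid()].
#' @return The chain with fitted references stored (`fitted = TRUE`).
#' @export
fit_chain <- function(chain, X_cal, grid) {
  stopifnot(inherits(chain, "pretreat_chain"))
  X <- as_spec_matrix(X_cal)
  for (i in seq_along(chain$steps)) {
    if (needs_reference(chain$steps[[i]]))
      chain$steps[[i]]$reference <- colMeans(X)
    X <- apply_step(chain$steps[[i]], X, grid)
  }
  chain$fitted <- TRUE
  chain$grid <- grid
  chain
}

#' Apply a fitted pre-treatment chain
#'
#' @param chain a chain fitted by [fit_chain()] (chains without MSC/EMSC steps
#'   may also be applied unfitted, since they carry no calibration state).
#' @param X spectra matrix to transform.
#' @param grid grid of `X`; defaults to the grid stored at fit time.
#' @return Transformed matrix of the same dimension as `X`.
#' @export
chain_transform <- function(chain, X, grid = chain$grid) {
  stopifnot(inherits(chain, "pretreat_chain"))
  if (!chain$fitted && any(vapply(chain$steps, needs_reference, logical(1))))
    stop("chain with MSC/EMSC steps must be fitted on calibration spectra first")
  if (is.null(grid)) stop("grid must be supplied for an unfitted chain")
  X <- as_spec_matrix(X)
  for (step in chain$steps) X <- apply_step(step, X, grid)
  X
}

#' Fit on calibration spectra and transform both sets
#'
#' Convenience wrapper: fits the chain on the calibration spectra, then
#' applies the identical transform to calibration and (optionally) new
#' spectra.
#'
#' @param chain a [parse_chain()] result (or chain spec string).
#' @param X_cal calibration spectra matrix.
#' @param X_new optional new/validation spectra matrix.
#' @param grid the [wl_grid()].
#' @return List with `calibration`, `validation` (NULL if `X_new` missing)
#'   and the fitted `chain`.
#' @export
apply_chain <- function(chain, X_cal, X_new = NULL, grid = wl_grid()) {
  if (is.character(chain)) chain <- parse_chain(chain)
  fitted <- fit_chain(chain, X_cal, grid)
  list(calibration = chain_transform(fitted, X_cal),
       validation = if (!is.null(X_new)) chain_transform(fitted, X_new),
       chain = fitted)
}
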