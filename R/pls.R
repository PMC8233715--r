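#' NIPALS partial least squares regression
#'
#' Fits a univariate PLS1 model by NIPALS deflation on column-mean-centered
#' `X` and mean-centered `y`. Spectra contain thousands of highly collinear
#' wavelengths; PLS compresses them into a few latent factors whose scores
#' are mutually orthogonal. No unit-variance scaling is applied to `X`
#' (standard for absorbance spectra). The regression coefficient vector `b`
#' in the original wavelength space satisfies
#' `yhat = y_mean + (X - x_mean) b`.
#'
#' @param X numeric matrix, samples x wavelengths.
#' @param y numeric response vector (concentration, mg/100 g).
#' @param n_factors number of latent factors F (>= 1,
#'   <= min(n_samples - 1, n_wavelengths)).
#' @param tol NIPALS convergence tolerance on the weight-vector change.
#' @param max_iter maximum NIPALS iterations per factor.
#' @param truncate_rank if `TRUE`, stop deflation early (with fewer factors
#'   than requested) when the residual X matrix is exhausted instead of
#'   raising an error; used by cross-validation over factor counts.
#' @return An object of class `nipals_pls` with elements `n_factors`,
#'   `x_mean`, `y_mean`, `weights` (p x F), `x_loadings` (p x F),
#'   `y_loadings` (length F), `scores` (calibration scores, n x F),
#'   `score_variances` (sample variance of each score column), `proj`
#'   (p x F matrix mapping centered spectra to scores), and `b`.
#' @references Wold, S. et al. PLS-regression: a basic tool of chemometrics.
#'   Chemometrics and Intelligent Laboratory Systems 58 (2001) 109-130.
#' @export
fit_pls <- function(X, y, n_factors, tol = 1e-10, max_iter = 500,
                    truncate_rank = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n_factors >= 1)
  if (n_factors > min(n - 1, p))
    stop("n_factors exceeds min(n_samples - 1, n_wavelengths)")
  if (n < n_factors + 2)
    stop("need at least n_factors + 2 samples")
  if (stats::var(y) <= 0) stop("degenerate target: y has zero variance")
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  u <- y - y_mean
  W <- P <- matrix(0, p, n_factors)
  Tm <- matrix(0, n, n_factors)
  q <- numeric(n_factors)
  achieved <- n_factors
  for (k in seq_len(n_factors)) {
    # NIPALS weight iteration; with a single response the y-side vector is
    # the fixed y residual, so the loop converges on the first pass
    w <- crossprod(Xc, u)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-300) {
      if (truncate_rank && k > 1) { achieved <- k - 1L; break }
      stop("degenerate factor ", k, ": X residual orthogonal to y residual")
    }
    w <- w / wn
    for (it in seq_len(max_iter)) {
      w_new <- crossprod(Xc, u)
      w_new <- w_new / sqrt(sum(w_new^2))
      delta <- sqrt(sum((w_new - w)^2))
      w <- w_new
      if (delta < tol) break
      if (it == max_iter)
        stop("NIPALS did not converge within max_iter iterations")
    }
    t_ <- Xc %*% w
    tt <- sum(t_^2)
    if (tt < n * .Machine$double.eps) {
      if (truncate_rank && k > 1) { achieved <- k - 1L; break }
      stop("degenerate factor ", k, ": zero score variance")
    }
    pk <- crossprod(Xc, t_) / tt
    qk <- sum(u * t_) / tt
    Xc <- Xc - t_ %*% t(pk)
    u <- u - qk * t_
    W[, k] <- w; P[, k] <- pk; Tm[, k] <- t_; q[k] <- qk
  }
  if (achieved < n_factors) {
    W <- W[, seq_len(achieved), drop = FALSE]
    P <- P[, seq_len(achieved), drop = FALSE]
    Tm <- Tm[, seq_len(achieved), drop = FALSE]
    q <- q[seq_len(achieved)]
  }
  proj <- W %*% solve(crossprod(P, W))   # maps centered X to scores
  b <- as.vector(proj %*% q)
  structure(list(n_factors = achieved, x_mean = x_mean, y_mean = y_mean,
                 weights = W, x_loadings = P, y_loadings = q,
                 scores = Tm, score_variances = apply(Tm, 2, stats::var),
                 proj = proj, b = b),
            class = "nipals_pls")
}

#' @export
print.nipals_pls <- function(x, ...) {
  cat(sprintf("NIPALS PLS model: %d factor(s), %d wavelengths\n",
              x$n_factors, length(x$b)))
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' @param object a [fit_pls()] model.
#' @param X_new matrix of new (identically pre-treated) spectra.
#' @param n_factors predict with a truncated number of factors
#'   (default: all fitted factors).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.nipals_pls <- function(object, X_new, n_factors = object$n_factors, ...) {
  X_new <- as_spec_matrix(X_new)
  if (ncol(X_new) != length(object$x_mean))
    stop(sprintf("wavelength mismatch: model has %d, new spectra have %d",
                 length(object$x_mean), ncol(X_new)))
  stopifnot(n_factors >= 1, n_factors <= object$n_factors)
  k <- seq_len(n_factors)
  b <- as.vector(object$proj[, k, drop = FALSE] %*% object$y_loadings[k])
  as.vector(object$y_mean + sweep(X_new, 2, object$x_mean) %*% b)
}

#' Select the number of PLS factors by cross-validation
#'
#' Venetian-blind k-fold cross-validation: sample order is shuffled once
#' (seeded), folds are the interleaved blinds, and the cross-validated R2
#' (squared correlation of held-out predictions with `y`) is computed for
#' each candidate factor count. The smallest F whose R2cv is within one
#' standard error (across folds) of the best is returned, so statistically
#' indistinguishable models resolve to the most parsimonious one.
#'
#' @param X,y calibration data.
#' @param F_max largest factor count to consider.
#' @param folds number of cross-validation folds (>= 2).
#' @param seed integer seed for the blind assignment.
#' @return Selected factor count (integer), with the per-F cross-validated
#'   R2 attached as attribute `"r2cv"`.
#' @export
select_factors <- function(X, y, F_max, folds = 10, seed = 1) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(folds >= 2, F_max >= 1)
  if (F_max > min(n - ceiling(n / folds) - 2, ncol(X)))
    stop("F_max too large for the fold sizes available")
  perm <- local_seeded(seed, sample.int(n))
  fold_of <- integer(n)
  fold_of[perm] <- (seq_len(n) - 1L) %% folds + 1L
  pred <- matrix(NA_real_, n, F_max)
  for (f in seq_len(folds)) {
    hold <- which(fold_of == f)
    m <- fit_pls(X[-hold, , drop = FALSE], y[-hold], F_max,
                 truncate_rank = TRUE)
    for (k in seq_len(F_max))
      pred[hold, k] <- predict(m, X[hold, , drop = FALSE],
                               n_factors = min(k, m$n_factors))
  }
  r2cv <- apply(pred, 2, function(p) suppressWarnings(stats::cor(p, y))^2)
  r2cv[is.na(r2cv)] <- 0
  # per-fold R2 of the best F, for the one-standard-error tie-break
  best <- which.max(r2cv)
  per_fold <- vapply(seq_len(folds), function(f) {
    h <- which(fold_of == f)
    r <- suppressWarnings(stats::cor(pred[h, best], y[h]))^2
    if (is.na(r)) 0 else r
  }, numeric(1))
  se <- stats::sd(per_fold) / sqrt(folds)
  chosen <- which(r2cv >= r2cv[best] - se)[1]
  structure(as.integer(chosen), r2cv = r2cv)
}

#' Plot PLS regression coefficients against wavelength
#'
#' @param x a [fit_pls()] model.
#' @param grid the [wl_grid()] the model was fitted on.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.nipals_pls <- function(x, grid = wl_grid(), ...) {
  graphics::plot(wavelengths(grid), x$b, type = "l",
                 xlab = "wavelength (nm)",
                 ylab = "regression coefficient", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

# evaluate expr with a temporary RNG state; restores any global seed
local_seeded <- function(seed, expr) {
  expr <- substitute(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(expr)
}

#' Hotelling statistic of samples in PLS score space
#'
#' For each sample, scores on the model's factors are standardized by the
#' calibration score variances and summed:
#' `H = sum_k t_k^2 / var(t_k)`. Calibration samples far from the centroid of
#' the score space get large H; the conventional cutoff used for outlier
#' screening here is 10.
#'
#' @param model a [fit_pls()] model.
#' @param X spectra matrix (same pre-treatment as the calibration data).
#' @param threshold outlier cutoff on H (default 10).
#' @return A `data.frame` with columns `H` and `outlier` (`H > threshold`),
#'   one row per row of `X`; `threshold` is attached as an attribute.
#' @export
hotelling_h <- function(model, X, threshold = 10) {
  stopifnot(inherits(model, "nipals_pls"))
  Tn <- sweep(as_spec_matrix(X), 2, model$x_mean) %*% model$proj
  H <- rowSums(sweep(Tn^2, 2, model$score_variances, "/"))
  structure(data.frame(H = H, outlier = H > threshold),
            threshold = threshold)
}

#' Fit, screen Hotelling outliers, and refit once
#'
#' Fits a PLS model, flags calibration samples with `H > threshold`, removes
#' them, and refits once on the remaining samples. If removal would leave
#' fewer than `n_factors + 2` samples, the original model is returned with a
#' warning and nothing is removed.
#'
#' @inheritParams fit_pls
#' @param threshold Hotelling cutoff (default 10).
#' @return List with `model` (the refit), `removed` (integer indices of
#'   removed rows), and `H` (the first-pass Hotelling table).
#' @export
remove_outliers_refit <- function(X, y, n_factors, threshold = 10) {
  X <- as.matrix(X)
  m0 <- fit_pls(X, y, n_factors)
  h <- hotelling_h(m0, X, threshold)
  out <- which(h$outlier)
  if (length(out) == 0)
    return(list(model = m0, removed = integer(0), H = h))
  if (nrow(X) - length(out) < n_factors + 2) {
    warning("outlier removal would leave too few samples; keeping all")
    return(list(model = m0, removed = integer(0), H = h))
  }
  m1 <- fit_pls(X[-out, , drop = FALSE], y[-out], n_factors)
  list(model = m1, removed = out, H = h)
}

#' Serialize a PLS model (plus context) to JSON
#'
#' Stores centering vectors, loadings, coefficients and score variances,
#' together with an optional pre-treatment chain spec and grid, so the model
#' can be reloaded and used for prediction.
#'
#' @param model a [fit_pls()] model.
#' @param path output JSON path.
#' @param chain_spec optional chain specification string stored alongside.
#' @param grid optional [wl_grid()] stored alongside.
#' @return `path`, invisibly.
#' @export
save_pls_model <- function(model, path, chain_spec = NULL, grid = NULL) {
  stopifnot(inherits(model, "nipals_pls"))
  doc <- list(n_factors = model$n_factors,
              x_mean = model$x_mean, y_mean = model$y_mean,
              weights = model$weights, x_loadings = model$x_loadings,
              y_loadings = model$y_loadings,
              score_variances = model$score_variances,
              proj = model$proj, b = model$b,
              chain_spec = chain_spec,
              grid = if (!is.null(grid)) unclass(grid))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a PLS model serialized by [save_pls_model()]
#'
#' @param path JSON path.
#' @return List with `model` (class `nipals_pls`, without calibration
#'   scores), `chain_spec`, and `grid` (or NULL where absent).
#' @export
load_pls_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- structure(list(
    n_factors = doc$n_factors,
    x_mean = doc$x_mean, y_mean = doc$y_mean,
    weights = as.matrix(doc$weights), x_loadings = as.matrix(doc$x_loadings),
    y_loadings = doc$y_loadings,
    scores = NULL,
    score_variances = doc$score_variances,
    proj = as.matrix(doc$proj), b = doc$b), class = "nipals_pls")
  grid <- if (!is.null(doc$grid))
    wl_grid(doc$grid$start_nm, doc$grid$step_nm, doc$grid$n_points)
  list(model = model, chain_spec = doc$chain_spec, grid = grid)
}
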