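#' Random calibration/validation split
#'
#' Per-sample Bernoulli split: a seeded uniform number is drawn for each
#' sample and samples with `u < threshold` go to the calibration set
#' (threshold 0.67 gives the conventional 67/33 split). With `strata`, the
#' same rule is applied independently within each stratum (e.g. breed).
#'
#' @param sample_ids character vector of sample identifiers.
#' @param threshold calibration probability in (0, 1).
#' @param seed integer seed.
#' @param strata optional factor of the same length as `sample_ids`.
#' @return List with `calibration` and `validation` id vectors.
#' @export
random_split <- function(sample_ids, threshold = 0.67, seed = 1,
                         strata = NULL) {
  stopifnot(threshold > 0, threshold < 1, !anyDuplicated(sample_ids))
  n <- length(sample_ids)
  u <- local_seeded(seed, {
    if (is.null(strata)) stats::runif(n)
    else {
      v <- numeric(n)
      for (s in unique(strata)) v[strata == s] <- stats::runif(sum(strata == s))
      v
    }
  })
  cal <- u < threshold
  if (!any(cal) || all(cal))
    stop("degenerate split: one set is empty; rerun with another seed")
  list(calibration = sample_ids[cal], validation = sample_ids[!cal])
}

# k-fold cross-validated predictive Q2 = 1 - PRESS/SStot for a fixed factor
# count. With mask_quantile > 0 the coefficient-magnitude mask is re-derived
# inside every training fold, so wavelength selection never sees held-out
# samples. Unlike squared correlation, Q2 penalizes overfitted predictions.
cv_q2 <- function(X, y, n_factors, folds = 10, seed = 1, mask_quantile = 0) {
  n <- nrow(X)
  perm <- local_seeded(seed, sample.int(n))
  fold_of <- integer(n)
  fold_of[perm] <- (seq_len(n) - 1L) %% folds + 1L
  pred <- numeric(n)
  for (f in seq_len(folds)) {
    hold <- which(fold_of == f)
    Xtr <- X[-hold, , drop = FALSE]
    cols <- if (mask_quantile > 0) {
      m0 <- fit_pls(Xtr, y[-hold], n_factors)
      abs(m0$b) >= stats::quantile(abs(m0$b), mask_quantile)
    } else rep(TRUE, ncol(X))
    m <- fit_pls(Xtr[, cols, drop = FALSE], y[-hold], n_factors)
    pred[hold] <- predict(m, X[hold, cols, drop = FALSE])
  }
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' Wavelength selection by regression-coefficient magnitude
#'
#' Retains wavelengths whose absolute regression coefficient exceeds the
#' given quantile of all absolute coefficients. The reduced wavelength set is
#' adopted only if it passes a cross-validated improvement check; otherwise
#' the full set is kept. The check uses predictive Q2 (1 - PRESS/SStot),
#' with the mask re-derived inside every training fold so the selection
#' never sees held-out samples, and demands both a margin over the full
#' model (`min_improvement`) and a genuinely predictive reduced model
#' (`q2_min`); reducing the wavelength set of a model with no predictive
#' value is never reported as an improvement.
#'
#' @param model a fitted [fit_pls()] model.
#' @param X,y the calibration data the model was fitted on.
#' @param quantile quantile of `|b|` in `[0, 1)` below which wavelengths are
#'   dropped (0 retains everything).
#' @param min_improvement smallest cross-validated Q2 gain that justifies
#'   the reduced wavelength set (guards against chasing CV noise).
#' @param q2_min smallest cross-validated Q2 the reduced model must reach to
#'   be adopted at all.
#' @param folds,seed cross-validation controls.
#' @return List with `mask` (logical over wavelengths: the retained set after
#'   the improvement check), `candidate_mask` (the coefficient-quantile mask
#'   before that check), `model` (possibly refit on the retained
#'   wavelengths), `improved`, `q2_full`, `q2_masked`.
#' @export
select_wavelengths <- function(model, X, y, quantile, folds = 10, seed = 1,
                               min_improvement = 0.01, q2_min = 0.2) {
  stopifnot(inherits(model, "nipals_pls"))
  if (quantile < 0 || quantile >= 1)
    stop("quantile must be in [0, 1)")
  all_on <- rep(TRUE, length(model$b))
  if (quantile == 0)
    return(list(mask = all_on, candidate_mask = all_on, model = model,
                improved = FALSE, q2_full = NA_real_,
                q2_masked = NA_real_))
  cand <- abs(model$b) >= stats::quantile(abs(model$b), quantile)
  q2_full <- cv_q2(X, y, model$n_factors, folds, seed)
  q2_mask <- cv_q2(X, y, model$n_factors, folds, seed,
                   mask_quantile = quantile)
  if (q2_mask > q2_full + min_improvement && q2_mask > q2_min) {
    list(mask = cand, candidate_mask = cand,
         model = fit_pls(X[, cand, drop = FALSE], y, model$n_factors),
         improved = TRUE, q2_full = q2_full, q2_masked = q2_mask)
  } else {
    list(mask = all_on, candidate_mask = cand, model = model,
         improved = FALSE, q2_full = q2_full, q2_masked = q2_mask)
  }
}

#' Per-analyte run configuration
#'
#' @param chain pre-treatment chain specification string (see
#'   [parse_chain()]).
#' @param n_factors fixed PLS factor count, or `"auto"` for cross-validated
#'   selection up to `f_max`.
#' @param split_threshold calibration probability of the random split.
#' @param seed integer seed governing split and factor selection.
#' @param outlier_threshold Hotelling H cutoff.
#' @param f_max upper bound for `"auto"` factor selection.
#' @param folds cross-validation folds for `"auto"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(chain = "None", n_factors = "auto",
                       split_threshold = 0.67, seed = 1,
                       outlier_threshold = 10, f_max = 15, folds = 10) {
  stopifnot(split_threshold > 0, split_threshold < 1,
            identical(n_factors, "auto") || n_factors >= 1)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full calibration workflow for one analyte
#'
#' Split -> fit the pre-treatment chain on calibration spectra -> transform
#' both sets -> fit NIPALS PLS (fixed or cross-validated factor count) ->
#' Hotelling outlier screen with one refit -> predict the validation set ->
#' compute the report row. `n` in the report is the number of calibration
#' samples retained after outlier removal; RPD uses the standard deviation
#' of the validation reference values.
#'
#' @param dataset an [assemble_dataset()] result.
#' @param config a [run_config()].
#' @return List with `row` (one-row data.frame:
#'   `fraction, analyte, n, SEC, R2c, SEP, R2p, RPD, Consistency, class,
#'   n_factors, n_removed, n_validation`), `model`, `chain` (fitted), and
#'   `split`.
#' @export
run_analyte <- function(dataset, config = run_config()) {
  stopifnot(inherits(dataset, "nir_dataset"), inherits(config, "run_config"))
  split <- random_split(dataset$sample_ids, config$split_threshold,
                        config$seed)
  ical <- match(split$calibration, dataset$sample_ids)
  ival <- match(split$validation, dataset$sample_ids)
  tr <- apply_chain(config$chain, dataset$X[ical, , drop = FALSE],
                    dataset$X[ival, , drop = FALSE], dataset$grid)
  Xc <- tr$calibration; Xv <- tr$validation
  yc <- dataset$y[ical]; yv <- dataset$y[ival]
  nf <- if (identical(config$n_factors, "auto")) {
    fmax <- min(config$f_max,
                nrow(Xc) - ceiling(nrow(Xc) / config$folds) - 2, ncol(Xc))
    as.integer(select_factors(Xc, yc, fmax, config$folds, config$seed))
  } else as.integer(config$n_factors)
  fit <- remove_outliers_refit(Xc, yc, nf, config$outlier_threshold)
  keep <- setdiff(seq_len(nrow(Xc)), fit$removed)
  yc_kept <- yc[keep]
  pred_c <- predict(fit$model, Xc[keep, , drop = FALSE])
  pred_v <- predict(fit$model, Xv)
  sec_v <- sec(yc_kept, pred_c, nf)
  sep_v <- sep(yv, pred_v)
  rpd_v <- rpd(stats::sd(yv), sep_v)
  row <- data.frame(fraction = dataset$fraction, analyte = dataset$analyte,
                    n = length(keep),
                    SEC = sec_v, R2c = r_squared(yc_kept, pred_c),
                    SEP = sep_v, R2p = r_squared(yv, pred_v),
                    RPD = rpd_v, Consistency = consistency(sec_v, sep_v),
                    class = classify_rpd(rpd_v),
                    n_factors = nf, n_removed = length(fit$removed),
                    n_validation = length(ival))
  list(row = row, model = fit$model, chain = tr$chain, split = split)
}

#' Run a suite of model configurations
#'
#' Runs [run_analyte()] for every row of a configuration table (default: the
#' packaged 48 published configurations, [model_configs()]) against one set
#' of spectra and reference chemistry. Failures are isolated per row: a
#' failing configuration contributes a row with `error` set and NA metrics.
#'
#' @param spectra replicate-averaged [nir_spectra()].
#' @param reference long-format reference table.
#' @param configs data.frame with columns `fraction`, `analyte`, `chain`,
#'   `factors` (use [model_configs()] for the published set).
#' @param seed split seed shared by all rows.
#' @param split_threshold,outlier_threshold passed to [run_config()].
#' @return A data.frame with one row per configuration, in input order.
#' @export
run_suite <- function(spectra, reference, configs = model_configs(),
                      seed = 1, split_threshold = 0.67,
                      outlier_threshold = 10) {
  rows <- vector("list", nrow(configs))
  for (i in seq_len(nrow(configs))) {
    cf <- configs[i, ]
    rows[[i]] <- tryCatch({
      ds <- assemble_dataset(spectra, reference, cf$fraction, cf$analyte)
      rc <- run_config(chain = cf$chain, n_factors = cf$factors,
                       split_threshold = split_threshold, seed = seed,
                       outlier_threshold = outlier_threshold)
      cbind(run_analyte(ds, rc)$row, error = NA_character_)
    }, error = function(e) {
      data.frame(fraction = cf$fraction, analyte = cf$analyte,
                 n = NA_integer_, SEC = NA_real_, R2c = NA_real_,
                 SEP = NA_real_, R2p = NA_real_, RPD = NA_real_,
                 Consistency = NA_real_, class = NA_character_,
                 n_factors = NA_integer_, n_removed = NA_integer_,
                 n_validation = NA_integer_, error = conditionMessage(e))
    })
  }
  if (length(rows) == 0)
    return(data.frame(fraction = character(), analyte = character(),
                      n = integer(), SEC = numeric(), R2c = numeric(),
                      SEP = numeric(), R2p = numeric(), RPD = numeric(),
                      Consistency = numeric(), class = character(),
                      n_factors = integer(), n_removed = integer(),
                      n_validation = integer(), error = character()))
  do.call(rbind, rows)
}
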