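#' Simulation configuration
#'
#' Collects the tunable parameters of the synthetic freeze-dried beef
#' generator. Defaults emulate the study conditions: 332 samples, two scans
#' per sample, multiplicative scatter with gain SD 0.1, additive offset SD
#' 0.02, white spectral noise SD 0.005 absorbance units, a latent "carcass
#' fatness" factor that drives the neutral-lipid fraction strongly
#' (`rho_neutral`) and the phospholipid fraction weakly (`rho_phospholipid`),
#' and a reported-FA coverage of 0.93 (the 20 quantified fatty acids
#' represent 93% of the total fatty-acid mass, so `TotalFA` exceeds the sum
#' of its reported constituents).
#'
#' @param n_samples number of samples.
#' @param seed integer seed; every draw of the generator is derived from it.
#' @param scans_per_sample replicate scans per sample.
#' @param scatter_gain_sd SD of the multiplicative scatter gain (gain ~
#'   `1 + N(0, sd)`).
#' @param scatter_offset_sd SD of the additive baseline offset.
#' @param noise_sd SD of iid additive spectral noise (absorbance units).
#' @param rho_neutral copula correlation of neutral-lipid analytes with the
#'   latent fatness factor.
#' @param rho_phospholipid same for phospholipid analytes.
#' @param coverage fraction of TotalFA mass covered by the 20 reported FAs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 332, seed = 1, scans_per_sample = 2,
                       scatter_gain_sd = 0.1, scatter_offset_sd = 0.02,
                       noise_sd = 0.005, rho_neutral = 0.93,
                       rho_phospholipid = 0.3, coverage = 0.93) {
  stopifnot(n_samples >= 2, scans_per_sample >= 1,
            scatter_gain_sd >= 0, scatter_offset_sd >= 0, noise_sd >= 0,
            abs(rho_neutral) < 1, abs(rho_phospholipid) < 1,
            coverage > 0, coverage <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# lognormal parameters matched to a target mean and CV% by moment inversion
lognormal_params <- function(mean, cv) {
  if (any(mean <= 0) || any(cv <= 0)) stop("infeasible prior: mean, cv must be > 0")
  sdlog2 <- log(1 + (cv / 100)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# Gaussian-copula lognormal draw correlated with latent factor zL
copula_lognormal <- function(zL, rho, mean, cv) {
  lp <- lognormal_params(mean, cv)
  z <- rho * zL + sqrt(1 - rho^2) * stats::rnorm(length(zL))
  stats::qlnorm(stats::pnorm(z), lp$meanlog, lp$sdlog)
}

#' Simulate fatty-acid reference chemistry
#'
#' Draws per-sample concentrations of the 20 fatty acids for both lipid
#' fractions, with marginal mean and CV taken from the packaged calibration
#' descriptive statistics ([fa_reference_stats()]) unless other priors are
#' supplied. Marginals are lognormal (concentrations are positive and
#' strongly right-skewed) matched by moment inversion. A latent lognormal
#' fatness factor correlates the neutral-lipid parts of all analytes
#' (Gaussian copula, `rho_neutral`), reproducing the structure in which the
#' total fraction is much more variable than the phospholipid fraction. For
#' each analyte the total-fraction value is constructed as phospholipid +
#' non-negative neutral draw, so `phospholipid <= total` holds by
#' construction; the neutral marginal is matched to the difference of the
#' fraction means and variances. Group sums (SFA incl. aldehydes, MUFA,
#' PUFA incl. CLA) are sums of their constituents, and `TotalFA` is the sum
#' of all 20 FAs divided by `coverage`.
#'
#' @param config a [sim_config()].
#' @param priors optional data.frame like `fa_reference_stats()` restricted
#'   to `set == "calibration"`; defaults to the packaged table.
#' @return Long-format reference table (`sample_id, fraction, analyte,
#'   value_mg_per_100g`) with the per-fraction wide concentration matrices
#'   attached as attributes `"wide_total"`, `"wide_phospholipid"` (samples x
#'   24 analytes).
#' @export
simulate_concentrations <- function(config = sim_config(), priors = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(priors)) {
    st <- fa_reference_stats()
    priors <- st[st$set == "calibration", ]
  }
  fas <- setdiff(analyte_names(), c("TotalFA", "SFA", "MUFA", "PUFA"))
  n <- config$n_samples
  local_seeded(config$seed, {
    zL <- stats::rnorm(n)  # latent fatness factor
    pl <- tot <- matrix(0, n, length(fas), dimnames = list(NULL, fas))
    for (j in seq_along(fas)) {
      prow <- priors[priors$fraction == "phospholipid" & priors$analyte == fas[j], ]
      trow <- priors[priors$fraction == "total" & priors$analyte == fas[j], ]
      stopifnot(nrow(prow) == 1, nrow(trow) == 1)
      pl[, j] <- copula_lognormal(zL, config$rho_phospholipid,
                                  prow$mean, prow$cv)
      nmean <- trow$mean - prow$mean
      nvar <- (trow$sd)^2 - (prow$sd)^2
      if (nmean <= 1e-9) {
        neutral <- 0  # analyte confined to the phospholipid fraction
      } else {
        # guard against priors where the phospholipid variance exceeds the
        # total variance; the floor is negligible against any real CV
        nsd <- sqrt(max(nvar, (1e-6 * nmean)^2))
        neutral <- copula_lognormal(zL, config$rho_neutral,
                                    nmean, nsd / nmean * 100)
      }
      tot[, j] <- pl[, j] + neutral
    }
    grp <- fa_groups()
    widen <- function(M) {
      G <- vapply(grp, function(g) rowSums(M[, g, drop = FALSE]),
                  numeric(n))
      cbind(M, G, TotalFA = rowSums(M) / config$coverage)[, analyte_names()]
    }
    wide_pl <- widen(pl)
    wide_tot <- widen(tot)
    ids <- sprintf("S%03d", seq_len(n))
    long <- rbind(
      data.frame(sample_id = rep(ids, ncol(wide_pl)),
                 fraction = "phospholipid",
                 analyte = rep(colnames(wide_pl), each = n),
                 value_mg_per_100g = as.vector(wide_pl)),
      data.frame(sample_id = rep(ids, ncol(wide_tot)),
                 fraction = "total",
                 analyte = rep(colnames(wide_tot), each = n),
                 value_mg_per_100g = as.vector(wide_tot)))
    rownames(wide_pl) <- rownames(wide_tot) <- ids
    structure(long, wide_total = wide_tot, wide_phospholipid = wide_pl)
  })
}

#' Stylized absorption band library
#'
#' Each fatty acid gets a handful of Gaussian absorption bands: shared C-H
#' bands in the 1700 nm overtone region and the 2200-2500 nm combination
#' region (notably near 2310 and 2348 nm, the classic lipid wavelengths),
#' with class-dependent weights (saturated vs mono- vs polyunsaturated), plus
#' one small analyte-specific band. Sharing bands across chemically similar
#' fatty acids deliberately induces the spectral collinearity that limits
#' the prediction of minor FAs. Water bands are absent: the emulated samples
#' are freeze-dried.
#'
#' @param grid the [wl_grid()] bands must fall inside.
#' @return Named list (one element per individual fatty acid, plus
#'   `"phospholipid_head"`) of data.frames with columns
#'   `center, width, amp`; absorptivity scale is `amp * 4e-5` absorbance
#'   units per mg/100 g at the band center.
#' @export
band_library <- function(grid = wl_grid()) {
  fas <- setdiff(analyte_names(), c("TotalFA", "SFA", "MUFA", "PUFA"))
  grp <- fa_groups()
  common <- data.frame(center = c(1215, 1725, 1765, 2310, 2348),
                       width  = c(18, 14, 14, 11, 11),
                       amp    = c(0.3, 0.8, 0.6, 1.0, 0.9))
  class_band <- list(SFA  = data.frame(center = 2270, width = 12, amp = 0.5),
                     MUFA = data.frame(center = 2190, width = 12, amp = 0.5),
                     PUFA = data.frame(center = 2140, width = 12, amp = 0.5))
  lam <- wavelengths(grid)
  out <- vector("list", length(fas))
  names(out) <- fas
  for (j in seq_along(fas)) {
    cls <- names(grp)[vapply(grp, function(g) fas[j] %in% g, logical(1))]
    unique_band <- data.frame(center = 2200 + 12 * j, width = 9, amp = 0.25)
    bands <- rbind(common, class_band[[cls]], unique_band)
    if (any(bands$center < min(lam)) || any(bands$center > max(lam)))
      stop("band center outside wavelength grid")
    out[[j]] <- bands
  }
  out$phospholipid_head <- data.frame(center = 2060, width = 16, amp = 0.6)
  out
}

# evaluate the summed Gaussian band shape of one analyte on the grid
band_shape <- function(bands, lam) {
  k <- numeric(length(lam))
  for (i in seq_len(nrow(bands)))
    k <- k + bands$amp[i] * exp(-0.5 * ((lam - bands$center[i]) / bands$width[i])^2)
  k
}

# smooth baseline: flat 0.4 up to 1600 nm, rising monotonically to 1.0 at 2500
spectral_baseline <- function(lam) {
  0.4 + 0.6 * pmax(0, (lam - 1600) / 900)^1.3
}

#' Simulate NIR spectra from reference chemistry
#'
#' Beer-Lambert-style linear mixing: for sample i,
#' `x_i(l) = gain_i * (baseline(l) + sum_j c_ij K k_j(l)) + offset_i + e(l)`
#' where `k_j` are the Gaussian band shapes of the total-fraction fatty acids
#' (plus a phospholipid head-group band driven by the phospholipid TotalFA),
#' `K = 4e-5` absorbance per mg/100 g, `gain ~ 1 + N(0, scatter_gain_sd)`,
#' `offset ~ N(0, scatter_offset_sd)` and `e` iid `N(0, noise_sd)`. The
#' baseline is flat at 0.4 absorbance up to 1600 nm and rises monotonically
#' to 1.0 at 2500 nm, matching the shape of freeze-dried beef spectra.
#' Each sample is scanned `config$scans_per_sample` times with independent
#' gain, offset and noise per scan.
#'
#' @param reference long-format reference table from
#'   [simulate_concentrations()] (or equivalent).
#' @param bands band library from [band_library()].
#' @param config a [sim_config()].
#' @param grid the [wl_grid()].
#' @return A [nir_spectra()] object with
#'   `config$n_samples * config$scans_per_sample` rows.
#' @export
simulate_spectra <- function(reference, bands = band_library(grid),
                             config = sim_config(), grid = wl_grid()) {
  stopifnot(inherits(config, "sim_config"))
  lam <- wavelengths(grid)
  fas <- setdiff(analyte_names(), c("TotalFA", "SFA", "MUFA", "PUFA"))
  tot <- reference[reference$fraction == "total" &
                     reference$analyte %in% fas, ]
  ids <- unique(reference$sample_id)
  C <- matrix(0, length(ids), length(fas), dimnames = list(ids, fas))
  C[cbind(match(tot$sample_id, ids), match(tot$analyte, fas))] <-
    tot$value_mg_per_100g
  plt <- reference[reference$fraction == "phospholipid" &
                     reference$analyte == "TotalFA", ]
  pl_total <- plt$value_mg_per_100g[match(ids, plt$sample_id)]
  if (anyNA(pl_total)) pl_total <- rep(0, length(ids))

  K <- 4e-5
  shapes <- vapply(fas, function(a) band_shape(bands[[a]], lam),
                   numeric(length(lam)))                       # p x 20
  chem <- C %*% t(shapes) * K                                   # n x p
  if (!is.null(bands$phospholipid_head))
    chem <- chem + (pl_total * K) %*% t(band_shape(bands$phospholipid_head, lam))
  pure <- sweep(chem, 2, spectral_baseline(lam), "+")

  n <- length(ids); s <- config$scans_per_sample
  local_seeded(config$seed + 1L, {
    A <- matrix(0, n * s, length(lam))
    sample_id <- character(n * s)
    scan_index <- integer(n * s)
    row <- 0L
    for (sc in seq_len(s)) {
      gain <- 1 + stats::rnorm(n, 0, config$scatter_gain_sd)
      offset <- stats::rnorm(n, 0, config$scatter_offset_sd)
      eps <- matrix(stats::rnorm(n * length(lam), 0, config$noise_sd),
                    n, length(lam))
      A[row + seq_len(n), ] <- pure * gain + offset + eps
      sample_id[row + seq_len(n)] <- ids
      scan_index[row + seq_len(n)] <- sc
      row <- row + n
    }
    ord <- order(match(sample_id, ids), scan_index)
    nir_spectra(A[ord, , drop = FALSE], sample_id[ord], grid,
                scan_index = scan_index[ord])
  })
}

#' Generate a complete synthetic dataset on disk
#'
#' Runs [simulate_concentrations()] and [simulate_spectra()] and writes the
#' package's CSV dialects: `spectra.csv` (one row per scan, two scans per
#' sample by default, exercising replicate averaging) and `chemistry.csv`
#' (long-format reference table), plus `manifest.json` recording the
#' generative parameters for recovery tests. Byte-identical output for a
#' given seed.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @param grid the [wl_grid()].
#' @return Invisibly, a list with the file paths and the in-memory objects
#'   (`spectra`, `reference`).
#' @export
generate_dataset <- function(config = sim_config(), dir, grid = wl_grid()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reference <- simulate_concentrations(config)
  spectra <- simulate_spectra(reference, band_library(grid), config, grid)
  spath <- file.path(dir, "spectra.csv")
  cpath <- file.path(dir, "chemistry.csv")
  mpath <- file.path(dir, "manifest.json")
  write_spectra(spectra, spath)
  write_reference_table(
    data.frame(sample_id = reference$sample_id,
               fraction = reference$fraction,
               analyte = reference$analyte,
               value_mg_per_100g = reference$value_mg_per_100g), cpath)
  jsonlite::write_json(unclass(config), mpath, auto_unbox = TRUE, digits = NA)
  invisible(list(spectra_path = spath, chemistry_path = cpath,
                 manifest_path = mpath, spectra = spectra,
                 reference = reference))
}
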