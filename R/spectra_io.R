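#' Spectra collection
#'
#' Container for a set of log(1/R) scans aligned to a common wavelength grid.
#' `absorbance` is a scans x wavelengths matrix; `sample_id` and `scan_index`
#' run parallel to its rows. `scan_index` is `NA` after replicate averaging.
#'
#' @param absorbance numeric matrix, one row per scan.
#' @param sample_id character vector of sample identifiers, one per row.
#' @param grid the shared [wl_grid()].
#' @param scan_index integer replicate number per row (optional).
#' @return An object of class `nir_spectra`.
#' @export
nir_spectra <- function(absorbance, sample_id, grid,
                        scan_index = rep(NA_integer_, nrow(absorbance))) {
  absorbance <- as.matrix(absorbance)
  stopifnot(inherits(grid, "wl_grid"),
            ncol(absorbance) == grid$n_points,
            length(sample_id) == nrow(absorbance),
            length(scan_index) == nrow(absorbance))
  if (!all(is.finite(absorbance)))
    stop("non-finite absorbance values in spectra")
  dimnames(absorbance) <- NULL
  structure(list(absorbance = absorbance,
                 sample_id = as.character(sample_id),
                 scan_index = as.integer(scan_index),
                 grid = grid),
            class = "nir_spectra")
}

#' @export
print.nir_spectra <- function(x, ...) {
  cat(sprintf("%d scan(s) of %d sample(s), %d wavelengths (%g-%g nm)\n",
              nrow(x$absorbance), length(unique(x$sample_id)),
              x$grid$n_points, x$grid$start_nm,
              x$grid$start_nm + x$grid$step_nm * (x$grid$n_points - 1)))
  invisible(x)
}

#' Write spectra to a delimited text file
#'
#' The file carrier is CSV: a header row `sample_id,scan_index,<wavelengths>`
#' followed by one row per scan. Wavelengths are written with full precision
#' so a write/read round trip is lossless.
#'
#' @param spectra a [nir_spectra()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_spectra()]
#' @export
write_spectra <- function(spectra, path) {
  stopifnot(inherits(spectra, "nir_spectra"))
  lam <- wavelengths(spectra$grid)
  dt <- data.table::data.table(sample_id = spectra$sample_id,
                               scan_index = spectra$scan_index)
  # %.17g guarantees the shortest round-trippable decimal for a double
  vals <- matrix(sprintf("%.17g", spectra$absorbance),
                 nrow(spectra$absorbance))
  dt <- cbind(dt, data.table::as.data.table(vals))
  data.table::setnames(dt, c("sample_id", "scan_index",
                             format(lam, digits = 15, trim = TRUE,
                                    scientific = FALSE)))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read spectra from a delimited text file
#'
#' Reads the CSV dialect written by [write_spectra()] and validates the header
#' wavelengths against `grid` (agreement within 1e-9 nm is required). Scan
#' order in the file is preserved.
#'
#' @param path input file path.
#' @param grid expected [wl_grid()]; defaults to the 1000-2500 nm, 0.5 nm grid.
#' @return A [nir_spectra()] object.
#' @export
read_spectra <- function(path, grid = wl_grid()) {
  stopifnot(inherits(grid, "wl_grid"))
  dt <- data.table::fread(path, header = TRUE, sep = ",")
  if (ncol(dt) < 3 || !identical(names(dt)[1:2], c("sample_id", "scan_index")))
    stop("spectra file must start with columns sample_id, scan_index")
  hdr <- suppressWarnings(as.numeric(names(dt)[-(1:2)]))
  if (anyNA(hdr))
    stop("non-numeric wavelength in header: ",
         names(dt)[-(1:2)][which(is.na(hdr))[1]])
  lam <- wavelengths(grid)
  if (length(hdr) != length(lam))
    stop(sprintf("grid mismatch: file has %d wavelengths, grid expects %d",
                 length(hdr), length(lam)))
  off <- which(abs(hdr - lam) > 1e-9)
  if (length(off))
    stop(sprintf("grid mismatch at wavelength %g nm (expected %g nm)",
                 hdr[off[1]], lam[off[1]]))
  A <- as.matrix(dt[, -(1:2)])
  if (!is.numeric(A)) {
    bad <- which(!vapply(dt[, -(1:2)], is.numeric, logical(1)))[1]
    row <- which(is.na(suppressWarnings(as.numeric(dt[[bad + 2L]]))))[1]
    stop(sprintf("non-numeric value at row %d, column %s", row,
                 names(dt)[bad + 2L]))
  }
  nir_spectra(A, dt$sample_id, grid, scan_index = dt$scan_index)
}

#' Average replicate scans per sample
#'
#' Instruments typically scan each cup twice; downstream modelling uses the
#' arithmetic mean of the replicates. Sample order follows first appearance
#' in the input; `scan_index` is cleared. Idempotent on already-averaged data.
#'
#' @param spectra a [nir_spectra()] object (>= 1 scan per sample).
#' @return A [nir_spectra()] with one row per unique `sample_id`.
#' @export
average_replicates <- function(spectra) {
  stopifnot(inherits(spectra, "nir_spectra"))
  ids <- unique(spectra$sample_id)
  f <- factor(spectra$sample_id, levels = ids)
  A <- rowsum(spectra$absorbance, f, reorder = FALSE) /
    as.vector(table(f)[ids])
  nir_spectra(A, ids, spectra$grid)
}

#' Read a reference-chemistry table
#'
#' Long-format CSV with columns `sample_id, fraction, analyte,
#' value_mg_per_100g`; `fraction` is `"phospholipid"` or `"total"` and values
#' are concentrations in mg FA per 100 g meat (non-negative).
#'
#' @param path input file path.
#' @return A `data.frame` with the four columns above.
#' @export
read_reference_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = ",",
                          colClasses = list(character = "sample_id"))
  need <- c("sample_id", "fraction", "analyte", "value_mg_per_100g")
  if (!all(need %in% names(dt)))
    stop("reference table must have columns: ", paste(need, collapse = ", "))
  if (!all(dt$fraction %in% c("phospholipid", "total")))
    stop("fraction must be 'phospholipid' or 'total'")
  if (any(!is.finite(dt$value_mg_per_100g)) || any(dt$value_mg_per_100g < 0))
    stop("concentrations must be finite and >= 0")
  as.data.frame(dt)
}

#' Write a reference-chemistry table
#'
#' @param reference data.frame as returned by [read_reference_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reference_table <- function(reference, path) {
  data.table::fwrite(reference, path)
  invisible(path)
}

#' Join spectra with reference chemistry for one analyte
#'
#' Inner join on `sample_id` between (replicate-averaged) spectra and the
#' reference table restricted to one `fraction`/`analyte`. Samples present in
#' the spectra but missing the requested chemistry are dropped with a warning
#' giving the count; row order follows the spectra.
#'
#' @param spectra a [nir_spectra()] (one row per sample; replicate-averaged).
#' @param reference long-format reference table ([read_reference_table()]).
#' @param fraction `"phospholipid"` or `"total"`.
#' @param analyte analyte name, e.g. `"16:0"` or `"TotalFA"`.
#' @return An object of class `nir_dataset` with elements `grid`, `X`
#'   (samples x wavelengths), `y`, `sample_ids`, `fraction`, `analyte`.
#' @export
assemble_dataset <- function(spectra, reference, fraction, analyte) {
  stopifnot(inherits(spectra, "nir_spectra"))
  if (anyDuplicated(spectra$sample_id))
    stop("spectra contain replicate scans; call average_replicates() first")
  ref <- reference[reference$fraction == fraction &
                     reference$analyte == analyte, , drop = FALSE]
  if (anyDuplicated(ref$sample_id))
    stop("duplicated sample_id in reference table for ", fraction, "/", analyte)
  keep <- spectra$sample_id %in% ref$sample_id
  if (!any(keep))
    stop("no sample_id overlap between spectra and reference chemistry for ",
         fraction, "/", analyte)
  n_drop <- sum(!keep)
  if (n_drop > 0)
    warning(sprintf("dropped %d sample(s) without %s/%s chemistry",
                    n_drop, fraction, analyte))
  ids <- spectra$sample_id[keep]
  y <- ref$value_mg_per_100g[match(ids, ref$sample_id)]
  structure(list(grid = spectra$grid,
                 X = spectra$absorbance[keep, , drop = FALSE],
                 y = y,
                 sample_ids = ids,
                 fraction = fraction,
                 analyte = analyte),
            class = "nir_dataset")
}

#' @export
print.nir_dataset <- function(x, ...) {
  cat(sprintf("NIR dataset: %d samples x %d wavelengths; target %s (%s fraction)\n",
              nrow(x$X), ncol(x$X), x$analyte, x$fraction))
  invisible(x)
}
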