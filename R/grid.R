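#' Wavelength grid
#'
#' A uniform wavelength axis shared by all spectra in an analysis. The
#' instrument convention emulated here records absorbance as log(1/R) from
#' 1000 to 2500 nm at 0.5 nm steps, giving 3001 points; that is the default.
#'
#' @param start_nm first wavelength in nm (> 0).
#' @param step_nm wavelength increment in nm (> 0).
#' @param n_points number of grid points (>= 2).
#' @return An object of class `wl_grid`.
#' @examples
#' g <- wl_grid()
#' length(wavelengths(g))  # 3001
#' @export
wl_grid <- function(start_nm = 1000, step_nm = 0.5, n_points = 3001) {
  stopifnot(is.numeric(start_nm), length(start_nm) == 1, start_nm > 0,
            is.numeric(step_nm), length(step_nm) == 1, step_nm > 0,
            is.numeric(n_points), length(n_points) == 1, n_points >= 2)
  structure(list(start_nm = as.numeric(start_nm),
                 step_nm = as.numeric(step_nm),
                 n_points = as.integer(n_points)),
            class = "wl_grid")
}

#' Wavelength vector of a grid
#'
#' @param grid a [wl_grid()].
#' @return Numeric vector of wavelengths in nm, length `grid$n_points`.
#' @export
wavelengths <- function(grid) {
  stopifnot(inherits(grid, "wl_grid"))
  grid$start_nm + grid$step_nm * (seq_len(grid$n_points) - 1)
}

#' @export
print.wl_grid <- function(x, ...) {
  cat(sprintf("Wavelength grid: %g-%g nm, step %g nm (%d points)\n",
              x$start_nm, x$start_nm + x$step_nm * (x$n_points - 1),
              x$step_nm, x$n_points))
  invisible(x)
}

# wavelengths rescaled to [-1, 1]; shared by detrend/EMSC polynomial terms
scaled_lambda <- function(grid) {
  lam <- wavelengths(grid)
  2 * (lam - lam[1]) / (lam[length(lam)] - lam[1]) - 1
}
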