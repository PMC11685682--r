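#' Wavelength grid
#'
#' A uniform wavelength sampling grid in nanometres. The default grid,
#' 380--780 nm in 1 nm steps (401 samples), is the grid every model in the
#' package is fitted and evaluated on.
#'
#' @param start_nm First wavelength (nm).
#' @param stop_nm Last wavelength (nm); must exceed `start_nm`.
#' @param step_nm Increment (nm); `(stop_nm - start_nm)` must be an integer
#'   multiple of it.
#' @return An object of class `wavelength_grid`.
#' @examples
#' g <- wavelength_grid()
#' length(wavelengths(g))  # 401
#' @export
wavelength_grid <- function(start_nm = 380, stop_nm = 780, step_nm = 1) {
  if (!is.finite(start_nm) || !is.finite(stop_nm) || !is.finite(step_nm))
    stop("wavelength grid parameters must be finite")
  if (start_nm >= stop_nm)
    stop("wavelength grid requires start_nm < stop_nm")
  if (step_nm <= 0)
    stop("wavelength grid requires step_nm > 0")
  n_steps <- (stop_nm - start_nm) / step_nm
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("(stop_nm - start_nm) must be an integer multiple of step_nm")
  structure(
    list(start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm),
    class = "wavelength_grid"
  )
}

#' @rdname wavelength_grid
#' @param grid A `wavelength_grid`.
#' @export
wavelengths <- function(grid) {
  seq(grid$start_nm, grid$stop_nm, by = grid$step_nm)
}

#' @rdname wavelength_grid
#' @export
grid_length <- function(grid) {
  as.integer(round((grid$stop_nm - grid$start_nm) / grid$step_nm)) + 1L
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g-%g nm, step %g nm (%d samples)\n",
              x$start_nm, x$stop_nm, x$step_nm, grid_length(x)))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-9))
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!same_grid(a, b))
    stop(sprintf("wavelength grid mismatch between %s", what))
  invisible(TRUE)
}
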