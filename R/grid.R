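#' Uniform wavelength grid
#'
#' A spectral grid is a uniformly spaced set of wavelengths in nm. The default
#' covers the second-overtone water region measured by handheld fruit
#' spectrometers, 800-1050 nm at a 3 nm step (84 points).
#'
#' @param start_nm first wavelength (nm).
#' @param stop_nm inclusive upper bound (nm); the last grid point is the
#'   largest `start_nm + k * step_nm` not exceeding it.
#' @param step_nm grid step (nm), must be positive.
#' @return An object of class `spectral_grid` with fields `start_nm`,
#'   `stop_nm`, `step_nm` and the vector of `wavelengths`.
#' @export
#' @examples
#' g <- spectral_grid()
#' length(wavelengths(g))  # 84
spectral_grid <- function(start_nm = 800, stop_nm = 1050, step_nm = 3) {
  if (!is.numeric(step_nm) || length(step_nm) != 1L || step_nm <= 0)
    stop("step_nm must be a positive number", call. = FALSE)
  if (stop_nm <= start_nm)
    stop("stop_nm must exceed start_nm", call. = FALSE)
  wl <- seq(start_nm, stop_nm, by = step_nm)
  structure(
    list(start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm,
         wavelengths = wl),
    class = "spectral_grid"
  )
}

#' @export
#' @rdname spectral_grid
wavelengths <- function(grid) {
  stopifnot(inherits(grid, "spectral_grid"))
  grid$wavelengths
}

# Tolerance for declaring a wavelength vector non-uniform (nm).
.grid_step_tol <- 1e-9

#' Build a grid from an explicit wavelength vector
#'
#' Validates that the wavelengths are strictly increasing and uniformly spaced
#' (any step deviating from the first by more than 1e-9 nm is rejected).
#'
#' @param wl numeric vector of wavelengths in nm.
#' @return A `spectral_grid`.
#' @export
grid_from_wavelengths <- function(wl) {
  if (length(wl) < 2L) stop("need at least two wavelengths", call. = FALSE)
  d <- diff(wl)
  if (any(d <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (any(abs(d - d[1L]) > .grid_step_tol))
    stop("wavelength grid is not uniform (step deviates by more than 1e-9 nm)",
         call. = FALSE)
  g <- spectral_grid(wl[1L], wl[length(wl)], d[1L])
  g$wavelengths <- as.numeric(wl)  # keep caller's exact values
  g
}

#' @export
length.spectral_grid <- function(x) length(x$wavelengths)

#' @export
print.spectral_grid <- function(x, ...) {
  cat(sprintf("<spectral_grid> %g-%g nm, step %g nm (%d points)\n",
              x$start_nm, x$stop_nm, x$step_nm, length(x$wavelengths)))
  invisible(x)
}

same_grid <- function(a, b) {
  length(a$wavelengths) == length(b$wavelengths) &&
    all(abs(a$wavelengths - b$wavelengths) <= .grid_step_tol)
}

#' Index of the grid point nearest a wavelength
#'
#' @param grid a `spectral_grid`.
#' @param wl_nm wavelength(s) in nm.
#' @return Integer index (vectorised); ties resolve to the lower wavelength.
#' @export
nearest_index <- function(grid, wl_nm) {
  vapply(wl_nm, function(w) {
    d <- abs(grid$wavelengths - w)
    which(d == min(d))[1L]
  }, integer(1L))
}
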