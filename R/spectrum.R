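#' Construct a reflectance spectrum
#'
#' A spectrum is a reflectance curve over a strictly increasing wavelength
#' grid for a single observation geometry. Reflectance is stored as a
#' unitless fraction (board-calibrated against a reference of reflectance 1).
#'
#' @param wavelength_nm numeric vector of wavelengths in nanometres,
#'   strictly increasing.
#' @param reflectance numeric vector of reflectance fractions, same length as
#'   `wavelength_nm`, finite and non-negative.
#' @return An object of class `"spectrum"`: a list with elements
#'   `wavelength_nm` and `reflectance`.
#' @examples
#' sp <- spectrum(400:900, rep(0.3, 501))
#' band_reflectance(sp, 550)
#' @export
spectrum <- function(wavelength_nm, reflectance) {
  wavelength_nm <- as.numeric(wavelength_nm)
  reflectance <- as.numeric(reflectance)
  if (length(wavelength_nm) != length(reflectance)) {
    opivi_error("wavelength and reflectance lengths differ.", "opivi_bad_spectrum")
  }
  if (length(wavelength_nm) < 2L) {
    opivi_error("a spectrum needs at least two grid points.", "opivi_bad_spectrum")
  }
  if (any(!is.finite(wavelength_nm)) || any(diff(wavelength_nm) <= 0)) {
    opivi_error("wavelengths must be finite and strictly increasing.",
                "opivi_bad_spectrum")
  }
  if (any(!is.finite(reflectance)) || any(reflectance < 0)) {
    opivi_error("reflectance must be finite and >= 0.", "opivi_bad_spectrum")
  }
  structure(list(wavelength_nm = wavelength_nm, reflectance = reflectance),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d bands, %.0f-%.0f nm, reflectance %.4f-%.4f\n",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm), min(x$reflectance), max(x$reflectance)))
  invisible(x)
}

is_uniform_grid <- function(w, tol = 1e-6) {
  d <- diff(w)
  max(abs(d - d[1])) <= tol * max(abs(d[1]), 1)
}

#' Savitzky-Golay smoothing
#'
#' Least-squares polynomial convolution smoothing on a uniform wavelength
#' grid. Interior points use the classical symmetric-window filter; the first
#' and last half-windows are smoothed by fitting the same polynomial order on
#' the leading/trailing full window and evaluating at the edge offsets, so a
#' polynomial of degree `poly_order` or less is reproduced exactly at every
#' grid point.
#'
#' @param spectrum_obj a [spectrum()].
#' @param window_length odd integer window width in grid points (default 15).
#' @param poly_order polynomial order (default 2, i.e. quadratic).
#' @return A smoothed [spectrum()] on the same grid.
#' @export
sg_smooth <- function(spectrum_obj, window_length = 15L, poly_order = 2L) {
  stopifnot(inherits(spectrum_obj, "spectrum"))
  w <- spectrum_obj$wavelength_nm
  y <- spectrum_obj$reflectance
  n <- length(y)
  window_length <- as.integer(window_length)
  poly_order <- as.integer(poly_order)
  if (window_length %% 2L != 1L || window_length <= poly_order) {
    opivi_error("window_length must be odd and greater than poly_order.",
                "opivi_bad_window")
  }
  if (window_length > n) {
    opivi_error(sprintf("window (%d) longer than spectrum (%d points).",
                        window_length, n), "opivi_bad_window")
  }
  if (!is_uniform_grid(w)) {
    opivi_error("Savitzky-Golay smoothing requires a uniform wavelength grid.",
                "opivi_nonuniform_grid")
  }
  S <- sg_matrix(n, window_length, poly_order)
  out <- as.numeric(S %*% y)
  # reflectance must remain >= 0; a polynomial filter can slightly undershoot
  out[out < 0] <- 0
  spectrum(w, out)
}

# Dense n x n smoothing operator: row i holds the weights producing the
# smoothed value at point i. Cached per (n, window, order) in the session.
sg_matrix <- local({
  cache <- new.env(parent = emptyenv())
  function(n, window_length, poly_order) {
    key <- paste(n, window_length, poly_order, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    h <- (window_length - 1L) %/% 2L
    X <- outer(seq(-h, h), 0:poly_order, `^`)
    # hat matrix of the within-window polynomial fit
    H <- X %*% solve(crossprod(X), t(X))
    S <- matrix(0, n, n)
    for (i in seq_len(n)) {
      if (i <= h) {
        S[i, 1:window_length] <- H[i, ]
      } else if (i > n - h) {
        S[i, (n - window_length + 1L):n] <- H[window_length - (n - i), ]
      } else {
        S[i, (i - h):(i + h)] <- H[h + 1L, ]
      }
    }
    cache[[key]] <- S
    S
  }
})

#' Point-band reflectance by linear interpolation
#'
#' Returns the reflectance at the requested wavelength(s), linearly
#' interpolated between the two bracketing grid points and exact at grid
#' nodes. Used to sample the R_lambda bands that the vegetation-index
#' formulas require.
#'
#' @param spectrum_obj a [spectrum()].
#' @param wavelength_nm wavelength(s) in nm, inside the spectrum's range.
#' @return numeric reflectance fraction(s).
#' @export
band_reflectance <- function(spectrum_obj, wavelength_nm) {
  stopifnot(inherits(spectrum_obj, "spectrum"))
  w <- spectrum_obj$wavelength_nm
  rng <- range(w)
  if (any(wavelength_nm < rng[1] | wavelength_nm > rng[2])) {
    opivi_error(sprintf(
      "wavelength outside spectrum range [%.1f, %.1f] nm", rng[1], rng[2]),
      "opivi_out_of_range")
  }
  stats::approx(w, spectrum_obj$reflectance, xout = wavelength_nm,
                method = "linear", ties = "ordered")$y
}

#' Resample a spectrum to a uniform grid
#'
#' Linear interpolation onto `grid` (default: the package working grid,
#' 1 nm from 350 to 1300 nm). The input must cover the target grid.
#'
#' @param spectrum_obj a [spectrum()].
#' @param grid numeric target grid (nm), strictly increasing.
#' @return A [spectrum()] on `grid`.
#' @export
resample_spectrum <- function(spectrum_obj, grid = working_grid()) {
  stopifnot(inherits(spectrum_obj, "spectrum"))
  w <- spectrum_obj$wavelength_nm
  if (min(grid) < min(w) || max(grid) > max(w)) {
    opivi_error(sprintf(
      "spectrum [%.0f, %.0f] nm does not cover the target grid [%.0f, %.0f] nm",
      min(w), max(w), min(grid), max(grid)), "opivi_out_of_range")
  }
  spectrum(grid, stats::approx(w, spectrum_obj$reflectance, xout = grid,
                               method = "linear", ties = "ordered")$y)
}

#' Default working wavelength grid
#'
#' The pigment/structure-sensitive 350-1300 nm window at 1 nm resolution;
#' the 1 nm step is needed because the index formulas distinguish
#' neighbouring bands such as R680 and R681.
#'
#' @param from,to,step grid bounds and step in nm.
#' @return numeric vector of wavelengths.
#' @export
working_grid <- function(from = 350, to = 1300, step = 1) {
  seq(from, to, by = step)
}
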