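#' UV-Vis absorbance spectrum
#'
#' @param wavelengths nm grid, increasing (default instrument range is
#'   200-800 nm at 1 nm).
#' @param absorbance dimensionless absorbance per wavelength.
#' @param path_length cuvette path in metres (default 0.01 m).
#' @return object of class `absorbance_spectrum`.
#' @export
absorbance_spectrum <- function(wavelengths, absorbance, path_length = 0.01) {
  if (length(wavelengths) != length(absorbance)) stop("grid/values length mismatch", call. = FALSE)
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be increasing", call. = FALSE)
  if (path_length <= 0) stop("path_length must be positive", call. = FALSE)
  structure(list(wavelengths = wavelengths, absorbance = absorbance,
                 path_length = path_length),
            class = "absorbance_spectrum")
}

#' CDOM absorption coefficient at 254 nm
#'
#' a254 = 2.303 x A254 / L (per metre), with A254 linearly interpolated when
#' 254 nm is not a grid point.
#'
#' @param spectrum an [absorbance_spectrum()].
#' @return a254 in 1/m.
#' @export
a254 <- function(spectrum) {
  stopifnot(inherits(spectrum, "absorbance_spectrum"))
  w <- spectrum$wavelengths
  if (254 < min(w) || 254 > max(w)) {
    stop("spectrum does not cover 254 nm", call. = FALSE)
  }
  A <- stats::approx(w, spectrum$absorbance, xout = 254)$y
  2.303 * A / spectrum$path_length
}

#' Excitation-emission matrix (EEM)
#'
#' Fluorescence intensity over an emission x excitation grid. Default grids
#' match the instrument settings emulated throughout the package:
#' excitation 200-450 nm step 2, emission 250-600 nm step 1.
#'
#' @param intensity matrix with `length(em_grid)` rows and
#'   `length(ex_grid)` columns.
#' @param ex_grid,em_grid increasing wavelength grids (nm).
#' @param sample_id label.
#' @return object of class `eem`.
#' @export
eem <- function(intensity, ex_grid = seq(200, 450, by = 2),
                em_grid = seq(250, 600, by = 1), sample_id = "sample") {
  if (any(diff(ex_grid) <= 0) || any(diff(em_grid) <= 0)) {
    stop("wavelength grids must be increasing", call. = FALSE)
  }
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != length(em_grid) || ncol(intensity) != length(ex_grid)) {
    stop("intensity must be em x ex shaped", call. = FALSE)
  }
  if (any(!is.finite(intensity))) stop("intensity must be finite", call. = FALSE)
  structure(list(intensity = intensity, ex_grid = ex_grid, em_grid = em_grid,
                 sample_id = sample_id),
            class = "eem")
}

#' Stack of EEMs on a shared grid
#'
#' @param eems list of [eem()] objects sharing identical grids.
#' @return object of class `eem_stack`: list with `data` (samples x em x ex
#'   array), `ex_grid`, `em_grid`, `sample_ids`.
#' @export
eem_stack <- function(eems) {
  if (length(eems) < 1) stop("need at least one EEM", call. = FALSE)
  ex <- eems[[1]]$ex_grid; em <- eems[[1]]$em_grid
  for (e in eems) {
    if (!identical(e$ex_grid, ex) || !identical(e$em_grid, em)) {
      stop("all EEMs in a stack must share identical grids", call. = FALSE)
    }
  }
  arr <- array(0, dim = c(length(eems), length(em), length(ex)))
  for (i in seq_along(eems)) arr[i, , ] <- eems[[i]]$intensity
  structure(list(data = arr, ex_grid = ex, em_grid = em,
                 sample_ids = vapply(eems, function(e) e$sample_id, "")),
            class = "eem_stack")
}

#' Absorbance-based inner-filter correction
#'
#' Multiplies every EEM cell by 10^((A_ex + A_em) / 2), the standard
#' primary+secondary inner-filter factor, using absorbance linearly
#' interpolated from the supplied spectrum. Off the default path: the
#' emulated protocol dilutes samples to A254 < 0.1 instead of correcting.
#'
#' @param x an [eem()].
#' @param spectrum an [absorbance_spectrum()] covering both grids.
#' @return the corrected [eem()].
#' @export
correct_inner_filter <- function(x, spectrum) {
  stopifnot(inherits(x, "eem"), inherits(spectrum, "absorbance_spectrum"))
  w <- spectrum$wavelengths
  need <- range(c(x$ex_grid, x$em_grid))
  if (need[1] < min(w) || need[2] > max(w)) {
    stop("absorbance spectrum does not cover the EEM grids", call. = FALSE)
  }
  a_ex <- stats::approx(w, spectrum$absorbance, xout = x$ex_grid)$y
  a_em <- stats::approx(w, spectrum$absorbance, xout = x$em_grid)$y
  x$intensity <- x$intensity * 10^(outer(a_em, a_ex, `+`) / 2)
  x
}

rayleigh_mask <- function(ex_grid, em_grid, width = 20, second_order = TRUE,
                          second_width = 20) {
  em <- matrix(em_grid, length(em_grid), length(ex_grid))
  ex <- matrix(ex_grid, length(em_grid), length(ex_grid), byrow = TRUE)
  mask <- (em - ex) < width
  if (second_order) mask <- mask | abs(em - 2 * ex) <= second_width
  mask
}

#' Zero the Rayleigh scatter regions of an EEM
#'
#' Sets every cell with (emission - excitation) < `rayleigh_width` nm to
#' zero (primary Rayleigh band plus everything below the diagonal). The
#' second-order band (emission about twice the excitation) is also zeroed
#' within +/- `second_width` nm when `second_order = TRUE` (default). The
#' operation is idempotent and touches no other cell.
#'
#' @param x an [eem()] or [eem_stack()].
#' @param rayleigh_width primary cut width in nm (default 20).
#' @param second_order also zero the second-order band (default TRUE).
#' @param second_width half-width of the second-order cut in nm.
#' @return object of the same class with masked intensities.
#' @export
preprocess_eem <- function(x, rayleigh_width = 20, second_order = TRUE,
                           second_width = 20) {
  mask <- rayleigh_mask(x$ex_grid, x$em_grid, rayleigh_width, second_order,
                        second_width)
  if (inherits(x, "eem")) {
    x$intensity[mask] <- 0
  } else if (inherits(x, "eem_stack")) {
    for (i in seq_len(dim(x$data)[1])) {
      slab <- x$data[i, , ]
      slab[mask] <- 0
      x$data[i, , ] <- slab
    }
  } else stop("x must be an eem or eem_stack", call. = FALSE)
  x
}
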