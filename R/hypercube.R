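#' Hyperspectral data cube
#'
#' A hypercube is a three-dimensional array with two spatial axes
#' (rows, columns) and one spectral axis, together with the wavelength
#' (nm) of every band. Wavelengths are carried explicitly per band —
#' never as an implied index — so that band subsets and nearest-band
#' matching are unambiguous.
#'
#' @param data numeric array, `rows x cols x bands`. Raw camera counts or
#'   reflectance; invalid pixels may be `NA`.
#' @param wavelengths numeric vector of band-centre wavelengths in nm,
#'   strictly increasing, with one entry per band.
#' @param reflectance logical; `TRUE` once the cube has been calibrated to
#'   relative reflectance (see [calibrate()]).
#'
#' @return An object of class `"hypercube"`.
#' @examples
#' cube <- hypercube(array(runif(4 * 3 * 5), c(4, 3, 5)), seq(500, 900, length.out = 5))
#' dim(cube$data)
#' @export
hypercube <- function(data, wavelengths, reflectance = FALSE) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("'data' must be a 3-D array (rows x cols x bands)", call. = FALSE)
  }
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3L]) {
    stop("length of 'wavelengths' must equal the number of bands", call. = FALSE)
  }
  if (length(wavelengths) >= 2L && any(diff(wavelengths) <= 0)) {
    stop("'wavelengths' must be strictly increasing", call. = FALSE)
  }
  structure(
    list(data = data, wavelengths = wavelengths, reflectance = isTRUE(reflectance)),
    class = "hypercube"
  )
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<hypercube> %d x %d pixels, %d bands (%.1f-%.1f nm), %s\n",
    d[1L], d[2L], d[3L], min(x$wavelengths), max(x$wavelengths),
    if (x$reflectance) "reflectance" else "counts"
  ))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

.check_same_grid <- function(a, b, what) {
  if (!identical(dim(a$data), dim(b$data))) {
    stop(sprintf("shape mismatch between raw and %s cube", what), call. = FALSE)
  }
  if (!isTRUE(all.equal(a$wavelengths, b$wavelengths))) {
    stop(sprintf("wavelength grid mismatch between raw and %s cube", what), call. = FALSE)
  }
}

#' Reflectance calibration with white and dark references
#'
#' Converts raw camera counts to relative reflectance per pixel and band:
#' `R = (raw - dark) / (white - dark)`. The white reference is treated as
#' 100% reflectance and the dark reference as 0%. Pixels/bands where
#' `white == dark` carry no radiometric information and are marked
#' invalid (`NA`); downstream ROI means and chemical maps exclude them.
#'
#' @param raw,white,dark [hypercube()] objects on identical grids.
#' @return A reflectance-flagged [hypercube()].
#' @examples
#' wl <- c(500, 600)
#' w <- hypercube(array(100, c(2, 2, 2)), wl)
#' d <- hypercube(array(10, c(2, 2, 2)), wl)
#' r <- hypercube(array(55, c(2, 2, 2)), wl)
#' calibrate(r, w, d)$data[1, 1, ]  # 0.5 0.5
#' @export
calibrate <- function(raw, white, dark) {
  stopifnot(inherits(raw, "hypercube"), inherits(white, "hypercube"),
            inherits(dark, "hypercube"))
  .check_same_grid(raw, white, "white")
  .check_same_grid(raw, dark, "dark")
  denom <- white$data - dark$data
  out <- (raw$data - dark$data) / denom
  out[denom == 0] <- NA_real_
  hypercube(out, raw$wavelengths, reflectance = TRUE)
}

#' Mean spectrum over a region of interest
#'
#' Arithmetic mean, band by band, over the pixels flagged `TRUE` in the
#' mask. Invalid (`NA`) pixel/band values are excluded from the mean of
#' their band.
#'
#' @param cube a [hypercube()].
#' @param mask logical matrix with the cube's spatial dimensions; at least
#'   one `TRUE` pixel.
#' @return Numeric vector of length `bands`, named by wavelength.
#' @export
mean_roi_spectrum <- function(cube, mask) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  if (!is.logical(mask) || !identical(dim(mask), d[1:2])) {
    stop("'mask' must be a logical matrix matching the cube's spatial dimensions",
         call. = FALSE)
  }
  if (!any(mask)) stop("ROI mask has no TRUE pixel", call. = FALSE)
  px <- matrix(cube$data, nrow = d[1L] * d[2L], ncol = d[3L])[as.vector(mask), , drop = FALSE]
  out <- colMeans(px, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  names(out) <- format(cube$wavelengths, trim = TRUE)
  out
}

#' Restrict to a wavelength interval
#'
#' Keeps bands whose wavelength lies in the closed interval
#' `[low_nm, high_nm]`; band order is preserved. Applies to cubes and to
#' spectra tables.
#'
#' @param x a [hypercube()] or [spectra_table()].
#' @param low_nm,high_nm interval endpoints in nm, `low_nm < high_nm`.
#' @return Object of the same class with the surviving bands.
#' @export
trim_bands <- function(x, low_nm, high_nm) UseMethod("trim_bands")

.trim_idx <- function(wavelengths, low_nm, high_nm) {
  if (!is.numeric(low_nm) || !is.numeric(high_nm) || low_nm >= high_nm) {
    stop("'low_nm' must be smaller than 'high_nm'", call. = FALSE)
  }
  keep <- which(wavelengths >= low_nm & wavelengths <= high_nm)
  if (length(keep) == 0L) {
    stop(sprintf("no band lies in [%g, %g] nm", low_nm, high_nm), call. = FALSE)
  }
  keep
}

#' @export
trim_bands.hypercube <- function(x, low_nm, high_nm) {
  keep <- .trim_idx(x$wavelengths, low_nm, high_nm)
  hypercube(x$data[, , keep, drop = FALSE], x$wavelengths[keep],
            reflectance = x$reflectance)
}
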