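#' Hypercube: a hyperspectral image cube
#'
#' A hypercube is a 3-D array with two spatial dimensions and one spectral
#' dimension, indexed `[row, col, band]`, together with an ascending
#' wavelength vector (nm) of length equal to the band dimension. `kind`
#' records whether the values are raw sensor counts (`"raw"`) or relative
#' reflectance (`"reflectance"`).
#'
#' @param data numeric 3-D array `[rows x cols x bands]`.
#' @param wavelengths numeric vector of band-center wavelengths in nm,
#'   strictly increasing, length `dim(data)[3]`.
#' @param kind `"raw"` or `"reflectance"`.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths, kind = c("raw", "reflectance")) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array [rows x cols x bands]")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3L])
    stop(sprintf("wavelength length (%d) does not match band dimension (%d)",
                 length(wavelengths), dim(data)[3L]))
  if (any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be strictly increasing")
  if (kind == "reflectance" && !all(is.finite(data)))
    stop("reflectance cube contains non-finite values")
  structure(list(data = data, wavelengths = wavelengths, kind = kind),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands (%.0f-%.0f nm), kind = %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths), x$kind))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' White and dark reference frames
#'
#' Container for the white (high-reflectance Teflon panel) and dark
#' (shutter-closed) raw-intensity reference cubes used for reflectance
#' calibration. Both must share the sample cube's shape.
#'
#' @param white,dark numeric 3-D arrays of raw counts, identical shapes.
#' @return An object of class `reference_images`.
#' @export
reference_images <- function(white, dark) {
  if (!identical(dim(white), dim(dark)))
    stop("white and dark reference shapes differ")
  if (length(dim(white)) != 3L)
    stop("reference images must be 3-D arrays [rows x cols x bands]")
  structure(list(white = white, dark = dark), class = "reference_images")
}

#' Calibrate raw counts to relative reflectance
#'
#' Converts a raw-intensity cube to relative reflectance element-wise:
#' \deqn{R = (R_0 - D) / (W - D)}
#' where \eqn{R_0} is the raw cube and \eqn{W}, \eqn{D} the white and dark
#' reference frames. Pixels/bands where \eqn{W \le D} cannot be calibrated;
#' they are flagged `NA` (never clipped) and their count is reported via
#' message and the `n_invalid` attribute. Reflectance above 1 (specular
#' highlights) is retained.
#'
#' @param raw a `hypercube` with `kind = "raw"`.
#' @param refs a [reference_images] object with the same shape as `raw`.
#' @return A `hypercube` with `kind = "reflectance"`; attribute `n_invalid`
#'   holds the flagged element count.
#' @export
calibrate_reflectance <- function(raw, refs) {
  stopifnot(inherits(raw, "hypercube"), inherits(refs, "reference_images"))
  if (raw$kind != "raw") stop("`raw` must be a raw-intensity cube")
  if (!identical(dim(raw$data), dim(refs$white)))
    stop("shape mismatch between raw cube and reference images")
  denom <- refs$white - refs$dark
  bad <- denom <= 0
  n_bad <- sum(bad)
  if (n_bad == length(denom))
    stop("all pixels invalid: white <= dark everywhere")
  r <- (raw$data - refs$dark) / denom
  if (n_bad > 0) {
    r[bad] <- NA_real_
    message(sprintf("calibrate_reflectance: %d invalid element(s) flagged (white <= dark)", n_bad))
  }
  out <- structure(list(data = r, wavelengths = raw$wavelengths,
                        kind = "reflectance"), class = "hypercube")
  attr(out, "n_invalid") <- n_bad
  out
}

#' Restrict a hypercube to a wavelength window
#'
#' Keeps bands with `lo_nm <= wavelength <= hi_nm` (both ends inclusive),
#' e.g. the NIR subset 700-1000 nm used to drop uninformative visible bands.
#'
#' @param cube a `hypercube`.
#' @param lo_nm,hi_nm window limits in nm, `lo_nm < hi_nm`.
#' @return The band-restricted `hypercube`.
#' @export
subset_bands <- function(cube, lo_nm, hi_nm) {
  stopifnot(inherits(cube, "hypercube"))
  if (!(lo_nm < hi_nm)) stop("`lo_nm` must be < `hi_nm`")
  keep <- cube$wavelengths >= lo_nm & cube$wavelengths <= hi_nm
  if (!any(keep))
    stop(sprintf("no bands in [%g, %g] nm (cube spans %g-%g nm)",
                 lo_nm, hi_nm, min(cube$wavelengths), max(cube$wavelengths)))
  structure(list(data = cube$data[, , keep, drop = FALSE],
                 wavelengths = cube$wavelengths[keep], kind = cube$kind),
            class = "hypercube")
}

# nearest band index; errors if target is farther than half the band spacing
.nearest_band <- function(wavelengths, nm) {
  i <- which.min(abs(wavelengths - nm))
  spacing <- if (length(wavelengths) > 1) stats::median(diff(wavelengths)) else Inf
  if (abs(wavelengths[i] - nm) > spacing / 2 + 1e-9)
    stop(sprintf("wavelength %g nm outside cube range (nearest band %g nm)",
                 nm, wavelengths[i]))
  i
}
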