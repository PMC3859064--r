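#' Band-difference image
#'
#' Subtracts a low-reflectance band image from a high-reflectance band image,
#' the standard first step for separating tissue (bright in the red/NIR) from
#' a dark background. Wavelengths are matched to the nearest band; a target
#' farther than half the band spacing from any band is an error.
#'
#' @param cube a [hypercube].
#' @param high_band_nm,low_band_nm wavelengths (nm) of the bright and dark
#'   bands to difference.
#' @return A numeric matrix `[rows x cols]`.
#' @export
band_difference <- function(cube, high_band_nm, low_band_nm) {
  stopifnot(inherits(cube, "hypercube"))
  hi <- .nearest_band(cube$wavelengths, high_band_nm)
  lo <- .nearest_band(cube$wavelengths, low_band_nm)
  cube$data[, , hi] - cube$data[, , lo]
}

#' Threshold a difference image into a foreground mask
#'
#' Foreground is strictly `diff > threshold`; ties go to background so the
#' mask is deterministic. An empty mask is allowed (reported via message).
#'
#' @param diff numeric matrix, finite.
#' @param threshold scalar reflectance-difference threshold.
#' @return A `mask` object: logical matrix `data` plus `n_foreground`.
#' @export
threshold_mask <- function(diff, threshold) {
  if (!all(is.finite(diff))) stop("difference image contains non-finite values")
  m <- diff > threshold
  n <- sum(m)
  if (n == 0) message("threshold_mask: empty mask (threshold above maximum)")
  structure(list(data = m, n_foreground = n), class = "mask")
}

#' @export
print.mask <- function(x, ...) {
  cat(sprintf("<mask> %d x %d, %d foreground pixel(s)\n",
              nrow(x$data), ncol(x$data), x$n_foreground))
  invisible(x)
}

#' Automatic threshold by Otsu's criterion
#'
#' Chooses the threshold maximizing the between-class variance
#' \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2} over all splits between
#' consecutive sorted unique values, returning the midpoint of the best
#' boundary pair. Exact (no histogram binning).
#'
#' @param diff numeric matrix with at least two distinct values.
#' @return Scalar threshold.
#' @export
auto_threshold <- function(diff) {
  v <- sort(as.vector(diff))
  if (!all(is.finite(v))) stop("difference image contains non-finite values")
  u <- unique(v)
  if (length(u) < 2) stop("cannot threshold a constant image")
  n <- length(v)
  cs <- cumsum(v); css <- sum(v)
  # candidate splits after each of the first n-1 sorted values, but only at
  # boundaries between distinct values
  idx <- which(diff(v) > 0)
  w0 <- idx / n
  mu0 <- cs[idx] / idx
  mu1 <- (css - cs[idx]) / (n - idx)
  bcv <- w0 * (1 - w0) * (mu0 - mu1)^2
  k <- idx[which.max(bcv)]
  (v[k] + v[k + 1]) / 2
}

#' Keep only the largest connected foreground component
#'
#' Optional morphological clean-up (off by default in the pipeline): labels
#' 4/8-connected components and keeps the largest.
#'
#' @param mask a `mask`.
#' @return A `mask` restricted to the largest component.
#' @export
largest_component <- function(mask) {
  stopifnot(inherits(mask, "mask"))
  if (mask$n_foreground == 0) return(mask)
  lab <- EBImage::bwlabel(mask$data * 1)
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  threshold_mask((lab == keep) * 1, 0.5)
}

#' Mean spectrum over masked pixels
#'
#' Per-band arithmetic mean over foreground pixels — produces the one
#' averaged spectrum per sample that feeds the regression model.
#'
#' @param cube a [hypercube].
#' @param mask a `mask` with the cube's spatial shape and at least one
#'   foreground pixel.
#' @return Numeric vector of length `n_bands`.
#' @export
mean_masked_spectrum <- function(cube, mask) {
  stopifnot(inherits(cube, "hypercube"), inherits(mask, "mask"))
  d <- dim(cube$data)
  if (!identical(dim(mask$data), d[1:2]))
    stop("mask shape does not match cube spatial shape")
  if (mask$n_foreground < 1) stop("empty mask: no foreground pixels to average")
  m <- matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
  colMeans(m[as.vector(mask$data), , drop = FALSE])
}

#' Extract the foreground pixel-spectra matrix
#'
#' @param cube a [hypercube].
#' @param mask a `mask` matching the cube's spatial shape.
#' @return Matrix `[n_foreground x n_bands]`, rows in column-major pixel order.
#' @export
masked_spectra <- function(cube, mask) {
  stopifnot(inherits(cube, "hypercube"), inherits(mask, "mask"))
  d <- dim(cube$data)
  if (!identical(dim(mask$data), d[1:2]))
    stop("mask shape does not match cube spatial shape")
  m <- matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
  m[as.vector(mask$data), , drop = FALSE]
}

#' Write a mask as a PNG (0/255) image
#'
#' @param mask a `mask`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "mask"))
  png::writePNG(mask$data * 1, path)
  invisible(path)
}
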