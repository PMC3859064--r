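#' Pixel-wise chemical image from a PLS regression model
#'
#' Applies the fitted regression to every foreground pixel's spectrum:
#' \deqn{map_{xy} = \sum_i \beta_i H_{xy,i} + c}
#' where \eqn{H_{xy}} is the pixel spectrum after the model's stored
#' preprocessing (the same transform the calibration spectra received) and
#' \eqn{c} is the intercept from mean-centering. Background pixels carry
#' `NA`, never 0 — 0 is a legal moisture percentage.
#'
#' @param cube reflectance [hypercube], band-subset to the model wavelengths.
#' @param model a `plsr_model` carrying `wavelengths` and (optionally) a
#'   `preprocess_state`.
#' @param mask a `mask` matching the cube's spatial shape, non-empty.
#' @return A `chemical_image`: `values` matrix (moisture %, NA background),
#'   `mask`, `n_lv`, `method`.
#' @export
pls_image <- function(cube, model, mask) {
  stopifnot(inherits(cube, "hypercube"), inherits(model, "plsr_model"),
            inherits(mask, "mask"))
  if (cube$kind != "reflectance") stop("cube must be reflectance-calibrated")
  if (!is.null(model$wavelengths)) {
    if (length(model$wavelengths) != length(cube$wavelengths) ||
        max(abs(model$wavelengths - cube$wavelengths)) > 1e-6)
      stop("cube wavelengths do not match model wavelengths")
  } else if (length(model$beta) != length(cube$wavelengths)) {
    stop("cube band count does not match model")
  }
  if (mask$n_foreground < 1) stop("empty mask")
  px <- masked_spectra(cube, mask)
  if (!is.null(model$preprocess_state))
    px <- preprocess_apply(model$preprocess_state, px)
  vals <- predict(model, px)
  img <- matrix(NA_real_, nrow(mask$data), ncol(mask$data))
  img[mask$data] <- vals
  structure(list(values = img, mask = mask, n_lv = model$n_lv,
                 method = if (!is.null(model$preprocess_state))
                   model$preprocess_state$method else "raw"),
            class = "chemical_image")
}

#' @export
print.chemical_image <- function(x, ...) {
  v <- x$values[x$mask$data]
  cat(sprintf("<chemical_image> %d x %d, %d foreground px, %.1f-%.1f %% (mean %.1f)\n",
              nrow(x$values), ncol(x$values), x$mask$n_foreground,
              min(v), max(v), mean(v)))
  invisible(x)
}

#' Render a chemical image to an RGB array / PNG
#'
#' Linear color mapping of foreground values clipped (not rescaled) to
#' `[lo, hi]` through a blue-to-red ramp; background rendered neutral gray.
#' A vertical color scale bar is appended on the right. Using one shared
#' `[lo, hi]` across images makes maps of different samples comparable.
#'
#' @param img a `chemical_image`.
#' @param lo,hi display range (moisture %), `lo < hi`.
#' @param path optional PNG output path.
#' @param n_colors ramp resolution.
#' @return RGB array `[rows x cols x 3]` (values in \[0, 1\]), invisibly if
#'   `path` is given.
#' @export
render_map <- function(img, lo = 60, hi = 75, path = NULL, n_colors = 256L) {
  stopifnot(inherits(img, "chemical_image"))
  if (lo >= hi) stop("`lo` must be < `hi`")
  ramp <- grDevices::colorRampPalette(
    c("darkblue", "blue", "cyan", "greenyellow", "yellow", "orange", "red"))(n_colors)
  rgbm <- grDevices::col2rgb(ramp) / 255
  v <- img$values
  idx <- pmin(pmax(round((v - lo) / (hi - lo) * (n_colors - 1)) + 1, 1), n_colors)
  nr <- nrow(v); nc <- ncol(v)
  out <- array(0.5, dim = c(nr, nc, 3))          # neutral background
  fg <- which(img$mask$data)
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[fg] <- rgbm[ch, idx[fg]]
    out[, , ch] <- plane
  }
  # append color bar (top = hi) with a 2-px gap
  barw <- max(4L, nc %/% 16L)
  bar_idx <- rev(round(seq(1, n_colors, length.out = nr)))
  bar <- array(1, dim = c(nr, barw + 2L, 3))
  for (ch in 1:3) bar[, 3:(barw + 2L), ch] <- matrix(rgbm[ch, bar_idx], nr, barw)
  out <- abind2(out, bar)
  if (!is.null(path)) {
    png::writePNG(out, path)
    return(invisible(out))
  }
  out
}

# bind two [r x c x 3] arrays along columns (avoids an abind dependency)
abind2 <- function(a, b) {
  out <- array(0, dim = c(dim(a)[1], dim(a)[2] + dim(b)[2], 3))
  out[, seq_len(dim(a)[2]), ] <- a
  out[, dim(a)[2] + seq_len(dim(b)[2]), ] <- b
  out
}

#' Center versus periphery statistics of a chemical image
#'
#' Splits the foreground by the Euclidean distance transform of the mask:
#' pixels with distance-to-boundary at or above the foreground median are
#' "center" (the inner ~50% of the area), the rest "periphery". Reports the
#' mean and standard deviation of the mapped values per region — the spatial
#' contrast the moisture maps are meant to reveal (interior wetter than rim).
#'
#' @param img a `chemical_image`.
#' @param center_area_frac fraction of foreground area treated as center.
#' @return `data.frame` with region, n_pixels, mean, sd.
#' @export
region_stats <- function(img, center_area_frac = 0.5) {
  stopifnot(inherits(img, "chemical_image"))
  d <- EBImage::distmap(img$mask$data * 1)
  dv <- d[img$mask$data]
  cut <- stats::quantile(dv, 1 - center_area_frac, names = FALSE)
  center <- img$mask$data & (d >= cut) & d > min(dv)
  if (all(dv == dv[1])) center <- img$mask$data & FALSE  # degenerate: no interior
  periph <- img$mask$data & !center
  if (sum(center) == 0 || sum(periph) == 0)
    stop("degenerate mask: center or periphery region is empty")
  st <- function(w) {
    v <- img$values[w]
    c(n = sum(w), mean = mean(v), sd = stats::sd(v))
  }
  a <- st(center); b <- st(periph)
  data.frame(region = c("center", "periphery"),
             n_pixels = c(a["n"], b["n"]),
             mean = c(a["mean"], b["mean"]),
             sd = c(a["sd"], b["sd"]), row.names = NULL)
}

#' Export a chemical image as a single-band ENVI file
#'
#' Background pixels are written as the no-data value -9999.
#'
#' @param img a `chemical_image`.
#' @param header_path output `.hdr` path.
#' @param wavelength nominal wavelength tag for the band (default 0).
#' @return `header_path`, invisibly.
#' @export
write_chemical_image <- function(img, header_path, wavelength = 0) {
  v <- img$values
  v[!img$mask$data] <- -9999
  cube <- hypercube(array(v, dim = c(nrow(v), ncol(v), 1)), wavelength,
                    kind = "raw")
  write_envi(cube, header_path, interleave = "bsq", dtype = 5L)
}
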