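#' Spectral pre-treatments
#'
#' The pipeline supports the eight treatments commonly compared in NIR
#' chemometrics: raw passthrough, mean/max/range normalization, standard
#' normal variate (SNV), multiplicative scatter correction (MSC), and
#' Savitzky-Golay first and second derivatives. Each operates row-wise on a
#' samples-x-bands matrix; the response is never transformed.
#'
#' @name preprocess
NULL

#' @export
PREPROCESS_METHODS <- c("raw", "mean_norm", "max_norm", "range_norm",
                        "snv", "msc", "sg1", "sg2")

#' Standard normal variate transform
#'
#' Centers and scales each spectrum (row) to mean 0 and unit sample
#' (n-1 denominator) standard deviation, removing additive baseline and
#' multiplicative scatter.
#'
#' @param X numeric matrix `[n_samples x n_bands]`.
#' @return Transformed matrix.
#' @export
snv <- function(X) {
  X <- .as_spectra_matrix(X)
  mu <- rowMeans(X)
  s <- apply(X, 1, stats::sd)
  bad <- which(s == 0 | !is.finite(s))
  if (length(bad))
    stop("SNV undefined for constant spectrum in row(s): ",
         paste(bad, collapse = ", "))
  (X - mu) / s
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum, `x ~ a * ref + b`, and
#' returns `(x - b) / a`. When no reference is given it is the column-mean
#' spectrum of `X` (the calibration set); the reference used is returned so
#' new spectra can be corrected against the calibration reference.
#'
#' @param X numeric matrix `[n_samples x n_bands]`, `n_bands >= 2`.
#' @param reference reference spectrum, or `NULL` to use `colMeans(X)`.
#' @return List with `X` (corrected matrix), `reference`, and `flagged`
#'   (rows with non-positive fitted slope, corrected but suspect).
#' @export
msc <- function(X, reference = NULL) {
  X <- .as_spectra_matrix(X)
  if (ncol(X) < 2) stop("MSC needs at least 2 bands")
  if (is.null(reference)) reference <- colMeans(X)
  if (length(reference) != ncol(X))
    stop("reference length does not match band count")
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  if (denom == 0) stop("MSC reference has zero variance")
  a <- as.vector(X %*% rc) / denom                 # per-row LS slope
  b <- rowMeans(X) - a * mean(reference)
  flagged <- which(a <= 0)
  if (length(flagged))
    warning("MSC fitted non-positive slope for row(s): ",
            paste(flagged, collapse = ", "))
  list(X = (X - b) / a, reference = reference, flagged = flagged)
}

#' Savitzky-Golay filtering and differentiation
#'
#' Sliding-window local polynomial least squares applied per spectrum.
#' Derivatives are scaled by the band spacing so coefficients are per nm
#' (`deriv = 1`) or per nm^2 (`deriv = 2`). The first and last half-windows
#' are handled by evaluating the terminal-window polynomial fit at each edge
#' point, so output length equals input length.
#'
#' @param X numeric matrix `[n_samples x n_bands]` (or a vector, treated as
#'   one spectrum).
#' @param window odd window length in points, `> polyorder`.
#' @param polyorder polynomial degree.
#' @param deriv derivative order: 0 (smoothing), 1, or 2.
#' @param delta spacing between bands in nm (default 1).
#' @return Matrix of the same shape.
#' @export
savgol <- function(X, window = 11L, polyorder = 2L, deriv = 0L, delta = 1) {
  vec <- is.vector(X)
  X <- .as_spectra_matrix(X)
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  deriv <- as.integer(deriv)
  if (window %% 2 == 0) stop("`window` must be odd")
  if (window <= polyorder) stop("`window` must exceed `polyorder`")
  if (deriv > polyorder) stop("`deriv` must not exceed `polyorder`")
  p <- ncol(X)
  if (p < window) stop(sprintf("window (%d) larger than band count (%d)", window, p))
  op <- .savgol_operator(p, window, polyorder, deriv) / delta^deriv
  out <- X %*% t(op)
  if (vec) out[1, ] else out
}

# n x n linear operator: interior rows are the central SG filter, edge rows
# evaluate the first/last full-window polynomial fit at the edge offsets
.savgol_operator <- function(n, window, polyorder, deriv) {
  h <- (window - 1L) %/% 2L
  # derivative row for evaluation offset e, given window offsets off
  row_for <- function(off, e) {
    A <- outer(off, 0:polyorder, `^`)
    pinv <- solve(crossprod(A), t(A))         # (p+1) x window
    # d-th derivative of sum_k c_k x^k at x = e
    k <- 0:polyorder
    co <- ifelse(k >= deriv, factorial(k) / factorial(pmax(k - deriv, 0)), 0)
    ev <- co * ifelse(k - deriv >= 0, e^pmax(k - deriv, 0), 0)
    as.vector(ev %*% pinv)
  }
  op <- matrix(0, n, n)
  central <- row_for(-h:h, 0)
  for (i in seq_len(n)) {
    s <- min(max(i - h, 1L), n - window + 1L)
    cols <- s:(s + window - 1L)
    if (i - h >= 1 && i + h <= n) {
      op[i, cols] <- central
    } else {
      op[i, cols] <- row_for(cols - i, 0)
    }
  }
  op
}

#' Row-wise spectrum normalization
#'
#' `mean`: divide by the row mean (row mean becomes 1); `max`: divide by the
#' row maximum (row max becomes 1); `range`: subtract the row minimum and
#' divide by the range (row spans \[0, 1\]).
#'
#' @param X numeric matrix `[n_samples x n_bands]`.
#' @param mode `"mean"`, `"max"`, or `"range"`.
#' @return Normalized matrix.
#' @export
normalize_spectra <- function(X, mode = c("mean", "max", "range")) {
  mode <- match.arg(mode)
  X <- .as_spectra_matrix(X)
  switch(mode,
    mean = {
      mu <- rowMeans(X)
      bad <- which(mu == 0)
      if (length(bad)) stop("zero row mean in row(s): ", paste(bad, collapse = ", "))
      X / mu
    },
    max = {
      mx <- apply(X, 1, max)
      bad <- which(mx == 0)
      if (length(bad)) stop("zero row maximum in row(s): ", paste(bad, collapse = ", "))
      X / mx
    },
    range = {
      mx <- apply(X, 1, max); mn <- apply(X, 1, min)
      bad <- which(mx <= mn)
      if (length(bad)) stop("zero row range in row(s): ", paste(bad, collapse = ", "))
      (X - mn) / (mx - mn)
    })
}

#' Fit a preprocessing state on calibration spectra
#'
#' Captures everything needed to apply the same transform to validation,
#' test, or pixel spectra: the method tag, the MSC reference (column-mean of
#' the calibration spectra only, so no test-set leakage), and the
#' Savitzky-Golay settings. Returns the state and the transformed
#' calibration matrix.
#'
#' @param X calibration matrix `[n_samples x n_bands]`.
#' @param method one of `PREPROCESS_METHODS`.
#' @param wavelengths band wavelengths (nm), used for the derivative spacing.
#' @param sg_window,sg_polyorder Savitzky-Golay window (odd) and degree.
#' @return List with `state` (class `preprocess_state`) and `X` (transformed).
#' @export
preprocess_fit <- function(X, method, wavelengths = NULL,
                           sg_window = 11L, sg_polyorder = 2L) {
  method <- match.arg(method, PREPROCESS_METHODS)
  X <- .as_spectra_matrix(X)
  delta <- if (!is.null(wavelengths) && length(wavelengths) > 1)
    stats::median(diff(wavelengths)) else 1
  state <- structure(list(method = method, msc_reference = NULL,
                          sg_window = as.integer(sg_window),
                          sg_polyorder = as.integer(sg_polyorder),
                          sg_deriv = switch(method, sg1 = 1L, sg2 = 2L, 0L),
                          delta = delta, n_bands = ncol(X)),
                     class = "preprocess_state")
  if (method == "msc") {
    fit <- msc(X)
    state$msc_reference <- fit$reference
    return(list(state = state, X = fit$X))
  }
  list(state = state, X = preprocess_apply(state, X))
}

#' Apply a fitted preprocessing state to new spectra
#'
#' @param state a `preprocess_state` from [preprocess_fit].
#' @param X matrix `[n x n_bands]` with the state's band count.
#' @return Transformed matrix.
#' @export
preprocess_apply <- function(state, X) {
  stopifnot(inherits(state, "preprocess_state"))
  X <- .as_spectra_matrix(X)
  if (ncol(X) != state$n_bands)
    stop(sprintf("band count (%d) does not match preprocessing state (%d)",
                 ncol(X), state$n_bands))
  switch(state$method,
    raw        = X,
    mean_norm  = normalize_spectra(X, "mean"),
    max_norm   = normalize_spectra(X, "max"),
    range_norm = normalize_spectra(X, "range"),
    snv        = snv(X),
    msc        = msc(X, reference = state$msc_reference)$X,
    sg1        = savgol(X, state$sg_window, state$sg_polyorder, 1L, state$delta),
    sg2        = savgol(X, state$sg_window, state$sg_polyorder, 2L, state$delta))
}

.as_spectra_matrix <- function(X) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  if (!is.matrix(X)) X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("spectra contain non-finite values")
  X
}
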