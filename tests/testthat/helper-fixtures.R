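# shared fixtures; heavy objects are built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

# the default synthetic study (72 samples at the study's conditions),
# plus calibrated mean spectra and masks — shared by the acceptance tests
default_study <- function(seed = 101L) {
  key <- paste0("study_", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cfg <- synth_config(seed = seed)
  ds <- generate_dataset(cfg)
  wl <- ds$wavelengths
  n <- length(ds$cubes)
  X <- matrix(NA_real_, n, length(wl))
  masks <- vector("list", n)
  agree <- numeric(n)
  for (i in seq_len(n)) {
    refl <- calibrate_reflectance(ds$cubes[[i]]$raw, ds$refs)
    d <- band_difference(refl, 700, 450)
    mk <- threshold_mask(d, auto_threshold(d))
    masks[[i]] <- mk
    agree[i] <- mean(mk$data == ds$cubes[[i]]$truth$mask$data)
    X[i, ] <- mean_masked_spectrum(refl, mk)
  }
  out <- list(cfg = cfg, ds = ds, wl = wl, X = X, masks = masks,
              agree = agree, y = ds$reference$moisture_pct)
  .fixture_cache[[key]] <- out
  out
}

# small random hypercube with float32-representable values
random_cube <- function(rows = 4, cols = 5, bands = 6, seed = 1) {
  set.seed(seed)
  v <- round(stats::runif(rows * cols * bands), 3)
  v <- as.numeric(.f32(v))
  hypercube(array(v, dim = c(rows, cols, bands)),
            seq(400, by = 10, length.out = bands), kind = "reflectance")
}

# round-trip a double vector through float32
.f32 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb"); writeBin(as.numeric(x), con, size = 4L); close(con)
  con <- file(f, "rb"); on.exit(close(con), add = TRUE)
  readBin(con, "numeric", n = length(x), size = 4L)
}

# small spectra table from the tissue spectral model + mild noise
toy_spectra <- function(n = 12, seed = 3, config = synth_config(),
                        moisture = NULL) {
  set.seed(seed)
  if (is.null(moisture)) moisture <- stats::runif(n, 63, 73)
  wl <- config$wavelengths
  X <- spectrum_model(moisture, wl, config)
  gain <- 1 + stats::rnorm(n, 0, 0.03)
  off <- stats::rnorm(n, 0, 0.01)
  X <- X * gain + off
  X <- X + matrix(stats::rnorm(n * length(wl), 0, 5e-4), n)
  list(X = X, y = moisture, wl = wl)
}

# closed-form 1-component PLS1 prediction (independent oracle)
pls1_one_lv <- function(X, y, x_new) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  v <- as.vector(crossprod(Xc, yc))
  w <- v / sqrt(sum(v^2))
  t_ <- as.vector(Xc %*% w)
  q <- sum(t_ * yc) / sum(t_^2)
  ym + sum((x_new - xm) * w) * q
}
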