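#' Configuration for the synthetic hyperspectral study
#'
#' Defines the simulated study: 36 breasts cooked at 50/60/70 deg C
#' (12 each), two slices per breast (72 samples), reflectance cubes on a
#' 400-1000 nm grid at 5 nm spacing (121 bands) with water O-H overtone
#' absorption bands at 970 nm (strong) and 760 nm (weak) whose depths grow
#' linearly with moisture, a within-sample radial moisture gradient (center
#' wetter than rim), per-sample multiplicative/additive scatter so SNV/MSC
#' have something to remove, and white/dark reference frames so reflectance
#' calibration is exercised end to end.
#'
#' @param n_breasts breasts per study (split evenly over temperatures).
#' @param slices_per_breast slices cut per breast.
#' @param temperatures cooking temperatures (deg C).
#' @param moisture_range_by_temp list of `[lo, hi]` moisture % per
#'   temperature: wetter at 50 deg C, driest at 70 deg C.
#' @param wavelengths band grid in nm.
#' @param band_centers,band_sigmas,band_depths O-H absorption bands: centers
#'   (nm), Gaussian widths (nm), and peak attenuation strength per unit
#'   moisture fraction (the exponent in the attenuation model at
#'   moisture = 100%; the 970 nm values give a ~35% reflectance dip at
#'   70% moisture, the 760 nm band stays weak).
#' @param gradient_strength center-minus-periphery moisture difference
#'   (percentage points).
#' @param moisture_noise_sd per-pixel moisture noise (percentage points).
#' @param pixel_scatter_gain_sd,pixel_scatter_offset_sd per-pixel scatter:
#'   each pixel's spectrum gets its own multiplicative gain and additive
#'   offset (surface topography and scattering-angle variation, constant
#'   across bands — the dominant pixel-to-pixel variation in tissue scans,
#'   and what per-spectrum transforms like SNV exist to remove).
#' @param pixel_noise_sd white (band-independent) reflectance noise floor
#'   per pixel and band — residual shot/readout noise after the
#'   spectrograph's point-spread smoothing.
#' @param sensor_noise_sd raw-count noise added to the sample scan.
#' @param scatter_gain_sd,scatter_offset_sd,scatter_tilt_sd per-sample
#'   multiplicative gain, additive offset, and wavelength-tilt scatter.
#' @param background_reflectance flat background level.
#' @param cube_rows,cube_cols spatial cube size.
#' @param white_level,dark_level reference frame count levels.
#' @param reference_error_sd sd (percentage points) of the oven-drying
#'   reference-method error: the measured moisture entering the reference
#'   table is the tissue moisture plus this weighing/drying error, so
#'   calibration statistics have a realistic floor instead of an exactly
#'   linear, error-free response.
#' @param w1_g,wet_mass_g pan weight and wet sample mass used to synthesize
#'   the oven-drying weighings.
#' @param seed integer RNG seed recorded in every output.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_breasts = 36L, slices_per_breast = 2L,
                         temperatures = c(50, 60, 70),
                         moisture_range_by_temp = list(`50` = c(70, 73),
                                                       `60` = c(66, 70),
                                                       `70` = c(63, 66)),
                         wavelengths = seq(400, 1000, by = 5),
                         band_centers = c(760, 970),
                         band_sigmas = c(18, 35),
                         band_depths = c(0.18, 1.28),
                         gradient_strength = 3,
                         moisture_noise_sd = 0.4,
                         pixel_scatter_gain_sd = 0.03,
                         pixel_scatter_offset_sd = 0.01,
                         pixel_noise_sd = 0.002,
                         sensor_noise_sd = 2,
                         scatter_gain_sd = 0.05,
                         scatter_offset_sd = 0.02,
                         scatter_tilt_sd = 0.01,
                         background_reflectance = 0.05,
                         cube_rows = 64L, cube_cols = 64L,
                         white_level = 3000, dark_level = 100,
                         reference_error_sd = 0.25,
                         w1_g = 5, wet_mass_g = 10,
                         seed = 1L) {
  cfg <- as.list(environment())
  for (r in moisture_range_by_temp)
    if (any(r < 0) || any(r > 100)) stop("moisture ranges must lie in [0, 100]")
  if (n_breasts %% length(temperatures) != 0)
    stop("n_breasts must divide evenly over temperatures")
  structure(cfg, class = "synth_config")
}

#' Noiseless tissue reflectance spectrum at a given moisture
#'
#' A smooth logistic tissue baseline (darker in the blue, brighter in the
#' red/NIR) attenuated by Gaussian O-H absorption bands at 760 nm (third
#' overtone, weak) and 970 nm (second overtone, strong):
#' \deqn{R(\lambda) = B(\lambda) \exp\{-(m/100) A(\lambda)\}}
#' with \eqn{A} the summed Gaussian band profile. The exponential form gives
#' the gentle band saturation real diffuse reflectance shows, so the
#' *normalized* band shape also carries moisture information, while band
#' depth still increases monotonically (and near-linearly over the moisture
#' range of interest) with moisture, vanishing at moisture 0. Values stay
#' in (0, 1).
#'
#' @param moisture moisture percentage in \[0, 100\].
#' @param wavelengths band grid (nm).
#' @param config a [synth_config].
#' @return Reflectance vector, length `length(wavelengths)` (or a matrix,
#'   one row per element of `moisture`).
#' @export
spectrum_model <- function(moisture, wavelengths = NULL, config = synth_config()) {
  if (any(moisture < 0) || any(moisture > 100))
    stop("moisture must lie in [0, 100]")
  if (is.null(wavelengths)) wavelengths <- config$wavelengths
  base <- .tissue_baseline(wavelengths)
  absorb <- .absorption_profile(wavelengths, config)
  if (length(moisture) == 1L)
    return(base * exp(-(moisture / 100) * absorb))
  sweep(exp(-(moisture / 100) %o% absorb), 2, base, `*`)
}

.tissue_baseline <- function(wl) 0.30 + 0.30 / (1 + exp(-(wl - 580) / 60))

# summed band profile per unit moisture fraction
.absorption_profile <- function(wl, config) {
  prof <- numeric(length(wl))
  for (k in seq_along(config$band_centers))
    prof <- prof + config$band_depths[k] *
      exp(-((wl - config$band_centers[k])^2) / (2 * config$band_sigmas[k]^2))
  prof
}

#' Generate one synthetic sample scan
#'
#' Builds an elliptical tissue region on a dark background, assigns each
#' foreground pixel a moisture value (sample moisture + radial gradient,
#' center high + pixel noise, recentered so the foreground mean equals the
#' sample moisture exactly), converts moisture to reflectance via
#' [spectrum_model], applies the per-sample scatter distortion, and encodes
#' everything as raw counts against white/dark reference frames so that
#' reflectance calibration inverts the synthesis.
#'
#' @param truth_moisture sample moisture %.
#' @param config a [synth_config].
#' @param seed optional integer; when given, generation runs under a local
#'   RNG seed (caller's RNG untouched), making the output a pure function of
#'   `(truth_moisture, config, seed)`.
#' @param refs optional shared [reference_images]; generated when `NULL`.
#' @return List: `raw` (raw-count [hypercube]), `refs`, `reflectance`
#'   (the scattered, pre-pixel-noise reflectance cube), and `truth`
#'   (`moisture`, `pixel_map` with NA background, `mask`).
#' @export
generate_sample_cube <- function(truth_moisture, config = synth_config(),
                                 seed = NULL, refs = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  nr <- config$cube_rows; nc <- config$cube_cols
  wl <- config$wavelengths; p <- length(wl)

  # elliptical foreground with mild shape jitter
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  a <- 0.38 * nr * stats::runif(1, 0.95, 1.05)
  b <- 0.38 * nc * stats::runif(1, 0.95, 1.05)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  r_norm <- sqrt(((rr - cy) / a)^2 + ((cc - cx) / b)^2)
  fg <- r_norm <= 1
  n_fg <- sum(fg)

  # per-pixel moisture: radial gradient (center wetter) + noise, recentered
  # so the foreground mean equals the sample moisture exactly
  mpix <- truth_moisture + config$gradient_strength * (0.5 - r_norm[fg]) +
    stats::rnorm(n_fg, 0, config$moisture_noise_sd)
  mpix <- mpix - mean(mpix) + truth_moisture
  mpix <- pmin(pmax(mpix, 0), 100)
  pixel_map <- matrix(NA_real_, nr, nc)
  pixel_map[fg] <- mpix

  # reflectance: tissue rows from the spectral model, flat dark background
  refl <- matrix(config$background_reflectance, nr * nc, p)
  refl[as.vector(fg), ] <- spectrum_model(mpix, wl, config)

  # per-sample scatter: multiplicative gain + additive, tilted offset
  gain <- min(max(1 + stats::rnorm(1, 0, config$scatter_gain_sd), 0.8), 1.2)
  offs <- min(max(stats::rnorm(1, 0, config$scatter_offset_sd), -0.05), 0.05)
  tilt <- min(max(stats::rnorm(1, 0, config$scatter_tilt_sd), -0.03), 0.03)
  offset_profile <- offs + tilt * (wl - 700) / 300
  refl <- sweep(gain * refl, 2, offset_profile, `+`)
  refl_cube <- hypercube(array(refl, dim = c(nr, nc, p)), wl, "reflectance")

  if (is.null(refs)) refs <- generate_reference_frames(config)

  noisy <- refl
  if (config$pixel_scatter_gain_sd > 0 || config$pixel_scatter_offset_sd > 0) {
    pg <- 1 + stats::rnorm(nr * nc, 0, config$pixel_scatter_gain_sd)
    po <- stats::rnorm(nr * nc, 0, config$pixel_scatter_offset_sd)
    pg <- pmin(pmax(pg, 0.7), 1.3); po <- pmin(pmax(po, -0.04), 0.04)
    noisy <- noisy * pg + po
  }
  if (config$pixel_noise_sd > 0)
    noisy <- noisy + stats::rnorm(length(noisy), 0, config$pixel_noise_sd)
  denom <- matrix(refs$white - refs$dark, nr * nc, p)
  dark <- matrix(refs$dark, nr * nc, p)
  raw <- noisy * denom + dark
  if (config$sensor_noise_sd > 0)
    raw <- raw + stats::rnorm(length(raw), 0, config$sensor_noise_sd)
  raw_cube <- hypercube(array(raw, dim = c(nr, nc, p)), wl, "raw")

  list(raw = raw_cube, refs = refs, reflectance = refl_cube,
       truth = list(moisture = truth_moisture, pixel_map = pixel_map,
                    mask = threshold_mask(fg * 1, 0.5)))
}

#' Synthetic white/dark reference frames
#'
#' Constant dark frame at `dark_level` counts; white frame follows a smooth
#' illumination profile peaking near 700 nm on top of the dark level.
#'
#' @param config a [synth_config].
#' @return A [reference_images] object sized `cube_rows x cube_cols x bands`.
#' @export
generate_reference_frames <- function(config = synth_config()) {
  nr <- config$cube_rows; nc <- config$cube_cols
  wl <- config$wavelengths; p <- length(wl)
  w_prof <- 0.6 + 0.4 * exp(-((wl - 700)^2) / (2 * 300^2))
  white <- array(rep(config$dark_level + config$white_level * w_prof,
                     each = nr * nc), dim = c(nr, nc, p))
  dark <- array(config$dark_level, dim = c(nr, nc, p))
  reference_images(white, dark)
}

#' Generate the full synthetic study
#'
#' Produces the 72-sample design (12 breasts per temperature, two slices
#' each), draws each sample's true moisture uniformly within its
#' temperature's range, generates all sample scans against one shared pair
#' of reference frames, and synthesizes the oven-drying weighings
#' (`w1`, `w2`, `w3`) to be exactly consistent with the true moisture, so
#' the reference-table arithmetic inverts the synthesis.
#'
#' @param config a [synth_config]; all randomness derives from `config$seed`.
#' @return List: `cubes` (per sample: `raw`, `reflectance`, `truth`),
#'   `refs` (shared reference frames), `reference` (the per-sample
#'   `data.frame` with weights and moisture), `wavelengths`, `config`.
#' @export
generate_dataset <- function(config = synth_config()) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(config$seed))

  per_temp <- config$n_breasts / length(config$temperatures)
  design <- expand.grid(slice = seq_len(config$slices_per_breast),
                        breast = seq_len(config$n_breasts))
  design$temperature_C <- config$temperatures[(design$breast - 1) %/% per_temp + 1]
  design$slice_location <- c("central", "peripheral")[design$slice]
  n <- nrow(design)
  moist <- numeric(n)
  for (i in seq_len(n)) {
    rg <- config$moisture_range_by_temp[[as.character(design$temperature_C[i])]]
    moist[i] <- stats::runif(1, rg[1], rg[2])
  }

  refs <- generate_reference_frames(config)
  cubes <- vector("list", n)
  for (i in seq_len(n))
    cubes[[i]] <- generate_sample_cube(moist[i], config, refs = refs)

  # measured moisture = tissue moisture + reference-method (weighing) error;
  # the weights are synthesized exactly consistent with the measured value,
  # so Eq.-1 arithmetic inverts the synthesis
  measured <- moist + stats::rnorm(n, 0, config$reference_error_sd)
  measured <- pmin(pmax(measured, 0), 100)
  w1 <- config$w1_g
  w2 <- w1 + config$wet_mass_g
  w3 <- w2 - (measured / 100) * (w2 - w1)
  reference <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    breast_id = sprintf("B%02d", design$breast),
    slice_location = design$slice_location,
    temperature_C = design$temperature_C,
    w1_g = w1, w2_g = w2, w3_g = w3,
    moisture_pct = moisture_percent(w1, w2, w3),
    true_moisture = moist,
    stringsAsFactors = FALSE)

  list(cubes = cubes, refs = refs, reference = reference,
       wavelengths = config$wavelengths, config = config)
}
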