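#' Pipeline run configuration
#'
#' Bundles every knob of the end-to-end analysis: the synthetic study
#' configuration, the wavelength ranges modelled (full VIS/NIR and the NIR
#' subset), the preprocessing methods compared, latent-variable budget,
#' calibration/test split, segmentation band pair, and map rendering range.
#'
#' @param synth a [synth_config] (its `seed` drives data generation).
#' @param ranges named list of `[lo, hi]` nm windows to model.
#' @param methods preprocessing tags (see [PREPROCESS_METHODS]).
#' @param max_lv maximum latent variables for cross-validation.
#' @param n_train calibration-set size (of 72).
#' @param split_seed seed for the calibration/test split.
#' @param seg_high_nm,seg_low_nm band pair for the background difference
#'   image (bright tissue band minus dark band).
#' @param sg_window,sg_polyorder Savitzky-Golay settings.
#' @param map_range which entry of `ranges` the chemical maps use.
#' @param map_method preprocessing of the mapping model. Pixel spectra carry
#'   strong per-pixel scatter, so pixel-wise mapping conventionally uses a
#'   per-spectrum scatter-corrective transform; SNV is the default. Set to
#'   `"best"` to map with the lowest-SEV model instead.
#' @param map_display lo/hi moisture % for rendering.
#' @return A `run_config` list.
#' @export
run_config <- function(synth = synth_config(),
                       ranges = list(full = c(400, 1000), nir = c(700, 1000)),
                       methods = PREPROCESS_METHODS,
                       max_lv = 20L, n_train = 52L, split_seed = 1L,
                       seg_high_nm = 700, seg_low_nm = 450,
                       sg_window = 11L, sg_polyorder = 2L,
                       map_range = "full", map_method = "snv",
                       map_display = c(60, 75)) {
  cfg <- as.list(environment())
  if (!map_range %in% names(ranges)) stop("map_range must name an entry of ranges")
  structure(cfg, class = "run_config")
}

#' Run the full moisture-analysis pipeline
#'
#' Executes, in order: synthetic study generation, reflectance calibration
#' of every scan, background segmentation (band-difference + automatic
#' threshold), mean foreground spectrum extraction, preprocessing-method
#' comparison with leave-one-out latent-variable selection for each
#' wavelength range, and pixel-wise chemical maps with center/periphery and
#' per-temperature statistics. All randomness derives from the two seeds in
#' the configuration, so a rerun with the same config reproduces every
#' output byte for byte.
#'
#' @param config a [run_config].
#' @param out_dir optional directory; when given, writes `report.csv`,
#'   `group_means.csv`, `region_stats.csv`, `manifest.json`, and one
#'   rendered map PNG per temperature group.
#' @param dataset optional pre-generated dataset (from [generate_dataset]);
#'   generated from `config$synth` when `NULL`.
#' @return List: `report` (method x range table), `best` (per range:
#'   method, model, models, cv, split), `group_means`, `region_stats`,
#'   `maps` (one `chemical_image` per temperature), `map_model`,
#'   `mask_agreement`, `sample_map_mean`, `reference`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL, dataset = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(dataset)) dataset <- generate_dataset(config$synth)
  wl <- dataset$wavelengths
  n <- length(dataset$cubes)

  # calibrate + segment + extract one mean spectrum per sample
  X <- matrix(NA_real_, n, length(wl))
  masks <- vector("list", n)
  mask_agree <- numeric(n)
  for (i in seq_len(n)) {
    refl <- calibrate_reflectance(dataset$cubes[[i]]$raw, dataset$refs)
    d <- band_difference(refl, config$seg_high_nm, config$seg_low_nm)
    mk <- threshold_mask(d, auto_threshold(d))
    masks[[i]] <- mk
    mask_agree[i] <- mean(mk$data == dataset$cubes[[i]]$truth$mask$data)
    X[i, ] <- mean_masked_spectrum(refl, mk)
  }
  y <- dataset$reference$moisture_pct

  # model selection per wavelength range
  reports <- list(); best <- list()
  for (rg in names(config$ranges)) {
    lohi <- config$ranges[[rg]]
    keep <- wl >= lohi[1] & wl <= lohi[2]
    sel <- select_model(X[, keep, drop = FALSE], y, wl[keep],
                        methods = config$methods, max_lv = config$max_lv,
                        n_train = config$n_train, seed = config$split_seed,
                        sg_window = config$sg_window,
                        sg_polyorder = config$sg_polyorder)
    rep_r <- cbind(range = rg, sel$report, stringsAsFactors = FALSE)
    reports[[rg]] <- rep_r
    best[[rg]] <- list(method = sel$best_method, model = sel$best_model,
                       models = sel$models, cv = sel$cv, split = sel$split)
  }
  report <- do.call(rbind, reports)
  rownames(report) <- NULL

  # chemical maps: the configured method's model for the mapping range,
  # refit at the parsimonious (one-standard-error) component count — extra
  # components chosen on near-noiseless mean spectra amplify per-pixel noise
  lohi <- config$ranges[[config$map_range]]
  # a deterministic pixel sample (first calibration-split cube) for the
  # map-aware noise estimate
  i0 <- best[[config$map_range]]$split[1]
  refl0 <- calibrate_reflectance(dataset$cubes[[i0]]$raw, dataset$refs)
  px0 <- masked_spectra(refl0, masks[[i0]])
  px0 <- px0[seq_len(min(500L, nrow(px0))), , drop = FALSE]
  map_model <- .mapping_model(X, y, wl, lohi, config,
                              sel_range = best[[config$map_range]],
                              pixel_sample = px0)
  if (is.null(map_model))
    stop("mapping model unavailable for method ", config$map_method)
  sample_map_mean <- numeric(n)
  temps <- dataset$reference$temperature_C
  rep_idx <- vapply(sort(unique(temps)), function(tp) which(temps == tp)[1], 0L)
  maps <- list(); rstats <- list()
  for (i in seq_len(n)) {
    refl <- calibrate_reflectance(dataset$cubes[[i]]$raw, dataset$refs)
    img <- pls_image(subset_bands(refl, lohi[1], lohi[2]), map_model, masks[[i]])
    sample_map_mean[i] <- mean(img$values[masks[[i]]$data])
    if (i %in% rep_idx) {
      tp <- as.character(temps[i])
      maps[[tp]] <- img
      rs <- region_stats(img)
      rstats[[tp]] <- cbind(temperature_C = temps[i],
                            sample_id = dataset$reference$sample_id[i], rs,
                            stringsAsFactors = FALSE)
    }
  }
  group_means <- stats::aggregate(
    list(map_mean = sample_map_mean, true_moisture = dataset$reference$true_moisture),
    by = list(temperature_C = temps), FUN = mean)
  region_df <- do.call(rbind, rstats); rownames(region_df) <- NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("hsimoist")),
    synth_seed = config$synth$seed, split_seed = config$split_seed,
    config_hash = config_hash(config),
    n_samples = n, n_bands = length(wl),
    ranges = config$ranges, methods = config$methods,
    mean_mask_agreement = mean(mask_agree))

  out <- list(report = report, best = best, group_means = group_means,
              region_stats = region_df, maps = maps, map_model = map_model,
              mask_agreement = mask_agree, sample_map_mean = sample_map_mean,
              reference = dataset$reference, manifest = manifest)
  if (!is.null(out_dir)) write_run_outputs(out, config, out_dir)
  out
}

# Mapping model: same protocol as the report models, but the component
# count minimizes the estimated *pixel-level* error. A pixel prediction
# carries the model's own error (the CV RMSE) plus spectral white noise
# propagated through the regression vector, sigma * ||beta_a||; components
# that barely improve the sample-level CV but inflate ||beta|| are poison
# for maps. sigma is estimated from the preprocessed pixel spectra by a
# robust second-difference estimator, so the choice is fully data-driven.
.mapping_model <- function(X, y, wl, lohi, config, sel_range, pixel_sample) {
  if (identical(config$map_method, "best")) return(sel_range$model)
  keep <- wl >= lohi[1] & wl <= lohi[2]
  idx <- sel_range$split
  cv <- sel_range$cv[[config$map_method]]
  if (is.null(cv))
    cv <- loo_cv(X[idx, keep, drop = FALSE], y[idx],
                 max_lv = min(config$max_lv, length(idx) - 2L, sum(keep)),
                 method = config$map_method, wavelengths = wl[keep],
                 sg_window = config$sg_window, sg_polyorder = config$sg_polyorder)
  pf <- preprocess_fit(X[idx, keep, drop = FALSE], config$map_method, wl[keep],
                       config$sg_window, config$sg_polyorder)
  path <- fit_plsr(pf$X, y[idx], n_lv = length(cv$rmse_by_lv),
                   preprocess_state = pf$state, wavelengths = wl[keep])
  zpx <- preprocess_apply(pf$state, pixel_sample[, keep, drop = FALSE])
  sigma <- .white_noise_sd(zpx)
  amp <- sigma * sqrt(colSums(path$beta_path^2))
  total <- sqrt(cv$rmse_by_lv^2 + amp^2)
  a <- which.min(total)
  fit_plsr(pf$X, y[idx], n_lv = a,
           preprocess_state = pf$state, wavelengths = wl[keep])
}

# robust per-band white-noise sd of spectra: second differences of a smooth
# signal are dominated by noise (sd sqrt(6) sigma); medians resist the
# curvature near absorption bands
.white_noise_sd <- function(Z) {
  p <- ncol(Z)
  if (p < 3) return(0)
  d2 <- Z[, 3:p, drop = FALSE] - 2 * Z[, 2:(p - 1), drop = FALSE] +
    Z[, 1:(p - 2), drop = FALSE]
  row_sigma <- apply(abs(d2), 1, stats::median) / (0.6744898 * sqrt(6))
  stats::median(row_sigma)
}

#' Write pipeline outputs to a run directory
#'
#' @param result a [run_pipeline] result.
#' @param config the [run_config] used.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_outputs <- function(result, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f) utils::write.csv(df, file.path(out_dir, f), row.names = FALSE)
  wr(result$report, "report.csv")
  wr(result$group_means, "group_means.csv")
  wr(result$region_stats, "region_stats.csv")
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (tp in names(result$maps))
    render_map(result$maps[[tp]], config$map_display[1], config$map_display[2],
               path = file.path(out_dir, sprintf("map_%sC.png", tp)))
  invisible(out_dir)
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical JSON serialization, for run manifests.
#'
#' @param config any serializable list.
#' @return Character MD5 digest.
#' @export
config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}
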