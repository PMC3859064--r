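# a small fitted model + matching cube for map tests
.map_fixture <- function() {
  if (!is.null(.fixture_cache$map_fixture)) return(.fixture_cache$map_fixture)
  tx <- toy_spectra(n = 20, seed = 61)
  pf <- preprocess_fit(tx$X, "snv", tx$wl)
  fit <- fit_plsr(pf$X, tx$y, n_lv = 2, preprocess_state = pf$state,
                  wavelengths = tx$wl)
  .fixture_cache$map_fixture <- list(tx = tx, fit = fit)
  .fixture_cache$map_fixture
}

test_that("a uniform cube maps to the sample's model prediction", {
  fx <- .map_fixture()
  sp <- fx$tx$X[4, ]
  cube <- hypercube(array(rep(sp, each = 9), dim = c(3, 3, length(sp))),
                    fx$tx$wl, "reflectance")
  mk <- threshold_mask(matrix(1, 3, 3), 0.5)
  img <- pls_image(cube, fx$fit, mk)
  want <- predict(fx$fit, preprocess_apply(fx$fit$preprocess_state,
                                           matrix(sp, 1)))
  expect_equal(unname(img$values[1, 1]), want)
  expect_true(all(abs(img$values - want) < 1e-12))
  # background carries NA, never zero
  mk2 <- threshold_mask(diag(3), 0.5)
  img2 <- pls_image(cube, fx$fit, mk2)
  expect_true(all(is.na(img2$values[mk2$data == FALSE])))
  # empty mask and wavelength mismatch are errors
  empty <- suppressMessages(threshold_mask(matrix(0, 3, 3), 0.5))
  expect_error(pls_image(cube, fx$fit, empty), "empty mask")
  sub <- subset_bands(cube, 500, 900)
  expect_error(pls_image(sub, fx$fit, mk), "wavelengths")
})

test_that("map values do not depend on pixel ordering", {
  fx <- .map_fixture()
  set.seed(62)
  p <- length(fx$tx$wl)
  a <- array(NA_real_, dim = c(2, 3, p))
  rows <- fx$tx$X[1:6, ]
  for (k in 1:6) a[((k - 1) %% 2) + 1, ((k - 1) %/% 2) + 1, ] <- rows[k, ]
  cube <- hypercube(a, fx$tx$wl, "reflectance")
  mk <- threshold_mask(matrix(1, 2, 3), 0.5)
  img <- pls_image(cube, fx$fit, mk)
  direct <- predict(fx$fit, preprocess_apply(fx$fit$preprocess_state, rows))
  got <- vapply(1:6, function(k) img$values[((k - 1) %% 2) + 1,
                                            ((k - 1) %/% 2) + 1], 0)
  expect_equal(got, direct, tolerance = 1e-12)
})

test_that("rendering clips to the display range with a colorbar appended", {
  vals <- matrix(70, 4, 4)
  mk <- threshold_mask(matrix(1, 4, 4), 0.5)
  img <- structure(list(values = vals, mask = mk, n_lv = 1, method = "raw"),
                   class = "chemical_image")
  out <- render_map(img, 60, 75)
  for (ch in 1:3)                                   # one uniform RGB color
    expect_equal(sd(as.vector(out[, 1:4, ch])), 0)
  # endpoint values hit the ramp endpoints
  vals2 <- matrix(c(60, 75, 60, 75), 2, 2)
  img2 <- structure(list(values = vals2,
                         mask = threshold_mask(matrix(1, 2, 2), 0.5),
                         n_lv = 1, method = "raw"), class = "chemical_image")
  out2 <- render_map(img2, 60, 75, n_colors = 8)
  lo_px <- out2[1, 1, ]; hi_px <- out2[2, 1, ]
  ramp <- grDevices::col2rgb(grDevices::colorRampPalette(
    c("darkblue", "blue", "cyan", "greenyellow", "yellow", "orange", "red"))(8)) / 255
  expect_equal(lo_px, unname(ramp[, 1]))
  expect_equal(hi_px, unname(ramp[, 8]))
  # out-of-range values clip to the same endpoints
  img3 <- structure(list(values = matrix(c(10, 99, 10, 99), 2, 2),
                         mask = threshold_mask(matrix(1, 2, 2), 0.5),
                         n_lv = 1, method = "raw"), class = "chemical_image")
  out3 <- render_map(img3, 60, 75, n_colors = 8)
  expect_equal(out3[1, 1, ], unname(ramp[, 1]))
  expect_error(render_map(img, 75, 60), "lo")
  f <- file.path(tempdir(), "map.png")
  render_map(img, 60, 75, path = f)
  expect_true(file.exists(f))
})

test_that("warmer cooking renders drier maps on a shared scale", {
  cfg <- synth_config()
  s50 <- generate_sample_cube(71.5, cfg, seed = 63)
  s70 <- generate_sample_cube(64.5, cfg, seed = 64)
  fx <- .map_fixture()
  mmean <- function(s) {
    refl <- calibrate_reflectance(s$raw, s$refs)
    img <- pls_image(refl, fx$fit, s$truth$mask)
    mean(img$values[s$truth$mask$data])
  }
  expect_gt(mmean(s50), mmean(s70))
})

test_that("region statistics find the wetter core", {
  # uniform map: both regions identical
  mkdat <- matrix(0, 9, 9); mkdat[2:8, 2:8] <- 1
  mk <- threshold_mask(mkdat, 0.5)
  uni <- structure(list(values = ifelse(mkdat > 0, 70, NA), mask = mk,
                        n_lv = 1, method = "raw"), class = "chemical_image")
  rs <- region_stats(uni)
  expect_equal(rs$mean[rs$region == "center"], rs$mean[rs$region == "periphery"])
  expect_equal(sum(rs$n_pixels), mk$n_foreground)
  # generated cube with a radial gradient: center > periphery
  fx <- .map_fixture()
  s <- generate_sample_cube(69, synth_config(), seed = 65)
  refl <- calibrate_reflectance(s$raw, s$refs)
  img <- pls_image(refl, fx$fit, s$truth$mask)
  rs2 <- region_stats(img)
  expect_gt(rs2$mean[rs2$region == "center"], rs2$mean[rs2$region == "periphery"])
  # a single-pixel mask has no periphery to compare
  one <- matrix(0, 5, 5); one[3, 3] <- 1
  mk1 <- threshold_mask(one, 0.5)
  img1 <- structure(list(values = ifelse(one > 0, 70, NA), mask = mk1,
                         n_lv = 1, method = "raw"), class = "chemical_image")
  expect_error(region_stats(img1), "degenerate")
})

test_that("chemical images export as ENVI with a no-data background", {
  vals <- matrix(NA_real_, 3, 3); vals[2, 2] <- 68.5
  one <- matrix(0, 3, 3); one[2, 2] <- 1
  img <- structure(list(values = vals, mask = threshold_mask(one, 0.5),
                        n_lv = 1, method = "raw"), class = "chemical_image")
  f <- file.path(tempdir(), "chem.hdr")
  write_chemical_image(img, f)
  back <- read_envi(f)
  expect_equal(back$data[2, 2, 1], 68.5)
  expect_equal(back$data[1, 1, 1], -9999)
})
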