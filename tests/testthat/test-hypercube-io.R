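test_that("ENVI round-trip is exact for every interleave", {
  cube <- random_cube(4, 4, 5, seed = 7)
  for (il in c("bsq", "bil", "bip")) {
    hdr <- file.path(tempdir(), paste0("rt_", il, ".hdr"))
    # float64 payload: bit-exact for arbitrary doubles
    write_envi(cube, hdr, interleave = il, dtype = 5L)
    back <- read_envi(hdr)
    expect_identical(back$data, cube$data)
    expect_equal(back$wavelengths, cube$wavelengths)
  }
  # float32 payload round-trips float32-representable values exactly
  hdr <- file.path(tempdir(), "rt_f32.hdr")
  write_envi(cube, hdr, interleave = "bsq", dtype = 4L)
  expect_identical(read_envi(hdr)$data, cube$data)
  # uint16 raw counts
  raw <- hypercube(array(as.numeric(0:23), dim = c(2, 3, 4)),
                   c(400, 500, 600, 700), kind = "raw")
  hdr <- file.path(tempdir(), "rt_u16.hdr")
  write_envi(raw, hdr, interleave = "bil", dtype = 12L)
  expect_identical(read_envi(hdr)$data, raw$data)
})

test_that("a 1x1x1 cube writes one scalar plus a parseable header", {
  cube <- hypercube(array(0.5, dim = c(1, 1, 1)), 500, "reflectance")
  hdr <- file.path(tempdir(), "tiny.hdr")
  write_envi(cube, hdr, dtype = 5L)
  expect_equal(file.info(sub("\\.hdr$", "", hdr))$size, 8)
  expect_equal(read_envi(hdr)$data[1, 1, 1], 0.5)
})

test_that("header wavelength list preserves values", {
  wlo <- seq(400, 420, by = 5) + 0.125
  cube <- hypercube(array(0, dim = c(2, 2, 5)), wlo, "reflectance")
  hdr <- file.path(tempdir(), "wl.hdr")
  write_envi(cube, hdr)
  expect_equal(read_envi(hdr)$wavelengths, wlo, tolerance = 1e-4)
})

test_that("BIL written by an independent encoder matches package BSQ read", {
  cube <- random_cube(3, 4, 5, seed = 11)
  # independent writer: loop lines, then bands, then samples (BIL layout)
  bin <- file.path(tempdir(), "indep_bil")
  con <- file(bin, "wb")
  for (r in seq_len(3)) for (b in seq_len(5))
    writeBin(as.numeric(cube$data[r, , b]), con, size = 8L, endian = "little")
  close(con)
  writeLines(c("ENVI", "samples = 4", "lines = 3", "bands = 5",
               "data type = 5", "interleave = bil", "byte order = 0",
               paste0("wavelength = { ",
                      paste(cube$wavelengths, collapse = ", "), " }")),
             paste0(bin, ".hdr"))
  indep <- read_envi(paste0(bin, ".hdr"))
  hdr2 <- file.path(tempdir(), "pkg_bsq.hdr")
  write_envi(cube, hdr2, interleave = "bsq", dtype = 5L)
  expect_identical(indep$data, read_envi(hdr2)$data)
})

test_that("header/binary inconsistencies and missing keys are errors", {
  cube <- random_cube(2, 2, 4, seed = 2)
  hdr <- file.path(tempdir(), "bad.hdr")
  write_envi(cube, hdr, dtype = 5L)
  # claim 5 bands while the binary holds 4
  txt <- readLines(hdr)
  writeLines(sub("^bands = 4", "bands = 5", txt), hdr)
  expect_error(read_envi(hdr), "wavelength|bands")
  writeLines(sub("wavelength = .*", "wavelength = { 1, 2, 3, 4, 5 }",
                 sub("^bands = 4", "bands = 5", txt)), hdr)
  expect_error(read_envi(hdr), "binary size")
  writeLines(grep("wavelength", txt, invert = TRUE, value = TRUE), hdr)
  expect_error(read_envi(hdr), "wavelength")
})

test_that("reflectance calibration matches its defining ratio", {
  cfg <- synth_config(cube_rows = 6L, cube_cols = 6L)
  refs <- generate_reference_frames(cfg)
  wl <- cfg$wavelengths
  as_cube <- function(a) hypercube(a, wl, "raw")
  expect_equal(calibrate_reflectance(as_cube(refs$white), refs)$data,
               array(1, dim = dim(refs$white)))
  expect_equal(calibrate_reflectance(as_cube(refs$dark), refs)$data,
               array(0, dim = dim(refs$white)))
  mid <- as_cube((refs$white + refs$dark) / 2)
  expect_equal(calibrate_reflectance(mid, refs)$data,
               array(0.5, dim = dim(refs$white)))
})

test_that("calibration is invariant to a common gain and offset", {
  set.seed(4)
  d <- c(3, 3, 5)
  wl <- seq(500, 540, 10)
  white <- array(runif(prod(d), 2000, 3000), d)
  dark <- array(runif(prod(d), 50, 100), d)
  raw <- array(runif(prod(d), 200, 1800), d)
  r1 <- calibrate_reflectance(hypercube(raw, wl, "raw"),
                              reference_images(white, dark))
  g <- 2.5; o <- 17
  r2 <- calibrate_reflectance(hypercube(g * raw + o, wl, "raw"),
                              reference_images(g * white + o, g * dark + o))
  expect_equal(r1$data, r2$data, tolerance = 1e-12)
})

test_that("invalid calibration pixels are flagged, not clipped", {
  wl <- c(500, 510)
  white <- array(100, c(2, 2, 2)); dark <- array(50, c(2, 2, 2))
  white[1, 1, 1] <- 40                       # white below dark: uncalibratable
  raw <- hypercube(array(75, c(2, 2, 2)), wl, "raw")
  expect_message(
    out <- calibrate_reflectance(raw, reference_images(white, dark)),
    "1 invalid")
  expect_true(is.na(out$data[1, 1, 1]))
  expect_equal(attr(out, "n_invalid"), 1)
  expect_equal(sum(is.na(out$data)), 1)
  all_bad <- reference_images(array(10, c(2, 2, 2)), array(50, c(2, 2, 2)))
  expect_error(calibrate_reflectance(raw, all_bad), "all pixels invalid")
})

test_that("band subsetting is inclusive, idempotent, and errors when empty", {
  cube <- hypercube(array(seq_len(4 * 4 * 121), dim = c(4, 4, 121)),
                    seq(400, 1000, 5), "raw")
  nir <- subset_bands(cube, 700, 1000)
  expect_equal(range(nir$wavelengths), c(700, 1000))
  expect_equal(length(nir$wavelengths), 61)
  expect_equal(subset_bands(nir, 700, 1000), nir)
  expect_equal(subset_bands(cube, 400, 1000), cube)
  expect_error(subset_bands(cube, 1100, 1200), "no bands")
})
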