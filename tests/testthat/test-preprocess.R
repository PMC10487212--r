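make_frames <- function(I, W, B, wl = c(500, 600, 700)) {
  arr <- function(v) array(rep(v, each = 4), c(2, 2, length(wl)))
  list(raw = hypercube(arr(I), wl, frame_kind = "raw"),
       white = hypercube(arr(W), wl, frame_kind = "white"),
       black = hypercube(arr(B), wl, frame_kind = "black"))
}

test_that("reflectance calibration matches its defining ratio", {
  f <- make_frames(I = c(900, 900, 900), W = c(900, 900, 900),
                   B = c(100, 100, 100))
  expect_equal(max(abs(calibrate_reflectance(f$raw, f$white, f$black)$data
                       - 1)), 0)
  f <- make_frames(I = c(100, 100, 100), W = c(900, 900, 900),
                   B = c(100, 100, 100))
  expect_equal(max(abs(calibrate_reflectance(f$raw, f$white, f$black)$data)),
               0)
  f <- make_frames(I = c(500, 500, 500), W = c(900, 900, 900),
                   B = c(100, 100, 100))
  expect_lt(max(abs(calibrate_reflectance(f$raw, f$white, f$black)$data
                    - 0.5)), 1e-12)
})

test_that("calibration is scale-invariant and flags saturation", {
  f <- make_frames(I = c(500, 600, 700), W = c(900, 950, 990),
                   B = c(100, 90, 80))
  r1 <- calibrate_reflectance(f$raw, f$white, f$black)$data
  g <- make_frames(I = 3.7 * c(500, 600, 700), W = 3.7 * c(900, 950, 990),
                   B = 3.7 * c(100, 90, 80))
  r2 <- calibrate_reflectance(g$raw, g$white, g$black)$data
  expect_lt(max(abs(r1 - r2)), 1e-12)
  bad <- make_frames(I = c(500, 500, 500), W = c(900, 80, 900),
                     B = c(100, 100, 100))
  expect_error(calibrate_reflectance(bad$raw, bad$white, bad$black), "600")
})

test_that("negative reflectance is clipped and >1 preserved with counts", {
  f <- make_frames(I = c(50, 950, 500), W = c(900, 900, 900),
                   B = c(100, 100, 100))
  out <- calibrate_reflectance(f$raw, f$white, f$black)
  expect_equal(min(out$data), 0)
  expect_gt(max(out$data), 1)
  expect_equal(attr(out, "n_clipped_negative"), 4L)
  expect_equal(attr(out, "n_above_one"), 4L)
})

test_that("Savitzky-Golay smoothing preserves polynomials and length", {
  x <- seq_len(101)
  const <- rep(3.3, 101)
  expect_equal(smooth_savitzky_golay(const), const)
  quad <- 2 + 0.5 * x - 0.01 * x^2
  sm <- smooth_savitzky_golay(quad, 11, 2)
  expect_equal(length(sm), 101)
  interior <- 6:96
  expect_lt(max(abs(sm[interior] - quad[interior])), 1e-10)
  expect_error(smooth_savitzky_golay(quad, 10, 2), "odd")
  expect_error(smooth_savitzky_golay(quad, 11, 11), "poly_order")
  expect_error(smooth_savitzky_golay(rep(1, 5), 11, 2), "exceeds")
})

test_that("smoothing strictly reduces white-noise variance", {
  set.seed(77)
  reduced <- replicate(20, {
    z <- rnorm(200)
    var(smooth_savitzky_golay(z)) < var(z)
  })
  expect_true(all(reduced))
})

test_that("trimming keeps exactly the 420-1600 nm bands", {
  wl <- seq(380, 1690, by = 5)
  X <- matrix(1, 2, length(wl))
  attr(X, "wavelengths") <- wl
  out <- trim_spectral_range(X)
  expect_equal(attr(out, "wavelengths")[1], 420)
  expect_equal(max(attr(out, "wavelengths")), 1600)
  expect_equal(ncol(out), 237)
  inside <- matrix(1, 2, 5)
  attr(inside, "wavelengths") <- c(500, 600, 700, 800, 900)
  expect_equal(ncol(trim_spectral_range(inside)), 5)
  expect_error(trim_spectral_range(X, lo = 1700, hi = 1800), "no bands")
})

test_that("fusion yields a 237-point grid, VIS below 1000 nm", {
  wv <- seq(380, 1000, by = 5); wn <- seq(860, 1690, by = 5)
  Xv <- matrix(1, 3, length(wv)); attr(Xv, "wavelengths") <- wv
  Xn <- matrix(1, 3, length(wn)); attr(Xn, "wavelengths") <- wn
  fused <- fuse_sensors(Xv, Xn)
  expect_equal(ncol(fused), 237)
  expect_true(all(fused == 1))
  # distinct values in the 860-1000 overlap: VIS wins below the boundary
  Xv2 <- Xv; Xv2[] <- 0.4; attr(Xv2, "wavelengths") <- wv
  Xn2 <- Xn; Xn2[] <- 0.9; attr(Xn2, "wavelengths") <- wn
  f2 <- fuse_sensors(Xv2, Xn2)
  grid <- attr(f2, "wavelengths")
  expect_true(all(f2[, grid < 1000] == 0.4))
  expect_true(all(f2[, grid >= 1000] == 0.9))
  expect_identical(unname(attr(f2, "source")[grid == 995]), "vis")
  expect_identical(unname(attr(f2, "source")[grid == 1000]), "nir")
  # on-grid inputs are copied unchanged
  set.seed(5)
  Xv3 <- matrix(runif(2 * length(wv)), 2); attr(Xv3, "wavelengths") <- wv
  Xn3 <- matrix(runif(2 * length(wn)), 2); attr(Xn3, "wavelengths") <- wn
  f3 <- fuse_sensors(Xv3, Xn3)
  expect_equal(unname(f3[, "r0420"]), Xv3[, wv == 420])
  expect_equal(unname(f3[, "r1600"]), Xn3[, wn == 1600])
  Xv_short <- Xv3[, wv >= 500, drop = FALSE]
  attr(Xv_short, "wavelengths") <- wv[wv >= 500]
  expect_error(fuse_sensors(Xv_short, Xn3), "VIS sensor")
})

test_that("trim and fuse commute on covered grids", {
  wv <- seq(380, 1000, by = 5); wn <- seq(860, 1690, by = 5)
  set.seed(9)
  Xv <- matrix(runif(2 * length(wv)), 2); attr(Xv, "wavelengths") <- wv
  Xn <- matrix(runif(2 * length(wn)), 2); attr(Xn, "wavelengths") <- wn
  a <- trim_spectral_range(fuse_sensors(Xv, Xn))
  b <- fuse_sensors(trim_spectral_range(Xv, hi = 1000),
                    trim_spectral_range(Xn, lo = 1000))
  expect_equal(matrix(a, nrow(a)), matrix(b, nrow(b)))
  expect_equal(attr(a, "wavelengths"), attr(b, "wavelengths"))
})

test_that("ROI mean spectra are per-label arithmetic means", {
  wl <- c(500, 600)
  arr <- array(0, c(2, 3, 2))
  arr[1, 1, ] <- 0.2; arr[2, 1, ] <- 0.4    # label 1: two pixels
  arr[1, 3, ] <- 0.7                         # label 2: one pixel
  cube <- hypercube(arr, wl, frame_kind = "reflectance")
  mask <- matrix(0L, 2, 3); mask[1:2, 1] <- 1L; mask[1, 3] <- 2L
  sp <- extract_roi_mean_spectra(cube, mask)
  expect_equal(unname(sp["1", ]), c(0.3, 0.3))
  expect_equal(unname(sp["2", ]), c(0.7, 0.7))
  expect_equal(unname(attr(sp, "pixel_count")), c(2L, 1L))
  expect_error(extract_roi_mean_spectra(cube, mask, expected_labels = 1:3),
               "3")
})

test_that("ROI spectra of a noiseless cube equal the forward model at the
           ROI-mean chemistry", {
  fld <- one_fruit_field(seed = 4)
  opt <- optics_model()
  g <- generate_hypercube(fld, opt, "vis", seed = 1, noise_frac = 0)
  Rc <- calibrate_reflectance(g$raw, g$white, g$black)
  roi_mask <- build_roi_mask(fld$layout$centers, fld$layout$shape)
  sp <- extract_roi_mean_spectra(Rc, roi_mask)
  means <- field_roi_means(fld)
  chem <- list(mc = means$mc_pct, ssc = means$ssc_pct,
               ta = means$ta_gpct, cc = means$cc_mg100gdm)
  want <- forward_reflectance(opt, chem, sensor_grid("vis"))
  # linear forward model: disc mean of reflectance = reflectance of disc
  # mean chemistry
  expect_lt(max(abs(unname(sp) - want)), 1e-9)
})
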