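test_that("flattening is row-major and invertible", {
  arr <- array(seq_len(2 * 2 * 3), c(2, 2, 3))
  cube <- hypercube(arr, c(500, 600, 700), frame_kind = "reflectance")
  flat <- flatten_hypercube(cube)
  expect_equal(dim(flat), c(4L, 3L))
  # row k (0-based) is pixel (k %/% cols, k %% cols)
  for (k in 0:3) {
    expect_equal(unname(flat[k + 1, ]),
                 arr[k %/% 2 + 1, k %% 2 + 1, ])
  }
  back <- unflatten_image(flat, c(2, 2))
  expect_equal(back, arr)
  set.seed(40)
  arr2 <- array(rnorm(5 * 7 * 4), c(5, 7, 4))
  cube2 <- hypercube(arr2, 1:4, frame_kind = "reflectance")
  expect_equal(unflatten_image(flatten_hypercube(cube2), c(5, 7)), arr2)
})

test_that("fixed thresholding recovers the generator slice mask exactly", {
  fld <- one_fruit_field(seed = 7)
  opt <- optics_model()
  g <- generate_hypercube(fld, opt, "vis", seed = 3, noise_frac = 0)
  Rc <- calibrate_reflectance(g$raw, g$white, g$black)
  band <- Rc$data[, , which(sensor_grid("vis") == 500)]
  mask <- background_mask(band, "fixed", threshold = 0.2)
  expect_equal(mask, fld$layout$mask)   # fiducials sit inside the slice
  expect_true(all(background_mask(matrix(0.5, 4, 4), "fixed",
                                  threshold = 0.2)))
  expect_equal(sum(mask) + sum(!mask), prod(fld$layout$shape))
})

test_that("otsu with bright-class postselection keeps the mid level", {
  set.seed(41)
  img <- matrix(0.02, 100, 100)
  img[20:80, 20:80] <- 0.4                      # slice
  img[30:34, 30:34] <- 0.95                     # fiducial
  img <- img + matrix(rnorm(1e4, 0, 0.005), 100)
  mask <- background_mask(img, "otsu", exclude_bright = TRUE)
  expect_true(all(!mask[img < 0.1]))
  expect_true(all(!mask[img > 0.9]))
  expect_true(mean(mask[25:75, 40:75]) > 0.99)
  expect_error(background_mask(matrix(0.5, 5, 5), "fixed", threshold = 1),
               "empty foreground")
})

test_that("in-package otsu agrees with the EBImage reference", {
  skip_if_not_installed("EBImage")
  set.seed(42)
  x <- c(rnorm(4000, 0.2, 0.05), rnorm(6000, 0.7, 0.08))
  x <- pmin(pmax(x, 0), 1)
  img <- matrix(x, 100, 100)
  ours <- chemmap:::otsu_threshold(img)
  ref <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  expect_lt(abs(ours - ref), 0.02)
})

test_that("prediction maps respect mask sentinels and wavelengths", {
  set.seed(43)
  n <- 300
  X <- matrix(rnorm(n * 2), n, 2); colnames(X) <- c("r0495", "r0505")
  y <- X[, 1] - X[, 2] + 10
  m <- train_mlp(X, y, 1:240, 241:300, seed = 2)
  flat <- matrix(rnorm(24 * 2), 24, 2)
  colnames(flat) <- c("r0495", "r0505")
  attr(flat, "shape") <- c(4L, 6L)
  mask <- matrix(TRUE, 4, 6); mask[1, ] <- FALSE
  dm <- predict_map(m, flat, mask, composition = "mc")
  expect_true(all(is.na(dm$values[1, ])))
  expect_true(all(is.finite(dm$values[2:4, ])))
  empty <- predict_map(m, flat, mask & FALSE, composition = "mc")
  expect_true(all(is.na(empty$values)))
  colnames(flat) <- c("r0495", "r0510")
  expect_error(predict_map(m, flat, mask), "505")
})

test_that("map path equals table path on a noiseless validation fruit", {
  fld <- one_fruit_field(seed = 8)
  opt <- optics_model()
  cubes <- lapply(c("vis", "nir"), function(sn) {
    g <- generate_hypercube(fld, opt, sn, seed = 1, noise_frac = 0)
    calibrate_reflectance(g$raw, g$white, g$black)
  })
  flat <- fuse_sensors(flatten_hypercube(cubes[[1]]),
                       flatten_hypercube(cubes[[2]]))
  attr(flat, "shape") <- fld$layout$shape
  # train on spectra from an independent table through the same optics
  ref <- generate_reference_table(seed = 30)
  sp <- make_roi_spectra(ref, opt, noise_sd = 0, seed = 1)
  plan <- partition_dataset(ref, seed = 3)
  cal <- which(plan$assignment == "calibration")
  cv <- which(plan$assignment == "cross_validation")
  m <- train_mlp(sp[, c("r0490", "r0495")], ref$mc_pct, cal, cv, seed = 5)
  mask <- background_mask(
    unflatten_image(flat[, "r0500"], fld$layout$shape), "fixed",
    threshold = 0.2, threshold_high = 0.8)
  dm <- predict_map(m, flat, mask, composition = "mc")
  roi_mask <- build_roi_mask(fld$layout$centers, fld$layout$shape)
  # table path: ROI mean spectra -> model; map path: ROI mean of pixel
  # predictions; reference values are the disc means
  roi_sp_v <- extract_roi_mean_spectra(cubes[[1]], roi_mask)
  roi_sp_n <- extract_roi_mean_spectra(cubes[[2]], roi_mask)
  roi_sp <- fuse_sensors(roi_sp_v, roi_sp_n)
  table_pred <- predict(m, roi_sp[, c("r0490", "r0495")])
  map_pred <- vapply(1:10, function(rg) {
    mean(dm$values[roi_mask == rg & mask])
  }, numeric(1))
  # the map path averages nonlinear pixel predictions over each disc; on a
  # smooth field the Jensen gap against predicting the disc-mean spectrum
  # stays far below the chemistry scale
  expect_lt(max(abs(table_pred - map_pred)), 0.05)
  expect_gt(cor(table_pred, map_pred), 0.999)
})

test_that("map path and table path agree exactly on a uniform fruit", {
  # constant chemistry: every pixel of a disc shares its spectrum, so
  # mean-of-predictions and prediction-of-mean must coincide
  rows <- data.frame(origin = 1, fruit = 1, region = 1:10,
                     mc_pct = 87, ssc_pct = 12, ta_gpct = 0.9,
                     cc_mg100gdm = 0.3)
  fld <- generate_chemistry_field(rows, c(160L, 160L), 1.0)
  opt <- optics_model()
  g <- generate_hypercube(fld, opt, "vis", seed = 1, noise_frac = 0)
  Rc <- calibrate_reflectance(g$raw, g$white, g$black)
  flat <- flatten_hypercube(Rc)
  ref <- generate_reference_table(seed = 31)
  sp <- make_roi_spectra(ref, opt, noise_sd = 0, seed = 1)
  plan <- partition_dataset(ref, seed = 3)
  m <- train_mlp(sp[, c("r0490", "r0495")], ref$mc_pct,
                 which(plan$assignment == "calibration"),
                 which(plan$assignment == "cross_validation"), seed = 5)
  mask <- fld$layout$mask
  dm <- predict_map(m, flat, mask, fld$layout$shape, composition = "mc")
  roi_mask <- build_roi_mask(fld$layout$centers, fld$layout$shape)
  roi_sp <- extract_roi_mean_spectra(Rc, roi_mask)
  table_pred <- predict(m, roi_sp[, c("r0490", "r0495")])
  map_pred <- vapply(1:10, function(rg) {
    mean(dm$values[roi_mask == rg & mask])
  }, numeric(1))
  expect_lt(max(abs(table_pred - map_pred)), 1e-6)
})

test_that("region-wise errors are absolute percentage differences", {
  ref <- data.frame(origin = 1, fruit = 1, region = 1:10,
                    mc_pct = 10, ssc_pct = 1, ta_gpct = 1,
                    cc_mg100gdm = 1)
  values <- matrix(11, 30, 30)
  mask <- matrix(TRUE, 30, 30)
  rm <- matrix(0L, 30, 30)
  for (rg in 1:10) rm[3 * rg + (-2:0), 5] <- rg
  dm <- structure(list(values = values, mask = mask, composition = "mc",
                       wavelengths = "r0495"), class = "distribution_map")
  re <- regionwise_errors(list("1_1" = dm), list("1_1" = rm), ref)
  expect_equal(unname(re$per_fruit["1_1", ]), rep(10, 10))
  values2 <- matrix(10, 30, 30)
  dm2 <- structure(list(values = values2, mask = mask, composition = "mc",
                        wavelengths = "r0495"), class = "distribution_map")
  re2 <- regionwise_errors(list("1_1" = dm2), list("1_1" = rm), ref)
  expect_equal(sum(re2$table$mean), 0)
})

test_that("Tukey letters separate a strongly shifted region", {
  set.seed(44)
  err <- matrix(rnorm(120, 20, 2), 12, 10,
                dimnames = list(NULL, 1:10))
  err[, 4] <- err[, 4] + 20         # 10 pooled SDs
  tk <- tukey_regions(err)
  others <- tk$letters[-4]
  expect_false(any(grepl(tk$letters[4], others, fixed = TRUE)))
  # identical data in all regions: degenerate single letter
  same <- matrix(5, 12, 10, dimnames = list(NULL, 1:10))
  tk2 <- tukey_regions(same)
  expect_true(all(tk2$letters == "a"))
  expect_true(tk2$degenerate)
})

test_that("our letter display agrees with multcomp on a worked case", {
  skip_if_not_installed("multcomp")
  set.seed(45)
  err <- matrix(rnorm(120, 20, 3), 12, 10, dimnames = list(NULL, 1:10))
  err[, 2] <- err[, 2] + 12
  err[, 7] <- err[, 7] - 12
  tk <- tukey_regions(err)
  long <- data.frame(error = as.vector(err),
                     region = factor(rep(1:10, each = 12)))
  fit <- stats::aov(error ~ region, data = long)
  glht <- multcomp::glht(fit, linfct = multcomp::mcp(region = "Tukey"))
  cld <- multcomp::cld(glht, level = 0.05)$mcletters$Letters
  # same sharing structure: groups share a letter in ours iff in multcomp
  share_ours <- outer(tk$letters, tk$letters,
                      Vectorize(function(a, b) {
                        any(strsplit(a, "")[[1]] %in% strsplit(b, "")[[1]])
                      }))
  share_ref <- outer(cld, cld,
                     Vectorize(function(a, b) {
                       any(strsplit(a, "")[[1]] %in% strsplit(b, "")[[1]])
                     }))
  expect_equal(unname(share_ours), unname(share_ref))
})

test_that("histogram statistics follow the stated moment conventions", {
  mask <- matrix(TRUE, 1, 5)
  dm <- structure(list(values = matrix(1:5, 1), mask = mask,
                       composition = "mc", wavelengths = "r0495"),
                  class = "distribution_map")
  st <- map_histogram_stats(dm)
  expect_equal(st$mean, 3)
  expect_equal(st$skewness, 0)
  const <- structure(list(values = matrix(2, 1, 5), mask = mask,
                          composition = "mc", wavelengths = "r0495"),
                     class = "distribution_map")
  stc <- map_histogram_stats(const)
  expect_true(stc$degenerate)
  expect_equal(stc$skewness, 0)
  set.seed(46)
  big <- matrix(rnorm(1e5), 250)
  dmb <- structure(list(values = big,
                        mask = matrix(TRUE, 250, 400),
                        composition = "mc", wavelengths = "r0495"),
                   class = "distribution_map")
  stb <- map_histogram_stats(dmb)
  expect_lt(abs(stb$skewness), 0.05)
  expect_lt(abs(stb$kurtosis - 3), 0.1)
})
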