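test_that("partitioning yields 390/90/120 with held-out fruit intact", {
  ref <- generate_reference_table(seed = 2)
  plan <- partition_dataset(ref, seed = 5)
  tab <- table(plan$assignment)
  expect_equal(unname(tab["calibration"]), 390L)
  expect_equal(unname(tab["cross_validation"]), 90L)
  expect_equal(unname(tab["validation"]), 120L)
  expect_equal(sum(tab), 600L)
  # validation rows are exactly all ROIs of the held-out fruit
  val_rows <- ref[plan$assignment == "validation", ]
  expect_equal(nrow(unique(val_rows[c("origin", "fruit")])), 12)
  expect_equal(nrow(plan$validation_fruit), 12)
  expect_true(all(table(val_rows$origin) == 20))
  key <- interaction(val_rows$origin, val_rows$fruit)
  expect_true(all(table(key)[table(key) > 0] == 10))
  # deterministic and disjoint
  plan2 <- partition_dataset(ref, seed = 5)
  expect_identical(plan$assignment, plan2$assignment)
})

test_that("non-proportionable designs are rejected with guidance", {
  small <- generate_reference_table(
    design = list(origins = 3L, fruit_per_origin = 4L,
                  regions_per_fruit = 2L), seed = 1)
  expect_error(partition_dataset(small, seed = 1), "fractions")
})

test_that("a representable linear target is fit nearly perfectly", {
  set.seed(30)
  n <- 480
  X <- matrix(rnorm(n), n, 1); colnames(X) <- "r0495"
  y <- 2 * X[, 1] + 1
  m <- train_mlp(X, y, 1:390, 391:480,
                 hyper = list(mse_goal = 1e-6), seed = 4)
  ev <- evaluate_model(m, X[391:480, , drop = FALSE], y[391:480])
  expect_gte(ev$R, 0.999)
  expect_lte(ev$RMSE / sd(y[1:390]), 1e-2)
  expect_true(m$stopping$reason %in% c("mse_goal", "max_val_fail",
                                       "max_epochs", "mu_overflow"))
})

test_that("training is deterministic per seed", {
  set.seed(31)
  X <- matrix(rnorm(300), 300, 1); colnames(X) <- "r0500"
  y <- sin(X[, 1]) + 2
  m1 <- train_mlp(X, y, 1:240, 241:300, seed = 7)
  m2 <- train_mlp(X, y, 1:240, 241:300, seed = 7)
  expect_identical(m1$theta, m2$theta)
  expect_identical(m1$stopping, m2$stopping)
})

test_that("pure-noise targets show no predictive skill on held-out data", {
  # cross-validation R itself is upward-biased by best-epoch restoration,
  # so the no-information check scores an untouched holdout
  set.seed(32)
  r_val <- vapply(1:20, function(s) {
    n <- 240
    X <- matrix(rnorm(n * 2), n, 2); colnames(X) <- c("r0495", "r0500")
    y <- rnorm(n) + 10
    m <- train_mlp(X, y, 1:160, 161:200, seed = s)
    evaluate_model(m, X[201:240, ], y[201:240])$R
  }, numeric(1))
  expect_lt(abs(mean(r_val)), 2.5 * sd(r_val) / sqrt(20))
})

test_that("performance metrics match hand-evaluated cases", {
  ev <- regression_metrics(c(10, 20), c(11, 18))
  expect_equal(ev$RMSE, sqrt((1 + 4) / 2))
  expect_equal(ev$MAPE, 10)
  ev2 <- regression_metrics(c(3, 5, 9), c(3, 5, 9))
  expect_equal(ev2$R, 1); expect_equal(ev2$RMSE, 0); expect_equal(ev2$MAPE, 0)
  y <- c(4, 7, 9)
  ev3 <- regression_metrics(y, -y + 20)
  expect_equal(ev3$R, -1)
  expect_error(regression_metrics(c(0, 1), c(1, 1)), "zero target")
})

test_that("predictions return in original units whatever the scaling", {
  set.seed(33)
  n <- 400
  X <- matrix(rnorm(n, 1000, 50), n, 1); colnames(X) <- "r0900"
  y <- 0.004 * X[, 1] + 80          # moisture-like scale
  m <- train_mlp(X, y, 1:320, 321:400, seed = 2)
  pred <- predict(m, X[321:400, , drop = FALSE])
  expect_lt(max(abs(pred - y[321:400])), 0.5)
  expect_gt(mean(pred), 80)
  expect_error(predict(m, matrix(1, 2, 1, dimnames = list(NULL, "r0495"))),
               "r0900")
})

test_that("nnet cross-check: both learners master the same linear task", {
  set.seed(34)
  n <- 300
  X <- matrix(rnorm(n), n, 1); colnames(X) <- "r0495"
  y <- 3 * X[, 1] + 5
  m <- train_mlp(X, y, 1:240, 241:300, seed = 1)
  ours <- evaluate_model(m, X[241:300, , drop = FALSE], y[241:300])$RMSE
  nn <- nnet::nnet(X[1:240, , drop = FALSE], matrix(y[1:240]), size = 4,
                   linout = TRUE, trace = FALSE, maxit = 500)
  theirs <- sqrt(mean((predict(nn, X[241:300, , drop = FALSE]) -
                         y[241:300])^2))
  expect_lt(ours, 0.1)
  expect_lt(theirs, 0.1)
})

test_that("replicate selection prefers a dominating wavelength set", {
  ref <- generate_reference_table(seed = 9)
  sp <- make_roi_spectra(ref, controlled_optics(), noise_sd = 0.002,
                         seed = 3)
  plan <- partition_dataset(ref, seed = 10)
  sets <- list(informative = c("r0495", "r0500"),
               blind = c("r0800", "r1100"))
  rs <- replicate_and_select(sets, sp, ref$mc_pct, plan,
                             n_replicates = 5, seed = 11)
  expect_equal(rs$best_set, "informative")
  expect_equal(nrow(rs$metrics), 2)
  expect_equal(rs$metrics$n_replicates, c(5, 5))
  expect_true(all(c("R_cv_mean", "R_cv_sd", "RMSE_c_mean", "MAPE_cv_sd")
                  %in% names(rs$metrics)))
  inf <- rs$metrics[rs$metrics$set == "informative", ]
  bl <- rs$metrics[rs$metrics$set == "blind", ]
  expect_gt(inf$R_cv_mean, bl$R_cv_mean)
  expect_s3_class(rs$best_model, "mlp_calibration")
})

test_that("model JSON serialisation restores identical predictions", {
  set.seed(35)
  X <- matrix(rnorm(200), 200, 1); colnames(X) <- "r0505"
  y <- X[, 1]^2 + 3
  m <- train_mlp(X, y, 1:160, 161:200, seed = 6)
  f <- tempfile(fileext = ".json")
  save_model_json(m, f)
  m2 <- load_model_json(f)
  expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-12)
})
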