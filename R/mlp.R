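#' Partition a reference table into calibration / cross-validation / validation
#'
#' Two fruit per origin are drawn at random and all their ROI rows form the
#' validation set (20% of a full factorial design). The remaining rows are
#' shuffled and split 65% / 15% of the *total* row count into calibration
#' and cross-validation. At the standard scale (6 origins x 10 fruit x 10
#' regions = 600 rows) this yields 390 / 90 / 120 rows.
#'
#' @param ref a reference table (full factorial over origin, fruit, region).
#' @param seed integer seed; the plan is deterministic per seed.
#' @param frac_calibration,frac_cross_validation fractions of the total row
#'   count; they must add to the non-validation share exactly (after
#'   rounding), else an error demands explicit fractions.
#' @param validation_fruit_per_origin fruit held out per origin (default 2).
#' @return An object of class `partition_plan`: list with
#'   `validation_fruit` (data.frame `origin, fruit`), `assignment` (factor
#'   per row: `calibration`, `cross_validation`, `validation`), `seed`.
#' @export
partition_dataset <- function(ref, seed = 1L,
                              frac_calibration = 0.65,
                              frac_cross_validation = 0.15,
                              validation_fruit_per_origin = 2L) {
  ref <- as.data.frame(ref)
  origins <- sort(unique(ref$origin))
  per_origin_fruit <- tapply(ref$fruit, ref$origin,
                             function(f) length(unique(f)))
  if (any(per_origin_fruit < validation_fruit_per_origin + 1)) {
    stop("every origin needs more than ", validation_fruit_per_origin,
         " fruit to hold some out for validation")
  }
  n <- nrow(ref)
  with_seed(seed, {
    val_fruit <- do.call(rbind, lapply(origins, function(o) {
      fr <- sort(unique(ref$fruit[ref$origin == o]))
      data.frame(origin = o,
                 fruit = sort(sample(fr, validation_fruit_per_origin)))
    }))
    is_val <- interaction(ref$origin, ref$fruit) %in%
      interaction(val_fruit$origin, val_fruit$fruit)
    n_cal <- round(frac_calibration * n)
    n_cv <- round(frac_cross_validation * n)
    n_rest <- sum(!is_val)
    if (n_cal + n_cv != n_rest) {
      stop("fractions (", frac_calibration, ", ", frac_cross_validation,
           ") of ", n, " rows give ", n_cal, " + ", n_cv,
           " != ", n_rest, " non-validation rows; use a design with the ",
           "standard 65/15/20 proportions or pass explicit fractions that ",
           "split the remainder exactly")
    }
    rest_idx <- sample(which(!is_val))
    assignment <- rep("validation", n)
    assignment[rest_idx[seq_len(n_cal)]] <- "calibration"
    assignment[rest_idx[n_cal + seq_len(n_cv)]] <- "cross_validation"
    structure(list(validation_fruit = val_fruit,
                   assignment = factor(assignment,
                                       levels = c("calibration",
                                                  "cross_validation",
                                                  "validation")),
                   seed = seed),
              class = "partition_plan")
  })
}

#' @export
print.partition_plan <- function(x, ...) {
  cat("partition_plan:", paste(names(table(x$assignment)),
                               table(x$assignment),
                               sep = " = ", collapse = ", "),
      "(seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

# forward pass of the 1-hidden-layer tanh network on standardized inputs;
# theta packs W1 (h x (p+1), bias last) then w2 (h+1, bias last)
mlp_unpack <- function(theta, p, h) {
  W1 <- matrix(theta[seq_len(h * (p + 1))], h, p + 1)
  w2 <- theta[h * (p + 1) + seq_len(h + 1)]
  list(W1 = W1, w2 = w2)
}

mlp_forward <- function(theta, Xb, h) {
  p <- ncol(Xb) - 1L
  w <- mlp_unpack(theta, p, h)
  Z <- tanh(Xb %*% t(w$W1))              # n x h
  drop(cbind(Z, 1) %*% w$w2)
}

# residuals and analytic Jacobian of residuals w.r.t. theta
mlp_jacobian <- function(theta, Xb, y, h) {
  p <- ncol(Xb) - 1L
  n <- nrow(Xb)
  w <- mlp_unpack(theta, p, h)
  A <- Xb %*% t(w$W1)
  Z <- tanh(A)
  yhat <- drop(cbind(Z, 1) %*% w$w2)
  r <- yhat - y
  dZ <- (1 - Z^2) * matrix(w$w2[seq_len(h)], n, h, byrow = TRUE)  # n x h
  J1 <- matrix(0, n, h * (p + 1))
  for (j in seq_len(h)) {
    J1[, (seq_len(p + 1) - 1) * h + j] <- dZ[, j] * Xb
  }
  J <- cbind(J1, Z, 1)
  list(r = r, J = J, yhat = yhat)
}

#' Train a replicate MLP calibration model
#'
#' One hidden layer of `n_hidden` tangent-sigmoid units and a linear output,
#' trained by full-batch Levenberg-Marquardt on the calibration split with
#' inputs and target z-scored on that split. After every epoch the
#' cross-validation MSE is monitored: training stops at the first of (i)
#' calibration MSE reaching `mse_goal`, (ii) `max_epochs`, (iii)
#' `max_val_fail` consecutive epochs without a new cross-validation
#' minimum, or (iv) damping overflow; the weights of the best
#' cross-validation epoch are restored. The nominal learning rate is kept
#' in the stored hyperparameters for configuration fidelity although LM
#' steps are governed by the damping parameter.
#'
#' @param X numeric matrix of reflectance at the selected wavelengths
#'   (named columns), all rows.
#' @param y target trait vector, all rows.
#' @param calibration,cross_validation row indices of the two training
#'   splits.
#' @param hyper list: `lr` (stored), `max_val_fail`, `mse_goal` (on the
#'   standardized target), `max_epochs`.
#' @param n_hidden hidden units (default 4).
#' @param seed integer seed for the weight initialisation; the same seed
#'   yields identical weights.
#' @return An object of class `mlp_calibration`.
#' @export
train_mlp <- function(X, y, calibration, cross_validation,
                      hyper = list(lr = 0.3, max_val_fail = 15L,
                                   mse_goal = 1e-4, max_epochs = 500L),
                      n_hidden = 4L, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 1, length(y) == nrow(X))
  hyper$lr <- hyper$lr %||% 0.3
  hyper$max_val_fail <- hyper$max_val_fail %||% 15L
  hyper$mse_goal <- hyper$mse_goal %||% 1e-4
  hyper$max_epochs <- hyper$max_epochs %||% 500L

  x_center <- colMeans(X[calibration, , drop = FALSE])
  x_scale <- apply(X[calibration, , drop = FALSE], 2, stats::sd)
  x_scale[x_scale == 0] <- 1
  y_center <- mean(y[calibration])
  y_scale <- stats::sd(y[calibration])
  if (y_scale == 0) stop("constant target on the calibration split")
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, `/`)
  ys <- (y - y_center) / y_scale

  p <- ncol(X); h <- n_hidden
  Xb_cal <- cbind(Xs[calibration, , drop = FALSE], 1)
  y_cal <- ys[calibration]
  Xb_cv <- cbind(Xs[cross_validation, , drop = FALSE], 1)
  y_cv <- ys[cross_validation]

  n_par <- h * (p + 1) + h + 1
  theta <- with_seed(seed, stats::runif(n_par, -0.5, 0.5))

  mse <- function(th, Xb, yv) mean((mlp_forward(th, Xb, h) - yv)^2)
  mu <- 1e-3
  best_cv <- Inf; best_theta <- theta; val_fail <- 0L
  stop_reason <- "max_epochs"
  epoch <- 0L
  cal_mse <- mse(theta, Xb_cal, y_cal)
  while (epoch < hyper$max_epochs) {
    epoch <- epoch + 1L
    jr <- mlp_jacobian(theta, Xb_cal, y_cal, h)
    g <- crossprod(jr$J, jr$r)
    Hm <- crossprod(jr$J)
    accepted <- FALSE
    while (mu <= 1e10) {
      delta <- tryCatch(
        solve(Hm + diag(mu, n_par), -g),
        error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- theta + drop(delta)
        cand_mse <- mse(cand, Xb_cal, y_cal)
        if (is.finite(cand_mse) && cand_mse < cal_mse) {
          theta <- cand; cal_mse <- cand_mse
          mu <- max(mu * 0.1, 1e-12)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * 10
    }
    if (!accepted) { stop_reason <- "mu_overflow"; break }
    if (!is.finite(cal_mse)) {
      stop("non-finite training loss at epoch ", epoch,
           " (seed ", seed, ")")
    }
    cv_mse <- mse(theta, Xb_cv, y_cv)
    if (cv_mse < best_cv - 1e-15) {
      best_cv <- cv_mse; best_theta <- theta; val_fail <- 0L
    } else {
      val_fail <- val_fail + 1L
      if (val_fail >= hyper$max_val_fail) {
        stop_reason <- "max_val_fail"; break
      }
    }
    if (cal_mse <= hyper$mse_goal) { stop_reason <- "mse_goal"; break }
  }
  structure(list(
    wavelengths = colnames(X) %||% paste0("x", seq_len(p)),
    n_hidden = h,
    theta = best_theta,
    scalers = list(x_center = x_center, x_scale = x_scale,
                   y_center = y_center, y_scale = y_scale),
    stopping = list(reason = stop_reason, epochs = epoch,
                    best_cv_mse = best_cv, optimizer = "levenberg_marquardt",
                    val_fail = val_fail),
    hyper = hyper, seed = seed,
    splits = list(calibration = calibration,
                  cross_validation = cross_validation)
  ), class = "mlp_calibration")
}

#' Predict from an MLP calibration model
#'
#' @param object an `mlp_calibration`.
#' @param newdata matrix with (at least) the model's wavelength columns.
#' @param ... unused.
#' @return Predictions in original target units.
#' @export
predict.mlp_calibration <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    missing <- setdiff(object$wavelengths, colnames(newdata))
    if (length(missing)) {
      stop("newdata lacks model wavelength(s): ",
           paste(missing, collapse = ", "))
    }
    newdata <- newdata[, object$wavelengths, drop = FALSE]
  } else if (ncol(newdata) != length(object$wavelengths)) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$wavelengths))
  }
  s <- object$scalers
  Xs <- sweep(sweep(newdata, 2, s$x_center), 2, s$x_scale, `/`)
  yhat_s <- mlp_forward(object$theta, cbind(Xs, 1), object$n_hidden)
  yhat_s * s$y_scale + s$y_center
}

#' @export
coef.mlp_calibration <- function(object, ...) {
  p <- length(object$wavelengths)
  w <- mlp_unpack(object$theta, p, object$n_hidden)
  rownames(w$W1) <- paste0("hidden", seq_len(object$n_hidden))
  colnames(w$W1) <- c(object$wavelengths, "bias")
  names(w$w2) <- c(paste0("hidden", seq_len(object$n_hidden)), "bias")
  w
}

#' @export
print.mlp_calibration <- function(x, ...) {
  cat("mlp_calibration:", length(x$wavelengths), "inputs (",
      paste(x$wavelengths, collapse = ", "), ") ->", x$n_hidden,
      "tanh units -> linear\n")
  cat("stopped:", x$stopping$reason, "after", x$stopping$epochs,
      "epochs; best cv MSE (std.)", signif(x$stopping$best_cv_mse, 4), "\n")
  invisible(x)
}

#' @export
summary.mlp_calibration <- function(object, ...) {
  print(object)
  cat("optimizer:", object$stopping$optimizer, "| seed:", object$seed, "\n")
  invisible(object)
}

#' Regression performance metrics
#'
#' Pearson correlation R, root mean square error in target units, and mean
#' absolute percentage error
#' `MAPE = mean(|yhat - y| / y) * 100` (targets must be strictly positive).
#'
#' @param y reference values.
#' @param yhat predictions.
#' @return list `R, RMSE, MAPE`.
#' @export
regression_metrics <- function(y, yhat) {
  if (any(y == 0)) stop("zero target value makes MAPE undefined")
  list(R = stats::cor(y, yhat),
       RMSE = sqrt(mean((yhat - y)^2)),
       MAPE = mean(abs(yhat - y) / abs(y)) * 100)
}

#' Evaluate an MLP calibration model on a data split
#'
#' @param model an `mlp_calibration`.
#' @param X,y data in original units.
#' @return list `R, RMSE, MAPE`.
#' @export
evaluate_model <- function(model, X, y) {
  regression_metrics(y, predict(model, X))
}

#' @export
residuals.mlp_calibration <- function(object, X, y, ...) {
  y - predict(object, X)
}

#' Train replicate models per wavelength set and pick the winner
#'
#' For every candidate wavelength set, `n_replicates` models are trained
#' from different weight initialisations and their calibration /
#' cross-validation (and optionally validation) metrics summarised as
#' mean +/- SD. The winning set has the highest mean cross-validation R
#' (ties: lower cross-validation RMSE, then MAPE); the returned model is
#' the winning set's replicate with the highest cross-validation R.
#'
#' @param wavelength_sets named list of character vectors of wavelength
#'   column names.
#' @param spectra full spectra matrix (all rows).
#' @param y trait vector (all rows).
#' @param plan a [partition_dataset()] plan.
#' @param n_replicates replicates per set (default 20).
#' @param hyper,n_hidden passed to [train_mlp()].
#' @param seed root seed; replicate r of set s trains with a seed derived
#'   from it.
#' @param evaluate_validation also report validation-stage metrics.
#' @return list with `best_model`, `best_set`, and `metrics` (data.frame:
#'   one row per set with mean/sd of R, RMSE, MAPE per stage and the
#'   replicate count).
#' @export
replicate_and_select <- function(wavelength_sets, spectra, y, plan,
                                 n_replicates = 20L,
                                 hyper = list(lr = 0.3, max_val_fail = 15L,
                                              mse_goal = 1e-4,
                                              max_epochs = 500L),
                                 n_hidden = 4L, seed = 1L,
                                 evaluate_validation = FALSE) {
  stopifnot(length(wavelength_sets) >= 1)
  if (is.null(names(wavelength_sets))) {
    names(wavelength_sets) <- vapply(wavelength_sets, paste,
                                     character(1), collapse = "+")
  }
  cal <- which(plan$assignment == "calibration")
  cv <- which(plan$assignment == "cross_validation")
  val <- which(plan$assignment == "validation")
  rows <- list(); models <- list()
  for (s in names(wavelength_sets)) {
    wls <- wavelength_sets[[s]]
    Xset <- spectra[, wls, drop = FALSE]
    reps <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      m <- tryCatch(
        train_mlp(Xset, y, cal, cv, hyper = hyper, n_hidden = n_hidden,
                  seed = derive_seed(seed, paste0(s, "#", r))),
        error = function(e) NULL)
      if (is.null(m)) next
      reps[[r]] <- list(
        model = m,
        cal = evaluate_model(m, Xset[cal, , drop = FALSE], y[cal]),
        cv = evaluate_model(m, Xset[cv, , drop = FALSE], y[cv]),
        val = if (evaluate_validation)
          evaluate_model(m, Xset[val, , drop = FALSE], y[val]) else NULL)
    }
    reps <- Filter(Negate(is.null), reps)
    if (!length(reps)) {
      rows[[s]] <- data.frame(set = s, failed = TRUE)
      next
    }
    grab <- function(stage, metric) {
      vapply(reps, function(x) x[[stage]][[metric]], numeric(1))
    }
    row <- data.frame(set = s, failed = FALSE, n_replicates = length(reps))
    suffix <- c(cal = "c", cv = "cv", val = "val")
    for (stage in c("cal", "cv", if (evaluate_validation) "val")) {
      for (metric in c("R", "RMSE", "MAPE")) {
        v <- grab(stage, metric)
        row[[paste0(metric, "_", suffix[stage], "_mean")]] <- mean(v)
        row[[paste0(metric, "_", suffix[stage], "_sd")]] <- stats::sd(v)
      }
    }
    rows[[s]] <- row
    cv_R <- grab("cv", "R")
    best_rep <- order(-cv_R, grab("cv", "RMSE"), grab("cv", "MAPE"))[1]
    models[[s]] <- reps[[best_rep]]$model
  }
  metrics <- do.call(rbind, lapply(rows, function(r) {
    if (isTRUE(r$failed)) {
      template <- rows[[which(!vapply(rows, function(z) isTRUE(z$failed),
                                      logical(1)))[1]]]
      for (cn in setdiff(names(template), names(r))) r[[cn]] <- NA
      r <- r[names(template)]
    }
    r
  }))
  rownames(metrics) <- NULL
  ok <- metrics[!metrics$failed, , drop = FALSE]
  if (!nrow(ok)) stop("all replicate trainings failed for every set")
  ord <- order(-ok$R_cv_mean, ok$RMSE_cv_mean, ok$MAPE_cv_mean)
  best_set <- ok$set[ord[1]]
  list(best_model = models[[best_set]], best_set = best_set,
       metrics = metrics)
}
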