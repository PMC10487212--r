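#' Flatten a hypercube to a pixels x bands matrix
#'
#' Row-major pixel ordering: matrix row `k` (0-based) holds the spectrum of
#' pixel `(k %/% cols, k %% cols)` (row, column; 0-based). Invertible via
#' [unflatten_image()].
#'
#' @param cube a [hypercube()].
#' @return Matrix with `r<wavelength>` column names and attributes
#'   `shape` (rows, cols) and `wavelengths`.
#' @export
flatten_hypercube <- function(cube) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  # row-major pixel order: transpose the spatial dims before unrolling
  flat <- matrix(aperm(cube$data, c(2, 1, 3)), d[1] * d[2], d[3])
  colnames(flat) <- sprintf("r%04d", round(cube$wavelengths))
  attr(flat, "shape") <- d[1:2]
  attr(flat, "wavelengths") <- cube$wavelengths
  flat
}

#' Restore a flattened per-pixel vector or matrix to image shape
#'
#' @param v vector of length rows*cols (row-major pixel order) or matrix
#'   with such rows stacked as columns.
#' @param shape c(rows, cols).
#' @return Matrix (rows x cols), or a rows x cols x k array for matrix `v`.
#' @export
unflatten_image <- function(v, shape) {
  rows <- shape[1]; cols <- shape[2]
  if (is.matrix(v)) {
    arr <- array(v, c(cols, rows, ncol(v)))
    return(aperm(arr, c(2, 1, 3)))
  }
  t(matrix(v, cols, rows))
}

# Otsu threshold: maximize between-class variance on a 256-bin histogram.
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  mids <- (br[-1] + br[-(n_bins + 1L)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  tot_w <- w[n_bins]; tot_m <- m[n_bins]
  w0 <- w[-n_bins]; w1 <- tot_w - w0
  m0 <- m[-n_bins] / pmax(w0, 1)
  m1 <- (tot_m - m[-n_bins]) / pmax(w1, 1)
  bcv <- w0 * w1 * (m0 - m1)^2
  bcv[w0 == 0 | w1 == 0] <- -Inf
  # the maximising bin is a plateau when the histogram has an empty gap;
  # take its midpoint so the threshold sits centrally in the gap
  peak <- which(bcv >= max(bcv) * (1 - 1e-12))
  mids[round(mean(range(peak)))]
}

#' Binary foreground mask for a slice image
#'
#' Separates the fruit-slice pixels (value 1) from the background (0),
#' either at a fixed threshold or by Otsu's method. With
#' `exclude_bright = TRUE` a second Otsu split is applied to the foreground
#' and the upper class (specularly bright fiducial screws) is removed,
#' keeping the mid-level slice class.
#'
#' @param image single-band image matrix (e.g. reflectance at one band).
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold threshold for `method = "fixed"`.
#' @param threshold_high optional fixed upper bound: pixels above it
#'   (specular fiducials) are dropped from the foreground.
#' @param exclude_bright drop the brightest Otsu class from the foreground
#'   (for scenes with a distinct bright level, e.g. background / slice /
#'   fiducial three-level images).
#' @return Logical matrix; errors if the foreground is empty.
#' @export
background_mask <- function(image, method = c("otsu", "fixed"),
                            threshold = NULL, threshold_high = NULL,
                            exclude_bright = FALSE) {
  method <- match.arg(method)
  stopifnot(is.matrix(image), all(is.finite(image)))
  thr <- if (method == "fixed") {
    if (is.null(threshold)) stop("method = 'fixed' needs a threshold")
    threshold
  } else {
    otsu_threshold(image)
  }
  fg <- image > thr
  if (!is.null(threshold_high)) fg <- fg & image < threshold_high
  if (exclude_bright && any(fg)) {
    thr2 <- otsu_threshold(image[fg])
    fg <- fg & image <= thr2
  }
  if (!any(fg)) stop("empty foreground after thresholding")
  fg
}

#' Pixel-wise composition prediction map
#'
#' Applies a calibration model to every pixel spectrum of a flattened
#' reflectance cube and reshapes to the raster, with background pixels set
#' to the `NA` sentinel (an explicit mask is kept rather than multiplying
#' by 0, so true zero predictions stay distinguishable from background).
#'
#' @param model an `mlp_calibration`.
#' @param flat flattened cube from [flatten_hypercube()] (needs the model's
#'   wavelength columns).
#' @param mask logical foreground matrix (from [background_mask()]).
#' @param shape c(rows, cols); defaults to `attr(flat, "shape")`.
#' @param composition trait name carried as metadata.
#' @return An object of class `distribution_map`: list with `values`
#'   (matrix, NA on background), `mask`, `composition`, `wavelengths`.
#' @export
predict_map <- function(model, flat, mask, shape = attr(flat, "shape"),
                        composition = "trait") {
  stopifnot(!is.null(shape))
  missing <- setdiff(model$wavelengths, colnames(flat))
  if (length(missing)) {
    stop("cube lacks model wavelength(s): ",
         paste(sub("^r0*", "", missing), collapse = ", "), " nm")
  }
  mask_flat <- as.vector(t(mask))          # row-major, matching flatten
  pred <- rep(NA_real_, nrow(flat))
  if (any(mask_flat)) {
    pred[mask_flat] <- predict(model,
                               flat[mask_flat, model$wavelengths,
                                    drop = FALSE])
  }
  values <- unflatten_image(pred, shape)
  structure(list(values = values, mask = mask, composition = composition,
                 wavelengths = model$wavelengths),
            class = "distribution_map")
}

#' @export
print.distribution_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat("distribution_map [", x$composition, "]: ",
      paste(dim(x$values), collapse = "x"), " px, ",
      sum(x$mask), " foreground px, range ",
      paste(signif(range(v, na.rm = TRUE), 4), collapse = " - "), "\n",
      sep = "")
  invisible(x)
}

#' @export
plot.distribution_map <- function(x, ...) {
  v <- x$values
  graphics::image(t(v[nrow(v):1, ]), useRaster = TRUE, axes = FALSE,
                  main = x$composition, ...)
  invisible(x)
}

#' Region-wise map errors against reference chemistry
#'
#' For each validation fruit and each ROI disc: the absolute percentage
#' difference between the map's mean prediction over the disc and the
#' wet-chemistry reference value. Summarised per region as mean +/- SD over
#' fruit.
#'
#' @param maps named list (one `distribution_map` per validation fruit).
#' @param roi_masks named list of labelled ROI masks aligned with `maps`.
#' @param ref reference table rows for those fruit; each map's name must be
#'   `"origin_fruit"` (e.g. `"3_7"`).
#' @param trait_col reference column to compare against.
#' @return list with `per_fruit` (fruit x region matrix of percentage
#'   errors) and `table` (data.frame `region, mean, sd, n`).
#' @export
regionwise_errors <- function(maps, roi_masks, ref,
                              trait_col = "mc_pct") {
  stopifnot(length(maps) == length(roi_masks),
            !is.null(names(maps)))
  ref <- as.data.frame(ref)
  regions <- 1:10
  per_fruit <- matrix(NA_real_, length(maps), length(regions),
                      dimnames = list(names(maps), regions))
  for (f in names(maps)) {
    key <- strsplit(f, "_")[[1]]
    rows <- ref[ref$origin == as.integer(key[1]) &
                  ref$fruit == as.integer(key[2]), ]
    m <- maps[[f]]; rm <- roi_masks[[f]]
    for (rg in regions) {
      idx <- rm == rg & m$mask
      if (!any(idx)) stop("ROI label ", rg, " missing for fruit ", f)
      pred <- mean(m$values[idx], na.rm = TRUE)
      actual <- rows[[trait_col]][rows$region == rg]
      per_fruit[f, as.character(rg)] <- abs(pred - actual) / actual * 100
    }
  }
  tab <- data.frame(region = regions,
                    mean = colMeans(per_fruit),
                    sd = apply(per_fruit, 2, stats::sd),
                    n = nrow(per_fruit))
  list(per_fruit = per_fruit, table = tab)
}

# compact letter display from a logical significance matrix (TRUE = the
# groups differ); insertion algorithm: start with one letter covering all
# groups, split any letter set containing a significant pair, absorb
# redundant sets.
letters_from_signif <- function(signif, group_names) {
  k <- nrow(signif)
  sets <- list(seq_len(k))
  pairs <- which(signif & upper.tri(signif), arr.ind = TRUE)
  if (nrow(pairs)) {
    for (q in seq_len(nrow(pairs))) {
      i <- pairs[q, 1]; j <- pairs[q, 2]
      for (s in seq_along(sets)) {
        if (i %in% sets[[s]] && j %in% sets[[s]]) {
          a <- setdiff(sets[[s]], i)
          b <- setdiff(sets[[s]], j)
          sets[[s]] <- a
          sets[[length(sets) + 1]] <- b
        }
      }
      # absorb sets contained in another
      keep <- rep(TRUE, length(sets))
      for (s in seq_along(sets)) {
        for (t in seq_along(sets)) {
          if (s != t && keep[t] &&
              all(sets[[s]] %in% sets[[t]]) &&
              (length(sets[[s]]) < length(sets[[t]]) || s > t)) {
            keep[s] <- FALSE
            break
          }
        }
      }
      sets <- sets[keep]
    }
  }
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  out <- vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
          collapse = "")
  }, character(1))
  stats::setNames(out, group_names)
}

#' Tukey HSD comparison of region-wise errors
#'
#' One-way ANOVA of the per-fruit errors over the ten regions followed by
#' Tukey's honestly-significant-difference pairwise comparisons
#' (Tukey-Kramer in the unbalanced case, as implemented by
#' [stats::TukeyHSD()]), summarised as a compact letter display: regions
#' sharing a letter do not differ at level `alpha`.
#'
#' @param per_fruit fruit x region error matrix (from
#'   [regionwise_errors()]), or a long data.frame with columns
#'   `error, region`.
#' @param alpha significance level (default 0.05).
#' @return list with `letters` (named per region), `anova_p`, `tukey`
#'   (the HSD table).
#' @export
tukey_regions <- function(per_fruit, alpha = 0.05) {
  if (is.matrix(per_fruit)) {
    long <- data.frame(
      error = as.vector(per_fruit),
      region = factor(rep(colnames(per_fruit) %||%
                            seq_len(ncol(per_fruit)),
                          each = nrow(per_fruit)),
                      levels = colnames(per_fruit) %||%
                        seq_len(ncol(per_fruit))))
  } else {
    long <- per_fruit
    long$region <- factor(long$region)
  }
  counts <- table(long$region)
  if (any(counts < 2)) stop("need >= 2 observations per region")
  groups <- levels(long$region)
  k <- length(groups)
  if (stats::var(long$error) == 0) {
    return(list(letters = stats::setNames(rep("a", k), groups),
                anova_p = NA_real_, tukey = NULL, degenerate = TRUE))
  }
  fit <- stats::aov(error ~ region, data = long)
  an_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  hsd <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$region
  signif <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  comp <- do.call(rbind, strsplit(rownames(hsd), "-"))
  for (q in seq_len(nrow(hsd))) {
    if (is.finite(hsd[q, "p adj"]) && hsd[q, "p adj"] < alpha) {
      signif[comp[q, 1], comp[q, 2]] <- TRUE
      signif[comp[q, 2], comp[q, 1]] <- TRUE
    }
  }
  list(letters = letters_from_signif(signif, groups),
       anova_p = an_p, tukey = hsd, degenerate = FALSE)
}

#' Histogram shape statistics of a distribution map
#'
#' Mean, skewness (standardized third central moment) and kurtosis
#' (standardized fourth central moment, non-excess convention: a normal
#' distribution scores 3) over the foreground pixels. With zero variance
#' the shape moments are reported as 0 and flagged.
#'
#' @param map a `distribution_map`.
#' @return list `mean, skewness, kurtosis, n, degenerate`.
#' @export
map_histogram_stats <- function(map) {
  v <- map$values[map$mask]
  v <- v[is.finite(v)]
  n <- length(v)
  if (n < 3) stop("need >= 3 foreground pixels")
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 == 0) {
    return(list(mean = m, skewness = 0, kurtosis = 0, n = n,
                degenerate = TRUE))
  }
  list(mean = m,
       skewness = mean((v - m)^3) / m2^1.5,
       kurtosis = mean((v - m)^4) / m2^2,
       n = n, degenerate = FALSE)
}
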