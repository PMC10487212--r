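#' White/dark reflectance calibration of a raw hypercube
#'
#' Converts raw counts to relative reflectance band by band:
#' `R = (I - B) / (W - B)` with the raw frame `I`, dark (black) reference
#' `B` and white reference `W`. Negative values (noise around zero
#' reflectance) are clipped to 0; values above 1 (white-reference
#' imperfection) are preserved. Both counts are reported in the result's
#' attributes.
#'
#' @param raw,white,black [hypercube()] frames of identical shape and
#'   wavelength axis.
#' @return A reflectance `hypercube` with attributes `n_clipped_negative`
#'   and `n_above_one`.
#' @export
calibrate_reflectance <- function(raw, white, black) {
  stopifnot(inherits(raw, "hypercube"), inherits(white, "hypercube"),
            inherits(black, "hypercube"))
  if (!identical(dim(raw$data), dim(white$data)) ||
      !identical(dim(raw$data), dim(black$data))) {
    stop("raw, white and black frames must have identical shapes")
  }
  if (max(abs(raw$wavelengths - white$wavelengths)) > 1e-9 ||
      max(abs(raw$wavelengths - black$wavelengths)) > 1e-9) {
    stop("raw, white and black frames must share one wavelength axis")
  }
  denom <- white$data - black$data
  band_ok <- apply(denom > 0, 3, all)
  if (!all(band_ok)) {
    stop("white <= black (saturated or swapped references) at band(s) ",
         paste(format(raw$wavelengths[!band_ok]), collapse = ", "), " nm")
  }
  R <- (raw$data - black$data) / denom
  n_neg <- sum(R < 0)
  n_hi <- sum(R > 1)
  R[R < 0] <- 0
  out <- hypercube(R, raw$wavelengths, raw$sensor_id, "reflectance")
  attr(out, "n_clipped_negative") <- n_neg
  attr(out, "n_above_one") <- n_hi
  out
}

# Savitzky-Golay smoothing of one or more spectra (rows) with mirror
# padding, so output length equals input length and interior points of a
# degree <= poly_order polynomial are reproduced exactly.
#' Savitzky-Golay smoothing of spectra
#'
#' Applies the central Savitzky-Golay convolution (coefficients from
#' `signal::sgolay`) along the wavelength axis with mirror padding at the
#' ends.
#'
#' @param spectra numeric vector (one spectrum) or matrix with spectra in
#'   rows.
#' @param window_len odd window length in grid points (default 11, i.e.
#'   55 nm on the 5 nm grid).
#' @param poly_order fitted polynomial order (default 2), `< window_len`.
#' @return Smoothed object of the same shape.
#' @export
smooth_savitzky_golay <- function(spectra, window_len = 11L,
                                  poly_order = 2L) {
  if (window_len %% 2 != 1) stop("window_len must be odd")
  if (poly_order >= window_len) stop("poly_order must be < window_len")
  vec <- is.null(dim(spectra))
  X <- if (vec) matrix(spectra, 1) else as.matrix(spectra)
  p <- ncol(X)
  if (window_len > p) {
    stop("window (", window_len, ") exceeds spectrum length (", p, ")")
  }
  h <- (window_len - 1L) / 2L
  coefs <- signal::sgolay(p = poly_order, n = window_len)[h + 1L, ]
  pad_idx <- c((h + 1L):2L, 1:p, (p - 1L):(p - h))   # mirror padding
  Xp <- X[, pad_idx, drop = FALSE]
  out <- matrix(0, nrow(X), p)
  for (k in seq_len(window_len)) {
    out <- out + coefs[k] * Xp[, k:(k + p - 1L), drop = FALSE]
  }
  dimnames(out) <- dimnames(X)
  if (vec) drop(out) else out
}

#' Trim a spectral axis to the well-behaved range
#'
#' Drops bands below `lo` or above `hi` (default 420-1600 nm, the range
#' outside which edge noise dominates), preserving band order.
#'
#' @param x a [hypercube()] or a matrix of spectra with wavelengths as
#'   column names (`r0420` style or plain numbers) or supplied via
#'   `wavelengths`.
#' @param lo,hi inclusive limits in nm.
#' @param wavelengths optional nm vector for matrix input.
#' @return Object of the same kind, trimmed. For matrix input the trimmed
#'   wavelength vector is attached as attribute `wavelengths`.
#' @export
trim_spectral_range <- function(x, lo = 420, hi = 1600, wavelengths = NULL) {
  if (inherits(x, "hypercube")) {
    keep <- x$wavelengths >= lo & x$wavelengths <= hi
    if (!any(keep)) stop("no bands inside [", lo, ", ", hi, "] nm")
    out <- hypercube(x$data[, , keep, drop = FALSE], x$wavelengths[keep],
                     x$sensor_id, x$frame_kind)
    return(out)
  }
  X <- as.matrix(x)
  wl <- wavelengths %||% spectra_wavelengths(X)
  keep <- wl >= lo & wl <= hi
  if (!any(keep)) stop("no bands inside [", lo, ", ", hi, "] nm")
  out <- X[, keep, drop = FALSE]
  attr(out, "wavelengths") <- wl[keep]
  out
}

spectra_wavelengths <- function(X) {
  wl <- attr(X, "wavelengths")
  if (!is.null(wl)) return(wl)
  cn <- colnames(X)
  if (is.null(cn)) stop("cannot infer wavelengths: no column names")
  as.numeric(sub("^r0*", "", cn))
}

#' Fuse visible and NIR spectra onto the common 420-1600 nm grid
#'
#' Interpolates both sensors' spectra linearly onto the 5 nm grid from
#' 420 to 1600 nm and takes the visible sensor below the `boundary`
#' (default 1000 nm) and the NIR sensor at and above it; no multiplicative
#' scale matching is applied (plain integration of the two ranges). In the
#' 860-1000 nm overlap the visible sensor is used exclusively.
#'
#' @param vis_spectra,nir_spectra matrices (spectra in rows) with
#'   wavelengths in column names or `attr(,"wavelengths")`.
#' @param boundary sensor switch wavelength in nm.
#' @param grid_step output grid step in nm.
#' @param lo,hi output grid limits in nm.
#' @return Matrix of fused spectra with columns named `r0420`..`r1600` and
#'   attributes `wavelengths` and `source` (per-band sensor bookkeeping).
#' @export
fuse_sensors <- function(vis_spectra, nir_spectra, boundary = 1000,
                         grid_step = 5, lo = 420, hi = 1600) {
  Xv <- as.matrix(vis_spectra); Xn <- as.matrix(nir_spectra)
  if (nrow(Xv) != nrow(Xn)) stop("sensor tables have different row counts")
  wv <- spectra_wavelengths(Xv); wn <- spectra_wavelengths(Xn)
  grid <- seq(lo, hi, by = grid_step)
  vis_part <- grid < boundary
  if (min(wv) > lo || max(wv) < max(grid[vis_part])) {
    stop("VIS sensor does not cover [", lo, ", ", boundary, ") nm")
  }
  if (min(wn) > boundary || max(wn) < hi) {
    stop("NIR sensor does not cover [", boundary, ", ", hi, "] nm")
  }
  interp_rows <- function(X, w, to) {
    t(apply(X, 1, function(s) stats::approx(w, s, xout = to)$y))
  }
  out <- matrix(NA_real_, nrow(Xv), length(grid))
  out[, vis_part] <- interp_rows(Xv, wv, grid[vis_part])
  out[, !vis_part] <- interp_rows(Xn, wn, grid[!vis_part])
  colnames(out) <- sprintf("r%04d", grid)
  rownames(out) <- rownames(Xv)
  attr(out, "wavelengths") <- grid
  attr(out, "source") <- ifelse(vis_part, "vis", "nir")
  out
}

#' Mean ROI spectra from a reflectance hypercube
#'
#' Bins the pixels of each labelled ROI disc to its arithmetic mean
#' spectrum, the spectral signature paired with that region's wet-chemistry
#' reference values.
#'
#' @param cube a reflectance [hypercube()].
#' @param roi_mask integer matrix of the cube's spatial shape with labels
#'   `1..k` on ROI pixels and 0 elsewhere.
#' @param expected_labels optional label vector that must all be present
#'   (error names any empty label).
#' @return Matrix (k x bands) of mean spectra, rows named by label, columns
#'   `r<wavelength>`; attribute `pixel_count` records the binned pixel
#'   count per label, attribute `wavelengths` the band axis.
#' @export
extract_roi_mean_spectra <- function(cube, roi_mask, expected_labels = NULL) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  if (!all(dim(roi_mask) == d[1:2])) {
    stop("roi_mask shape does not match the cube's spatial shape")
  }
  labels <- sort(unique(as.integer(roi_mask[roi_mask > 0])))
  if (!length(labels)) stop("roi_mask contains no labels")
  if (!is.null(expected_labels)) {
    absent <- setdiff(expected_labels, labels)
    if (length(absent)) {
      stop("ROI label(s) ", paste(absent, collapse = ", "),
           " have no pixels in the mask")
    }
    labels <- sort(expected_labels)
  }
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  out <- matrix(NA_real_, length(labels), d[3])
  counts <- integer(length(labels))
  for (i in seq_along(labels)) {
    idx <- which(as.vector(roi_mask) == labels[i])
    if (!length(idx)) stop("ROI label ", labels[i], " has no pixels")
    counts[i] <- length(idx)
    out[i, ] <- colMeans(flat[idx, , drop = FALSE])
  }
  rownames(out) <- labels
  colnames(out) <- sprintf("r%04d", round(cube$wavelengths))
  attr(out, "wavelengths") <- cube$wavelengths
  attr(out, "pixel_count") <- stats::setNames(counts, labels)
  out
}
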