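#' Default forward optics model linking chemistry to reflectance
#'
#' A linear Gaussian-band reflectance model: reflectance at wavelength
#' \eqn{\lambda} is a smooth baseline plus, per trait, a sum of Gaussian
#' absorption/reflection bands scaled by the trait's deviation from its
#' pooled reference level. Band placement follows the known chromophores and
#' overtones of fruit flesh: carotenoid absorption in the blue-green
#' (negative carotenoid band near 505 nm; the displaced water fraction makes
#' the moisture response positive near 490 nm and the sugar response
#' negative near 489 nm), the second OH overtone of water near 960 nm, sugar
#' and organic-acid CH2 combination bands near 1215/1240 nm, and the first
#' OH overtone near 1425 nm. Amplitudes are per unit trait deviation
#' (z-scored internally by `scale`), signed so that the reflectance-trait
#' correlations at the visible bands have the conventional signs (moisture
#' positive near 490-500 nm, soluble solids negative near 485-495 nm,
#' carotenoids negative near 505-510 nm).
#'
#' @param noise_frac raw-frame Gaussian noise SD as a fraction of the white
#'   level (default 0.01); inflated x5 outside 420-1600 nm to emulate the
#'   poor photon sensitivity at the sensor edges.
#' @param bands optional replacement band table: named list (`mc, ssc, ta,
#'   cc`) of data.frames with columns `center` (nm), `width` (nm), `amp`
#'   (reflectance per SD of the trait; sign included). Traits may have
#'   zero-row tables (no spectral coupling). Used to construct controlled
#'   scenes, e.g. a trait coupled to a single known band.
#' @return An object of class `optics_model`.
#' @export
optics_model <- function(noise_frac = 0.01, bands = NULL) {
  default_bands <- list(
    mc = data.frame(center = c(492, 960, 1425), width = c(15, 40, 40),
                    amp = c(0.060, -0.050, -0.060)),
    ssc = data.frame(center = c(489, 1215), width = c(12, 25),
                     amp = c(-0.050, -0.040)),
    ta = data.frame(center = c(512, 1240), width = c(15, 25),
                    amp = c(0.030, 0.035)),
    cc = data.frame(center = c(506, 1425), width = c(12, 30),
                    amp = c(-0.060, 0.020))
  )
  if (is.null(bands)) bands <- default_bands
  # pooled reference levels and scales (z-scoring of trait deviations)
  pm <- pooled_moments(origin_chemistry_defaults())
  ref_levels <- colMeans(pm$means)
  ref_scales <- sqrt(pm$total_var)
  structure(list(bands = bands, ref_levels = ref_levels,
                 ref_scales = ref_scales, noise_frac = noise_frac,
                 edge_inflation = 5, background_reflectance = 0.02,
                 fiducial_reflectance = 0.95),
            class = "optics_model")
}

# Smooth baseline reflectance of fruit flesh: high VIS-NIR plateau with a
# mild blue falloff and water-related dips.
optics_baseline <- function(wavelengths) {
  0.55 - 0.12 * exp(-((wavelengths - 430) / 60)^2) -
    0.08 * exp(-((wavelengths - 1450) / 90)^2) +
    0.03 * sin(wavelengths / 300)
}

# Per-trait spectral response (reflectance change per 1 SD of the trait).
optics_response <- function(optics, trait, wavelengths) {
  b <- optics$bands[[trait]]
  resp <- numeric(length(wavelengths))
  for (i in seq_len(nrow(b))) {
    resp <- resp + b$amp[i] * exp(-((wavelengths - b$center[i])^2) /
                                    (2 * b$width[i]^2))
  }
  resp
}

#' Forward-model reflectance spectra from trait values
#'
#' @param optics an [optics_model()].
#' @param chem named list or data.frame with elements/columns
#'   `mc, ssc, ta, cc` (vectors of equal length n).
#' @param wavelengths nm vector.
#' @return n x length(wavelengths) matrix of reflectance in `[0, 1.2]`.
#' @export
forward_reflectance <- function(optics, chem, wavelengths) {
  n <- length(chem$mc)
  R <- matrix(rep(optics_baseline(wavelengths), each = n), n,
              length(wavelengths))
  for (t in c("mc", "ssc", "ta", "cc")) {
    z <- (chem[[t]] - optics$ref_levels[t]) / optics$ref_scales[t]
    R <- R + outer(z, optics_response(optics, t, wavelengths))
  }
  pmin(pmax(R, 0), 1.2)
}

#' Sensor wavelength grids of the two imaging units
#'
#' The visible/short-wave unit spans 380-1000 nm and the NIR unit
#' 860-1690 nm, both on a 5 nm grid.
#'
#' @param sensor `"vis"` or `"nir"`.
#' @return nm vector.
#' @export
sensor_grid <- function(sensor = c("vis", "nir")) {
  sensor <- match.arg(sensor)
  if (sensor == "vis") seq(380, 1000, by = 5) else seq(860, 1690, by = 5)
}

#' Generate a raw hypercube (plus white/black reference frames)
#'
#' Renders the slice scene through the forward optics model on the sensor's
#' native grid and converts reflectance to raw counts:
#' `I = B0 + R * (W0 - B0)` with spatially uniform white level `W0(lambda)`
#' and dark level `B0`. Independent Gaussian noise (SD =
#' `noise_frac * W0`, x`edge_inflation` outside 420-1600 nm) is added to the
#' raw, white and black frames, so white/dark calibration of a noiseless
#' cube recovers the forward-model reflectance exactly. Fiducial screws are
#' painted at high reflectance; background at low reflectance.
#'
#' @param field a [generate_chemistry_field()] result.
#' @param optics an [optics_model()].
#' @param sensor `"vis"` or `"nir"`.
#' @param seed integer seed.
#' @param noise_frac overrides the optics model's noise fraction if given
#'   (0 for a noiseless cube).
#' @return list with `raw`, `white`, `black` hypercubes (see [hypercube()]).
#' @export
generate_hypercube <- function(field, optics = optics_model(),
                               sensor = c("vis", "nir"), seed = 1L,
                               noise_frac = NULL) {
  sensor <- match.arg(sensor)
  wl <- sensor_grid(sensor)
  nf <- noise_frac %||% optics$noise_frac
  layout <- field$layout
  rows <- layout$shape[1]; cols <- layout$shape[2]
  npx <- rows * cols

  chem <- lapply(field$fields, as.vector)
  R <- forward_reflectance(optics, chem, wl)       # npx x bands
  bg <- !as.vector(layout$mask)
  R[bg, ] <- optics$background_reflectance
  fid <- rep(FALSE, npx)
  for (i in seq_len(nrow(layout$fiducials))) {
    f <- layout$fiducials[i, ]
    fid <- fid | as.vector((layout$xg - f$x)^2 + (layout$yg - f$y)^2 <= f$r^2)
  }
  R[fid, ] <- optics$fiducial_reflectance

  W0 <- 1000 * (0.9 + 0.1 * exp(-((wl - 800) / 400)^2))  # counts
  B0 <- rep(50, length(wl))
  I <- sweep(sweep(R, 2, W0 - B0, `*`), 2, B0, `+`)
  Wf <- matrix(rep(W0, each = npx), npx)
  Bf <- matrix(rep(B0, each = npx), npx)

  if (nf > 0) {
    with_seed(seed, {
      sdv <- nf * W0
      edge <- wl < 420 | wl > 1600
      sdv[edge] <- sdv[edge] * optics$edge_inflation
      for (b in seq_along(wl)) {
        I[, b] <- I[, b] + stats::rnorm(npx, 0, sdv[b])
        Wf[, b] <- Wf[, b] + stats::rnorm(npx, 0, sdv[b])
        Bf[, b] <- Bf[, b] + stats::rnorm(npx, 0, sdv[b])
      }
    })
  }
  to_cube <- function(m, kind) {
    hypercube(array(m, c(rows, cols, length(wl))), wl, sensor, kind)
  }
  list(raw = to_cube(I, "raw"), white = to_cube(Wf, "white"),
       black = to_cube(Bf, "black"))
}

#' Construct a hypercube object
#'
#' A hypercube is a rows x cols x bands reflectance or raw-count array with
#' a strictly increasing wavelength axis, a sensor id and a frame kind.
#'
#' @param data 3-D numeric array (rows x cols x bands).
#' @param wavelengths nm vector, length = band count, strictly increasing.
#' @param sensor_id character sensor label.
#' @param frame_kind one of `"raw"`, `"white"`, `"black"`, `"reflectance"`.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths, sensor_id = "vis",
                      frame_kind = c("raw", "white", "black", "reflectance")) {
  frame_kind <- match.arg(frame_kind)
  stopifnot(length(dim(data)) == 3L)
  if (dim(data)[3] != length(wavelengths)) {
    stop("band count (", dim(data)[3], ") != wavelength count (",
         length(wavelengths), ")")
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  structure(list(data = data, wavelengths = as.numeric(wavelengths),
                 sensor_id = sensor_id, frame_kind = frame_kind),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("hypercube [%s, %s]: %d x %d px, %d bands (%g-%g nm)\n",
              x$sensor_id, x$frame_kind, d[1], d[2], d[3],
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}
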