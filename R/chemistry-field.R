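#' Lay out slice geometry for a raster
#'
#' Computes the circular slice foreground, the ten 18-mm ROI disc centers
#' (two columns of five along the stem axis, the row direction), and three
#' fiducial screw positions near the slice rim.
#'
#' @param raster_shape c(rows, cols) of the raster.
#' @param mm_per_px physical pixel pitch in mm (default 0.5, so the 18-mm
#'   cork-borer discs are 36 px across).
#' @param n_regions number of ROI discs (10 in the standard design).
#' @return A list with `mask` (logical matrix), `centers` (data.frame
#'   `region,x,y,r` in 0-based pixel coordinates, x = column, y = row),
#'   `fiducials` (data.frame `x,y,r`), `mm_per_px`, `shape`.
#' @export
slice_layout <- function(raster_shape = c(256L, 256L), mm_per_px = 0.5,
                         n_regions = 10L) {
  rows <- raster_shape[1]; cols <- raster_shape[2]
  cy <- (rows - 1) / 2; cx <- (cols - 1) / 2
  slice_r <- 0.45 * min(rows, cols)
  roi_r <- 9 / mm_per_px                   # 18 mm diameter discs
  unit <- 0.156 * min(rows, cols)
  if (n_regions != 10L) stop("the standard design uses 10 ROI discs")
  # two columns of five, the row (y) direction is the stem axis
  grid <- expand.grid(kx = c(-1, 1), ky = -2:2)
  centers <- data.frame(
    region = seq_len(n_regions),
    x = cx + grid$kx * unit,
    y = cy + grid$ky * unit
  )
  centers$r <- roi_r
  # feasibility: discs inside the slice and pairwise disjoint
  d_center <- sqrt((centers$x - cx)^2 + (centers$y - cy)^2)
  if (any(d_center + roi_r > slice_r) || 2 * roi_r > unit * 2) {
    stop("raster too small to fit 10 disjoint 18 mm discs at ",
         mm_per_px, " mm/px; increase raster_shape or mm_per_px")
  }
  dd <- as.matrix(stats::dist(centers[, c("x", "y")]))
  diag(dd) <- Inf
  if (min(dd) < 2 * roi_r) {
    stop("ROI discs overlap; raster too small for the layout")
  }
  xg <- matrix(rep(0:(cols - 1), each = rows), rows, cols)
  yg <- matrix(rep(0:(rows - 1), times = cols), rows, cols)
  mask <- (xg - cx)^2 + (yg - cy)^2 <= slice_r^2
  ang <- c(-2.35, 0, 2.35)                  # screws near the rim, off the ROIs
  fid <- data.frame(
    x = cx + 0.88 * slice_r * sin(ang),
    y = cy - 0.88 * slice_r * cos(ang),
    r = max(2, 2 / mm_per_px)
  )
  list(mask = mask, centers = centers[, c("region", "x", "y", "r")],
       fiducials = fid, mm_per_px = mm_per_px, shape = c(rows, cols),
       slice_center = c(x = cx, y = cy), slice_r = slice_r, xg = xg, yg = yg)
}

roi_disc_index <- function(layout, i) {
  c0 <- layout$centers[i, ]
  which((layout$xg - c0$x)^2 + (layout$yg - c0$y)^2 <= c0$r^2)
}

#' Generate smooth per-trait chemistry fields for one fruit slice
#'
#' Builds, for each trait, a smooth 2-D field over the slice raster whose
#' mean over every ROI disc equals the corresponding reference-table value
#' exactly (to solver precision). The field is a linear combination of wide
#' Gaussian bumps centered on the ROI discs plus an optional axial
#' (stem-axis) linear trend; the bump coefficients are solved from the
#' 10x10 linear system of disc-average constraints, so re-extracting disc
#' means reproduces the inputs. This mimics the within-slice maturity
#' gradient: feed it ROI values that rise along the axis and the field rises
#' along the axis.
#'
#' @param ref_rows reference-table rows for one fruit (one per region,
#'   regions 1..10).
#' @param raster_shape,mm_per_px raster geometry, see [slice_layout()].
#' @param gradient named list of per-trait axial slopes (trait units per
#'   raster height) added as a background trend, e.g. `list(ssc = 2)`;
#'   disc-mean constraints still hold exactly.
#' @param seed unused randomness hook kept for interface uniformity (the
#'   field construction is deterministic).
#' @return An object of class `chemistry_field`: list with `fields` (named
#'   list of matrices, traits `mc, ssc, ta, cc`), `layout`, `ref_rows`.
#' @export
generate_chemistry_field <- function(ref_rows,
                                     raster_shape = c(256L, 256L),
                                     mm_per_px = 0.5,
                                     gradient = NULL,
                                     seed = NULL) {
  ref_rows <- as.data.frame(ref_rows)
  ref_rows <- ref_rows[order(ref_rows$region), ]
  if (!identical(as.integer(ref_rows$region), 1:10)) {
    stop("`ref_rows` must contain exactly regions 1..10 of one fruit")
  }
  layout <- slice_layout(raster_shape, mm_per_px)
  rows <- layout$shape[1]; cols <- layout$shape[2]
  n <- nrow(layout$centers)
  disc_idx <- lapply(seq_len(n), function(i) roi_disc_index(layout, i))

  # Gaussian bump basis, one per ROI center
  sigma <- 0.8 * 0.156 * min(rows, cols)
  basis <- lapply(seq_len(n), function(j) {
    c0 <- layout$centers[j, ]
    exp(-((layout$xg - c0$x)^2 + (layout$yg - c0$y)^2) / (2 * sigma^2))
  })
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) A[i, j] <- mean(basis[[j]][disc_idx[[i]]])
  }

  cy <- layout$slice_center["y"]
  axial <- (layout$yg - cy) / rows           # unit trend along the stem axis
  trait_cols <- trait_columns()
  fields <- list()
  for (t in names(trait_cols)) {
    v <- ref_rows[[trait_cols[t]]]
    slope <- if (!is.null(gradient[[t]])) gradient[[t]] else 0
    base <- mean(v) + slope * axial
    rhs <- v - vapply(disc_idx, function(ix) mean(base[ix]), numeric(1))
    a <- solve(A, rhs)
    f <- base
    for (j in seq_len(n)) f <- f + a[j] * basis[[j]]
    fields[[t]] <- f
  }
  structure(list(fields = fields, layout = layout, ref_rows = ref_rows),
            class = "chemistry_field")
}

#' Extract disc-mean trait values from a chemistry field
#'
#' The inverse of the constraint built into [generate_chemistry_field()]:
#' averages each trait field over each ROI disc.
#'
#' @param field a `chemistry_field`.
#' @return data.frame `region, mc_pct, ssc_pct, ta_gpct, cc_mg100gdm`.
#' @export
field_roi_means <- function(field) {
  layout <- field$layout
  n <- nrow(layout$centers)
  trait_cols <- trait_columns()
  out <- data.frame(region = layout$centers$region)
  for (t in names(trait_cols)) {
    out[[trait_cols[t]]] <- vapply(seq_len(n), function(i) {
      mean(field$fields[[t]][roi_disc_index(layout, i)])
    }, numeric(1))
  }
  out
}

#' @export
print.chemistry_field <- function(x, ...) {
  cat("chemistry_field:", paste(x$layout$shape, collapse = "x"),
      "raster at", x$layout$mm_per_px, "mm/px;",
      nrow(x$layout$centers), "ROI discs of r =",
      round(x$layout$centers$r[1], 1), "px\n")
  invisible(x)
}
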