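#' Detect circles by a gradient-vote Hough transform
#'
#' Circular Hough accumulator at 1 px radius resolution: edge pixels
#' (gradient magnitude above a quantile threshold) cast votes along and
#' against their gradient direction at each candidate radius; accumulator
#' scores are normalised by circumference so radii compete fairly. Peaks
#' are returned after non-maximum suppression with radius
#' `min(radius_range)`; ties are broken by larger accumulator value, then
#' smaller radius.
#'
#' @param image grayscale matrix.
#' @param radius_range integer vector `c(min, max)` of radii in px.
#' @param expected_count number of circles to return at most.
#' @param edge_quantile gradient-magnitude quantile (among nonzero gradients) used as the edge threshold.
#' @param score_min minimum normalised score (fraction of the circumference
#'   voting) for a detection to count.
#' @return data.frame `x, y, r, score` (0-based center coordinates,
#'   x = column), ranked by score; fewer than `expected_count` rows (with a
#'   warning) if too few circles score above `score_min`.
#' @export
detect_circles <- function(image, radius_range, expected_count = 10L,
                           edge_quantile = 0.5, score_min = 0.2) {
  stopifnot(is.matrix(image), length(radius_range) >= 2,
            all(radius_range > 0))
  rows <- nrow(image); cols <- ncol(image)
  radii <- seq(as.integer(min(radius_range)),
               as.integer(max(radius_range)), by = 1L)

  # central-difference gradients (x = column direction, y = row direction)
  gx <- matrix(0, rows, cols); gy <- matrix(0, rows, cols)
  gx[, 2:(cols - 1)] <- (image[, 3:cols] - image[, 1:(cols - 2)]) / 2
  gy[2:(rows - 1), ] <- (image[3:rows, ] - image[1:(rows - 2), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  pos <- mag[mag > 0]
  if (!length(pos)) {
    warning("no gradient structure in image; no circles detected")
    return(data.frame(x = numeric(0), y = numeric(0), r = numeric(0),
                      score = numeric(0)))
  }
  thr <- stats::quantile(pos, edge_quantile)
  edge <- which(mag >= thr)
  ey <- ((edge - 1) %% rows)          # 0-based row
  ex <- ((edge - 1) %/% rows)         # 0-based col
  ux <- gx[edge] / mag[edge]
  uy <- gy[edge] / mag[edge]

  acc_best <- matrix(0, rows, cols)
  acc_r <- matrix(NA_integer_, rows, cols)
  for (r in radii) {
    acc <- matrix(0L, rows, cols)
    for (s in c(-1, 1)) {                  # dark-on-bright and bright-on-dark
      cx <- round(ex + s * r * ux)
      cy <- round(ey + s * r * uy)
      ok <- cx >= 0 & cx < cols & cy >= 0 & cy < rows
      if (!any(ok)) next
      idx <- cy[ok] + 1L + cx[ok] * rows
      tab <- tabulate(idx, nbins = rows * cols)
      acc <- acc + matrix(tab, rows, cols)
    }
    # 3x3 box sum concentrates votes scattered by direction quantisation
    box <- acc + rbind(0, acc[-rows, ]) + rbind(acc[-1, ], 0)
    box <- box + cbind(0, box[, -cols]) + cbind(box[, -1], 0)
    score <- box / (2 * pi * r)
    better <- score > acc_best
    acc_best[better] <- score[better]
    acc_r[better] <- r
  }

  nms_r <- min(radii)
  found <- list()
  acc_work <- acc_best
  repeat {
    if (length(found) >= expected_count) break
    peak <- which.max(acc_work)
    sc <- acc_work[peak]
    if (!is.finite(sc) || sc < score_min) break
    py <- (peak - 1) %% rows
    px <- (peak - 1) %/% rows
    found[[length(found) + 1]] <- data.frame(
      x = px, y = py, r = acc_r[peak], score = sc)
    # suppress the neighbourhood
    y0 <- max(0, py - nms_r); y1 <- min(rows - 1, py + nms_r)
    x0 <- max(0, px - nms_r); x1 <- min(cols - 1, px + nms_r)
    acc_work[(y0:y1) + 1, (x0:x1) + 1] <- -Inf
  }
  out <- if (length(found)) do.call(rbind, found) else
    data.frame(x = numeric(0), y = numeric(0), r = numeric(0),
               score = numeric(0))
  if (nrow(out) < expected_count) {
    warning("only ", nrow(out), " of ", expected_count,
            " expected circles scored above ", score_min)
  }
  out[order(-out$score, out$r), , drop = FALSE]
}

#' Build a labelled ROI mask in the hypercube frame
#'
#' Maps circle centers from the detection frame into the hypercube frame
#' through `transform` and labels each disc by center distance
#' (`<= radius` after mapping the center). Discs are labelled 1..k in input
#' order; discs clipped by the image edge keep their in-image pixels and
#' the clipped pixel count is recorded.
#'
#' @param circles data.frame `x, y, r` (0-based, detection frame).
#' @param image_shape c(rows, cols) of the target (hypercube) raster.
#' @param transform a `transform2d` mapping detection frame -> hypercube
#'   frame (default identity).
#' @return Integer matrix of labels with attributes `centers` (mapped
#'   centers) and `clipped` (per-label count of off-image pixels).
#' @export
build_roi_mask <- function(circles, image_shape, transform = NULL) {
  rows <- image_shape[1]; cols <- image_shape[2]
  ctr <- as.matrix(circles[, c("x", "y")])
  if (!is.null(transform)) ctr <- apply_transform(transform, ctr)
  r <- circles$r
  k <- nrow(ctr)
  # overlap check on mapped centers
  if (k > 1) {
    dd <- as.matrix(stats::dist(ctr))
    pairs <- which(dd < outer(r, r, `+`) & upper.tri(dd), arr.ind = TRUE)
    if (nrow(pairs)) {
      stop("overlapping ROI discs after mapping: label pairs ",
           paste(apply(pairs, 1, paste, collapse = "-"), collapse = ", "))
    }
  }
  xg <- matrix(rep(0:(cols - 1), each = rows), rows, cols)
  yg <- matrix(rep(0:(rows - 1), times = cols), rows, cols)
  mask <- matrix(0L, rows, cols)
  clipped <- integer(k)
  for (i in seq_len(k)) {
    inside <- (xg - ctr[i, 1])^2 + (yg - ctr[i, 2])^2 <= r[i]^2
    mask[inside] <- i
    # full disc pixel count on an unbounded grid, for clipping bookkeeping
    gx <- seq(floor(ctr[i, 1] - r[i]), ceiling(ctr[i, 1] + r[i]))
    gy <- seq(floor(ctr[i, 2] - r[i]), ceiling(ctr[i, 2] + r[i]))
    full <- sum(outer(gy - ctr[i, 2], gx - ctr[i, 1],
                      function(a, b) a^2 + b^2) <= r[i]^2)
    clipped[i] <- full - sum(inside)
  }
  attr(mask, "centers") <- ctr
  attr(mask, "clipped") <- clipped
  mask
}

#' Order detected circles into the standard two-column region layout
#'
#' Region numbering follows the sampling pattern: two columns of five
#' discs, numbered left-right then top-bottom along the stem axis.
#'
#' @param circles data.frame `x, y, r`.
#' @return The same rows reordered and renumbered to regions 1..10.
#' @export
order_circles_as_regions <- function(circles) {
  stopifnot(nrow(circles) == 10)
  left <- circles$x < stats::median(circles$x)
  out <- NULL
  for (rowk in 1:5) {
    lefts <- circles[left, ][order(circles$y[left]), ]
    rights <- circles[!left, ][order(circles$y[!left]), ]
    out <- rbind(out, lefts[rowk, ], rights[rowk, ])
  }
  out$region <- 1:10
  rownames(out) <- NULL
  out
}
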