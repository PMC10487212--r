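#' Construct a planar transform
#'
#' Homogeneous 3x3 planar transforms of three nested families:
#' `nonreflective_similarity` (translation + rotation + isotropic scale),
#' `affine` (adds shear/anisotropy), `projective` (adds perspective).
#' Points are 0-based pixel coordinates, x = column, y = row; the transform
#' maps source-frame points to target-frame points.
#'
#' @param matrix 3x3 homogeneous matrix (last row `(0,0,1)` for the first
#'   two families).
#' @param kind transform family.
#' @return An object of class `transform2d`.
#' @export
transform2d <- function(matrix,
                        kind = c("nonreflective_similarity", "affine",
                                 "projective")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(matrix), all(dim(matrix) == c(3, 3)))
  if (abs(det(matrix)) < 1e-12) stop("transform matrix is singular")
  matrix <- matrix / matrix[3, 3]
  if (kind != "projective" &&
      any(abs(matrix[3, 1:2]) > 1e-9)) {
    stop("non-projective transforms must have bottom row (0, 0, 1)")
  }
  if (kind == "nonreflective_similarity") {
    A <- matrix[1:2, 1:2]
    if (abs(A[1, 1] - A[2, 2]) > 1e-6 * max(abs(A)) ||
        abs(A[1, 2] + A[2, 1]) > 1e-6 * max(abs(A))) {
      stop("similarity transform must have an equal-scale rotation block")
    }
  }
  structure(list(matrix = matrix, kind = kind), class = "transform2d")
}

#' Apply a planar transform to points
#'
#' @param transform a [transform2d()].
#' @param pts n x 2 matrix or data.frame of (x, y) points.
#' @return n x 2 matrix of mapped points.
#' @export
apply_transform <- function(transform, pts) {
  pts <- as.matrix(pts)[, 1:2, drop = FALSE]
  h <- cbind(pts, 1) %*% t(transform$matrix)
  h[, 1:2, drop = FALSE] / h[, 3]
}

#' Invert a planar transform
#'
#' @param transform a [transform2d()].
#' @return The inverse `transform2d` of the same kind.
#' @export
invert_transform <- function(transform) {
  transform2d(solve(transform$matrix), transform$kind)
}

min_pairs_for <- function(kind) {
  switch(kind, nonreflective_similarity = 2L, affine = 3L, projective = 4L)
}

collinear_all <- function(pts) {
  if (nrow(pts) < 3) return(FALSE)
  p <- sweep(as.matrix(pts), 2, colMeans(pts))
  sv <- svd(p)$d
  sv[2] < 1e-8 * max(sv[1], 1)
}

#' Fit a planar transform to control-point pairs
#'
#' Least-squares fit within the chosen family: the similarity and affine
#' fits are linear least squares on the matrix entries; the projective fit
#' is a normalized direct linear transform refined by Gauss-Newton on the
#' geometric (point-residual) error. With the minimum pair count and a
#' non-degenerate configuration the fit interpolates the pairs exactly.
#'
#' @param src n x 2 source-frame points (the distorted image).
#' @param dst n x 2 target-frame points (the reference image).
#' @param kind transform family, see [transform2d()].
#' @return A `transform2d` mapping `src` to `dst` in the least-squares sense.
#' @export
fit_transform <- function(src, dst,
                          kind = c("nonreflective_similarity", "affine",
                                   "projective")) {
  kind <- match.arg(kind)
  src <- as.matrix(src)[, 1:2, drop = FALSE]
  dst <- as.matrix(dst)[, 1:2, drop = FALSE]
  stopifnot(nrow(src) == nrow(dst))
  n <- nrow(src)
  if (n < min_pairs_for(kind)) {
    stop(kind, " needs at least ", min_pairs_for(kind), " point pairs, got ", n)
  }
  if (kind != "nonreflective_similarity" && collinear_all(src)) {
    stop("degenerate configuration: source points are collinear")
  }
  if (kind == "nonreflective_similarity" &&
      max(stats::dist(src)) < 1e-12) {
    stop("degenerate configuration: source points are coincident")
  }

  if (kind == "nonreflective_similarity") {
    # model: x' = a x - b y + tx ; y' = b x + a y + ty
    X <- rbind(cbind(src[, 1], -src[, 2], 1, 0),
               cbind(src[, 2], src[, 1], 0, 1))
    yv <- c(dst[, 1], dst[, 2])
    beta <- stats::lm.fit(X, yv)$coefficients
    M <- matrix(c(beta[1], -beta[2], beta[3],
                  beta[2], beta[1], beta[4],
                  0, 0, 1), 3, 3, byrow = TRUE)
    return(transform2d(M, kind))
  }
  if (kind == "affine") {
    X <- cbind(src, 1)
    beta <- stats::lm.fit(X, dst)$coefficients   # 3 x 2
    M <- rbind(t(beta), c(0, 0, 1))
    return(transform2d(M, kind))
  }
  # projective: normalized DLT
  norm_pts <- function(p) {
    ctr <- colMeans(p)
    sc <- sqrt(2) / mean(sqrt(rowSums(sweep(p, 2, ctr)^2)))
    Tn <- matrix(c(sc, 0, -sc * ctr[1], 0, sc, -sc * ctr[2], 0, 0, 1),
                 3, 3, byrow = TRUE)
    list(T = Tn, p = t(Tn %*% rbind(t(p), 1))[, 1:2])
  }
  ns <- norm_pts(src); nd <- norm_pts(dst)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- ns$p[i, 1]; y <- ns$p[i, 2]; u <- nd$p[i, 1]; v <- nd$p[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ] <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  sv <- svd(A, nv = 9)
  if (sv$d[8] < 1e-10 * sv$d[1]) {
    stop("degenerate configuration: points do not determine a projective map",
         " (three points collinear or coincident)")
  }
  H <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% H %*% ns$T
  H <- H / H[3, 3]
  if (n > 4) {
    # refine on geometric error; start from both the DLT solution and the
    # affine least-squares fit (a projective with zero perspective terms),
    # so the refined fit never does worse than the nested affine optimum
    obj <- function(par) {
      Hm <- matrix(c(par, 1), 3, 3, byrow = TRUE)
      pr <- cbind(src, 1) %*% t(Hm)
      sum((pr[, 1:2] / pr[, 3] - dst)^2)
    }
    Ha <- fit_transform(src, dst, "affine")$matrix
    starts <- list(as.vector(t(H))[1:8], as.vector(t(Ha))[1:8])
    fits <- lapply(starts, function(s0) {
      stats::optim(s0, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14))
    })
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
    H <- matrix(c(best$par, 1), 3, 3, byrow = TRUE)
  }
  transform2d(H, "projective")
}

#' Registration error metrics on control and check points
#'
#' RMSE pools the per-point Euclidean distances between mapped and target
#' points (pixels); MAPE pools the per-coordinate absolute percentage errors
#' `|mapped - target| / |target| * 100` over both coordinates of all points.
#'
#' @param transform a fitted `transform2d`.
#' @param control list/data.frame pair with `src`, `dst` control points.
#' @param check same structure for held-out check points (optional).
#' @return list with `kind`, `rmse_reg`, `mape_reg`, `rmse_chk`, `mape_chk`.
#' @export
registration_errors <- function(transform, control, check = NULL) {
  err <- function(src, dst) {
    if (is.null(src) || nrow(as.matrix(src)) == 0) {
      return(c(rmse = NA_real_, mape = NA_real_))
    }
    dst <- as.matrix(dst)[, 1:2, drop = FALSE]
    if (any(dst == 0)) {
      stop("zero target coordinate makes MAPE undefined; ",
           "offset the point frame away from the origin")
    }
    pred <- apply_transform(transform, src)
    d2 <- rowSums((pred - dst)^2)
    c(rmse = sqrt(mean(d2)),
      mape = mean(abs(pred - dst) / abs(dst)) * 100)
  }
  e_reg <- err(control$src, control$dst)
  e_chk <- if (is.null(check)) c(rmse = NA_real_, mape = NA_real_) else
    err(check$src, check$dst)
  list(kind = transform$kind,
       rmse_reg = unname(e_reg["rmse"]), mape_reg = unname(e_reg["mape"]),
       rmse_chk = unname(e_chk["rmse"]), mape_chk = unname(e_chk["mape"]))
}

#' Select the best transform family from registration reports
#'
#' Picks the family with the lowest check-point RMSE; ties are broken by
#' check-point MAPE, then by the family needing fewer control points
#' (similarity before affine before projective).
#'
#' @param reports list of [registration_errors()] results.
#' @return The `kind` string of the winning report.
#' @export
select_best_transform <- function(reports) {
  stopifnot(length(reports) >= 1)
  rmse <- vapply(reports, function(r) r$rmse_chk, numeric(1))
  mape <- vapply(reports, function(r) r$mape_chk, numeric(1))
  kinds <- vapply(reports, function(r) r$kind, character(1))
  need <- vapply(kinds, min_pairs_for, integer(1))
  ord <- order(rmse, mape, need)
  kinds[ord[1]]
}

#' @export
print.transform2d <- function(x, digits = 4, ...) {
  cat("transform2d [", x$kind, "]\n", sep = "")
  print(round(x$matrix, digits))
  invisible(x)
}
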