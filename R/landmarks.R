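#' Generate a distorted landmark scene for registration testing
#'
#' Renders the slice as it would appear in the post-extraction photograph:
#' a grayscale image in a distorted frame, with dark circular holes at the
#' ROI positions (where the cork borer removed tissue) and three bright
#' fiducial screws whose head slits carry the control landmarks. Each
#' screw contributes two slit-end control points (6 control per slice);
#' the three check points are the centers of three boreholes spread across
#' the slice (regions 1, 6 and 10), so the held-out points probe the fit
#' away from the control clusters. `true_transform` maps the distorted
#' frame to the reference (hypercube) frame; point pairs are exact
#' correspondences under it, plus optional isotropic Gaussian jitter on the
#' distorted-frame coordinates.
#'
#' @param field a [generate_chemistry_field()] result (supplies geometry).
#' @param true_transform a `transform2d` mapping distorted -> reference.
#' @param jitter_sd landmark localisation jitter SD in px (default 0.5).
#' @param seed integer seed for the jitter.
#' @return list with `image` (distorted-frame matrix in `[0,1]`), `points`
#'   (data.frame `frame, x, y, role, index` stacking both frames),
#'   `control` / `check` (lists with `src` distorted and `dst` reference
#'   matrices), and `true_transform`.
#' @export
generate_landmark_scene <- function(field, true_transform,
                                    jitter_sd = 0.5, seed = 1L) {
  layout <- field$layout
  rows <- layout$shape[1]; cols <- layout$shape[2]
  Tinv <- invert_transform(true_transform)

  # landmark geometry in the reference frame: slit of half-length ~ screw r
  fid <- layout$fiducials
  slit_ang <- c(0.4, 1.6, 2.9)
  ref_pts <- NULL
  roles <- character(0)
  for (i in seq_len(nrow(fid))) {
    u <- c(cos(slit_ang[i]), sin(slit_ang[i])) * fid$r[i] * 0.8
    ends <- rbind(c(fid$x[i], fid$y[i]) + u, c(fid$x[i], fid$y[i]) - u)
    ref_pts <- rbind(ref_pts, ends)
    roles <- c(roles, "control", "control")
  }
  chk <- as.matrix(layout$centers[c(1, 6, 10), c("x", "y")])
  ref_pts <- rbind(ref_pts, chk)
  dimnames(ref_pts) <- NULL
  roles <- c(roles, rep("check", 3))
  dist_pts <- apply_transform(Tinv, ref_pts)
  if (jitter_sd > 0) {
    with_seed(seed, {
      dist_pts <- dist_pts + matrix(stats::rnorm(length(dist_pts), 0,
                                                 jitter_sd),
                                    ncol = 2)
    })
  }

  # render the distorted image by sampling the reference-frame scene
  xg <- layout$xg; yg <- layout$yg
  ref_xy <- apply_transform(true_transform, cbind(as.vector(xg),
                                                  as.vector(yg)))
  ctr <- layout$slice_center
  inside <- (ref_xy[, 1] - ctr["x"])^2 + (ref_xy[, 2] - ctr["y"])^2 <=
    layout$slice_r^2
  img <- ifelse(inside, 0.55, 0.05)
  for (i in seq_len(nrow(layout$centers))) {
    c0 <- layout$centers[i, ]
    hole <- (ref_xy[, 1] - c0$x)^2 + (ref_xy[, 2] - c0$y)^2 <= c0$r^2
    img[hole] <- 0.08
  }
  for (i in seq_len(nrow(fid))) {
    scr <- (ref_xy[, 1] - fid$x[i])^2 + (ref_xy[, 2] - fid$y[i])^2 <=
      fid$r[i]^2
    img[scr] <- 0.95
  }
  img <- matrix(img, rows, cols)

  idx <- seq_len(nrow(ref_pts))
  points <- rbind(
    data.frame(frame = "distorted", x = dist_pts[, 1], y = dist_pts[, 2],
               role = roles, index = idx),
    data.frame(frame = "reference", x = ref_pts[, 1], y = ref_pts[, 2],
               role = roles, index = idx)
  )
  ctl <- roles == "control"
  list(image = img, points = points,
       control = list(src = dist_pts[ctl, , drop = FALSE],
                      dst = ref_pts[ctl, , drop = FALSE]),
       check = list(src = dist_pts[!ctl, , drop = FALSE],
                    dst = ref_pts[!ctl, , drop = FALSE]),
       true_transform = true_transform)
}

#' Write / read landmark point files
#'
#' CSV with columns `frame,x,y,role,index`; `role` is `control` or `check`.
#'
#' @param points the `points` data.frame of a landmark scene.
#' @param path file path.
#' @export
write_landmark_points <- function(points, path) {
  stopifnot(all(c("frame", "x", "y", "role", "index") %in% names(points)))
  utils::write.csv(points[c("frame", "x", "y", "role", "index")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_landmark_points
#' @export
read_landmark_points <- function(path) {
  pts <- utils::read.csv(path)
  need <- c("frame", "x", "y", "role", "index")
  missing <- setdiff(need, names(pts))
  if (length(missing)) {
    stop("landmark file is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- !pts$role %in% c("control", "check")
  if (any(bad)) {
    stop("invalid role at line(s) ", paste(which(bad) + 1, collapse = ", "),
         " (expected 'control' or 'check')")
  }
  pts
}

#' Split a landmark points table into fit-ready pairs
#'
#' @param points data.frame as read by [read_landmark_points()].
#' @return list with `control` and `check`, each `list(src, dst)` with the
#'   distorted frame as `src` and the reference frame as `dst`.
#' @export
landmark_pairs <- function(points) {
  grab <- function(role) {
    s <- points[points$frame == "distorted" & points$role == role, ]
    d <- points[points$frame == "reference" & points$role == role, ]
    s <- s[order(s$index), ]; d <- d[order(d$index), ]
    if (!identical(s$index, d$index)) {
      stop("unmatched ", role, " point indices between frames")
    }
    list(src = as.matrix(s[c("x", "y")]), dst = as.matrix(d[c("x", "y")]))
  }
  list(control = grab("control"), check = grab("check"))
}
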