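#' Graft placement deviation
#'
#' The experiment's independent variable: a rigid translation (mm, anatomical
#' L-R / A-P / I-S components), rotations (degrees, right-hand rule about the
#' L-R, A-P and I-S axes) and a uniform size scale of the graft relative to
#' its designed pose.
#'
#' @param translation_mm numeric length 3: (L-R, A-P, I-S) translation in mm.
#' @param rotation_deg numeric length 3: right-hand-rule angles (degrees)
#'   about the L-R, A-P, I-S axes.
#' @param scale unitless size factor (> 0); `scale < 1` is an undersized graft.
#' @return Object of class `deviation_spec`.
#' @export
deviation_spec <- function(translation_mm = c(0, 0, 0),
                           rotation_deg = c(0, 0, 0), scale = 1) {
  translation_mm <- as.numeric(translation_mm)
  rotation_deg <- as.numeric(rotation_deg)
  stopifnot(length(translation_mm) == 3L, length(rotation_deg) == 3L)
  if (!is.finite(scale) || scale <= 0) stop("deviation scale must be positive")
  structure(list(translation_mm = translation_mm, rotation_deg = rotation_deg,
                 scale = scale),
            class = "deviation_spec")
}

#' @export
print.deviation_spec <- function(x, ...) {
  cat(sprintf("<deviation> t=(%g, %g, %g) mm, r=(%g, %g, %g) deg, scale=%g\n",
              x$translation_mm[1], x$translation_mm[2], x$translation_mm[3],
              x$rotation_deg[1], x$rotation_deg[2], x$rotation_deg[3], x$scale))
  invisible(x)
}

is_zero_deviation <- function(dev) {
  all(dev$translation_mm == 0) && all(dev$rotation_deg == 0) && dev$scale == 1
}

rot_x <- function(a) rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
rot_y <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
rot_z <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))

# Intrinsic rotations in the order L-R (x), then A-P (y), then I-S (z).
deviation_rotation <- function(rotation_deg) {
  a <- rotation_deg * pi / 180
  rot_x(a[1]) %*% rot_y(a[2]) %*% rot_z(a[3])
}

# Inverse of deviation_rotation: angles (deg) from a rotation matrix, XYZ
# intrinsic convention. Flags gimbal degeneracy (middle angle near +/-90 deg).
euler_xyz_deg <- function(R) {
  b <- asin(max(-1, min(1, R[1, 3])))
  gimbal <- abs(cos(b)) < 1e-7
  if (gimbal) {
    a <- atan2(R[2, 1], R[2, 2])
    c <- 0
  } else {
    a <- atan2(-R[2, 3], R[3, 3])
    c <- atan2(-R[1, 2], R[1, 1])
  }
  list(angles_deg = c(a, b, c) * 180 / pi, gimbal = gimbal)
}

#' Apply a placement deviation to a designed graft
#'
#' Rigidly rotates the graft about the proximal anastomosis-plane center
#' (right-hand rule, intrinsic L-R then A-P then I-S), translates it, and
#' scales it uniformly about the same center. The anastomosis plane is
#' co-transformed exactly for the L-R translation component and for all
#' rotations (those shift the resection location), and left unchanged for the
#' A-P and I-S translation components (which slide the graft relative to a
#' fixed resection site).
#'
#' @param graft a [design_graft()] result.
#' @param plane the proximal anastomosis [cut_plane()].
#' @param dev a [deviation_spec()].
#' @return list with the transformed `graft` and `plane`.
#' @export
apply_deviation <- function(graft, plane, dev) {
  stopifnot(inherits(graft, "graft_model"), inherits(plane, "cut_plane"),
            inherits(dev, "deviation_spec"))
  if (dev$scale <= 0) stop("deviation scale must be positive")
  if (is_zero_deviation(dev)) return(list(graft = graft, plane = plane))
  ctr <- plane$origin
  R <- deviation_rotation(dev$rotation_deg)
  t <- dev$translation_mm
  g <- graft$surface
  g$nodes <- sweep(dev$scale * (sweep(g$nodes, 2, ctr) %*% t(R)), 2, ctr + t, `+`)
  graft$surface <- g
  # accumulated pose (rotation+translation+scale about the plane center)
  pose <- diag(4)
  pose[1:3, 1:3] <- dev$scale * R
  pose[1:3, 4] <- ctr + t - dev$scale * (R %*% ctr)
  graft$design_pose <- pose %*% graft$design_pose
  new_plane <- cut_plane(plane$origin + c(t[1], 0, 0),
                         drop(R %*% plane$normal),
                         plane$axes %*% t(R))
  list(graft = graft, plane = new_plane)
}

#' Deviation ranges from observed in-vivo placements
#'
#' For each axis (and for size), the sweep threshold range is the sample mean
#' of the observed deviations plus/minus two sample standard deviations,
#' covering the plausible spread of surgical imprecision.
#'
#' @param observed list of [deviation_spec()] objects (>= 2).
#' @return list with `translation` and `rotation` (3 x 2 matrices of lo/hi per
#'   axis, rows named LR/AP/IS) and `scale` (length-2 range).
#' @export
sample_deviation_thresholds <- function(observed) {
  if (!is.list(observed) || length(observed) < 2L)
    stop("need at least 2 observed deviations")
  tr <- t(vapply(observed, function(d) d$translation_mm, numeric(3)))
  ro <- t(vapply(observed, function(d) d$rotation_deg, numeric(3)))
  sc <- vapply(observed, function(d) d$scale, numeric(1))
  rng <- function(x) {
    m <- mean(x); s <- sd(x)
    c(m - 2 * s, m + 2 * s)
  }
  tr_r <- t(apply(tr, 2, rng)); ro_r <- t(apply(ro, 2, rng))
  dimnames(tr_r) <- dimnames(ro_r) <- list(c("LR", "AP", "IS"), c("lo", "hi"))
  list(translation = tr_r, rotation = ro_r, scale = rng(sc))
}
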