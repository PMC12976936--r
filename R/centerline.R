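#' Vessel centerline
#'
#' An ordered polyline through the lumen with a per-point radius, the
#' geometric substrate for lofted tube surfaces. All coordinates are in mm.
#'
#' @param points numeric matrix (n x 3) of ordered centerline coordinates (mm).
#' @param radii numeric vector of per-point lumen radii (mm), all positive.
#' @return An object of class `centerline` with fields `points`, `radii` and
#'   `arclength` (cumulative, starting at 0, strictly increasing).
#' @export
centerline <- function(points, radii) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) < 2L || ncol(points) != 3L)
    stop("centerline needs at least 2 points with 3 coordinates each")
  radii <- rep_len(as.numeric(radii), nrow(points))
  if (any(!is.finite(radii)) || any(radii <= 0))
    stop("centerline radii must be positive and finite")
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  if (any(seg <= 0)) stop("centerline points must be distinct and ordered")
  structure(list(points = points, radii = radii,
                 arclength = c(0, cumsum(seg))),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, length %.2f mm, radius %.2f-%.2f mm\n",
              nrow(x$points), max(x$arclength), min(x$radii), max(x$radii)))
  invisible(x)
}

total_arclength <- function(cl) max(cl$arclength)

# Linear interpolation of position / radius / tangent at arclength s.
centerline_point_at <- function(cl, s) {
  vapply(1:3, function(k) stats::approx(cl$arclength, cl$points[, k],
                                        xout = s, rule = 2)$y, numeric(length(s)))
}

centerline_radius_at <- function(cl, s) {
  stats::approx(cl$arclength, cl$radii, xout = s, rule = 2)$y
}

centerline_tangent_at <- function(cl, s) {
  i <- findInterval(s, cl$arclength, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(cl$points) - 1L)
  d <- cl$points[i + 1L, , drop = FALSE] - cl$points[i, , drop = FALSE]
  d / sqrt(rowSums(d^2))
}

# Resample to n points at even arclength spacing.
resample_centerline <- function(cl, n) {
  s <- seq(0, total_arclength(cl), length.out = n)
  centerline(centerline_point_at(cl, s), centerline_radius_at(cl, s))
}

# Rotation-minimizing frames along the centerline (double-reflection method).
# Avoids the twist flips Frenet frames produce at inflection points.
# Returns list(tangent, normal, binormal), each n x 3.
rmf_frames <- function(cl) {
  p <- cl$points
  n <- nrow(p)
  tg <- matrix(0, n, 3)
  tg[-n, ] <- p[-1L, ] - p[-n, ]
  tg[n, ] <- tg[n - 1L, ]
  tg <- tg / sqrt(rowSums(tg^2))
  # midpoint tangents for interior points
  for (i in 2:(n - 1L)) tg[i, ] <- unitize(p[i + 1L, ] - p[i - 1L, ])
  nor <- matrix(0, n, 3)
  seed <- c(0, 0, 1)
  if (abs(sum(seed * tg[1L, ])) > 0.9) seed <- c(1, 0, 0)
  nor[1L, ] <- unitize(seed - sum(seed * tg[1L, ]) * tg[1L, ])
  for (i in 1:(n - 1L)) {
    v1 <- p[i + 1L, ] - p[i, ]
    c1 <- sum(v1 * v1)
    rL <- nor[i, ] - (2 / c1) * sum(v1 * nor[i, ]) * v1
    tL <- tg[i, ] - (2 / c1) * sum(v1 * tg[i, ]) * v1
    v2 <- tg[i + 1L, ] - tL
    c2 <- sum(v2 * v2)
    ni <- if (c2 < .Machine$double.eps) rL else rL - (2 / c2) * sum(v2 * rL) * v2
    ni <- ni - sum(ni * tg[i + 1L, ]) * tg[i + 1L, ]
    nor[i + 1L, ] <- unitize(ni)
  }
  bi <- cbind(tg[, 2] * nor[, 3] - tg[, 3] * nor[, 2],
              tg[, 3] * nor[, 1] - tg[, 1] * nor[, 3],
              tg[, 1] * nor[, 2] - tg[, 2] * nor[, 1])
  list(tangent = tg, normal = nor, binormal = bi)
}
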