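# Shared fixtures, all built in code.

straight_cfg <- function(radius = 10, length = 100, n_circ = 24L,
                         n_axial = 40L, branches = 0L) {
  anatomy_config(arch_radius_mm = 0, arch_angle_deg = 0,
                 vessel_radius_profile = radius, branch_count = branches,
                 asc_length_mm = length / 2, desc_length_mm = length / 2,
                 n_circumferential = n_circ, n_axial = n_axial)
}

make_tube <- function(z0, z1, r = 8, n_circ = 16L, n_axial = 8L,
                      loop_names = c("bot", "top"), region = "tube") {
  cl <- centerline(cbind(0, 0, seq(z0, z1, length.out = n_axial + 1L)), r)
  loft_surface(cl, n_circ, n_axial, region = region, loop_names = loop_names)
}

# Two coaxial cylinders with an axial suture gap; native far end and graft
# far end clamped.
two_cylinder_assembly <- function(gap = 2, r = 8, n_circ = 16L, n_axial = 8L,
                                  graft_mult = 2.5, ...) {
  native <- make_tube(0, 30, r, n_circ, n_axial, c("n_bot", "n_top"))
  graft <- make_tube(30 + gap, 60 + gap, r, n_circ, n_axial,
                     c("g_bot", "g_top"), region = "TEVG")
  fe_assembly(native, graft,
              materials = list(native = yeoh_material(),
                               graft = yeoh_material(
                                 thickness = 0.7,
                                 stiffness_multiplier = graft_mult)),
              loop_pairs = list(c("g_bot", "n_top")),
              fixed_loops = c("n_bot", "g_top"), ...)
}

# A compact arch implantation case for pipeline-level tests.
small_case <- function(n_axial = 40L, n_circ = 12L, ...) {
  tevg_case(anatomy_config(n_axial = n_axial, n_circumferential = n_circ),
            n_stations = 40L, ...)
}

# Hand-built single-segment lumen profile (straight tube).
single_segment_profile <- function(r = 10, L = 100, n = 11L) {
  s <- seq(0, L, length.out = n)
  structure(list(trunk = list(stations = s, areas = rep(pi * r^2, n),
                              effective_radii = rep(r, n),
                              centers = cbind(0, 0, s),
                              segment = rep("trunk", n))),
            class = "lumen_profile")
}

# Profile with two identical branches taking off the trunk mid-station.
branched_profile <- function(r_trunk = 10, r_branch = 5, L = 100, n = 11L) {
  pr <- single_segment_profile(r_trunk, L, n)
  mid <- (n + 1L) %/% 2L
  sb <- seq(0, 30, length.out = 5L)
  br <- function(x0) list(stations = sb, areas = rep(pi * r_branch^2, 5L),
                          effective_radii = rep(r_branch, 5L),
                          centers = cbind(x0, 0, 50 + sb),
                          attach_station = mid)
  pr$branch_1 <- br(-20); pr$branch_2 <- br(20)
  pr
}

default_outlets <- function(profile) {
  out <- list(DAo = windkessel_params(Rp = 0.05, C = 0.1, Rd = 1))
  for (nm in grep("^branch_", names(profile), value = TRUE))
    out[[nm]] <- windkessel_params(Rp = 0.1, C = 0.05, Rd = 2)
  out
}

# Least-squares circle radius of an ordered ring of points (exact for a
# planar circle: mean distance to the centroid).
circle_fit_radius <- function(points) {
  ctr <- colMeans(points)
  mean(sqrt(rowSums(sweep(points, 2, ctr)^2)))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

norm3 <- function(v) sqrt(sum(v^2))

rot_z_test <- function(a) {
  rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
}

map_nodes_test <- function(m, f) { m$nodes <- f(m$nodes); m }

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
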