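test_that("identical clouds register to the identity", {
  set.seed(1)
  P <- matrix(rnorm(300), ncol = 3)
  tf <- register_rigid(P, P, "known")
  expect_lt(max(abs(tf$rotation - diag(3))), 1e-10)
  expect_lt(max(abs(tf$translation)), 1e-10)
})

test_that("known-correspondence registration recovers applied transforms", {
  set.seed(2)
  P <- matrix(rnorm(1500, sd = 20), ncol = 3)
  R <- rot_z_test(30 * pi / 180)
  Q <- sweep(P %*% t(R), 2, c(1, 2, 3), `+`)
  tf <- register_rigid(P, Q, "known")
  ang_err <- acos(pmin(1, (sum(diag(t(tf$rotation) %*% R)) - 1) / 2)) * 180 / pi
  expect_lt(ang_err, 0.01)
  expect_lt(max(abs(tf$translation - c(1, 2, 3))), 1e-6)
})

test_that("3-point registration beats a brute-force rotation search", {
  set.seed(3)
  S <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 7, 2))
  R <- random_rotation()
  TT <- sweep(S %*% t(R), 2, c(3, -2, 5), `+`)
  tf <- register_rigid(S, TT, "known")
  resid <- function(Rm) {
    tr <- colMeans(TT) - drop(Rm %*% colMeans(S))
    sum((sweep(S %*% t(Rm), 2, tr, `+`) - TT)^2)
  }
  # coarse brute-force search over an Euler grid
  best <- Inf
  for (a in seq(-pi, pi, length.out = 25))
    for (b in seq(-pi / 2, pi / 2, length.out = 13))
      for (c in seq(-pi, pi, length.out = 25)) {
        Rm <- tevgsim:::rot_x(a) %*% tevgsim:::rot_y(b) %*% tevgsim:::rot_z(c)
        best <- min(best, resid(Rm))
      }
  expect_lte(resid(tf$rotation), best + 1e-9)
  expect_lt(resid(tf$rotation), 1e-12)
})

test_that("collinear configurations are rejected", {
  P <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(register_rigid(P, P, "known"), "collinear|degenerate")
})

test_that("ICP refines an unknown-correspondence alignment", {
  set.seed(4)
  m <- generate_aorta(straight_cfg(radius = 8, length = 60, n_circ = 16,
                                   n_axial = 20))
  P <- m$nodes
  R <- rot_z_test(8 * pi / 180)
  Q <- sweep(P %*% t(R), 2, c(1, -0.5, 0.7), `+`)
  tf <- register_rigid(P, Q, "unknown")
  moved <- apply_transform(tf, P)
  expect_lt(mean(sqrt(rowSums((moved - Q)^2))), 1e-6)
})

test_that("registration residual is invariant under common rigid motion", {
  set.seed(5)
  P <- matrix(rnorm(450, sd = 10), ncol = 3)
  Q <- P + matrix(rnorm(450, sd = 0.5), ncol = 3)
  resid_of <- function(S, TT) {
    tf <- register_rigid(S, TT, "known")
    sqrt(mean(rowSums((apply_transform(tf, S) - TT)^2)))
  }
  r0 <- resid_of(P, Q)
  R <- random_rotation(); t <- c(4, -7, 2)
  r1 <- resid_of(sweep(P %*% t(R), 2, t, `+`), sweep(Q %*% t(R), 2, t, `+`))
  expect_equal(r0, r1, tolerance = 1e-9)
})

test_that("anatomical frame sits at the loop centroid with patient axes", {
  set.seed(6)
  ring <- cbind(5 * cos(seq(0, 2 * pi, length.out = 17)[-17]),
                5 * sin(seq(0, 2 * pi, length.out = 17)[-17]), 3)
  m <- vessel_model(ring, matrix(c(1, 2, 3, 4), 1), "x",
                    loops = list(lp = 1:16))
  pl <- cut_plane(colMeans(ring), c(0, 0, 1))
  fr <- build_frame(pl)
  expect_equal(fr$origin, c(0, 0, 3), tolerance = 1e-12)
  expect_equal(crossprod(fr$axes), diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_gt(det(fr$axes), 0)
  # invariant to loop re-ordering: centroid is permutation invariant
  perm <- sample(16)
  pl2 <- cut_plane(colMeans(ring[perm, ]), c(0, 0, 1))
  expect_equal(build_frame(pl2)$origin, fr$origin, tolerance = 1e-12)
})

test_that("deviation decomposition reproduces in-vivo-style measurements", {
  fr <- build_frame(cut_plane(c(10, 5, -2), c(0, 1, 0)))
  # pure 6.9 mm superior translation (the largest observed displacement)
  tf <- rigid_transform(diag(3), c(0, 0, 6.9))
  d <- decompose_deviation(tf, fr, 100, 100)
  expect_equal(d$translation_mm, c(0, 0, 6.9), tolerance = 1e-12)
  expect_equal(d$rotation_deg, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(d$volume_ratio, 1)
  # pure 38 degree rotation about L-R (the tubular-graft observation)
  R <- tevgsim:::rot_x(38 * pi / 180)
  d2 <- decompose_deviation(rigid_transform(R, c(0, 0, 0)), fr, 80, 100)
  expect_equal(d2$rotation_deg, c(38, 0, 0), tolerance = 1e-9)
  expect_equal(d2$volume_ratio, 0.8)
  d3 <- decompose_deviation(rigid_transform(), fr, 50, 50)
  expect_equal(unname(unlist(d3[c("translation_mm", "rotation_deg")])),
               rep(0, 6))
  expect_equal(d3$volume_ratio, 1)
})

test_that("deviation decomposition round-trips apply_deviation", {
  case <- small_case()
  g <- case$graft
  plane <- case$planes$prox
  fr <- build_frame(plane)
  set.seed(8)
  for (i in 1:10) {
    dev <- deviation_spec(runif(3, -5, 5), runif(3, -40, 40))
    moved <- apply_deviation(g, plane, dev)
    tf <- register_rigid(g$surface$nodes, moved$graft$surface$nodes, "known")
    d <- decompose_deviation(tf, fr)
    expect_equal(d$translation_mm, dev$translation_mm, tolerance = 1e-6)
    expect_equal(d$rotation_deg, dev$rotation_deg, tolerance = 1e-4)
  }
})

test_that("enclosed volume is exact under scaling and rigid motion", {
  m <- generate_aorta(straight_cfg(radius = 10, length = 100))
  v <- enclosed_volume(m)
  expect_equal(v, pi * 100 * 100, tolerance = 0.02)
  s <- 1.23
  ms <- map_nodes_test(m, function(n) n * s)
  expect_equal(enclosed_volume(ms) / v, s^3, tolerance = 1e-9)
  set.seed(9)
  R <- random_rotation()
  mr <- map_nodes_test(m, function(n) sweep(n %*% t(R), 2, c(5, -3, 11), `+`))
  expect_equal(enclosed_volume(mr), v, tolerance = 1e-9)
})

test_that("surface distance obeys simple geometric oracles", {
  # identical surfaces
  m <- make_tube(0, 20, 5, 12, 6)
  d0 <- surface_distance(m, m, n_samples = 500, seed = 1)
  expect_equal(d0$hausdorff_mm, 0, tolerance = 1e-12)
  expect_equal(d0$mean_surface_distance_mm, 0, tolerance = 1e-12)
  # two parallel flat square patches offset by d
  grid <- expand.grid(x = 0:4, y = 0:4)
  mk_patch <- function(z) {
    nodes <- cbind(grid$x, grid$y, z)
    quads <- NULL
    for (i in 1:4) for (j in 1:4) {
      a <- (j - 1) * 5 + i
      quads <- rbind(quads, c(a, a + 1, a + 6, a + 5))
    }
    vessel_model(nodes, quads, rep("patch", nrow(quads)))
  }
  off <- 1.7
  dd <- surface_distance(mk_patch(0), mk_patch(off), n_samples = 400, seed = 2)
  expect_equal(dd$hausdorff_mm, off, tolerance = 1e-12)
  expect_equal(dd$mean_surface_distance_mm, off, tolerance = 1e-12)
})

test_that("vertex-mode distances equal the brute-force all-pairs oracle", {
  set.seed(10)
  for (k in 1:50) {
    n1 <- sample(20:200, 1); n2 <- sample(20:200, 1)
    A <- matrix(rnorm(3 * n1, sd = 10), ncol = 3)
    B <- sweep(matrix(rnorm(3 * n2, sd = 10), ncol = 3), 2,
               runif(3, -5, 5), `+`)
    got <- surface_distance(A, B, mode = "vertex")
    # all-pairs brute force in plain double arithmetic
    min_to <- function(P, Q) {
      vapply(seq_len(nrow(P)), function(i) {
        dx <- P[i, 1] - Q[, 1]; dy <- P[i, 2] - Q[, 2]; dz <- P[i, 3] - Q[, 3]
        sqrt(min(dx * dx + dy * dy + dz * dz))
      }, numeric(1))
    }
    dab <- min_to(A, B); dba <- min_to(B, A)
    expect_identical(got$hausdorff_mm, max(max(dab), max(dba)))
    expect_identical(got$directed_ab$max, max(dab))
    expect_equal(got$mean_surface_distance_mm,
                 (mean(dab) + mean(dba)) / 2, tolerance = 1e-15)
  }
})

test_that("surface distance grows monotonically with rigid offset", {
  m <- make_tube(0, 20, 5, 12, 6)
  means <- vapply(c(0.5, 1, 2, 4), function(d) {
    m2 <- map_nodes_test(m, function(n) sweep(n, 2, c(d, 0, 0), `+`))
    surface_distance(m, m2, n_samples = 400, seed = 3)$mean_surface_distance_mm
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
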