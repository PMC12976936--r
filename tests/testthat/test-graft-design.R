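test_that("resection planes sit perpendicular to the centerline", {
  m <- generate_aorta(straight_cfg(radius = 10, length = 100))
  pl <- place_resection_planes(m, 30, 70)
  # straight tube: two parallel planes 40 mm apart
  expect_equal(abs(sum(pl$prox$normal * pl$dist$normal)), 1, tolerance = 1e-12)
  expect_equal(abs(sum((pl$dist$origin - pl$prox$origin) * pl$prox$normal)),
               40, tolerance = 1e-9)
  # normal . tangent = 1 at both stations
  for (s in c(30, 70)) {
    tg <- as.numeric(tevgsim:::centerline_tangent_at(m$centerline, s))
    p <- place_resection_planes(m, s, s + 10)$prox
    expect_equal(sum(p$normal * tg), 1, tolerance = 1e-9)
  }
  expect_error(place_resection_planes(m, 70, 30), "s_prox < s_dist")
  expect_error(place_resection_planes(m, 0, 200), "s_prox < s_dist|arclength")
})

test_that("planes through a branch ostium are rejected", {
  m <- generate_aorta(anatomy_config())
  sb <- m$branch_attach[["branch_1"]]
  expect_error(place_resection_planes(m, sb, sb + 40), "ostium")
})

test_that("a mid-arch plane separates the branch-side element sets", {
  # signed-distance classification: elements proximal to the plane lie on the
  # first-branch side, distal ones on the second-branch side
  m <- generate_aorta(anatomy_config())
  s1 <- m$branch_attach[["branch_1"]]; s2 <- m$branch_attach[["branch_2"]]
  pl <- place_resection_planes(m, (s1 + s2) / 2, s2 + 15)$prox
  r1 <- colMeans(m$nodes[m$rings$branch_1[1, ], ])
  r2 <- colMeans(m$nodes[m$rings$branch_2[1, ], ])
  d1 <- sum((r1 - pl$origin) * pl$normal)
  d2 <- sum((r2 - pl$origin) * pl$normal)
  expect_lt(d1, 0)
  expect_gt(d2, 0)
})

test_that("resection conserves elements and cut areas", {
  m <- generate_aorta(straight_cfg(radius = 10, length = 100))
  pl <- place_resection_planes(m, 30, 70)
  rs <- resect(m, pl)
  expect_equal(nrow(rs$remnant$quads) + nrow(rs$resected$quads), nrow(m$quads))
  expect_equal(surface_area(rs$remnant) + surface_area(rs$resected),
               surface_area(m), tolerance = 0.01)
  # resected lateral area ~ 2 pi r L
  expect_equal(surface_area(rs$resected), 2 * pi * 10 * 40, tolerance = 0.02)
  # mating loops carry equal node counts
  expect_equal(length(rs$remnant$loops$anastomosis_prox),
               length(rs$resected$loops$cut_prox))
  expect_error(resect(m, place_resection_planes(m, 98, 99)), "empty|boundary")
})

test_that("identity graft design reproduces the native cut geometry", {
  m <- generate_aorta(anatomy_config())
  pl <- place_resection_planes(m, max(m$branch_attach) + 8, 130)
  rs <- resect(m, pl)
  g <- design_graft(rs, diameter_scale = 1)
  gl <- g$surface$loops$graft_prox
  nl <- rs$remnant$loops$anastomosis_prox
  rg <- circle_fit_radius(g$surface$nodes[gl, ])
  rn <- circle_fit_radius(rs$remnant$nodes[nl, ])
  expect_equal(rg, rn, tolerance = 1e-6)
  expect_equal(length(gl), length(nl))
  expect_identical(g$design_pose, diag(4))
})

test_that("graft diameter scaling shows up in the mid-graft section", {
  m <- generate_aorta(straight_cfg(radius = 10, length = 100))
  rs <- resect(m, place_resection_planes(m, 30, 70))
  g1 <- design_graft(rs, diameter_scale = 1)
  g11 <- design_graft(rs, diameter_scale = 1.1)
  mid <- function(g) {
    rings <- g$surface$rings$TEVG
    circle_fit_radius(g$surface$nodes[rings[round(nrow(rings) / 2), ], ])
  }
  expect_equal(mid(g11) / mid(g1), 1.1, tolerance = 0.01)
  expect_error(design_graft(rs, diameter_scale = 0), "positive")
})

test_that("branched graft design carries a stub for the orphaned branch", {
  m <- generate_aorta(anatomy_config())
  s1 <- m$branch_attach[["branch_1"]]; s2 <- m$branch_attach[["branch_2"]]
  pl <- place_resection_planes(m, (s1 + s2) / 2, s2 + 20)
  rs <- resect(m, pl)
  expect_equal(rs$cut_info$orphaned_branches, "branch_2")
  gb <- design_graft(rs, branched = TRUE, aorta = m)
  expect_equal(length(gb$branch_loops), 1L)
  expect_equal(length(gb$surface$loops[[gb$branch_loops]]),
               length(m$loops$branch_2_root))
  gt <- design_graft(rs, branched = FALSE)
  expect_equal(length(gt$branch_loops), 0L)
})

test_that("zero deviation leaves graft and plane bitwise unchanged", {
  case <- small_case()
  out <- apply_deviation(case$graft, case$planes$prox, deviation_spec())
  expect_identical(out$graft, case$graft)
  expect_identical(out$plane, case$planes$prox)
})

test_that("a full turn about any axis is the identity", {
  case <- small_case()
  for (ax in 1:3) {
    rot <- c(0, 0, 0); rot[ax] <- 360
    out <- apply_deviation(case$graft, case$planes$prox, deviation_spec(
      rotation_deg = rot))
    expect_lt(max(abs(out$graft$surface$nodes - case$graft$surface$nodes)),
              1e-9)
  }
})

test_that("plane co-transformation follows the translation rules", {
  case <- small_case()
  pl <- case$planes$prox
  # I-S translation by the largest observed in-vivo displacement: plane fixed,
  # every graft node shifted exactly
  out <- apply_deviation(case$graft, pl, deviation_spec(
    translation_mm = c(0, 0, 6.9)))
  expect_identical(out$plane$origin, pl$origin)
  expect_identical(out$plane$normal, pl$normal)
  shift <- out$graft$surface$nodes - case$graft$surface$nodes
  expect_equal(max(abs(sweep(shift, 2, c(0, 0, 6.9)))), 0, tolerance = 1e-12)
  # A-P translation: plane unchanged too
  out_ap <- apply_deviation(case$graft, pl, deviation_spec(
    translation_mm = c(0, 3, 0)))
  expect_identical(out_ap$plane$origin, pl$origin)
  # L-R translation: plane moves with the graft (resection location shifts)
  out_lr <- apply_deviation(case$graft, pl, deviation_spec(
    translation_mm = c(4, 0, 0)))
  expect_equal(out_lr$plane$origin, pl$origin + c(4, 0, 0), tolerance = 1e-12)
  # rotations co-rotate the plane
  out_r <- apply_deviation(case$graft, pl, deviation_spec(
    rotation_deg = c(0, 0, 30)))
  R30 <- tevgsim:::deviation_rotation(c(0, 0, 30))
  expect_equal(out_r$plane$normal, drop(R30 %*% pl$normal), tolerance = 1e-12)
  expect_error(deviation_spec(scale = -1), "positive")
})

test_that("successive rigid deviations compose as rigid transforms", {
  case <- small_case()
  pl <- case$planes$prox
  ctr <- pl$origin
  set.seed(21)
  for (i in 1:5) {
    A <- deviation_spec(c(0, runif(2, -3, 3)), runif(3, -20, 20))
    B <- deviation_spec(c(0, runif(2, -3, 3)), runif(3, -20, 20))
    s1 <- apply_deviation(case$graft, pl, A)
    s2 <- apply_deviation(s1$graft, pl, B)   # same center (zero L-R shift)
    RA <- tevgsim:::deviation_rotation(A$rotation_deg)
    RB <- tevgsim:::deviation_rotation(B$rotation_deg)
    X <- case$graft$surface$nodes
    X1 <- sweep(sweep(X, 2, ctr) %*% t(RA), 2, ctr + A$translation_mm, `+`)
    X2 <- sweep(sweep(X1, 2, ctr) %*% t(RB), 2, ctr + B$translation_mm, `+`)
    expect_lt(max(abs(s2$graft$surface$nodes - X2)), 1e-9)
  }
})

test_that("graft volume scales with the cube of the size deviation", {
  case <- small_case()
  v0 <- enclosed_volume(case$graft$surface)
  for (s in c(0.8, 1.05, 1.2)) {
    out <- apply_deviation(case$graft, case$planes$prox,
                           deviation_spec(scale = s))
    expect_equal(enclosed_volume(out$graft$surface) / v0, s^3,
                 tolerance = 1e-9)
  }
})

test_that("deviation thresholds are mean plus/minus two sample SDs", {
  mk <- function(t1) deviation_spec(translation_mm = c(t1, 0, 0))
  thr <- sample_deviation_thresholds(list(mk(1), mk(3)))
  expect_equal(unname(thr$translation["LR", ]), c(2 - 2 * sqrt(2),
                                                  2 + 2 * sqrt(2)))
  thr2 <- sample_deviation_thresholds(list(mk(2), mk(2), mk(2)))
  expect_equal(unname(thr2$translation["LR", ]), c(2, 2))
  # symmetric observations about 0 give a symmetric range
  thr3 <- sample_deviation_thresholds(list(mk(-4), mk(4)))
  expect_equal(sum(thr3$translation["LR", ]), 0, tolerance = 1e-12)
  expect_error(sample_deviation_thresholds(list(mk(1))), "at least 2")
})

test_that("resection plus identity design reproduces the aorta shape", {
  case <- small_case()
  asm <- fe_assembly(case$remnant, case$graft, materials = case$materials,
                     load_steps = case$load_steps)
  rep <- solve_implantation(asm)
  expect_true(rep$converged)
  d <- surface_distance(rep$deformed, case$aorta, n_samples = 2000, seed = 3)
  expect_lt(d$mean_surface_distance_mm, 0.5)
})
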