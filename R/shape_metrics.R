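#' Rigid transform
#'
#' @param rotation 3 x 3 proper orthogonal matrix.
#' @param translation 3-vector (mm).
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper orthogonal")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param tf a [rigid_transform()].
#' @param points n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(tf, points) {
  sweep(points %*% t(tf$rotation), 2, tf$translation, `+`)
}

compose_transform <- function(a, b) {  # a after b
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

#' Rigid registration of two point sets
#'
#' With known correspondence this is the least-squares optimal rotation and
#' translation (Kabsch/Umeyama via SVD). With unknown correspondence an
#' iterative-closest-point refinement is run from `init`: nearest-neighbor
#' matching alternated with Kabsch until the mean closest distance changes by
#' less than `tol` mm.
#'
#' @param source,target n x 3 (and m x 3) point matrices; with known
#'   correspondence both must have equal row counts, row i matching row i.
#' @param correspondence `"known"` or `"unknown"`.
#' @param init initial [rigid_transform()] for ICP.
#' @param max_iter ICP iteration cap.
#' @param tol ICP convergence tolerance on the mean distance change (mm).
#' @return A [rigid_transform()] mapping source onto target. For ICP the mean
#'   closest distance is attached as attribute `mean_distance`.
#' @export
register_rigid <- function(source, target,
                           correspondence = c("known", "unknown"),
                           init = rigid_transform(), max_iter = 100L,
                           tol = 1e-6) {
  correspondence <- match.arg(correspondence)
  source <- as.matrix(source); target <- as.matrix(target)
  if (nrow(source) < 3L) stop("need at least 3 points")
  check_degenerate <- function(P) {
    s <- svd(sweep(P, 2, colMeans(P)))$d
    if (s[2] < 1e-9 * max(s[1], 1))
      stop("degenerate (collinear) point configuration")
  }
  kabsch <- function(S, TT) {
    cs <- colMeans(S); ct <- colMeans(TT)
    H <- crossprod(sweep(S, 2, cs), sweep(TT, 2, ct))
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    rigid_transform(R, ct - drop(R %*% cs))
  }
  if (correspondence == "known") {
    if (nrow(source) != nrow(target))
      stop("known correspondence needs equal point counts")
    check_degenerate(source)
    return(kabsch(source, target))
  }
  check_degenerate(source)
  tf <- init
  prev <- Inf
  for (i in seq_len(max_iter)) {
    moved <- apply_transform(tf, source)
    nn <- .nn_index(moved, target)
    matched <- target[nn, , drop = FALSE]
    md <- mean(sqrt(rowSums((moved - matched)^2)))
    tf <- kabsch(source, matched)
    if (abs(prev - md) < tol) break
    prev <- md
  }
  attr(tf, "mean_distance") <- md
  tf
}

#' Anatomical frame at the designed anastomosis plane
#'
#' Origin at the anastomosis-plane center (the graft edge-loop centroid);
#' axes are the global patient axes (+x = Left, +y = Anterior, +z = Superior)
#' translated to that origin, because deviations are reported along anatomical
#' directions rather than plane-aligned ones.
#'
#' @param plane a [cut_plane()] whose origin is the anastomosis loop centroid.
#' @param patient_axes 3 x 3 orthonormal right-handed matrix (rows L-R, A-P,
#'   I-S); defaults to the global axes.
#' @return Object of class `anatomical_frame` with `origin` and `axes`.
#' @export
build_frame <- function(plane, patient_axes = diag(3)) {
  patient_axes <- as.matrix(patient_axes)
  if (max(abs(crossprod(patient_axes) - diag(3))) > 1e-12 ||
      det(patient_axes) < 0)
    stop("patient axes must be orthonormal and right-handed")
  structure(list(origin = plane$origin, axes = patient_axes),
            class = "anatomical_frame")
}

#' Decompose a rigid transform into anatomical deviation components
#'
#' Expresses the translation of the frame origin in the frame axes and
#' decomposes the rotation into right-hand-rule angles about the L-R, A-P and
#' I-S axes (intrinsic rotations in that order). The graft size mismatch is
#' reported as the designed/postoperative volume ratio.
#'
#' @param transform a [rigid_transform()] mapping designed onto postoperative.
#' @param frame an [anatomical_frame()].
#' @param designed_volume,postop_volume graft volumes (mm^3).
#' @return list with `translation_mm` (L-R, A-P, I-S), `rotation_deg`,
#'   `volume_ratio`, `gimbal` flag.
#' @export
decompose_deviation <- function(transform, frame, designed_volume = 1,
                                postop_volume = 1) {
  if (postop_volume <= 0 || designed_volume <= 0)
    stop("volumes must be positive")
  shift <- apply_transform(transform, matrix(frame$origin, 1)) - frame$origin
  t_frame <- drop(frame$axes %*% as.numeric(shift))
  Rf <- t(frame$axes) %*% transform$rotation %*% frame$axes
  eu <- euler_xyz_deg(Rf)
  list(translation_mm = t_frame, rotation_deg = eu$angles_deg,
       volume_ratio = designed_volume / postop_volume, gimbal = eu$gimbal)
}

#' Enclosed volume of a shell mesh with virtual planar caps
#'
#' Divergence-theorem volume of the surface closed by flat polygon fans over
#' each boundary loop. The caps are virtual (not added to the mesh). Each
#' connected component is closed and measured separately and the magnitudes
#' summed, so branch tubes contribute their own capped volumes.
#'
#' @param model a [vessel_model()].
#' @return volume in mm^3 (positive).
#' @export
enclosed_volume <- function(model) {
  nodes <- model$nodes
  tris <- triangulate_quads(model$quads)
  # orientability: every interior edge must be traversed once in each
  # direction
  e1 <- rbind(model$quads[, 1:2], model$quads[, 2:3], model$quads[, 3:4],
              model$quads[, c(4, 1)])
  key <- paste(pmin(e1[, 1], e1[, 2]), pmax(e1[, 1], e1[, 2]))
  dir <- ifelse(e1[, 1] < e1[, 2], 1L, -1L)
  cnt <- table(key)
  if (any(cnt > 2L)) stop("non-manifold surface")
  netdir <- tapply(dir, key, sum)
  if (any(cnt == 2L & abs(netdir[names(cnt)]) != 0))
    stop("inconsistent orientation: surface is not orientable as given")

  comp <- node_components(model)
  cap_tris <- NULL
  bound_keys <- names(cnt)[cnt == 1L]
  for (nm in names(model$loops)) {
    lp <- model$loops[[nm]]
    k1 <- paste(pmin(lp[1L], lp[2L]), pmax(lp[1L], lp[2L]))
    if (!k1 %in% bound_keys) next  # loop is interior in this mesh
    # orient the cap fan against the adjacent shell edge direction
    i <- which(key == k1 & cnt[key] == 1L)[1L]
    shell_dir <- all(e1[i, ] == c(lp[1L], lp[2L]))
    seqv <- if (shell_dir) rev(lp) else lp
    ctr_id <- nrow(nodes) + 1L
    nodes <- rbind(nodes, colMeans(model$nodes[lp, , drop = FALSE]))
    nl <- length(seqv)
    fan <- cbind(rep(ctr_id, nl), seqv, seqv[c(2:nl, 1L)])
    cap_tris <- rbind(cap_tris, fan)
  }
  all_tris <- rbind(tris, cap_tris)
  a <- nodes[all_tris[, 1L], , drop = FALSE]
  b <- nodes[all_tris[, 2L], , drop = FALSE]
  cc <- nodes[all_tris[, 3L], , drop = FALSE]
  svol <- (a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
           a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
           a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
  tri_comp <- comp[ifelse(all_tris[, 2L] <= length(comp), all_tris[, 2L],
                          all_tris[, 3L])]
  sum(abs(tapply(svol, tri_comp, sum)))
}

#' Hausdorff and mean surface distance between two shells
#'
#' Directed distances are computed point-to-triangle from seeded,
#' area-weighted uniform samples of each surface to the full triangulation of
#' the other; the Hausdorff distance is the larger directed maximum and the
#' mean surface distance the average of the two directed means. In
#' `mode = "vertex"` the mesh vertices themselves are compared point-to-point
#' (the exact discrete metric used for oracle checks).
#'
#' @param a,b [vessel_model()]s (or bare point matrices in vertex mode).
#' @param n_samples samples per surface in sampled mode.
#' @param seed RNG seed for the area-weighted sampling.
#' @param mode `"sampled"` (point-to-triangle) or `"vertex"` (point-to-point).
#' @return list with `hausdorff_mm`, `mean_surface_distance_mm`, and directed
#'   components `directed_ab`/`directed_ba` (each `max` and `mean`).
#' @export
surface_distance <- function(a, b, n_samples = 10000L, seed = 1L,
                             mode = c("sampled", "vertex")) {
  mode <- match.arg(mode)
  pts_of <- function(m) if (inherits(m, "vessel_model")) m$nodes else as.matrix(m)
  if (mode == "vertex") {
    A <- pts_of(a); B <- pts_of(b)
    dab <- ab_min_dists(A, B)
    dba <- ab_min_dists(B, A)
  } else {
    sa <- sample_surface(a, n_samples, seed)
    sb <- sample_surface(b, n_samples, seed + 1L)
    dab <- .point_tri_min_dist(sa, b$nodes, triangulate_quads(b$quads))
    dba <- .point_tri_min_dist(sb, a$nodes, triangulate_quads(a$quads))
  }
  list(hausdorff_mm = max(max(dab), max(dba)),
       mean_surface_distance_mm = (mean(dab) + mean(dba)) / 2,
       directed_ab = list(max = max(dab), mean = mean(dab)),
       directed_ba = list(max = max(dba), mean = mean(dba)))
}

ab_min_dists <- function(A, B) {
  nn <- .nn_index(A, B)
  d <- A - B[nn, , drop = FALSE]
  # plain double accumulation (rowSums would accumulate in long double)
  sqrt(d[, 1] * d[, 1] + d[, 2] * d[, 2] + d[, 3] * d[, 3])
}

# Seeded area-weighted uniform samples on a quad shell.
sample_surface <- function(model, n, seed) {
  tris <- triangulate_quads(model$quads)
  ar <- tri_areas(model$nodes, tris)
  with_seed(seed, {
    pick <- sample.int(nrow(tris), n, replace = TRUE, prob = ar)
    r1 <- sqrt(runif(n)); r2 <- runif(n)
    a <- model$nodes[tris[pick, 1L], , drop = FALSE]
    b <- model$nodes[tris[pick, 2L], , drop = FALSE]
    cc <- model$nodes[tris[pick, 3L], , drop = FALSE]
    (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * cc
  })
}
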