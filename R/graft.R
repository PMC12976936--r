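#' Virtual clamp / anastomosis plane
#'
#' A plane with an orthonormal right-handed frame: `normal` and two
#' `in_plane_axes`. Used both as the virtual clamp/resection plane and as the
#' anastomosis reference plane for deviation bookkeeping.
#'
#' @param origin 3-vector (mm).
#' @param normal plane normal (normalized internally).
#' @param axes optional 2 x 3 matrix of in-plane axes; constructed if missing.
#' @return Object of class `cut_plane`.
#' @export
cut_plane <- function(origin, normal, axes = NULL) {
  normal <- unitize(as.numeric(normal))
  if (is.null(axes)) {
    seed <- if (abs(normal[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- unitize(seed - sum(seed * normal) * normal)
    v <- c(normal[2] * u[3] - normal[3] * u[2],
           normal[3] * u[1] - normal[1] * u[3],
           normal[1] * u[2] - normal[2] * u[1])
    axes <- rbind(u, v)
  }
  axes <- as.matrix(axes)
  # right-handed check: u x v = normal
  u <- axes[1, ]; v <- axes[2, ]
  cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  if (max(abs(cr - normal)) > 1e-9)
    stop("plane axes and normal must form a right-handed orthonormal triple")
  structure(list(origin = as.numeric(origin), normal = normal, axes = axes),
            class = "cut_plane")
}

plane_signed_distance <- function(plane, points) {
  drop(sweep(points, 2, plane$origin) %*% plane$normal)
}

#' Place the virtual clamp / resection planes
#'
#' Defines the two resection planes perpendicular to the trunk centerline at
#' arclength stations `s_prox` and `s_dist` (the virtual analogue of clamp
#' placement between the upper arch branches). Planes that would cut through a
#' branch ostium are rejected.
#'
#' @param aorta a [vessel_model()] from [generate_aorta()].
#' @param s_prox,s_dist arclength stations (mm), `0 < s_prox < s_dist < L`.
#' @return list with `cut_plane`s `prox` and `dist`.
#' @export
place_resection_planes <- function(aorta, s_prox, s_dist) {
  cl <- aorta$centerline
  L <- total_arclength(cl)
  if (!(0 < s_prox && s_prox < s_dist && s_dist < L))
    stop("need 0 < s_prox < s_dist < total arclength")
  for (s in c(s_prox, s_dist)) {
    for (nm in names(aorta$branch_attach)) {
      sb <- aorta$branch_attach[[nm]]
      rb <- 0
      if (!is.null(aorta$rings[[nm]])) {
        ring <- aorta$rings[[nm]][1L, ]
        ctr <- colMeans(aorta$nodes[ring, , drop = FALSE])
        rb <- mean(sqrt(rowSums(sweep(aorta$nodes[ring, , drop = FALSE], 2, ctr)^2)))
      }
      if (abs(s - sb) < rb)
        stop(sprintf("resection plane at s=%.1f mm intersects the ostium of %s", s, nm))
    }
  }
  mk <- function(s) {
    cut_plane(as.numeric(centerline_point_at(cl, s)),
              as.numeric(centerline_tangent_at(cl, s)))
  }
  list(prox = mk(s_prox), dist = mk(s_dist))
}

#' Virtually resect the native arch region
#'
#' Splits the trunk at the two resection planes. Elements are partitioned by
#' signed distance of their strip to the planes; the cut is snapped to the
#' nearest structured ring and that ring is then projected exactly onto the
#' plane (the cut-band re-mesh), so the two mating loops automatically carry
#' equal node counts at identical parametric stations. Branch tubes always
#' stay with the native remnant; a branch whose take-off lies inside the
#' resected span has its root loop recorded as an extra anastomosis target.
#'
#' @param aorta a [vessel_model()] from [generate_aorta()].
#' @param planes output of [place_resection_planes()].
#' @return list with [vessel_model()]s `remnant` (loops gain
#'   `anastomosis_prox`, `anastomosis_dist`) and `resected` (loops
#'   `cut_prox`, `cut_dist`), plus `cut_info`.
#' @export
resect <- function(aorta, planes) {
  cl <- aorta$centerline
  rings <- aorta$rings$trunk
  nr <- nrow(rings)
  n_circ <- ncol(rings)
  ring_s <- seq(0, total_arclength(cl), length.out = nr)
  i_p <- which.min(abs(ring_s - proj_station(cl, planes$prox)))
  i_d <- which.min(abs(ring_s - proj_station(cl, planes$dist)))
  if (i_p <= 1L || i_d >= nr || i_d <= i_p)
    stop("resection planes leave an empty or boundary-touching resected set")

  nodes <- aorta$nodes
  # cut-band re-mesh: project the two cut rings exactly onto their planes
  for (pr in list(list(i = i_p, pl = planes$prox),
                  list(i = i_d, pl = planes$dist))) {
    idx <- rings[pr$i, ]
    d <- plane_signed_distance(pr$pl, nodes[idx, , drop = FALSE])
    nodes[idx, ] <- nodes[idx, , drop = FALSE] - outer(d, pr$pl$normal)
  }

  strip_of <- rep(seq_len(nr - 1L), each = n_circ)
  trunk_el <- which(aorta$region %in% c("AAo", "arch", "DAo", "trunk"))
  stopifnot(length(trunk_el) == (nr - 1L) * n_circ)
  res_el <- trunk_el[strip_of >= i_p & strip_of < i_d]
  rem_el <- setdiff(seq_len(nrow(aorta$quads)), res_el)

  sub <- function(el, keep_loops, ring_sets) {
    q <- aorta$quads[el, , drop = FALSE]
    used <- sort(unique(as.integer(q)))
    map <- integer(nrow(nodes)); map[used] <- seq_along(used)
    lp <- list()
    for (nm in names(keep_loops)) {
      ol <- keep_loops[[nm]]
      if (all(ol %in% used)) lp[[nm]] <- map[ol]
    }
    rg <- lapply(ring_sets, function(m) {
      if (all(m %in% used)) matrix(map[m], nrow(m), ncol(m)) else NULL
    })
    rg <- rg[!vapply(rg, is.null, logical(1))]
    vessel_model(nodes[used, , drop = FALSE], matrix(map[q], ncol = 4),
                 aorta$region[el], lp, thickness = aorta$thickness,
                 centerline = NULL, rings = rg,
                 branch_attach = aorta$branch_attach)
  }

  rem_loops <- c(aorta$loops,
                 list(anastomosis_prox = rings[i_p, ],
                      anastomosis_dist = rings[i_d, ]))
  rem_rings <- c(list(trunk_prox = rings[seq_len(i_p), , drop = FALSE],
                      trunk_dist = rings[i_d:nr, , drop = FALSE]),
                 aorta$rings[setdiff(names(aorta$rings), "trunk")])
  remnant <- sub(rem_el, rem_loops, rem_rings)
  remnant$centerline <- cl

  res_loops <- list(cut_prox = rings[i_p, ], cut_dist = rings[i_d, ])
  resected <- sub(res_el, res_loops,
                  list(resected = rings[i_p:i_d, , drop = FALSE]))
  # orphaned branches: take-off inside the resected span
  orphan <- character(0)
  for (nm in names(aorta$branch_attach)) {
    sb <- aorta$branch_attach[[nm]]
    if (sb > ring_s[i_p] && sb < ring_s[i_d]) orphan <- c(orphan, nm)
  }
  sub_cl <- resample_centerline(
    centerline(centerline_point_at(cl, seq(ring_s[i_p], ring_s[i_d], length.out = 64)),
               centerline_radius_at(cl, seq(ring_s[i_p], ring_s[i_d], length.out = 64))),
    i_d - i_p + 1L)
  resected$centerline <- sub_cl
  cut_info <- list(i_prox = i_p, i_dist = i_d, s_prox = ring_s[i_p],
                   s_dist = ring_s[i_d], planes = planes, n_circ = n_circ,
                   orphaned_branches = orphan)
  list(remnant = remnant, resected = resected, cut_info = cut_info)
}

# Arclength station of the centerline point nearest the plane origin (the
# origin lies on the centerline for planes built by place_resection_planes).
proj_station <- function(cl, plane) {
  d2 <- rowSums(sweep(cl$points, 2, plane$origin)^2)
  cl$arclength[which.min(d2)]
}

#' Design a TEVG replacing a resected segment
#'
#' Lofts a graft tube along the resected segment's centerline with the native
#' radius profile scaled by `diameter_scale`. The end loops are re-meshed at
#' the same parametric stations as the native cut loops (same node count per
#' ring), honoring the equal-node anastomosis contract; at `diameter_scale = 1`
#' the graft end rings coincide with the native cut loops. A branched graft
#' additionally carries a stub tube toward each orphaned native branch root.
#'
#' @param resection output of [resect()] (list with `resected` and `cut_info`),
#'   or the `resected` [vessel_model()] itself plus `cut_info`.
#' @param diameter_scale unitless diameter scaling of the graft (> 0).
#' @param branched logical; carry stubs for orphaned branches.
#' @param cut_info the `cut_info` from [resect()] if `resection` is a bare model.
#' @param aorta the original aorta (needed to locate orphaned branch roots when
#'   `branched = TRUE`); defaults to branch info carried in `cut_info`.
#' @return Object of class `graft_model`: fields `surface` (a [vessel_model()]
#'   tagged `TEVG`), `proximal_loop`, `distal_loop`, `branch_loops`,
#'   `design_pose` (identity 4 x 4), `planes`.
#' @export
design_graft <- function(resection, diameter_scale = 1, branched = FALSE,
                         cut_info = NULL, aorta = NULL) {
  if (is.list(resection) && !inherits(resection, "vessel_model")) {
    cut_info <- resection$cut_info
    aorta <- aorta %||% attr(resection, "aorta")
    resected <- resection$resected
  } else resected <- resection
  if (is.null(cut_info)) stop("cut_info from resect() is required")
  if (nrow(resected$quads) == 0L) stop("resected segment is empty")
  if (diameter_scale <= 0) stop("diameter_scale must be positive")
  cl <- resected$centerline
  n_ax <- nrow(resected$rings$resected) - 1L
  n_circ <- cut_info$n_circ
  gcl <- centerline(cl$points, cl$radii * diameter_scale)
  g <- loft_surface(gcl, n_circ, n_ax, region = "TEVG",
                    thickness = resected$thickness,
                    loop_names = c("graft_prox", "graft_dist"))
  names(g$rings) <- "TEVG"
  # the graft end rings are designed to mate the native cut loops exactly:
  # take the native cut-ring geometry, scaled about its centroid, assigned to
  # the angularly paired graft nodes (so the loops coincide at scale 1)
  for (pr in list(list(lp = "graft_prox", nl = resected$loops$cut_prox),
                  list(lp = "graft_dist", nl = resected$loops$cut_dist))) {
    gl <- g$loops[[pr$lp]]
    native_ring <- resected$nodes[pr$nl, , drop = FALSE]
    pairing <- pair_nodes(g$nodes[gl, , drop = FALSE], native_ring)
    ctr <- colMeans(native_ring)
    tgt <- native_ring[pairing$pairs[, "native"], , drop = FALSE]
    g$nodes[gl, ] <- sweep(sweep(tgt, 2, ctr) * diameter_scale, 2, ctr, `+`)
  }
  branch_loops <- character(0)
  if (branched && length(cut_info$orphaned_branches)) {
    if (is.null(aorta))
      stop("branched graft design needs the original aorta for branch roots")
    for (nm in cut_info$orphaned_branches) {
      root_ring <- aorta$rings[[nm]][1L, ]
      root_ctr <- colMeans(aorta$nodes[root_ring, , drop = FALSE])
      rb <- mean(sqrt(rowSums(sweep(aorta$nodes[root_ring, , drop = FALSE],
                                    2, root_ctr)^2)))
      sb <- aorta$branch_attach[[nm]]
      p0 <- as.numeric(centerline_point_at(aorta$centerline, sb))
      dir <- unitize(root_ctr - p0)
      start <- p0 + dir * (0.5 * centerline_radius_at(aorta$centerline, sb))
      stub_cl <- centerline(rbind(start, root_ctr), rb * diameter_scale)
      stub <- loft_surface(stub_cl, n_circ, 2L, region = "TEVG",
                           thickness = resected$thickness,
                           loop_names = c(paste0("stub_", nm, "_base"),
                                          paste0("stub_", nm)))
      off <- nrow(g$nodes)
      g$nodes <- rbind(g$nodes, stub$nodes)
      g$quads <- rbind(g$quads, stub$quads + off)
      g$region <- c(g$region, stub$region)
      g$loops[[paste0("stub_", nm)]] <- stub$loops[[paste0("stub_", nm)]] + off
      g$rings[[paste0("stub_", nm)]] <- stub$rings[[1L]] + off
      branch_loops <- c(branch_loops, paste0("stub_", nm))
    }
  }
  # contract: mating loops must carry equal node counts
  if (length(g$loops$graft_prox) != n_circ ||
      length(g$loops$graft_dist) != n_circ)
    stop("graft loop node count does not match the native cut loops")
  structure(list(surface = g, proximal_loop = "graft_prox",
                 distal_loop = "graft_dist", branch_loops = branch_loops,
                 design_pose = diag(4), planes = cut_info$planes,
                 cut_info = cut_info),
            class = "graft_model")
}

#' @export
print.graft_model <- function(x, ...) {
  cat(sprintf("<graft_model> %d nodes, %d quads, %d boundary loops\n",
              nrow(x$surface$nodes), nrow(x$surface$quads),
              2L + length(x$branch_loops)))
  invisible(x)
}
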