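#' Configuration for a synthetic aortic anatomy
#'
#' Parametric description of a synthetic porcine-like thoracic aorta: a
#' straight ascending segment, a circular arch carrying 0-2 supra-aortic
#' branches (emulating brachiocephalic trunk and left subclavian placement),
#' and a straight descending segment. The coordinate convention is a
#' right-handed patient frame: +x = anatomical Left, +y = Anterior,
#' +z = Superior; all geometry in mm. The arch lies in the A-P / I-S plane.
#'
#' The design-stage growth allowance (the design anatomy is the imaged anatomy
#' expanded uniformly by 5% to account for animal growth between imaging and
#' implantation) is carried as `growth_scale = 1.05`; apply it with
#' [scale_uniform()].
#'
#' Porcine aortic dimensions are not published for this protocol beyond animal
#' mass, so the defaults are configurable stand-ins sized like a 20-30 kg pig
#' (lumen radius ~6 mm, arch radius ~25 mm).
#'
#' @param arch_radius_mm radius of the arch centerline arc (mm); with
#'   `arch_angle_deg = 0` the trunk is a straight tube.
#' @param vessel_radius_profile lumen radius (mm): a scalar or a function of
#'   arclength fraction in `[0, 1]` returning radii.
#' @param branch_count number of supra-aortic branch tubes (0, 1 or 2).
#' @param branch_radii_mm radii of the branch tubes (recycled).
#' @param n_circumferential nodes per ring (>= 8).
#' @param n_axial axial element strips along the trunk.
#' @param seed integer seed for the optional radial noise.
#' @param growth_scale uniform design expansion factor (> 0).
#' @param asc_length_mm,desc_length_mm straight segment lengths (mm).
#' @param arch_angle_deg arch sweep angle (degrees; 180 = full candy-cane,
#'   0 = straight tube).
#' @param branch_angles_deg take-off positions along the arch (degrees from
#'   the ascending end of the arch).
#' @param branch_length_mm branch tube length (mm).
#' @param noise_amplitude_mm amplitude of seeded smooth radial noise
#'   (mm; 0 disables it, the default).
#' @param thickness_mm wall thickness (mm).
#' @return An object of class `anatomy_config`.
#' @export
anatomy_config <- function(arch_radius_mm = 25,
                           vessel_radius_profile = 6,
                           branch_count = 2,
                           branch_radii_mm = c(3.5, 3),
                           n_circumferential = 16,
                           n_axial = 60,
                           seed = 1L,
                           growth_scale = 1.05,
                           asc_length_mm = 35,
                           desc_length_mm = 55,
                           arch_angle_deg = 180,
                           branch_angles_deg = c(55, 105),
                           branch_length_mm = 14,
                           noise_amplitude_mm = 0,
                           thickness_mm = 1.5) {
  if (n_circumferential < 8L) stop("n_circumferential must be >= 8")
  if (!branch_count %in% 0:2) stop("branch_count must be 0, 1 or 2")
  if (growth_scale <= 0) stop("growth_scale must be positive")
  structure(list(arch_radius_mm = arch_radius_mm,
                 vessel_radius_profile = vessel_radius_profile,
                 branch_count = as.integer(branch_count),
                 branch_radii_mm = branch_radii_mm,
                 n_circumferential = as.integer(n_circumferential),
                 n_axial = as.integer(n_axial),
                 seed = as.integer(seed),
                 growth_scale = growth_scale,
                 asc_length_mm = asc_length_mm,
                 desc_length_mm = desc_length_mm,
                 arch_angle_deg = arch_angle_deg,
                 branch_angles_deg = branch_angles_deg,
                 branch_length_mm = branch_length_mm,
                 noise_amplitude_mm = noise_amplitude_mm,
                 thickness_mm = thickness_mm),
            class = "anatomy_config")
}

radius_fun <- function(profile) {
  if (is.function(profile)) return(profile)
  if (!is.numeric(profile) || any(!is.finite(profile)))
    stop("vessel_radius_profile must be a positive scalar or a function")
  function(f) rep_len(profile, length(f))
}

# Trunk centerline: ascending (+z), arch arc in the y-z plane, descending (-z).
aorta_trunk_centerline <- function(config, n_pts = 241L) {
  R <- config$arch_radius_mm
  ang <- config$arch_angle_deg * pi / 180
  La <- config$asc_length_mm
  Ld <- config$desc_length_mm
  Lc <- R * ang
  Ltot <- La + Lc + Ld
  s <- seq(0, Ltot, length.out = n_pts)
  pts <- matrix(0, n_pts, 3)
  if (Lc <= 0) {
    pts[, 3] <- s
  } else {
    asc <- s <= La
    arc <- s > La & s <= La + Lc
    des <- s > La + Lc
    pts[asc, 2] <- R
    pts[asc, 3] <- s[asc] - La
    th <- (s[arc] - La) / R
    pts[arc, 2] <- R * cos(th)
    pts[arc, 3] <- R * sin(th)
    # descending segment continues along the end-of-arch tangent
    pE <- c(0, R * cos(ang), R * sin(ang))
    tE <- c(0, -sin(ang), cos(ang))
    sd_ <- s[des] - La - Lc
    pts[des, ] <- rep(pE, each = sum(des)) + outer(sd_, tE)
  }
  rf <- radius_fun(config$vessel_radius_profile)
  radii <- rf(s / Ltot)
  if (any(!is.finite(radii)) || any(radii <= 0))
    stop("degenerate radius profile: radii must be positive")
  if (config$noise_amplitude_mm > 0) {
    radii <- radii + with_seed(config$seed, {
      raw <- rnorm(n_pts)
      as.numeric(stats::filter(raw, rep(1 / 15, 15), circular = TRUE)) *
        config$noise_amplitude_mm * sqrt(15)
    })
    if (any(radii <= 0)) stop("degenerate radius profile after noise")
  }
  centerline(pts, radii)
}

#' Loft a structured quad tube surface along a centerline
#'
#' Builds an open structured tube: `n_axial + 1` rings of `n_circ` nodes each,
#' placed on rotation-minimizing frames so the parametrization carries no
#' spurious twist. Element orientation is consistently outward.
#'
#' @param cl a [centerline()].
#' @param n_circ nodes per circumferential ring.
#' @param n_axial number of axial element strips.
#' @param region region tag for all elements.
#' @param thickness wall thickness (mm).
#' @param loop_names names for the first/last ring boundary loops.
#' @return A [vessel_model()] with `rings$tube` (or the supplied region name).
#' @export
loft_surface <- function(cl, n_circ, n_axial, region = "tube",
                         thickness = 1.5,
                         loop_names = c("inlet", "outlet")) {
  stopifnot(inherits(cl, "centerline"), n_circ >= 3L, n_axial >= 1L)
  rs <- resample_centerline(cl, n_axial + 1L)
  fr <- rmf_frames(rs)
  nr <- n_axial + 1L
  phi <- 2 * pi * (seq_len(n_circ) - 1L) / n_circ
  nodes <- matrix(0, nr * n_circ, 3)
  rings <- matrix(0L, nr, n_circ)
  for (i in seq_len(nr)) {
    idx <- (i - 1L) * n_circ + seq_len(n_circ)
    rings[i, ] <- idx
    nodes[idx, ] <- rep(rs$points[i, ], each = n_circ) +
      rs$radii[i] * (outer(cos(phi), fr$normal[i, ]) +
                     outer(sin(phi), fr$binormal[i, ]))
  }
  quads <- matrix(0L, n_axial * n_circ, 4)
  e <- 0L
  for (i in seq_len(n_axial)) {
    for (j in seq_len(n_circ)) {
      jn <- if (j == n_circ) 1L else j + 1L
      e <- e + 1L
      quads[e, ] <- c(rings[i, j], rings[i, jn], rings[i + 1L, jn],
                      rings[i + 1L, j])
    }
  }
  # self-intersection guard: tube radius exceeding the local curvature radius
  kinked <- FALSE
  if (nr >= 3L) {
    for (i in 2:(nr - 1L)) {
      t1 <- unitize(rs$points[i, ] - rs$points[i - 1L, ])
      t2 <- unitize(rs$points[i + 1L, ] - rs$points[i, ])
      dth <- acos(min(1, max(-1, sum(t1 * t2))))
      ds <- (rs$arclength[i + 1L] - rs$arclength[i - 1L]) / 2
      if (dth > 0 && rs$radii[i] * dth / ds > 1) kinked <- TRUE
    }
  }
  if (kinked)
    warning("lofted tube radius exceeds local centerline curvature radius; ",
            "surface may self-intersect")
  lp <- list(rings[1L, ], rings[nr, ])
  names(lp) <- loop_names
  rg <- list(rings)
  names(rg) <- region
  m <- vessel_model(nodes, quads, rep(region, nrow(quads)), lp,
                    thickness = thickness, centerline = rs, rings = rg)
  attr(m, "self_intersecting") <- kinked
  m
}

#' Generate a synthetic aorta
#'
#' Builds the tagged shell mesh of a synthetic thoracic aorta from an
#' [anatomy_config()]: trunk regions `AAo`, `arch`, `DAo` plus `branch_i`
#' tubes taking off from the arch, with boundary loops `inlet`,
#' `outlet_DAo`, `outlet_branch_i` and (for branches) `branch_i_root`.
#' Deterministic for a fixed seed.
#'
#' @param config an [anatomy_config()].
#' @return A [vessel_model()].
#' @export
generate_aorta <- function(config) {
  stopifnot(inherits(config, "anatomy_config"))
  cl <- aorta_trunk_centerline(config)
  trunk <- loft_surface(cl, config$n_circumferential, config$n_axial,
                        region = "trunk", thickness = config$thickness_mm,
                        loop_names = c("inlet", "outlet_DAo"))
  # retag trunk elements by arclength of the strip midpoint
  La <- config$asc_length_mm
  Lc <- config$arch_radius_mm * config$arch_angle_deg * pi / 180
  nstrip <- config$n_axial
  smid <- (seq_len(nstrip) - 0.5) / nstrip * total_arclength(cl)
  strip_tag <- ifelse(smid <= La, "AAo", ifelse(smid <= La + Lc, "arch", "DAo"))
  region <- rep(strip_tag, each = config$n_circumferential)
  names(trunk$rings) <- "trunk"

  nodes <- trunk$nodes
  quads <- trunk$quads
  loops <- trunk$loops
  rings <- trunk$rings
  battach <- numeric(0)
  if (config$branch_count > 0L && Lc > 0) {
    radii_b <- rep_len(config$branch_radii_mm, config$branch_count)
    for (b in seq_len(config$branch_count)) {
      th <- config$branch_angles_deg[b] * pi / 180
      sb <- La + config$arch_radius_mm * th
      p0 <- as.numeric(centerline_point_at(cl, sb))
      dir <- unitize(p0 - c(0, 0, 0))   # radially away from the arch center
      r_trunk <- centerline_radius_at(cl, sb)
      start <- p0 + dir * (0.9 * r_trunk)
      bcl <- centerline(rbind(start, start + dir * config$branch_length_mm),
                        radii_b[b])
      nb <- max(4L, round(config$branch_length_mm / 3))
      bt <- loft_surface(bcl, config$n_circumferential, nb,
                         region = sprintf("branch_%d", b),
                         thickness = config$thickness_mm,
                         loop_names = c(sprintf("branch_%d_root", b),
                                        sprintf("outlet_branch_%d", b)))
      off <- nrow(nodes)
      nodes <- rbind(nodes, bt$nodes)
      quads <- rbind(quads, bt$quads + off)
      region <- c(region, bt$region)
      for (nm in names(bt$loops)) loops[[nm]] <- bt$loops[[nm]] + off
      rings[[sprintf("branch_%d", b)]] <- bt$rings[[1L]] + off
      battach[sprintf("branch_%d", b)] <- sb
    }
  }
  vessel_model(nodes, quads, region, loops, thickness = config$thickness_mm,
               centerline = cl, rings = rings,
               branch_attach = if (length(battach)) battach else NULL)
}

#' Scale a vessel model uniformly about its centroid
#'
#' The design-stage growth allowance: expands every node coordinate about the
#' model centroid (factor 1.05 reproduces the 5% uniform growth expansion used
#' when designing grafts one month ahead of implantation). Topology, tags and
#' loops are unchanged.
#'
#' @param model a [vessel_model()].
#' @param factor positive scale factor.
#' @return The scaled [vessel_model()].
#' @export
scale_uniform <- function(model, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("scale factor must be a positive number")
  ctr <- colMeans(model$nodes)
  model$nodes <- sweep(sweep(model$nodes, 2, ctr) * factor, 2, ctr, `+`)
  if (!is.null(model$centerline)) {
    p <- sweep(sweep(model$centerline$points, 2, ctr) * factor, 2, ctr, `+`)
    model$centerline <- centerline(p, model$centerline$radii * factor)
  }
  if (!is.null(model$branch_attach))
    model$branch_attach <- model$branch_attach * factor
  model
}
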