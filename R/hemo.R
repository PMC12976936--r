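#' Blood properties
#'
#' Newtonian closure with the single printed viscosity value; density in
#' kg/m^3, dynamic viscosity in Pa.s.
#'
#' @param density kg/m^3.
#' @param viscosity Pa.s.
#' @return Object of class `blood_properties`.
#' @export
blood_properties <- function(density = 1060, viscosity = 0.00371) {
  if (density <= 0 || viscosity <= 0) stop("blood properties must be positive")
  structure(list(density = density, viscosity = viscosity),
            class = "blood_properties")
}

#' Three-element Windkessel outlet parameters
#'
#' @param Rp proximal resistance (mmHg.s/mL).
#' @param C compliance (mL/mmHg).
#' @param Rd distal resistance (mmHg.s/mL).
#' @return Object of class `windkessel_params`.
#' @export
windkessel_params <- function(Rp, C, Rd) {
  if (any(c(Rp, C, Rd) <= 0)) stop("Windkessel parameters must be positive")
  structure(list(Rp = Rp, C = C, Rd = Rd), class = "windkessel_params")
}

#' Pulsatile inflow waveform
#'
#' Default: half-sinusoid systolic ejection over the first third of the cycle
#' and zero diastolic flow, a generic mammalian aortic-root shape (the study's
#' own waveform is not published; amplitude and period are configurable).
#'
#' @param period cardiac period (s).
#' @param samples named numeric flow samples (mL/s) at
#'   `time = seq(0, period, length.out = length(samples))`, or `NULL` for the
#'   default shape.
#' @param peak_flow peak systolic flow (mL/s) for the default shape.
#' @param n number of samples for the default shape.
#' @return Object of class `flow_waveform` with `period`, `time`, `flow`.
#' @export
flow_waveform <- function(period = 0.5, samples = NULL, peak_flow = 200,
                          n = 201L) {
  if (period <= 0) stop("period must be positive")
  if (is.null(samples)) {
    tt <- seq(0, period, length.out = n)
    q <- ifelse(tt <= period / 3, peak_flow * sin(pi * tt / (period / 3)), 0)
  } else {
    q <- as.numeric(samples)
    tt <- seq(0, period, length.out = length(q))
  }
  structure(list(period = period, time = tt, flow = q),
            class = "flow_waveform")
}

waveform_at <- function(wf, t) {
  tm <- t %% wf$period
  stats::approx(wf$time, wf$flow, xout = tm, rule = 2)$y
}

#' Profile the lumen of a (deformed) vessel model
#'
#' Cross-sections are taken at the structured mesh rings carried by the model
#' (the rings deform with the shell, so no re-slicing of the deformed surface
#' is needed). The section area is the planar polygon (vector) area of each
#' ring; the effective radius is the area-equivalent circle radius. Branch
#' segments are profiled separately and attached to the nearest trunk station.
#'
#' @param deformed a [vessel_model()] with `rings` (for an implanted assembly:
#'   `trunk_prox`, `TEVG`, `trunk_dist` and `branch_i`).
#' @param n_stations target number of trunk stations (rings are subsampled
#'   evenly if they exceed this; all rings are used otherwise).
#' @return Object of class `lumen_profile`: per-segment stations (arclength
#'   mm), areas (mm^2), effective radii (mm), a segment table, and branch
#'   attachment indices.
#' @export
extract_lumen_profile <- function(deformed, n_stations = 60L) {
  rings <- deformed$rings
  if (is.null(rings)) stop("model carries no structured rings to profile")
  trunk_names <- intersect(c("trunk", "trunk_prox", "TEVG", "resected",
                             "trunk_dist"), names(rings))
  if (!length(trunk_names)) stop("no trunk ring sets found")
  ring_stack <- NULL
  seg_of_ring <- character(0)
  for (nm in trunk_names) {
    m <- rings[[nm]]
    if (!is.null(ring_stack) &&
        ring_centroid_dist(deformed$nodes, ring_stack[nrow(ring_stack), ],
                           m[1L, ]) < 1e-6)
      m <- m[-1L, , drop = FALSE]   # shared cut ring: drop the duplicate
    ring_stack <- rbind(ring_stack, m)
    seg_of_ring <- c(seg_of_ring, rep(nm, nrow(m)))
  }
  if (nrow(ring_stack) > n_stations) {
    keep <- unique(round(seq(1, nrow(ring_stack), length.out = n_stations)))
    ring_stack <- ring_stack[keep, , drop = FALSE]
    seg_of_ring <- seg_of_ring[keep]
  }
  tr <- profile_rings(deformed$nodes, ring_stack)
  out <- list(trunk = c(tr, list(segment = seg_of_ring)))
  for (nm in grep("^branch_", names(rings), value = TRUE)) {
    br <- profile_rings(deformed$nodes, rings[[nm]])
    ctr0 <- br$centers[1L, ]
    att <- which.min(rowSums(sweep(tr$centers, 2, ctr0)^2))
    out[[nm]] <- c(br, list(attach_station = att))
  }
  structure(out, class = "lumen_profile")
}

ring_centroid_dist <- function(nodes, r1, r2) {
  vnorm(colMeans(nodes[r1, , drop = FALSE]) - colMeans(nodes[r2, , drop = FALSE]))
}

profile_rings <- function(nodes, rings) {
  nr <- nrow(rings)
  centers <- matrix(0, nr, 3)
  areas <- numeric(nr)
  for (i in seq_len(nr)) {
    p <- nodes[rings[i, ], , drop = FALSE]
    centers[i, ] <- colMeans(p)
    q <- p[c(2:nrow(p), 1L), , drop = FALSE]
    va <- c(sum(p[, 2] * q[, 3] - p[, 3] * q[, 2]),
            sum(p[, 3] * q[, 1] - p[, 1] * q[, 3]),
            sum(p[, 1] * q[, 2] - p[, 2] * q[, 1])) / 2
    areas[i] <- vnorm(va)
  }
  if (any(areas <= 0)) stop("degenerate ring with non-positive area")
  s <- c(0, cumsum(sqrt(rowSums(diff(centers)^2))))
  list(stations = s, areas = areas, effective_radii = sqrt(areas / pi),
       centers = centers)
}

#' Build the 0-D Poiseuille/Windkessel network
#'
#' The documented reduced-order surrogate for the 3-D hemodynamics: each
#' inter-station segment becomes a Poiseuille resistance
#' `R = 8 mu L / (pi r^4)` (trapezoidal in `r^-4` between stations, converted
#' to mmHg.s/mL), series-connected along each segment; branch segments attach
#' at their take-off station; every terminal station carries a three-element
#' Windkessel. This preserves the boundary-condition structure and the
#' monotone geometry-to-hemodynamics relationships the tolerance maps rely on.
#'
#' @param profile an [extract_lumen_profile()].
#' @param outlets named list of [windkessel_params()]; names `DAo` plus the
#'   `branch_i` present in the profile.
#' @param blood a [blood_properties()].
#' @return Object of class `lumped_network`.
#' @export
build_network <- function(profile, outlets, blood = blood_properties()) {
  stopifnot(inherits(profile, "lumen_profile"))
  seg_res <- function(pr) {
    mu <- blood$viscosity
    r <- pr$effective_radii * 1e-3           # m
    L <- diff(pr$stations) * 1e-3            # m
    rinv4 <- (head(r, -1)^-4 + tail(r, -1)^-4) / 2
    R_SI <- 8 * mu * L * rinv4 / pi          # Pa.s/m^3
    R_SI / PA_PER_MMHG / 1e6                 # mmHg.s/mL
  }
  tr <- profile$trunk
  nt <- length(tr$stations)
  nodes <- data.frame(segment = "trunk", station = seq_len(nt),
                      radius_mm = tr$effective_radii,
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = seq_len(nt - 1L), to = 2:nt,
                      R = seg_res(tr),
                      r_mm = (tr$effective_radii[-nt] + tr$effective_radii[-1L]) / 2,
                      segment = "trunk", stringsAsFactors = FALSE)
  outlet_nodes <- c(DAo = nt)
  for (nm in grep("^branch_", names(profile), value = TRUE)) {
    br <- profile[[nm]]
    nb <- length(br$stations)
    base <- nrow(nodes)
    nodes <- rbind(nodes, data.frame(segment = nm, station = seq_len(nb),
                                     radius_mm = br$effective_radii,
                                     stringsAsFactors = FALSE))
    Rb <- seg_res(br)
    edges <- rbind(edges,
                   data.frame(from = c(br$attach_station,
                                       base + seq_len(nb - 1L)),
                              to = base + seq_len(nb),
                              R = c(Rb[1L] / 2, Rb),
                              r_mm = c(br$effective_radii[1L],
                                       (br$effective_radii[-nb] +
                                        br$effective_radii[-1L]) / 2),
                              segment = nm, stringsAsFactors = FALSE))
    outlet_nodes[nm] <- base + nb
  }
  for (nm in names(outlet_nodes))
    if (is.null(outlets[[nm]]))
      stop(sprintf("missing Windkessel parameters for outlet '%s'", nm))
  structure(list(nodes = nodes, edges = edges, inlet = 1L,
                 outlet_nodes = outlet_nodes,
                 outlets = outlets[names(outlet_nodes)], blood = blood),
            class = "lumped_network")
}

#' Simulate pulsatile flow in the lumped network
#'
#' Nodal pressures solve the resistive network at every time step (Kirchhoff
#' balance, prescribed inlet flow); each Windkessel compliance state is
#' integrated with the trapezoidal theta-scheme coupled implicitly to the
#' network solve. Cycles repeat until the cycle-to-cycle maximum pressure
#' change falls below `p_tol` mmHg (or `max_cycles`).
#'
#' @param network a [build_network()].
#' @param inflow a [flow_waveform()].
#' @param dt time step (s); must satisfy `dt < period/100`.
#' @param max_cycles cycle cap (<= 10 by default, as in pulsatile CFD
#'   practice).
#' @param p_tol periodic-convergence tolerance (mmHg).
#' @param theta time integration parameter (0.5 = trapezoidal, 1 = implicit
#'   Euler).
#' @param pc0 optional initial Windkessel compliance pressures (mmHg, one per
#'   outlet); defaults to zero.
#' @return Object of class `hemo_result`: final-cycle `time`, nodal pressures
#'   `p` (mmHg), edge flows `Q` (mL/s), edge WSS `tau` (Pa),
#'   `cycles_to_converge`, `converged_periodic`, plus the network.
#' @export
simulate_network <- function(network, inflow, dt = inflow$period / 200,
                             max_cycles = 10L, p_tol = 0.1, theta = 0.5,
                             pc0 = NULL) {
  if (dt >= inflow$period / 100) stop("dt must be below period/100")
  nsteps <- max(2L, round(inflow$period / dt))
  dt <- inflow$period / nsteps
  nn <- nrow(network$nodes)
  edges <- network$edges
  g <- 1 / edges$R
  G <- matrix(0, nn, nn)
  for (e in seq_len(nrow(edges))) {
    i <- edges$from[e]; j <- edges$to[e]
    G[i, i] <- G[i, i] + g[e]; G[j, j] <- G[j, j] + g[e]
    G[i, j] <- G[i, j] - g[e]; G[j, i] <- G[j, i] - g[e]
  }
  ow <- network$outlets
  no <- length(ow)
  on <- unname(network$outlet_nodes)
  nun <- nn + no
  A <- matrix(0, nun, nun)
  A[1:nn, 1:nn] <- G
  for (k in seq_len(no)) {
    o <- on[k]; w <- ow[[k]]
    A[o, o] <- A[o, o] + 1 / w$Rp
    A[o, nn + k] <- A[o, nn + k] - 1 / w$Rp
    # theta-scheme compliance row:
    # pc' - pc = dt/C [ theta ((po'-pc')/Rp - pc'/Rd) + (1-theta)(rhs at t_n) ]
    A[nn + k, nn + k] <- 1 + dt * theta / w$C * (1 / w$Rp + 1 / w$Rd)
    A[nn + k, o] <- -dt * theta / (w$C * w$Rp)
  }
  Ainv <- solve(A)

  pc <- if (is.null(pc0)) numeric(no) else rep_len(as.numeric(pc0), no)
  p_prev_cycle <- NULL
  p_hist <- matrix(0, nsteps, nn)
  t_hist <- (seq_len(nsteps)) * dt
  qin <- waveform_at(inflow, t_hist)
  cycles <- 0L
  conv <- FALSE
  p_now <- numeric(nn)
  # per-outlet coefficients of the explicit part of the theta scheme
  co_p <- vapply(ow, function(w) dt * (1 - theta) / (w$C * w$Rp), numeric(1))
  co_c <- vapply(ow, function(w)
    1 - dt * (1 - theta) / w$C * (1 / w$Rp + 1 / w$Rd), numeric(1))
  for (cyc in seq_len(max_cycles)) {
    for (st in seq_len(nsteps)) {
      b <- numeric(nun)
      b[network$inlet] <- qin[st]
      b[nn + seq_len(no)] <- co_c * pc + co_p * p_now[on]
      z <- Ainv %*% b
      p_now <- z[1:nn]
      pc <- z[nn + seq_len(no)]
      p_hist[st, ] <- p_now
    }
    cycles <- cyc
    if (!is.null(p_prev_cycle)) {
      if (max(abs(p_hist - p_prev_cycle)) < p_tol) { conv <- TRUE; break }
    }
    p_prev_cycle <- p_hist
  }
  Q_hist <- t(g * (t(p_hist[, edges$from, drop = FALSE]) -
                   t(p_hist[, edges$to, drop = FALSE])))
  # junction mass residual on the final step (resistive nodes only)
  resid <- drop(G %*% p_now)
  resid[network$inlet] <- resid[network$inlet] - waveform_at(inflow, t_hist[nsteps])
  for (k in seq_len(no)) resid[on[k]] <- resid[on[k]] + (p_now[on[k]] - pc[k]) / ow[[k]]$Rp
  mass_resid <- max(abs(resid))

  mu <- network$blood$viscosity
  tau <- sweep(abs(Q_hist) * 1e-6, 2, 4 * mu / (pi * (edges$r_mm * 1e-3)^3), `*`)
  structure(list(time = t_hist, p = p_hist, Q = Q_hist, tau = tau,
                 pc = pc, cycles_to_converge = cycles,
                 converged_periodic = conv, mass_residual = mass_resid,
                 network = network, inflow = inflow, dt = dt),
            class = "hemo_result")
}

#' Peak systolic pressure drop
#'
#' The AAo-to-DAo pressure difference evaluated at the instant of peak inflow
#' within the final converged cycle (`mode = "peak_inflow"`, the default), or
#' the maximum instantaneous difference over the cycle (`mode = "max_diff"`).
#' Floored at zero.
#'
#' @param result a [simulate_network()] result.
#' @param inlet_station,dao_station node indices; default inlet and DAo
#'   outlet.
#' @param mode see above.
#' @return PSPD in mmHg.
#' @export
compute_pspd <- function(result, inlet_station = NULL, dao_station = NULL,
                         mode = c("peak_inflow", "max_diff")) {
  mode <- match.arg(mode)
  net <- result$network
  i <- inlet_station %||% net$inlet
  j <- dao_station %||% unname(net$outlet_nodes["DAo"])
  dp <- result$p[, i] - result$p[, j]
  if (mode == "peak_inflow") {
    qin <- waveform_at(result$inflow, result$time)
    dp <- dp[which.max(qin)]
  } else dp <- max(dp)
  max(0, dp)
}

#' Time-averaged wall shear stress
#'
#' Poiseuille closure per network edge, `tau = 4 mu |Q| / (pi r^3)`, averaged
#' over the final cycle; the maximum over edges is the surrogate for the
#' pointwise surface maximum.
#'
#' @param result a [simulate_network()] result.
#' @return list with `per_segment` (per-edge TAWSS, Pa), `max`, `min`.
#' @export
compute_tawss <- function(result) {
  tw <- colMeans(result$tau)
  list(per_segment = tw, max = max(tw), min = min(tw))
}
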