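test_that("lumen profiling recovers cylinder sections", {
  m <- generate_aorta(straight_cfg(radius = 10, length = 100, n_circ = 32))
  pr <- extract_lumen_profile(m, n_stations = 30)
  expect_equal(unname(pr$trunk$areas), rep(pi * 100, length(pr$trunk$areas)),
               tolerance = 0.01)
  expect_equal(unname(pr$trunk$effective_radii[1]), 10, tolerance = 0.005)
})

test_that("a local narrowing shows up as the minimum effective radius", {
  prof_fun <- function(f) 10 - 4 * exp(-((f - 0.5) / 0.08)^2)  # dip to 6 mm
  m <- generate_aorta(straight_cfg(radius = 10, length = 100, n_circ = 24,
                                   n_axial = 60))
  m2 <- generate_aorta(anatomy_config(arch_radius_mm = 0, arch_angle_deg = 0,
                                      vessel_radius_profile = prof_fun,
                                      branch_count = 0, asc_length_mm = 50,
                                      desc_length_mm = 50,
                                      n_circumferential = 32, n_axial = 60))
  pr <- extract_lumen_profile(m2, n_stations = 61)
  expect_equal(min(pr$trunk$effective_radii), 6, tolerance = 0.02)
})

test_that("station refinement leaves the total resistance stable", {
  blood <- blood_properties()
  R_tot <- function(n) {
    pr <- single_segment_profile(r = 8, L = 100, n = n)
    net <- build_network(pr, default_outlets(pr), blood)
    sum(net$edges$R)
  }
  expect_equal(R_tot(21), R_tot(41), tolerance = 0.02)
})

test_that("Poiseuille segment resistance matches the closed form", {
  # mu = 0.00371 Pa.s, r = 10 mm, L = 100 mm, Q = 100 mL/s
  pr <- single_segment_profile(r = 10, L = 100)
  net <- build_network(pr, default_outlets(pr), blood_properties())
  R_tot <- sum(net$edges$R)                     # mmHg.s/mL
  dP_mmHg <- R_tot * 100
  dP_Pa <- dP_mmHg * 133.322
  expect_equal(dP_Pa, 9.447, tolerance = 1e-3)
  expect_equal(dP_mmHg, 0.0709, tolerance = 1e-3)
  # r^-4 law
  pr2 <- single_segment_profile(r = 5, L = 100)
  net2 <- build_network(pr2, default_outlets(pr2), blood_properties())
  expect_equal(sum(net2$edges$R) / R_tot, 16, tolerance = 1e-9)
  # missing outlet parameters are rejected
  expect_error(build_network(pr, list(), blood_properties()), "missing")
})

test_that("identical parallel branches split the flow evenly", {
  pr <- branched_profile()
  out <- default_outlets(pr)
  # make the DAo outlet stiff so flow prefers the branches symmetrically
  net <- build_network(pr, out, blood_properties())
  wf <- flow_waveform(period = 0.5, samples = rep(100, 11))
  res <- simulate_network(net, wf, dt = 0.5 / 200, max_cycles = 10)
  b1 <- res$Q[nrow(res$Q), net$edges$segment == "branch_1"][1]
  b2 <- res$Q[nrow(res$Q), net$edges$segment == "branch_2"][1]
  expect_equal(b1, b2, tolerance = 1e-9)
})

test_that("steady RCR inlet pressure equals Q (Rp + Rd)", {
  pr <- single_segment_profile(r = 10, L = 10)
  net <- build_network(pr, list(DAo = windkessel_params(Rp = 0.05, C = 0.3,
                                                        Rd = 1)),
                       blood_properties())
  wf <- flow_waveform(period = 1, samples = rep(100, 11))
  res <- simulate_network(net, wf, dt = 1 / 150, max_cycles = 10, p_tol = 0.01)
  p_in <- res$p[nrow(res$p), net$inlet]
  expect_equal(p_in, 100 * (0.05 + 1), tolerance = 1e-3)
})

test_that("sinusoidal RCR response matches the analytic periodic solution", {
  Rp <- 0.06; Rd <- 1.1; C <- 0.8
  period <- 0.8
  w <- 2 * pi / period
  Q0 <- 80; Q1 <- 40
  n <- 2001
  tt <- seq(0, period, length.out = n)
  wf <- flow_waveform(period = period, samples = Q0 + Q1 * sin(w * tt))
  pr <- single_segment_profile(r = 12, L = 5, n = 3)  # negligible resistance
  net <- build_network(pr, list(DAo = windkessel_params(Rp, C, Rd)),
                       blood_properties())
  res <- simulate_network(net, wf, dt = period / 1000, max_cycles = 10,
                          p_tol = 0.001)
  # analytic: pc responds to Q through Rd/(1 + i w Rd C); p_in = Q Rp + pc
  H <- Rd / sqrt(1 + (w * Rd * C)^2)
  phi <- atan(w * Rd * C)
  p_ref <- Q0 * (Rp + Rd) + Q1 * Rp * sin(w * res$time) +
    Q1 * H * sin(w * res$time - phi)
  p_in <- res$p[, net$inlet]
  err <- max(abs(p_in - p_ref)) / diff(range(p_ref))
  expect_lt(err, 0.005)
})

test_that("pressures decay passively once the inflow stops", {
  pr <- single_segment_profile(r = 10, L = 10)
  net <- build_network(pr, list(DAo = windkessel_params(Rp = 0.05, C = 0.5,
                                                        Rd = 1)),
                       blood_properties())
  # charged compliance, zero inflow: strictly monotone passive decay
  wfz <- flow_waveform(period = 1, samples = rep(0, 11))
  res <- simulate_network(net, wfz, dt = 1 / 200, max_cycles = 1, pc0 = 80)
  p_in <- res$p[, net$inlet]
  expect_true(all(diff(p_in) < 0))
  expect_gt(p_in[length(p_in)], 0)
})

test_that("junction mass balance closes to solver precision", {
  pr <- branched_profile()
  net <- build_network(pr, default_outlets(pr), blood_properties())
  res <- simulate_network(net, flow_waveform(), dt = 0.5 / 200)
  expect_lt(res$mass_residual, 1e-9)
})

test_that("the linear network scales pressures with the inflow", {
  pr <- single_segment_profile(r = 8, L = 80)
  net <- build_network(pr, default_outlets(pr), blood_properties())
  wf1 <- flow_waveform(period = 0.5, samples = rep(50, 11))
  wf2 <- flow_waveform(period = 0.5, samples = rep(100, 11))
  r1 <- simulate_network(net, wf1, max_cycles = 10, p_tol = 1e-4)
  r2 <- simulate_network(net, wf2, max_cycles = 10, p_tol = 1e-4)
  expect_equal(2 * r1$p[nrow(r1$p), ], r2$p[nrow(r2$p), ], tolerance = 1e-6)
})

test_that("PSPD reads the AAo-DAo drop at peak inflow and never goes negative", {
  pr <- single_segment_profile(r = 6, L = 120)
  net <- build_network(pr, default_outlets(pr), blood_properties())
  res <- simulate_network(net, flow_waveform(peak_flow = 200))
  ps <- compute_pspd(res)
  qpk <- which.max(tevgsim:::waveform_at(res$inflow, res$time))
  expect_equal(ps, res$p[qpk, net$inlet] - res$p[qpk, net$outlet_nodes["DAo"]],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_gte(ps, 0)
  expect_equal(compute_pspd(res, inlet_station = 3, dao_station = 3), 0)
  expect_gte(compute_pspd(res, mode = "max_diff"), ps)
})

test_that("PSPD rises strictly as the lumen narrows", {
  radii <- seq(10, 5, by = -0.5)
  ps <- vapply(radii, function(r) {
    pr <- single_segment_profile(r = r, L = 100)
    net <- build_network(pr, default_outlets(pr), blood_properties())
    compute_pspd(simulate_network(net, flow_waveform(peak_flow = 200)))
  }, numeric(1))
  expect_true(all(diff(ps) > 0))
})

test_that("TAWSS follows the Poiseuille closure arithmetic", {
  # steady Q = 100 mL/s, r = 10 mm: tau = 4 mu Q / (pi r^3) = 0.4724 Pa
  pr <- single_segment_profile(r = 10, L = 100)
  net <- build_network(pr, default_outlets(pr), blood_properties())
  wf <- flow_waveform(period = 0.5, samples = rep(100, 11))
  res <- simulate_network(net, wf, max_cycles = 10, p_tol = 1e-4)
  tw <- compute_tawss(res)
  expect_equal(unname(tw$max), 0.4724, tolerance = 1e-3)
  # r^-3 law at fixed flow
  pr2 <- single_segment_profile(r = 5, L = 100)
  net2 <- build_network(pr2, default_outlets(pr2), blood_properties())
  tw2 <- compute_tawss(simulate_network(net2, wf, max_cycles = 10,
                                        p_tol = 1e-4))
  expect_equal(tw2$max / tw$max, 8, tolerance = 1e-9)
})

test_that("time averaging of the wall shear is a plain mean", {
  # square-wave tau alternating 0 and 4 Pa in equal halves -> TAWSS 2 Pa
  pr <- single_segment_profile(r = 10, L = 100, n = 3)
  net <- build_network(pr, default_outlets(pr), blood_properties())
  n <- 200
  q_for_tau4 <- 4 * pi * (10e-3)^3 / (4 * blood_properties()$viscosity) * 1e6
  wf <- flow_waveform(period = 1, samples = rep(c(q_for_tau4, 0),
                                                each = n / 2))
  res <- simulate_network(net, wf, dt = 1 / n, max_cycles = 10, p_tol = 1e-3)
  tw <- compute_tawss(res)
  expect_equal(unname(tw$max), 2, tolerance = 0.02)
})

test_that("hemodynamic metrics are invariant to rigid motion of the shape", {
  m <- generate_aorta(straight_cfg(radius = 8, length = 100, n_circ = 16))
  run <- function(model) {
    pr <- extract_lumen_profile(model, 30)
    net <- build_network(pr, default_outlets(pr), blood_properties())
    res <- simulate_network(net, flow_waveform())
    c(compute_pspd(res), compute_tawss(res)$max)
  }
  base <- run(m)
  set.seed(17)
  R <- random_rotation()
  mr <- map_nodes_test(m, function(n) sweep(n %*% t(R), 2, c(9, -4, 2), `+`))
  expect_equal(run(mr), base, tolerance = 1e-9)
})
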