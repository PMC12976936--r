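test_that("percent differences follow the reporting convention", {
  # a 2.5 mmHg rise on a 5 mmHg baseline is 50%; 7.2 Pa on 10 Pa is 72%
  expect_equal(percent_diff(7.5, 5.0), 50)
  expect_equal(percent_diff(17.2, 10.0), 72)
  expect_equal(percent_diff(3.3, 3.3), 0)
  expect_equal(percent_diff(2.5, 5), -50)
  expect_error(percent_diff(1, 0), "nonzero")
})

test_that("safety classification applies the clinical thresholds strictly", {
  lim <- safe_limits()
  expect_true(classify_safe(10, tawss_max = 5, tawss_min = 1, lim))
  expect_false(classify_safe(25, tawss_max = 5, tawss_min = 1, lim))
  expect_false(classify_safe(10, tawss_max = 16, tawss_min = 1, lim))
  # TAWSS floor: below 0.4 Pa flags atherosclerosis susceptibility
  expect_false(classify_safe(10, tawss_max = 5, tawss_min = 0.3, lim))
  # strictness at the boundaries
  expect_false(classify_safe(20, tawss_max = 5, tawss_min = 1, lim))
  expect_false(classify_safe(10, tawss_max = 15, tawss_min = 1, lim))
  expect_false(classify_safe(10, tawss_max = 5, tawss_min = 0.4, lim))
  expect_error(safe_limits(tawss_min = 15, tawss_max = 0.4), "invalid")
})

test_that("the sweep grid holds the prescribed increments and baseline", {
  g <- sweep_grid(translation_mm = 5, rotation_deg = 20,
                  scale_range = c(0.8, 1.2))
  expect_equal(sum(g$factor == "baseline"), 1L)
  expect_equal(nrow(g), 1 + 3 * 10 + 3 * 8 + 8)
  tl <- sort(g$value[g$factor == "t_IS"])
  expect_equal(tl, setdiff(-5:5, 0))
  rl <- sort(g$value[g$factor == "r_AP"])
  expect_equal(rl, setdiff(seq(-20, 20, 5), 0))
  sl <- sort(g$value[g$factor == "size"])
  expect_equal(sl, setdiff(seq(0.8, 1.2, 0.05), 1))
  # threshold-driven grid stays inside mean +/- 2 SD
  thr <- sample_deviation_thresholds(list(
    deviation_spec(c(1, 0, 0)), deviation_spec(c(3, 0, 0))))
  g2 <- sweep_grid(thresholds = thr)
  expect_true(all(g2$value[g2$factor == "t_LR"] >=
                    thr$translation["LR", "lo"] - 1e-9))
})

test_that("a small one-factor sweep is safe at baseline with 0% differences", {
  case <- small_case()
  grid <- sweep_grid(translation_mm = 2, rotation_deg = 5,
                     scale_range = c(0.95, 1.05), t_step = 2, r_step = 5,
                     s_step = 0.05)
  map <- run_sweep(case, grid)
  rec <- map$records
  b <- rec[rec$factor == "baseline", ]
  expect_equal(b$pspd_pct, 0)
  expect_equal(b$tawss_pct, 0)
  expect_true(b$safe)
  expect_true(all(c("t_LR", "t_AP", "t_IS", "r_LR", "r_AP", "r_IS", "size")
                  %in% names(map$allowable)))
  for (rng in map$allowable) expect_true(rng["lo"] <= rng["hi"])
  # reversing the sweep order leaves the records identical (statelessness)
  grid_rev <- grid[rev(seq_len(nrow(grid))), ]
  map_rev <- run_sweep(case, grid_rev)
  rr <- map_rev$records[order(map_rev$records$factor, map_rev$records$value), ]
  oo <- rec[order(rec$factor, rec$value), ]
  rownames(rr) <- rownames(oo) <- NULL
  expect_equal(rr, oo)
})

test_that("allowable ranges are contiguous intervals containing zero", {
  rec <- data.frame(factor = c("baseline", rep("t_IS", 4)),
                    value = c(0, -2, -1, 1, 2),
                    safe = c(TRUE, FALSE, TRUE, TRUE, TRUE),
                    evaluated = TRUE)
  rng <- tevgsim:::allowable_ranges(rec)
  expect_equal(unname(rng$t_IS), c(-1, 2))
  # an unsafe gap cuts the interval even if points beyond it are safe
  rec2 <- data.frame(factor = c("baseline", rep("t_IS", 4)),
                     value = c(0, 1, 2, 3, 4),
                     safe = c(TRUE, TRUE, FALSE, TRUE, TRUE),
                     evaluated = TRUE)
  rng2 <- tevgsim:::allowable_ranges(rec2)
  expect_equal(unname(rng2$t_IS), c(0, 1))
  # unsafe baseline-size convention: zero deviation for size is scale 1
  rec3 <- data.frame(factor = c("baseline", rep("size", 2)),
                     value = c(0, 0.95, 1.05),
                     safe = c(TRUE, TRUE, TRUE),
                     evaluated = TRUE)
  rng3 <- tevgsim:::allowable_ranges(rec3)
  expect_equal(unname(rng3$size), c(0.95, 1.05))
})

test_that("two-factor grid points are generated on demand", {
  g <- sweep_grid(translation_mm = 2, rotation_deg = 5, t_step = 1,
                  scale_range = c(1, 1))
  ext <- tevgsim:::expand_pairs(g, list(c("t_IS", "t_AP")))
  expect_equal(nrow(ext), 16)
  expect_true(all(ext$t_IS != 0 & ext$t_AP != 0))
})

test_that("undersized grafts hurt hemodynamics more than oversized ones", {
  # pure size sweep on the straight-tube fixture: smaller grafts raise PSPD
  # and peak TAWSS monotonically
  case <- tevg_case(straight_cfg(radius = 6, length = 100, n_circ = 12,
                                 n_axial = 40), s_prox = 35, s_dist = 65,
                    load_steps = 4)
  sizes <- c(0.8, 0.9, 1)
  out <- lapply(sizes, function(s)
    evaluate_case(case, deviation_spec(scale = s)))
  expect_true(all(vapply(out, function(r) r$converged, logical(1))))
  ps <- vapply(out, function(r) r$pspd, numeric(1))
  tw <- vapply(out, function(r) r$tawss_max, numeric(1))
  expect_true(all(diff(ps) < 0))   # shrinking size ordered 0.8 < 0.9 < 1
  expect_true(all(diff(tw) < 0))
})

test_that("shape validation improves on the uncorrected design", {
  case <- small_case()
  # identity deviation: prediction equals design, improvement ~ 0
  v0 <- run_shape_validation(case, deviation_spec(), noise_mm = 0.2, seed = 4,
                             n_samples = 1500)
  expect_lt(abs(v0$improvement_pct), 5)
  # a real deviation: the FE-informed prediction is strictly closer
  v1 <- run_shape_validation(case, deviation_spec(translation_mm = c(0, 0, 4)),
                             noise_mm = 0.2, seed = 4, n_samples = 1500)
  expect_gt(v1$improvement_pct, 0)
  expect_lt(v1$report_fe$mean_surface_distance_mm,
            v1$report_design$mean_surface_distance_mm)
})

test_that("sweep CSV output is byte-identical across reruns", {
  case <- small_case()
  grid <- sweep_grid(translation_mm = 1, rotation_deg = 5,
                     scale_range = c(1, 1), t_step = 1, r_step = 5)
  grid <- grid[grid$factor %in% c("baseline", "t_IS", "r_LR"), ]
  class(grid) <- c("sweep_grid", "data.frame")
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_tolerance_csv(run_sweep(case, grid), f1)
  write_tolerance_csv(run_sweep(case, grid), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
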