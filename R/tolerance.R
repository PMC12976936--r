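#' Percentage difference against a baseline metric
#'
#' `100 * (value - baseline) / baseline`; the convention behind all reported
#' sensitivity percentages (a 2.5 mmHg rise on a 5 mmHg baseline is 50%).
#'
#' @param value,baseline metric values; `baseline != 0`.
#' @return percent difference.
#' @export
percent_diff <- function(value, baseline) {
  if (any(baseline == 0)) stop("baseline metric must be nonzero")
  100 * (value - baseline) / baseline
}

#' Hemodynamically safe limits
#'
#' Clinical thresholds: PSPD below 20 mmHg (larger drops mark stenosis needing
#' reintervention) and TAWSS strictly between 0.4 Pa (atherosclerosis
#' susceptibility below) and 15 Pa (thrombosis risk above).
#'
#' @param pspd_max mmHg.
#' @param tawss_min,tawss_max Pa, `tawss_min < tawss_max`.
#' @return Object of class `safe_limits`.
#' @export
safe_limits <- function(pspd_max = 20, tawss_min = 0.4, tawss_max = 15) {
  if (!(tawss_min < tawss_max) || any(c(pspd_max, tawss_min, tawss_max) <= 0))
    stop("invalid safe limits")
  structure(list(pspd_max = pspd_max, tawss_min = tawss_min,
                 tawss_max = tawss_max), class = "safe_limits")
}

#' Classify a case as hemodynamically safe
#'
#' @param pspd peak systolic pressure drop (mmHg).
#' @param tawss_max,tawss_min extreme per-segment TAWSS values (Pa).
#' @param limits a [safe_limits()].
#' @return logical: `TRUE` iff `pspd < pspd_max`, `tawss_min` above the floor
#'   and `tawss_max` below the ceiling (strict inequalities).
#' @export
classify_safe <- function(pspd, tawss_max, tawss_min, limits = safe_limits()) {
  pspd < limits$pspd_max & tawss_min > limits$tawss_min &
    tawss_max < limits$tawss_max
}

#' One-factor-at-a-time deviation sweep grid
#'
#' Translations in 1-mm increments along each anatomical direction, rotations
#' in 5 degree increments about each axis, size in 5% increments; the
#' zero-deviation baseline is always included. Ranges are either given
#' directly or derived from observed deviations via
#' [sample_deviation_thresholds()].
#'
#' @param translation_mm half-range per direction (mm), length 3 or scalar.
#' @param rotation_deg half-range per axis (degrees), length 3 or scalar.
#' @param scale_range size-scale range, length 2.
#' @param t_step,r_step,s_step increments (1 mm / 5 deg / 0.05 by default).
#' @param thresholds optional [sample_deviation_thresholds()] output; ranges
#'   are then `[lo, hi]` per axis.
#' @return Object of class `sweep_grid`: data.frame of grid points with
#'   columns `factor` ("baseline", "t_LR", ..., "r_IS", "size"), `value`, and
#'   the full deviation columns.
#' @export
sweep_grid <- function(translation_mm = 5, rotation_deg = 20,
                       scale_range = c(0.8, 1.2), t_step = 1, r_step = 5,
                       s_step = 0.05, thresholds = NULL) {
  axes <- c("LR", "AP", "IS")
  seq_range <- function(lo, hi, by) {
    v <- sort(unique(c(0, seq(ceiling(lo / by) * by, floor(hi / by) * by, by = by))))
    v[v >= lo - 1e-9 & v <= hi + 1e-9 | v == 0]
  }
  if (!is.null(thresholds)) {
    t_rng <- thresholds$translation
    r_rng <- thresholds$rotation
    s_rng <- thresholds$scale
  } else {
    t_half <- rep_len(translation_mm, 3)
    r_half <- rep_len(rotation_deg, 3)
    t_rng <- cbind(-t_half, t_half)
    r_rng <- cbind(-r_half, r_half)
    s_rng <- scale_range
  }
  rows <- data.frame(factor = "baseline", value = 0, t_LR = 0, t_AP = 0,
                     t_IS = 0, r_LR = 0, r_AP = 0, r_IS = 0, size = 1,
                     stringsAsFactors = FALSE)
  for (k in 1:3) {
    for (v in setdiff(seq_range(t_rng[k, 1], t_rng[k, 2], t_step), 0)) {
      r <- rows[1, ]; r$factor <- paste0("t_", axes[k]); r$value <- v
      r[[paste0("t_", axes[k])]] <- v
      rows <- rbind(rows, r)
    }
    for (v in setdiff(seq_range(r_rng[k, 1], r_rng[k, 2], r_step), 0)) {
      r <- rows[1, ]; r$factor <- paste0("r_", axes[k]); r$value <- v
      r[[paste0("r_", axes[k])]] <- v
      rows <- rbind(rows, r)
    }
  }
  sv <- seq(round(s_rng[1] / s_step) * s_step, round(s_rng[2] / s_step) * s_step,
            by = s_step)
  for (v in setdiff(round(sv, 10), 1)) {
    r <- rows[1, ]; r$factor <- "size"; r$value <- v; r$size <- v
    rows <- rbind(rows, r)
  }
  rownames(rows) <- NULL
  structure(rows, class = c("sweep_grid", "data.frame"))
}

#' Bundle a configured implantation case
#'
#' Precomputes the resection and designed graft for a synthetic anatomy so
#' deviation scenarios can be evaluated repeatedly.
#'
#' @param config an [anatomy_config()].
#' @param s_prox,s_dist resection stations (mm); defaults pick the arch
#'   segment distal to the branch take-offs.
#' @param diameter_scale designed graft diameter scaling.
#' @param branched carry branch stubs for orphaned branches.
#' @param materials FE materials (see [fe_assembly()]).
#' @param inflow a [flow_waveform()].
#' @param outlets named list of [windkessel_params()]; defaults sized so the
#'   baseline mean pressure is arterial (~90 mmHg).
#' @param blood a [blood_properties()].
#' @param load_steps FE gap-closing ramp increments for pipeline evaluations
#'   (2 by default: the adaptive substepping and direct-solve fallback of
#'   [solve_implantation()] refine the ramp automatically wherever an
#'   increment fails, so a coarse initial ramp costs less without losing
#'   robustness).
#' @param n_stations lumen-profiling stations.
#' @return Object of class `tevg_case`.
#' @export
tevg_case <- function(config = anatomy_config(), s_prox = NULL, s_dist = NULL,
                      diameter_scale = 1, branched = FALSE,
                      materials = list(native = yeoh_material(),
                                       graft = yeoh_material(
                                         thickness = 0.7,
                                         stiffness_multiplier = 2.5)),
                      inflow = flow_waveform(),
                      outlets = NULL, blood = blood_properties(),
                      load_steps = 2L, n_stations = 50L) {
  aorta <- generate_aorta(config)
  L <- total_arclength(aorta$centerline)
  if (is.null(s_prox)) {
    s_prox <- if (length(aorta$branch_attach)) max(aorta$branch_attach) + 8
    else 0.35 * L
  }
  if (is.null(s_dist)) s_dist <- min(s_prox + 0.3 * L, 0.9 * L)
  planes <- place_resection_planes(aorta, s_prox, s_dist)
  rs <- resect(aorta, planes)
  graft <- design_graft(rs, diameter_scale = diameter_scale,
                        branched = branched, aorta = aorta)
  if (is.null(outlets)) {
    outlets <- list(DAo = windkessel_params(Rp = 0.08, C = 0.08, Rd = 2.6))
    for (nm in grep("^branch_", names(aorta$rings), value = TRUE))
      outlets[[nm]] <- windkessel_params(Rp = 0.3, C = 0.015, Rd = 9)
  }
  structure(list(config = config, aorta = aorta, planes = planes,
                 remnant = rs$remnant, resected = rs$resected,
                 cut_info = rs$cut_info, graft = graft, materials = materials,
                 inflow = inflow, outlets = outlets, blood = blood,
                 load_steps = as.integer(load_steps),
                 n_stations = as.integer(n_stations)),
            class = "tevg_case")
}

#' Evaluate one deviation scenario of a case
#'
#' Applies the deviation to the designed graft, solves the anastomosis FE
#' problem, profiles the deformed lumen, simulates the 0-D hemodynamics and
#' returns the metrics.
#'
#' @param case a [tevg_case()].
#' @param dev a [deviation_spec()].
#' @param keep_fields optional character vector of heavyweight fields to keep
#'   (`"report"`, `"profile"`, `"hemo"`).
#' @return list with `pspd`, `tawss_max`, `tawss_min`, `converged`,
#'   `strain_energy`, and any requested heavy fields.
#' @export
evaluate_case <- function(case, dev = deviation_spec(),
                          keep_fields = character(0)) {
  moved <- apply_deviation(case$graft, case$planes$prox, dev)
  asm <- fe_assembly(case$remnant, moved$graft, materials = case$materials,
                     load_steps = case$load_steps)
  rep <- solve_implantation(asm)
  if (!rep$converged)
    return(list(pspd = NA_real_, tawss_max = NA_real_, tawss_min = NA_real_,
                converged = FALSE, strain_energy = rep$strain_energy,
                reason = rep$diagnostics))
  prof <- extract_lumen_profile(rep$deformed, case$n_stations)
  net <- build_network(prof, case$outlets, case$blood)
  hemo <- simulate_network(net, case$inflow)
  tw <- compute_tawss(hemo)
  out <- list(pspd = compute_pspd(hemo), tawss_max = tw$max,
              tawss_min = tw$min, converged = TRUE,
              strain_energy = rep$strain_energy)
  if ("report" %in% keep_fields) out$report <- rep
  if ("profile" %in% keep_fields) out$profile <- prof
  if ("hemo" %in% keep_fields) out$hemo <- hemo
  out
}

#' Run a one-factor deviation sweep and build the tolerance map
#'
#' Evaluates every grid point of a one-factor-at-a-time sweep (optionally
#' plus 2-D factor pairs), computes percentage differences in PSPD and
#' maximum TAWSS against the zero-deviation baseline, classifies each point
#' against the safe limits, and extracts the per-direction allowable ranges
#' as the maximal contiguous safe interval containing the baseline. Failed FE
#' solves are recorded as unevaluated, never dropped.
#'
#' @param case a [tevg_case()].
#' @param grid a [sweep_grid()].
#' @param limits a [safe_limits()].
#' @param pairs optional list of factor-name pairs for 2-D grids, e.g.
#'   `list(c("t_IS", "t_AP"))`.
#' @param verbose print progress.
#' @return Object of class `tolerance_map`: `records` data.frame (deviation,
#'   metrics, percent differences, `safe`, `evaluated`), `baseline`,
#'   `allowable`, `limits`.
#' @export
run_sweep <- function(case, grid, limits = safe_limits(), pairs = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(grid, "sweep_grid") || is.data.frame(grid))
  grid <- as.data.frame(grid)
  if (!is.null(pairs)) grid <- rbind(grid, expand_pairs(grid, pairs))
  n <- nrow(grid)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    gp <- grid[i, ]
    dev <- deviation_spec(c(gp$t_LR, gp$t_AP, gp$t_IS),
                          c(gp$r_LR, gp$r_AP, gp$r_IS), gp$size)
    res[[i]] <- evaluate_case(case, dev)
    if (verbose)
      message(sprintf("[%d/%d] %s=%g: PSPD=%.3f TAWSSmax=%.3f %s", i, n,
                      gp$factor, gp$value, res[[i]]$pspd %||% NA,
                      res[[i]]$tawss_max %||% NA,
                      if (isTRUE(res[[i]]$converged)) "" else "(FE failed)"))
  }
  rec <- cbind(grid, data.frame(
    pspd = vapply(res, function(r) r$pspd, numeric(1)),
    tawss_max = vapply(res, function(r) r$tawss_max, numeric(1)),
    tawss_min = vapply(res, function(r) r$tawss_min, numeric(1)),
    evaluated = vapply(res, function(r) isTRUE(r$converged), logical(1))))
  ib <- which(rec$factor == "baseline")[1L]
  base <- rec[ib, ]
  if (!base$evaluated) stop("baseline case failed to solve or simulate")
  rec$pspd_pct <- percent_diff(rec$pspd, base$pspd)
  rec$tawss_pct <- percent_diff(rec$tawss_max, base$tawss_max)
  rec$safe <- classify_safe(rec$pspd, rec$tawss_max, rec$tawss_min, limits) &
    rec$evaluated
  structure(list(records = rec,
                 baseline = list(pspd = base$pspd, tawss_max = base$tawss_max,
                                 tawss_min = base$tawss_min),
                 allowable = allowable_ranges(rec), limits = limits),
            class = "tolerance_map")
}

expand_pairs <- function(grid, pairs) {
  out <- NULL
  for (pr in pairs) {
    v1 <- sort(unique(c(0, grid$value[grid$factor == pr[1]])))
    v2 <- sort(unique(c(0, grid$value[grid$factor == pr[2]])))
    for (a in v1) for (b in v2) {
      if (a == 0 || b == 0) next
      r <- grid[grid$factor == "baseline", ][1, ]
      r$factor <- paste(pr, collapse = "x")
      r$value <- NA_real_
      r[[pr[1]]] <- a
      r[[pr[2]]] <- b
      if (startsWith(pr[1], "size")) r$size <- a
      if (startsWith(pr[2], "size")) r$size <- b
      out <- rbind(out, r)
    }
  }
  out
}

# Maximal contiguous safe interval containing zero deviation, per factor.
allowable_ranges <- function(rec) {
  out <- list()
  for (f in setdiff(unique(rec$factor), "baseline")) {
    if (grepl("x", f, fixed = TRUE)) next
    r <- rec[rec$factor == f | rec$factor == "baseline", ]
    zero <- if (f == "size") 1 else 0
    v <- sort(unique(c(zero, r$value[r$factor == f])))
    safe_at <- function(x) {
      if (x == zero) {
        rr <- rec[rec$factor == "baseline", ]
      } else rr <- r[r$factor == f & r$value == x, ]
      isTRUE(rr$safe[1L])
    }
    lo <- zero; hi <- zero
    below <- sort(v[v < zero], decreasing = TRUE)
    for (x in below) { if (safe_at(x)) lo <- x else break }
    above <- sort(v[v > zero])
    for (x in above) { if (safe_at(x)) hi <- x else break }
    out[[f]] <- c(lo = lo, hi = hi)
  }
  out
}

#' @export
print.tolerance_map <- function(x, ...) {
  cat(sprintf("<tolerance_map> %d record(s); baseline PSPD %.3f mmHg, max TAWSS %.3f Pa\n",
              nrow(x$records), x$baseline$pspd, x$baseline$tawss_max))
  for (nm in names(x$allowable))
    cat(sprintf("  %-6s allowable [%g, %g]\n", nm, x$allowable[[nm]]["lo"],
                x$allowable[[nm]]["hi"]))
  invisible(x)
}

#' Validate shape prediction against a synthetic postoperative reference
#'
#' Reproduces the shape-validation protocol: the observed placement deviation
#' is applied to the designed graft and the anastomosis FE solve yields the
#' predicted postoperative shape. Distance report A compares the unchanged
#' design to the postoperative reference, report B compares the FE-informed
#' prediction to the same reference; the improvement is
#' `100 (A_mean - B_mean) / A_mean`.
#'
#' @param case a [tevg_case()].
#' @param observed_deviation a [deviation_spec()].
#' @param reference_postop a reference postoperative [vessel_model()]; if
#'   `NULL` a synthetic one is built by solving the FE problem under the
#'   observed deviation and adding seeded measurement noise of `noise_mm`.
#' @param noise_mm synthetic surface-measurement noise amplitude (mm).
#' @param seed RNG seed for noise and surface sampling.
#' @param n_samples surface-distance samples.
#' @return list with `report_design` (A), `report_fe` (B), `improvement_pct`,
#'   `reference`.
#' @export
run_shape_validation <- function(case, observed_deviation,
                                 reference_postop = NULL, noise_mm = 0.2,
                                 seed = 1L, n_samples = 4000L) {
  designed <- evaluate_case(case, deviation_spec(), keep_fields = "report")
  if (!designed$converged) stop("designed baseline FE solve failed")
  designed_shape <- designed$report$deformed
  predicted <- evaluate_case(case, observed_deviation, keep_fields = "report")
  if (!predicted$converged) stop("deviated FE solve failed")
  predicted_shape <- predicted$report$deformed
  if (is.null(reference_postop)) {
    reference_postop <- predicted_shape
    reference_postop$nodes <- reference_postop$nodes +
      with_seed(seed + 7L,
                matrix(rnorm(length(reference_postop$nodes), sd = noise_mm),
                       ncol = 3))
  }
  A <- surface_distance(designed_shape, reference_postop,
                        n_samples = n_samples, seed = seed)
  B <- surface_distance(predicted_shape, reference_postop,
                        n_samples = n_samples, seed = seed)
  list(report_design = A, report_fe = B,
       improvement_pct = 100 * (A$mean_surface_distance_mm -
                                B$mean_surface_distance_mm) /
         A$mean_surface_distance_mm,
       reference = reference_postop)
}

#' Write tolerance-map records as CSV
#'
#' Deterministic writer (fixed column order and formatting) so identical
#' configurations and seeds reproduce byte-identical files.
#'
#' @param map a [run_sweep()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tolerance_csv <- function(map, path) {
  rec <- map$records
  num <- vapply(rec, is.numeric, logical(1))
  rec[num] <- lapply(rec[num], function(x) formatC(x, digits = 10, format = "g"))
  write.csv(rec, path, row.names = FALSE, quote = TRUE, eol = "\n")
  invisible(path)
}
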