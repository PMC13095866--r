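# Usability screening for kernel home-range estimates. Five a priori
# criteria decide whether a bear's KUD95 is trustworthy: (i) data
# sufficiency, (ii) temporal regularity, (iii) bandwidth stability,
# (iv) convergence of the area/cumulative-fix curve, (v) shape diagnostics.
# Bears failing any criterion keep their MCP but lose KUD summaries.

#' Usability criteria configuration
#'
#' @param min_fixes minimum usable fixes (default 150).
#' @param min_span_days minimum tracking span in days (default 45, inclusive).
#' @param max_median_interval_h maximum median fix interval (h, inclusive).
#' @param max_gap_days maximum tolerated gap (days); strictly larger fails.
#' @param href_nn_ratio admissible range of href / median nearest-neighbour
#'   distance (inclusive bounds).
#' @param plateau_slope_pct maximum absolute percent change in KUD95 area per
#'   additional `plateau_step` fixes (strictly smaller passes).
#' @param plateau_step fixes added per convergence-curve evaluation.
#' @param plateau_mode `"terminal"` (last segment only) or `"last_k"`.
#' @param plateau_last_k number of trailing segments when `plateau_mode =
#'   "last_k"`.
#' @param outside_mass_max maximum UD mass outside the buffered point hull.
#' @param hull_buffer_m buffer around the convex hull (m).
#' @param max_patches maximum disjoint patches in the 95% isopleth.
#' @export
usability_config <- function(min_fixes = 150, min_span_days = 45,
                             max_median_interval_h = 6, max_gap_days = 10,
                             href_nn_ratio = c(0.5, 3.0),
                             plateau_slope_pct = 1.0, plateau_step = 50,
                             plateau_mode = c("terminal", "last_k"),
                             plateau_last_k = 3,
                             outside_mass_max = 0.10, hull_buffer_m = 1000,
                             max_patches = 5) {
  plateau_mode <- match.arg(plateau_mode)
  stopifnot(min_fixes > 0, min_span_days > 0, max_median_interval_h > 0,
            max_gap_days > 0, href_nn_ratio[1] < href_nn_ratio[2],
            plateau_slope_pct > 0, plateau_step > 0, outside_mass_max > 0,
            hull_buffer_m > 0, max_patches > 0)
  structure(as.list(environment()), class = "usability_config")
}

#' Temporal regularity of a fix schedule
#'
#' @param traj trajectory with a `timestamp` column (post-QC).
#' @return list: `median_interval_h`, `max_gap_days`.
#' @export
temporal_regularity <- function(traj) {
  if (nrow(traj) < 2) stop("temporal_regularity requires >= 2 fixes", call. = FALSE)
  dt_h <- diff(as.numeric(traj$timestamp)) / 3600
  list(median_interval_h = stats::median(dt_h),
       max_gap_days = max(dt_h) / 24)
}

#' Bandwidth stability: href relative to the median nearest-neighbour distance
#'
#' @param h bandwidth (m).
#' @param points planar points (m).
#' @return list: `ratio` (`NA` when the median nearest-neighbour distance is
#'   zero), `median_nn_m`, `degenerate` flag.
#' @export
bandwidth_stability <- function(h, points) {
  pts <- as_xy(points)
  if (nrow(pts) < 2) stop("bandwidth_stability requires >= 2 points", call. = FALSE)
  D <- as.matrix(stats::dist(pts))
  diag(D) <- Inf
  med_nn <- stats::median(apply(D, 1, min))
  if (med_nn <= 0) return(list(ratio = NA_real_, median_nn_m = med_nn, degenerate = TRUE))
  list(ratio = h / med_nn, median_nn_m = med_nn, degenerate = FALSE)
}

#' KUD95 area versus cumulative-fix convergence curve
#'
#' Recomputes href and the KUD95 area on chronological prefixes of the track
#' (n = step, 2*step, ..., N, always including N) over a fixed grid covering
#' the full point set, and measures the terminal percent change per segment.
#'
#' @param points planar points in chronological order (m).
#' @param grid optional [make_grid()] over the full set.
#' @param step fixes added per evaluation (default 50).
#' @param level isopleth level.
#' @return list: `curve` (data.frame n, area_km2), `terminal_slope_pct`
#'   (`NA` when fewer than two evaluation points exist), `slopes_pct`.
#' @export
convergence_curve <- function(points, grid = NULL, step = 50, level = 95) {
  pts <- as_xy(points)
  N <- nrow(pts)
  if (N < 2 * step)
    return(list(curve = data.frame(n = integer(), area_km2 = numeric()),
                terminal_slope_pct = NA_real_, slopes_pct = numeric()))
  if (is.null(grid)) grid <- make_grid(pts)
  ns <- unique(c(seq(step, N, by = step), N))
  area <- vapply(ns, function(n) {
    sub <- pts[seq_len(n), , drop = FALSE]
    h <- tryCatch(href_bandwidth(sub), error = function(e) NA_real_)
    if (!is.finite(h)) return(NA_real_)
    ud_isopleth(kud(sub, grid, h), level)$area_km2
  }, numeric(1))
  curve <- data.frame(n = ns, area_km2 = area)
  slopes <- 100 * abs(diff(area)) / utils::head(area, -1)
  list(curve = curve,
       terminal_slope_pct = slopes[length(slopes)],
       slopes_pct = slopes)
}

#' Shape diagnostics of a utilisation distribution
#'
#' Measures the UD mass in cells whose centres lie outside the convex hull of
#' the points dilated by `hull_buffer_m`, and the number of disjoint patches
#' in the isopleth.
#'
#' @param ud a [kud()] estimate.
#' @param points the planar points the UD was fitted to.
#' @param cfg a [usability_config()].
#' @param level isopleth level.
#' @return list: `outside_mass_fraction`, `patch_count`.
#' @export
shape_diagnostics <- function(ud, points, cfg = usability_config(), level = 95) {
  pts <- as_xy(points)
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  cc <- expand.grid(x = ud$grid$xc, y = ud$grid$yc)  # column-major: x fastest
  inside <- points_near_polygon(cc$x, cc$y, hull, cfg$hull_buffer_m)
  # mass matrix is rows = y, cols = x; transpose to match expand.grid order
  mvec <- as.vector(t(ud$mass))
  outside_mass <- sum(mvec[!inside])
  iso <- ud_isopleth(ud, level)
  list(outside_mass_fraction = outside_mass, patch_count = iso$patch_count)
}

# TRUE for points within `buffer` of a convex polygon (inside or near edge)
points_near_polygon <- function(px, py, hull, buffer) {
  n <- nrow(hull)
  if (n == 1) {
    return(sqrt((px - hull[1, 1])^2 + (py - hull[1, 2])^2) <= buffer)
  }
  inside <- rep(TRUE, length(px))
  mindist2 <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- hull[i, 1]; ay <- hull[i, 2]
    bx <- hull[j, 1]; by <- hull[j, 2]
    # hull from chull() is clockwise; inside = consistent cross-product sign
    cross <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
    inside <- inside & (cross <= 0)
    # squared distance to segment
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 > 0) pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2)) else 0
    d2 <- (px - (ax + t * vx))^2 + (py - (ay + t * vy))^2
    mindist2 <- pmin(mindist2, d2)
  }
  inside | mindist2 <= buffer^2
}

#' Assess KUD usability for one bear
#'
#' Evaluates all five criteria and reports measured values, per-criterion
#' pass flags, and their conjunction. Degenerate conditions (undefined
#' bandwidth ratio, unevaluable convergence curve) fail the criterion rather
#' than erroring.
#'
#' @param traj cleaned trajectory (lon/lat + timestamps).
#' @param proj a [projection_spec()]; default brackets the trajectory.
#' @param cfg a [usability_config()].
#' @param cell_size,buffer grid parameters (m).
#' @return object of class `usability_report`: list of measured values,
#'   `flags` (named logical, 5), `overall_pass`.
#' @export
assess_usability <- function(traj, proj = NULL, cfg = usability_config(),
                             cell_size = 250, buffer = 10000) {
  n <- nrow(traj)
  span_days <- if (n >= 2)
    as.numeric(difftime(max(traj$timestamp), min(traj$timestamp), units = "days"))
  else 0
  sufficiency <- n >= cfg$min_fixes && span_days >= cfg$min_span_days

  if (n >= 2) {
    reg <- temporal_regularity(traj)
    regularity <- reg$median_interval_h <= cfg$max_median_interval_h &&
      reg$max_gap_days <= cfg$max_gap_days
  } else {
    reg <- list(median_interval_h = NA_real_, max_gap_days = NA_real_)
    regularity <- FALSE
  }

  ptr <- project_trajectory(traj, proj)
  pts <- cbind(ptr$x, ptr$y)
  h <- tryCatch(href_bandwidth(pts), error = function(e) NA_real_)
  bw <- if (is.finite(h)) bandwidth_stability(h, pts)
        else list(ratio = NA_real_, median_nn_m = NA_real_, degenerate = TRUE)
  bandwidth_ok <- !is.na(bw$ratio) &&
    bw$ratio >= cfg$href_nn_ratio[1] && bw$ratio <= cfg$href_nn_ratio[2]

  grid <- if (is.finite(h)) make_grid(pts, cell_size, buffer) else NULL
  conv <- if (is.finite(h))
    convergence_curve(pts, grid, step = cfg$plateau_step)
  else list(curve = NULL, terminal_slope_pct = NA_real_, slopes_pct = numeric())
  slope_ok <- if (cfg$plateau_mode == "terminal") {
    !is.na(conv$terminal_slope_pct) && conv$terminal_slope_pct < cfg$plateau_slope_pct
  } else {
    k <- min(cfg$plateau_last_k, length(conv$slopes_pct))
    k > 0 && all(utils::tail(conv$slopes_pct, k) < cfg$plateau_slope_pct, na.rm = FALSE)
  }

  if (is.finite(h)) {
    ud <- kud(pts, grid, h)
    shp <- shape_diagnostics(ud, pts, cfg)
    shape_ok <- shp$outside_mass_fraction <= cfg$outside_mass_max &&
      shp$patch_count <= cfg$max_patches
  } else {
    shp <- list(outside_mass_fraction = NA_real_, patch_count = NA_integer_)
    shape_ok <- FALSE
  }

  flags <- c(sufficiency = sufficiency, regularity = regularity,
             bandwidth_stability = bandwidth_ok, convergence = slope_ok,
             shape = shape_ok)
  structure(list(animal_id = traj$animal_id[1],
                 n_fixes = n, span_days = span_days,
                 median_interval_h = reg$median_interval_h,
                 max_gap_days = reg$max_gap_days,
                 href_m = h, href_nn_ratio = bw$ratio,
                 terminal_slope_pct = conv$terminal_slope_pct,
                 outside_mass_fraction = shp$outside_mass_fraction,
                 patch_count = shp$patch_count,
                 flags = flags,
                 overall_pass = all(flags)),
            class = "usability_report")
}
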