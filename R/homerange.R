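# Home-range estimators: 95% minimum convex polygon and kernel utilisation
# distribution with the reference (href) bandwidth, volume isopleths, and
# areas in km2. All geometry is planar (equal-area projected metres).

#' Minimum convex polygon home range
#'
#' Retains the `floor(percent/100 * n)` points nearest (Euclidean) to the
#' arithmetic mean centre and returns the convex hull of the retained points
#' with its area.
#'
#' @param points matrix or data.frame with planar `x`, `y` in metres.
#' @param percent percentage of locations enclosed (default 95).
#' @return list: `polygon` (hull vertices, closed implicitly), `area_km2`,
#'   `n_used`, `degenerate` flag (collinear/zero-area geometry).
#' @export
mcp <- function(points, percent = 95) {
  pts <- as_xy(points)
  n <- nrow(pts)
  if (n < 5) stop("mcp requires at least 5 points", call. = FALSE)
  if (percent <= 0 || percent > 100) stop("percent must be in (0, 100]", call. = FALSE)
  ctr <- colMeans(pts)
  d <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  keep <- order(d)[seq_len(floor(percent / 100 * n))]
  sub <- pts[keep, , drop = FALSE]
  hull <- grDevices::chull(sub)
  poly <- sub[hull, , drop = FALSE]
  a <- polygon_area(poly[, 1], poly[, 2])
  list(polygon = poly, area_km2 = a / 1e6, n_used = length(keep),
       degenerate = a <= 0 || length(hull) < 3)
}

# shoelace; vertices in any consistent order
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

as_xy <- function(points) {
  if (is.data.frame(points)) {
    stopifnot(all(c("x", "y") %in% names(points)))
    points <- cbind(points$x, points$y)
  }
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  pts[stats::complete.cases(pts), , drop = FALSE]
}

#' Reference bandwidth for a bivariate kernel density
#'
#' `h = sqrt(0.5 * (var(x) + var(y))) * n^(-1/6)` with n-1 denominators —
#' the standard bivariate normal reference ("href") smoothing parameter.
#'
#' @param points planar points (m).
#' @return bandwidth in metres.
#' @export
href_bandwidth <- function(points) {
  pts <- as_xy(points)
  n <- nrow(pts)
  if (n < 2) stop("href_bandwidth requires at least 2 points", call. = FALSE)
  h <- sqrt(0.5 * (stats::var(pts[, 1]) + stats::var(pts[, 2]))) * n^(-1 / 6)
  if (!is.finite(h) || h <= 0)
    stop("degenerate input: zero spatial variance, href undefined", call. = FALSE)
  h
}

#' Analysis grid covering a point set plus a buffer
#'
#' Cell origins are snapped to multiples of `cell_size` so translated copies
#' of a point set re-anchor consistently.
#'
#' @param points planar points (m).
#' @param cell_size grid resolution (m), default 250.
#' @param buffer margin around the point extent (m), default 10000.
#' @return object of class `grid_spec` with `xmin, ymin, cell_size, n_cols,
#'   n_rows` and cell-centre accessors `xc`, `yc`.
#' @export
make_grid <- function(points, cell_size = 250, buffer = 10000) {
  pts <- as_xy(points)
  if (cell_size <= 0) stop("cell_size must be positive", call. = FALSE)
  xmin <- floor((min(pts[, 1]) - buffer) / cell_size) * cell_size
  ymin <- floor((min(pts[, 2]) - buffer) / cell_size) * cell_size
  n_cols <- ceiling((max(pts[, 1]) + buffer - xmin) / cell_size)
  n_rows <- ceiling((max(pts[, 2]) + buffer - ymin) / cell_size)
  structure(list(xmin = xmin, ymin = ymin, cell_size = cell_size,
                 n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                 xc = xmin + (seq_len(n_cols) - 0.5) * cell_size,
                 yc = ymin + (seq_len(n_rows) - 0.5) * cell_size),
            class = "grid_spec")
}

#' Kernel utilisation distribution on a grid
#'
#' Isotropic bivariate Gaussian kernel density evaluated at cell centres and
#' normalised so cell masses sum to 1 over the grid. The Gaussian kernel is
#' separable, so the density field is a single matrix product.
#'
#' @param points planar points (m).
#' @param grid a [make_grid()] object (default: 250 m cells, 10 km buffer).
#' @param h bandwidth in metres (default [href_bandwidth()]).
#' @return object of class `ud_estimate`: `grid`, `href`, `mass` (n_rows x
#'   n_cols matrix of cell masses summing to 1), `total_mass` (pre-normalised
#'   coverage, ~1 when the buffer holds the kernels).
#' @export
kud <- function(points, grid = NULL, h = NULL) {
  pts <- as_xy(points)
  if (is.null(h)) h <- href_bandwidth(pts)
  if (h <= 0) stop("bandwidth h must be positive", call. = FALSE)
  if (is.null(grid)) grid <- make_grid(pts)
  # A[i, k] = phi((xc_i - x_k)/h), B[j, k] likewise for y; density = B %*% t(A)
  A <- outer(grid$xc, pts[, 1], function(cx, px) stats::dnorm(cx - px, sd = h))
  B <- outer(grid$yc, pts[, 2], function(cy, py) stats::dnorm(cy - py, sd = h))
  dens <- (B %*% t(A)) / nrow(pts)             # rows = y, cols = x
  raw_mass <- dens * grid$cell_size^2
  total <- sum(raw_mass)
  structure(list(grid = grid, href = h, mass = raw_mass / total,
                 total_mass = total),
            class = "ud_estimate")
}

#' Volume isopleth of a utilisation distribution
#'
#' Cells are sorted by density descending (ties broken by row-major cell
#' index) and included until the cumulative mass reaches `level`/100. The
#' isopleth is the union of included cell squares; its area is the included
#' cell count times the cell area, and patches are counted with
#' 8-connectivity.
#'
#' @param ud a [kud()] estimate.
#' @param level isopleth level in percent (default 95).
#' @return list: `included` (logical matrix), `area_km2`, `patch_count`,
#'   `mass_enclosed`.
#' @export
ud_isopleth <- function(ud, level = 95) {
  stopifnot(inherits(ud, "ud_estimate"))
  m <- ud$mass
  ord <- order(-as.vector(m), seq_along(m))
  cum <- cumsum(as.vector(m)[ord])
  k <- which(cum >= level / 100)[1]
  if (is.na(k)) k <- length(ord)
  inc <- logical(length(m))
  inc[ord[seq_len(k)]] <- TRUE
  inc <- matrix(inc, nrow(m), ncol(m))
  list(included = inc,
       area_km2 = sum(inc) * ud$grid$cell_size^2 / 1e6,
       patch_count = count_patches(inc),
       mass_enclosed = cum[k])
}

# connected components of a logical matrix under 8-connectivity
count_patches <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(0L)
  nr <- nrow(mask)
  nc <- ncol(mask)
  id <- matrix(NA_integer_, nr, nc)
  id[idx] <- seq_along(idx)
  edges <- list()
  shifts <- list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  for (s in shifts) {
    dr <- s[1]; dc <- s[2]
    r1 <- max(1, 1 + dr):min(nr, nr + dr)
    r0 <- r1 - dr
    c1 <- max(1, 1 + dc):min(nc, nc + dc)
    c0 <- c1 - dc
    a <- id[r0, c0, drop = FALSE]
    b <- id[r1, c1, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) edges[[length(edges) + 1]] <- cbind(a[ok], b[ok])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  igraph::components(g)$no
}

#' Per-bear home-range estimation over a set of cleaned trajectories
#'
#' For each animal: project to equal-area metres, compute MCP at `percent`,
#' the href bandwidth, and (optionally) the kernel UD and its 95% isopleth.
#' Animals with fewer than `min_fixes` usable fixes are excluded with a
#' reason. Tracking days are the elapsed time between first and last fix,
#' rounded up.
#'
#' @param trajectories list of cleaned trajectories (lon/lat) or a single
#'   data.frame with an `animal_id` column.
#' @param proj a [projection_spec()]; default brackets all fixes jointly.
#' @param cell_size,buffer grid parameters for the UD (m).
#' @param percent MCP/isopleth level.
#' @param min_fixes minimum usable fixes for estimation (default 30).
#' @param compute_kud if `FALSE`, skip the kernel estimator (MCP-only runs).
#' @return data.frame: `animal_id, mcp_km2, kud_km2, href_m, n_fixes,
#'   tracking_days, excluded_reason`; attribute `uds` carries the per-animal
#'   [kud()] objects when computed.
#' @export
estimate_home_ranges <- function(trajectories, proj = NULL, cell_size = 250,
                                 buffer = 10000, percent = 95, min_fixes = 30,
                                 compute_kud = TRUE) {
  if (is.data.frame(trajectories))
    trajectories <- split(trajectories, trajectories$animal_id)
  if (is.null(proj)) {
    all_lon <- unlist(lapply(trajectories, `[[`, "lon"))
    all_lat <- unlist(lapply(trajectories, `[[`, "lat"))
    proj <- projection_for(all_lon, all_lat)
  }
  uds <- list()
  rows <- lapply(trajectories, function(tr) {
    id <- tr$animal_id[1]
    n <- nrow(tr)
    days <- if (n >= 2) ceiling(as.numeric(difftime(max(tr$timestamp), min(tr$timestamp),
                                                    units = "days"))) else 0
    if (n < min_fixes)
      return(data.frame(animal_id = id, mcp_km2 = NA_real_, kud_km2 = NA_real_,
                        href_m = NA_real_, n_fixes = n, tracking_days = days,
                        excluded_reason = "insufficient fixes",
                        stringsAsFactors = FALSE))
    ptr <- project_trajectory(tr, proj)
    pts <- cbind(ptr$x, ptr$y)
    m <- mcp(pts, percent)
    kud_a <- NA_real_
    h <- tryCatch(href_bandwidth(pts), error = function(e) NA_real_)
    if (compute_kud && is.finite(h)) {
      ud <- kud(pts, make_grid(pts, cell_size, buffer), h)
      uds[[id]] <<- ud
      kud_a <- ud_isopleth(ud, percent)$area_km2
    }
    data.frame(animal_id = id, mcp_km2 = m$area_km2, kud_km2 = kud_a,
               href_m = h, n_fixes = n, tracking_days = days,
               excluded_reason = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "uds") <- uds
  attr(out, "projection") <- proj
  out
}
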