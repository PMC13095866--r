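# Projection and home-range estimators against closed-form oracles.

test_that("the projection origin maps to (0,0) and round-trips are sub-metre", {
  ps <- study_projection()
  o <- albers_forward(42.6, 40.2, ps)
  expect_equal(o$x, 0, tolerance = 1e-9)
  expect_equal(o$y, 0, tolerance = 1e-9)

  set.seed(1)
  lon <- runif(100, 42.4, 42.8)
  lat <- runif(100, 40.2, 40.5)
  xy <- albers_forward(lon, lat, ps)
  ll <- albers_inverse(xy$x, xy$y, ps)
  # 1e-5 degrees ~ 1 m
  expect_lt(max(abs(ll$lon - lon)), 1e-5)
  expect_lt(max(abs(ll$lat - lat)), 1e-5)
})

test_that("projected areas match the spherical closed form within 0.1%", {
  ps <- study_projection()
  lon0 <- 42.5; lon1 <- 42.7; lat0 <- 40.25; lat1 <- 40.40
  R <- 6371007.181
  truth <- R^2 * (lon1 - lon0) * pi / 180 * (sin(lat1 * pi / 180) - sin(lat0 * pi / 180))
  # dense boundary of the lon/lat rectangle, projected, shoelace area
  k <- 200
  blon <- c(seq(lon0, lon1, length.out = k), rep(lon1, k),
            seq(lon1, lon0, length.out = k), rep(lon0, k))
  blat <- c(rep(lat0, k), seq(lat0, lat1, length.out = k),
            rep(lat1, k), seq(lat1, lat0, length.out = k))
  xy <- albers_forward(blon, blat, ps)
  a <- bearhr:::polygon_area(xy$x, xy$y)
  expect_lt(abs(a - truth) / truth, 0.001)
})

test_that("MCP retains the nearest points and returns the hull area", {
  # 100% of a unit-km square: hull area equals the square
  set.seed(2)
  sq <- rbind(cbind(c(0, 0, 1000, 1000), c(0, 1000, 0, 1000)),
              matrix(runif(192, 100, 900), ncol = 2))
  m <- mcp(sq, percent = 100)
  expect_equal(m$area_km2, 1, tolerance = 1e-12)

  # one extreme outlier among 20 points is peeled at 95%
  inner <- rbind(cbind(c(0, 0, 1000, 1000), c(0, 1000, 0, 1000)),
                 matrix(runif(30, 200, 800), ncol = 2))
  pts <- rbind(inner, c(1e5, 1e5))
  m95 <- mcp(pts, percent = 95)     # floor(0.95*20) = 19 points retained
  expect_equal(m95$n_used, 19)
  expect_equal(m95$area_km2, 1, tolerance = 1e-12)

  # collinear points: degenerate zero-area polygon, flagged
  line <- cbind(seq(0, 1000, length.out = 6), seq(0, 2000, length.out = 6))
  ml <- mcp(line, 100)
  expect_equal(ml$area_km2, 0)
  expect_true(ml$degenerate)

  expect_error(mcp(matrix(0, 4, 2)), "at least 5")
})

test_that("MCP area is non-decreasing in the percent level", {
  set.seed(3)
  pts <- matrix(rnorm(400, 0, 1500), ncol = 2)
  areas <- vapply(c(50, 70, 90, 95, 100), function(p) mcp(pts, p)$area_km2, numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("href follows the reference formula and its scale equivariance", {
  set.seed(4)
  pts <- matrix(rnorm(200, 0, 1000), ncol = 2)
  n <- nrow(pts)
  expect_equal(href_bandwidth(pts),
               sqrt(0.5 * (var(pts[, 1]) + var(pts[, 2]))) * n^(-1 / 6))
  expect_equal(href_bandwidth(2 * pts), 2 * href_bandwidth(pts), tolerance = 1e-12)
  expect_error(href_bandwidth(matrix(5, 10, 2)), "degenerate")

  # isotropic normal: h ~= sigma * n^(-1/6) (Monte Carlo, fixed seed)
  set.seed(5)
  big <- matrix(rnorm(20000, 0, 2000), ncol = 2)
  expect_lt(abs(href_bandwidth(big) / (2000 * 10000^(-1 / 6)) - 1), 0.02)
})

test_that("kernel UD conserves mass and reproduces single-kernel probabilities", {
  pt <- matrix(c(0, 0), 1, 2)
  grid <- make_grid(pt, cell_size = 250, buffer = 10000)
  ud <- kud(pt, grid, h = 1000)
  expect_equal(sum(ud$mass), 1, tolerance = 1e-6)
  expect_equal(ud$total_mass, 1, tolerance = 1e-6)  # buffer >= 5h holds the kernel
  expect_true(all(ud$mass >= 0))

  # analytic bivariate normal cell probability vs midpoint-rule mass
  ix <- which.min(abs(grid$xc - 600))
  iy <- which.min(abs(grid$yc - (-300)))
  cs <- grid$cell_size
  exact <- (pnorm((grid$xc[ix] + cs / 2) / 1000) - pnorm((grid$xc[ix] - cs / 2) / 1000)) *
           (pnorm((grid$yc[iy] + cs / 2) / 1000) - pnorm((grid$yc[iy] - cs / 2) / 1000))
  expect_lt(abs(ud$mass[iy, ix] - exact) / exact, 0.01)
  expect_error(kud(pt, grid, h = 0), "positive")
})

test_that("the UD reflects when the points reflect about the grid axis", {
  set.seed(6)
  pts <- matrix(rnorm(300, 0, 800), ncol = 2)
  grid <- list(xmin = -5000, ymin = -5000, cell_size = 250,
               n_cols = 40L, n_rows = 40L,
               xc = -5000 + (1:40 - 0.5) * 250, yc = -5000 + (1:40 - 0.5) * 250)
  class(grid) <- "grid_spec"
  ud1 <- kud(pts, grid, h = 500)
  ud2 <- kud(cbind(-pts[, 1], pts[, 2]), grid, h = 500)
  expect_equal(ud2$mass, ud1$mass[, ncol(ud1$mass):1], tolerance = 1e-12)
})

test_that("isopleths are monotone in level and count separated patches", {
  set.seed(7)
  pts <- matrix(rnorm(600, 0, 1000), ncol = 2)
  ud <- kud(pts)
  i95 <- ud_isopleth(ud, 95)
  i100 <- ud_isopleth(ud, 100)
  expect_gte(i100$area_km2, i95$area_km2)
  expect_gte(i95$mass_enclosed, 0.95)
  expect_equal(i95$patch_count, 1)

  # two tight clusters 50h apart -> two patches
  h <- 200
  two <- rbind(matrix(rnorm(200, 0, 300), ncol = 2),
               matrix(rnorm(200, 50 * h, 300), ncol = 2))
  ud2 <- kud(two, make_grid(two, 250, 5000), h = h)
  expect_equal(ud_isopleth(ud2, 95)$patch_count, 2)
})

test_that("KUD95 of an OU track converges to the smoothed Gaussian oracle", {
  mp <- movement_params(sigma = 2000, beta_ou = 0.25, n_fixes = 2000)
  tr <- simulate_trajectory(mp, seed = 7)
  pts <- cbind(tr$x, tr$y)
  h <- href_bandwidth(pts)
  area <- ud_isopleth(kud(pts, make_grid(pts), h), 95)$area_km2
  oracle <- pi * (2000^2 + h^2) * qchisq(0.95, 2) / 1e6
  expect_lt(abs(area - oracle) / oracle, 0.10)
})

test_that("KUD95 area is invariant to rigid translation of the point set", {
  set.seed(8)
  pts <- matrix(rnorm(500, 0, 1200), ncol = 2)
  a0 <- ud_isopleth(kud(pts, make_grid(pts), h = 500), 95)$area_km2
  shift <- pts; shift[, 1] <- shift[, 1] + 250 * 173; shift[, 2] <- shift[, 2] - 250 * 91
  a1 <- ud_isopleth(kud(shift, make_grid(shift), h = 500), 95)$area_km2
  expect_equal(a1, a0, tolerance = 1e-12)   # grid re-anchors on cell multiples
  odd <- pts + 137.3
  a2 <- ud_isopleth(kud(odd, make_grid(odd), h = 500), 95)$area_km2
  expect_lt(abs(a2 - a0) / a0, 0.01)
})

test_that("per-bear estimation excludes data-poor bears and is deterministic", {
  trajs <- list(
    sim_clean_geo_track(sigma = 1500, n_fixes = 200, seed = 1, animal_id = "B001"),
    sim_clean_geo_track(sigma = 2500, n_fixes = 200, seed = 2, animal_id = "B002"),
    sim_clean_geo_track(sigma = 1500, n_fixes = 10, seed = 3, animal_id = "B003"))
  trajs <- lapply(trajs, function(t) t[, setdiff(names(t), c("x", "y", "defect"))])
  hr1 <- estimate_home_ranges(trajs, compute_kud = TRUE)
  hr2 <- estimate_home_ranges(trajs, compute_kud = TRUE)
  expect_identical(hr1$mcp_km2, hr2$mcp_km2)
  expect_identical(hr1$kud_km2, hr2$kud_km2)
  expect_equal(hr1$excluded_reason[hr1$animal_id == "B003"], "insufficient fixes")
  expect_true(is.na(hr1$mcp_km2[hr1$animal_id == "B003"]))
  expect_gt(hr1$mcp_km2[hr1$animal_id == "B002"], hr1$mcp_km2[hr1$animal_id == "B001"])
  expect_equal(hr1$tracking_days[1], ceiling(199 / 24))
})

test_that("both estimators rank true range areas (Spearman >= 0.9, 30 bears)", {
  spec <- population_spec(n_males = 20, n_females = 10, seed = 77)
  sim <- simulate_population(spec, movement_params(n_fixes = 800), no_errors())
  hr <- estimate_home_ranges(split(sim$fixes, sim$fixes$animal_id), compute_kud = TRUE)
  m <- merge(hr, sim$truth, by = "animal_id")
  expect_gte(cor(m$mcp_km2, m$true_area_km2, method = "spearman"), 0.9)
  expect_gte(cor(m$kud_km2, m$true_area_km2, method = "spearman"), 0.9)
})

test_that("the UD surface matches an independent kernel density implementation", {
  skip_if_not_installed("MASS")
  set.seed(9)
  pts <- matrix(rnorm(400, 0, 900), ncol = 2)
  grid <- make_grid(pts, cell_size = 500, buffer = 3000)
  h <- 600
  ud <- kud(pts, grid, h)
  # MASS::kde2d uses bandwidth = 4 * kernel SD and an inclusive sequence grid
  kd <- MASS::kde2d(pts[, 1], pts[, 2], h = 4 * h,
                    n = c(grid$n_cols, grid$n_rows),
                    lims = c(range(grid$xc), range(grid$yc)))
  ref <- t(kd$z)                      # kde2d: rows = x; ud: rows = y
  ref_mass <- ref / sum(ref)
  expect_lt(max(abs(ud$mass - ref_mass)), 1e-10)
})
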