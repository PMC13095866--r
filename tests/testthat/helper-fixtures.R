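# Shared fixtures built in code.

# clean OU track in WGS84 lon/lat placed in the study window
sim_clean_geo_track <- function(sigma = 1800, n_fixes = 2000, seed = 3,
                                beta_ou = 0.25, fix_interval = 1,
                                animal_id = "B001") {
  mp <- movement_params(sigma = sigma, beta_ou = beta_ou,
                        fix_interval = fix_interval, n_fixes = n_fixes)
  tr <- simulate_trajectory(mp, seed = seed, animal_id = animal_id)
  ps <- study_projection()
  ll <- albers_inverse(tr$x, tr$y, ps)
  tr$lon <- ll$lon
  tr$lat <- ll$lat
  tr
}

# raw fix row constructor with sensible defaults
make_fix <- function(animal_id = "A", timestamp, lon = 42.6, lat = 40.35,
                     fix_type = "3D", hdop = 2, altitude_m = 2000) {
  data.frame(animal_id = animal_id,
             timestamp = as.POSIXct(timestamp, tz = "UTC"),
             lon = lon, lat = lat, fix_type = fix_type, hdop = hdop,
             altitude_m = altitude_m, stringsAsFactors = FALSE)
}

# degrees of latitude giving an exact haversine distance (pure north-south)
lat_offset_for_m <- function(dist_m) dist_m / 6371000 * 180 / pi

# bear-record table on the truth scale (no movement simulation): log area
# model with configurable sex effect; mass dimorphic and independent of area
truth_scale_table <- function(seed, n_m = 46, n_f = 23, beta_sex = 0.65,
                              sd_log = 0.7) {
  set.seed(seed)
  sex <- c(rep("M", n_m), rep("F", n_f))
  la <- log(40) + beta_sex * (sex == "M") + rnorm(n_m + n_f, 0, sd_log)
  mass <- ifelse(sex == "M", rnorm(n_m + n_f, 160, 35), rnorm(n_m + n_f, 108, 22))
  data.frame(animal_id = sprintf("B%03d", seq_along(sex)), sex = sex,
             mcp_km2 = exp(la), log_mcp = la, log_mass = log(mass),
             stringsAsFactors = FALSE)
}

# corrupted OU track in lon/lat: defects injected on the planar track, then
# projected so the corrupted coordinates are the geographic ones
sim_corrupt_geo_track <- function(em, sigma = 1500, n_fixes = 600, seed = 14,
                                  animal_id = "B001") {
  mp <- movement_params(sigma = sigma, beta_ou = 0.25, n_fixes = n_fixes)
  tr <- simulate_trajectory(mp, seed = seed, animal_id = animal_id)
  tr <- corrupt_trajectory(tr, em, seed = seed + 1L)
  ps <- study_projection()
  ll <- albers_inverse(tr$x, tr$y, ps)
  tr$lon <- ll$lon
  tr$lat <- ll$lat
  tr[, c("animal_id", "timestamp", "lon", "lat", "fix_type", "hdop",
         "altitude_m", "defect")]
}
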