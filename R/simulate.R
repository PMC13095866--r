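# Synthetic bear populations: Ornstein-Uhlenbeck movement with known
# home-range geometry, GPS defect injection, and sexually dimorphic
# correlated morphometrics. The OU stationary law is isotropic bivariate
# normal, so the true 95% home-range area has the closed form
# pi * sigma^2 * qchisq(0.95, 2), which downstream estimators are tested
# against.

#' Movement parameters for an Ornstein-Uhlenbeck track
#'
#' @param center numeric length-2, range centre in projected metres.
#' @param sigma stationary per-axis SD of position (m).
#' @param beta_ou mean-reversion rate (1/h); larger values decorrelate
#'   successive fixes faster.
#' @param fix_interval time between fixes (h).
#' @param n_fixes number of fixes.
#' @param start_time first timestamp (POSIXct, UTC).
#' @return object of class `movement_params`.
#' @export
movement_params <- function(center = c(0, 0), sigma = 1800, beta_ou = 0.25,
                            fix_interval = 1, n_fixes = 2000,
                            start_time = as.POSIXct("2023-05-01 00:00:00", tz = "UTC")) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0)
    stop("sigma must be a single non-negative number", call. = FALSE)
  if (!is.numeric(beta_ou) || length(beta_ou) != 1 || beta_ou <= 0)
    stop("beta_ou must be a single positive number", call. = FALSE)
  if (!is.numeric(n_fixes) || n_fixes < 2)
    stop("n_fixes must be >= 2", call. = FALSE)
  if (!is.numeric(fix_interval) || fix_interval <= 0)
    stop("fix_interval must be positive", call. = FALSE)
  structure(list(center = center, sigma = sigma, beta_ou = beta_ou,
                 fix_interval = fix_interval, n_fixes = as.integer(n_fixes),
                 start_time = start_time),
            class = "movement_params")
}

#' GPS defect model
#'
#' Probabilities and magnitudes of the defect classes that the quality-control
#' cascade is designed to remove: missing coordinates, low-quality fix types,
#' high-HDOP fixes with degraded positions, teleport outliers, and dropout
#' gaps.
#'
#' @param p_missing_coord probability a fix loses its coordinates.
#' @param p_bad_fixtype probability a fix is demoted to a `2D-low`/`0D` type.
#' @param p_high_hdop probability a fix gets HDOP > 5 plus positional noise.
#' @param hdop_noise_sd SD (m) of the positional noise added to high-HDOP fixes.
#' @param p_teleport probability a fix is displaced by `teleport_dist`.
#' @param teleport_dist displacement (m) of teleport outliers.
#' @param gap_spec list of `c(start_index, length)` dropout windows.
#' @param altitude_range plausible altitude band (m) used when simulating.
#' @return object of class `error_model`.
#' @export
error_model <- function(p_missing_coord = 0.01, p_bad_fixtype = 0.02,
                        p_high_hdop = 0.02, hdop_noise_sd = 300,
                        p_teleport = 0.005, teleport_dist = 20000,
                        gap_spec = list(), altitude_range = c(1500, 3000)) {
  p <- c(p_missing_coord, p_bad_fixtype, p_high_hdop, p_teleport)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (teleport_dist <= 0) stop("teleport_dist must be positive", call. = FALSE)
  structure(list(p_missing_coord = p_missing_coord, p_bad_fixtype = p_bad_fixtype,
                 p_high_hdop = p_high_hdop, hdop_noise_sd = hdop_noise_sd,
                 p_teleport = p_teleport, teleport_dist = teleport_dist,
                 gap_spec = gap_spec, altitude_range = altitude_range),
            class = "error_model")
}

#' A defect-free error model (identity corruption)
#' @export
no_errors <- function() {
  error_model(p_missing_coord = 0, p_bad_fixtype = 0, p_high_hdop = 0,
              p_teleport = 0, gap_spec = list())
}

# Default morphometric trait set written to the morpho CSV.
morpho_trait_names <- function() {
  c("mass_kg", "body_length_cm", "chest_circ_cm", "shoulder_height_cm",
    "head_length_cm", "tail_length_cm",
    "front_paw_w_l_cm", "front_paw_w_r_cm", "hind_paw_w_l_cm", "hind_paw_w_r_cm")
}

# Trait correlation structure: the published correlations among mass, body
# length, chest circumference and shoulder height, extended with plausible
# values for head/tail lengths and paw widths (paw left/right pairs nearly
# collinear). Checked positive definite at build time of the spec object.
default_morpho_corr <- function() {
  tr <- morpho_trait_names()
  p <- length(tr)
  R <- matrix(0.55, p, p, dimnames = list(tr, tr))
  R["mass_kg", "body_length_cm"] <- R["body_length_cm", "mass_kg"] <- 0.79
  R["mass_kg", "chest_circ_cm"] <- R["chest_circ_cm", "mass_kg"] <- 0.93
  R["mass_kg", "shoulder_height_cm"] <- R["shoulder_height_cm", "mass_kg"] <- 0.71
  R["body_length_cm", "chest_circ_cm"] <- R["chest_circ_cm", "body_length_cm"] <- 0.76
  R["body_length_cm", "shoulder_height_cm"] <- R["shoulder_height_cm", "body_length_cm"] <- 0.69
  R["chest_circ_cm", "shoulder_height_cm"] <- R["shoulder_height_cm", "chest_circ_cm"] <- 0.73
  R["head_length_cm", "mass_kg"] <- R["mass_kg", "head_length_cm"] <- 0.70
  R["head_length_cm", "body_length_cm"] <- R["body_length_cm", "head_length_cm"] <- 0.68
  R["tail_length_cm", c("mass_kg", "body_length_cm")] <- 0.35
  R[c("mass_kg", "body_length_cm"), "tail_length_cm"] <- 0.35
  R["tail_length_cm", setdiff(tr, c("mass_kg", "body_length_cm", "tail_length_cm"))] <- 0.30
  R[setdiff(tr, c("mass_kg", "body_length_cm", "tail_length_cm")), "tail_length_cm"] <- 0.30
  paw <- grep("paw", tr, value = TRUE)
  R[paw, paw] <- 0.75
  R["front_paw_w_l_cm", "front_paw_w_r_cm"] <- R["front_paw_w_r_cm", "front_paw_w_l_cm"] <- 0.92
  R["hind_paw_w_l_cm", "hind_paw_w_r_cm"] <- R["hind_paw_w_r_cm", "hind_paw_w_l_cm"] <- 0.92
  diag(R) <- 1
  R
}

# Sex-specific trait means and SDs. Males ~45% heavier than females,
# consistent with strong sexual size dimorphism in brown bears.
default_morpho_means <- function() {
  list(
    M = c(mass_kg = 160, body_length_cm = 182, chest_circ_cm = 128,
          shoulder_height_cm = 102, head_length_cm = 40, tail_length_cm = 12,
          front_paw_w_l_cm = 14, front_paw_w_r_cm = 14,
          hind_paw_w_l_cm = 13, hind_paw_w_r_cm = 13),
    F = c(mass_kg = 108, body_length_cm = 160, chest_circ_cm = 108,
          shoulder_height_cm = 90, head_length_cm = 35.5, tail_length_cm = 10.5,
          front_paw_w_l_cm = 12, front_paw_w_r_cm = 12,
          hind_paw_w_l_cm = 11.2, hind_paw_w_r_cm = 11.2))
}

default_morpho_sds <- function() {
  list(
    M = c(mass_kg = 35, body_length_cm = 12, chest_circ_cm = 12,
          shoulder_height_cm = 8, head_length_cm = 3, tail_length_cm = 2,
          front_paw_w_l_cm = 1, front_paw_w_r_cm = 1,
          hind_paw_w_l_cm = 1, hind_paw_w_r_cm = 1),
    F = c(mass_kg = 22, body_length_cm = 10, chest_circ_cm = 10,
          shoulder_height_cm = 7, head_length_cm = 2.5, tail_length_cm = 1.8,
          front_paw_w_l_cm = 0.9, front_paw_w_r_cm = 0.9,
          hind_paw_w_l_cm = 0.9, hind_paw_w_r_cm = 0.9))
}

#' Population-level simulation settings
#'
#' Defaults reproduce the study conditions: 46 males and 23 females, a
#' male-female contrast of 0.65 natural-log units in home-range area
#' (ratio e^0.65 = 1.92), a typical female range of 40 km2 (so a typical
#' male range of ~76 km2), and five individuals with missing body mass.
#'
#' @param n_males,n_females numbers of bears per sex.
#' @param log_area_ratio male-female contrast in log home-range area
#'   (natural-log units).
#' @param female_median_area median female true range area (km2).
#' @param between_bear_sd SD of log true area among bears of the same sex.
#' @param morpho_means_by_sex list with `M` and `F` named trait-mean vectors.
#' @param morpho_sds_by_sex list with `M` and `F` named trait-SD vectors.
#' @param morpho_corr trait correlation matrix (symmetric positive definite,
#'   unit diagonal).
#' @param n_missing_mass number of bears whose mass measurement is dropped.
#' @param seed integer seed.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(n_males = 46, n_females = 23,
                            log_area_ratio = 0.65, female_median_area = 40,
                            between_bear_sd = 0.7,
                            morpho_means_by_sex = default_morpho_means(),
                            morpho_sds_by_sex = default_morpho_sds(),
                            morpho_corr = default_morpho_corr(),
                            n_missing_mass = 5, seed = 1L) {
  if (n_males < 0 || n_females < 0) stop("sex counts must be >= 0", call. = FALSE)
  check_corr_matrix(morpho_corr)
  structure(list(n_males = as.integer(n_males), n_females = as.integer(n_females),
                 log_area_ratio = log_area_ratio,
                 female_median_area = female_median_area,
                 between_bear_sd = between_bear_sd,
                 morpho_means_by_sex = morpho_means_by_sex,
                 morpho_sds_by_sex = morpho_sds_by_sex,
                 morpho_corr = morpho_corr,
                 n_missing_mass = as.integer(n_missing_mass),
                 seed = as.integer(seed)),
            class = "population_spec")
}

check_corr_matrix <- function(R) {
  if (!is.matrix(R) || nrow(R) != ncol(R))
    stop("morpho_corr must be a square matrix", call. = FALSE)
  if (max(abs(R - t(R))) > 1e-10)
    stop("morpho_corr must be symmetric", call. = FALSE)
  if (max(abs(diag(R) - 1)) > 1e-10)
    stop("morpho_corr must have unit diagonal", call. = FALSE)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("morpho_corr must be positive definite", call. = FALSE)
  invisible(TRUE)
}

# chi-square 0.95 quantile with 2 df; pi*sigma^2*chi2_95_2 is the area of the
# 95% probability region of an isotropic bivariate normal with per-axis SD sigma.
chi2_95_2 <- function() stats::qchisq(0.95, df = 2)

#' True 95% range area (km2) of an isotropic Gaussian range with per-axis SD sigma (m)
#' @param sigma per-axis SD in metres.
#' @export
gaussian_range_area_km2 <- function(sigma) pi * sigma^2 * chi2_95_2() / 1e6

#' Per-axis SD (m) implied by a true 95% range area in km2
#' @param area_km2 area of the 95% probability region.
#' @export
sigma_from_area_km2 <- function(area_km2) sqrt(area_km2 * 1e6 / (pi * chi2_95_2()))

#' Simulate one Ornstein-Uhlenbeck GPS track
#'
#' Exact discrete-time OU transition per axis:
#' `x[t+1] = mu + a * (x[t] - mu) + N(0, sigma^2 * (1 - a^2))` with
#' `a = exp(-beta_ou * fix_interval)`; the initial position is drawn from the
#' stationary law `N(mu, sigma^2)`. Fixes carry clean metadata
#' (`fix_type = "3D"`, HDOP in (0, 5], plausible altitude).
#'
#' @param params a [movement_params()] object.
#' @param seed integer seed; identical seeds give identical tracks.
#' @param animal_id identifier written to the track.
#' @return data.frame with columns `animal_id, timestamp, x, y, fix_type,
#'   hdop, altitude_m, defect` (planar coordinates in metres; `defect` is the
#'   ground-truth corruption flag, empty for clean fixes).
#' @export
simulate_trajectory <- function(params, seed = 1L, animal_id = "B001") {
  if (!inherits(params, "movement_params")) stop("params must be movement_params", call. = FALSE)
  set.seed(seed)
  n <- params$n_fixes
  a <- exp(-params$beta_ou * params$fix_interval)
  innov_sd <- params$sigma * sqrt(1 - a^2)
  sim_axis <- function(mu) {
    z0 <- stats::rnorm(1, 0, params$sigma)
    eps <- stats::rnorm(n - 1, 0, innov_sd)
    mu + c(z0, stats::filter(eps, a, method = "recursive", init = z0))
  }
  x <- sim_axis(params$center[1])
  y <- sim_axis(params$center[2])
  ts <- params$start_time + seq(0, by = params$fix_interval * 3600, length.out = n)
  data.frame(animal_id = animal_id, timestamp = ts, x = x, y = y,
             fix_type = "3D",
             hdop = round(stats::runif(n, 0.5, 5.0), 2),
             altitude_m = round(stats::runif(n, 1600, 2800), 1),
             defect = "", stringsAsFactors = FALSE)
}

#' Inject GPS defects into a trajectory
#'
#' Applies, in order: dropout gaps, missing coordinates, bad fix types,
#' high-HDOP positional noise, and teleport displacements. Every corrupted
#' fix is flagged in the `defect` column so quality-control recall and
#' precision can be computed against ground truth. Defect classes are drawn
#' on disjoint fix sets so each flagged fix has exactly one cause.
#'
#' @param traj trajectory data.frame (planar `x`/`y` metres or `lon`/`lat`).
#' @param em an [error_model()].
#' @param seed integer seed.
#' @return trajectory of the same shape with defects applied and flagged.
#' @export
corrupt_trajectory <- function(traj, em, seed = 1L) {
  if (!inherits(em, "error_model")) stop("em must be an error_model", call. = FALSE)
  set.seed(seed)
  out <- traj
  planar <- all(c("x", "y") %in% names(out))
  cx <- if (planar) "x" else "lon"
  cy <- if (planar) "y" else "lat"

  if (length(em$gap_spec)) {
    drop <- unlist(lapply(em$gap_spec, function(g) seq(g[1], length.out = g[2])))
    drop <- drop[drop >= 1 & drop <= nrow(out)]
    if (length(drop)) out <- out[-unique(drop), , drop = FALSE]
  }
  n <- nrow(out)
  if (n == 0) return(out)

  u <- stats::runif(n)
  # disjoint assignment: cumulative probability bands
  p1 <- em$p_missing_coord
  p2 <- p1 + em$p_bad_fixtype
  p3 <- p2 + em$p_high_hdop
  p4 <- p3 + em$p_teleport
  miss <- which(u < p1)
  badf <- which(u >= p1 & u < p2)
  hih <- which(u >= p2 & u < p3)
  tele <- which(u >= p3 & u < p4)
  tele <- setdiff(tele, c(1L, n))   # keep endpoints anchored

  if (length(miss)) {
    out[miss, c(cx, cy)] <- NA_real_
    out$defect[miss] <- "missing_coord"
  }
  if (length(badf)) {
    out$fix_type[badf] <- sample(c("2D-low", "0D"), length(badf), replace = TRUE)
    out$defect[badf] <- "bad_fixtype"
  }
  if (length(hih)) {
    out$hdop[hih] <- round(stats::runif(length(hih), 5.01, 15), 2)
    noise <- matrix(stats::rnorm(2 * length(hih), 0, em$hdop_noise_sd), ncol = 2)
    out <- displace(out, hih, noise[, 1], noise[, 2], cx, cy, planar)
    out$defect[hih] <- "high_hdop"
  }
  if (length(tele)) {
    ang <- stats::runif(length(tele), 0, 2 * pi)
    out <- displace(out, tele, em$teleport_dist * cos(ang), em$teleport_dist * sin(ang),
                    cx, cy, planar)
    out$defect[tele] <- "teleport"
  }
  out
}

# displace rows idx by (dx, dy) metres; lon/lat displacement uses the local
# metres-per-degree scale (adequate for the defect magnitudes simulated).
displace <- function(df, idx, dx, dy, cx, cy, planar) {
  if (planar) {
    df[idx, cx] <- df[idx, cx] + dx
    df[idx, cy] <- df[idx, cy] + dy
  } else {
    m_per_deg_lat <- 111320
    df[idx, cy] <- df[idx, cy] + dy / m_per_deg_lat
    df[idx, cx] <- df[idx, cx] + dx / (m_per_deg_lat * cos(df[idx, cy] * pi / 180))
  }
  df
}

#' Simulate correlated sexually dimorphic morphometrics
#'
#' Draws per-sex multivariate normal traits on the standardised scale with
#' the spec's trait correlation matrix, then maps to trait units via
#' sex-specific means and SDs.
#'
#' @param spec a [population_spec()].
#' @return data.frame with `animal_id`, `sex` and one column per trait.
#' @export
simulate_morphometrics <- function(spec) {
  if (!inherits(spec, "population_spec")) stop("spec must be a population_spec", call. = FALSE)
  set.seed(spec$seed + 1000L)
  tr <- colnames(spec$morpho_corr)
  L <- chol(spec$morpho_corr)
  draw_sex <- function(n, sex) {
    if (n == 0) return(NULL)
    Z <- matrix(stats::rnorm(n * length(tr)), n) %*% L
    mu <- spec$morpho_means_by_sex[[sex]][tr]
    sd <- spec$morpho_sds_by_sex[[sex]][tr]
    X <- sweep(sweep(Z, 2, sd, `*`), 2, mu, `+`)
    colnames(X) <- tr
    data.frame(sex = sex, X, stringsAsFactors = FALSE)
  }
  out <- rbind(draw_sex(spec$n_males, "M"), draw_sex(spec$n_females, "F"))
  if (is.null(out)) return(data.frame())
  out <- cbind(animal_id = sprintf("B%03d", seq_len(nrow(out))), out)
  if (spec$n_missing_mass > 0 && nrow(out) > 0) {
    k <- min(spec$n_missing_mass, nrow(out))
    out$mass_kg[sample.int(nrow(out), k)] <- NA_real_
  }
  out
}

#' Simulate a full population: tracks, morphometrics and ground truth
#'
#' Per bear, the true 95% range area is drawn on the log scale:
#' `log(area) = log(female_median_area) + log_area_ratio * I(male) +
#' N(0, between_bear_sd^2)`; the OU per-axis SD follows from the Gaussian
#' 95%-region identity `area = pi * sigma^2 * qchisq(.95, 2)`. Range centres
#' are spread over the study window so projection code is exercised; tracks
#' are corrupted with `em` after simulation. Truth columns are returned in a
#' separate table, never inside the fixes.
#'
#' @param spec a [population_spec()].
#' @param mp_template [movement_params()] supplying schedule, `beta_ou`, size.
#' @param em an [error_model()] applied to every track.
#' @param geographic if `TRUE`, fixes are returned as WGS84 lon/lat placed in
#'   the study window (40.2-40.5 N, 42.4-42.8 E); otherwise planar metres.
#' @return list with `fixes` (one data.frame, defect column removed),
#'   `morpho`, and `truth` (`animal_id, sex, true_area_km2, sigma_m`, defect
#'   flags per fix in `truth_fixes`).
#' @export
simulate_population <- function(spec, mp_template = movement_params(),
                                em = error_model(), geographic = TRUE) {
  morpho <- simulate_morphometrics(spec)
  n <- nrow(morpho)
  set.seed(spec$seed)
  log_area <- log(spec$female_median_area) +
    spec$log_area_ratio * (morpho$sex == "M") +
    stats::rnorm(n, 0, spec$between_bear_sd)
  area <- exp(log_area)
  sigma <- sigma_from_area_km2(area)

  # spread centres on a coarse grid inside the nominal study window
  proj <- study_projection()
  ncol_g <- ceiling(sqrt(n))
  gx <- ((seq_len(n) - 1) %% ncol_g) * 25000
  gy <- ((seq_len(n) - 1) %/% ncol_g) * 25000

  fixes <- vector("list", n)
  truth_fixes <- vector("list", n)
  for (i in seq_len(n)) {
    mp <- movement_params(center = c(gx[i], gy[i]), sigma = sigma[i],
                          beta_ou = mp_template$beta_ou,
                          fix_interval = mp_template$fix_interval,
                          n_fixes = mp_template$n_fixes,
                          start_time = mp_template$start_time)
    tr <- simulate_trajectory(mp, seed = spec$seed + 13L * i, animal_id = morpho$animal_id[i])
    tr <- corrupt_trajectory(tr, em, seed = spec$seed + 13L * i + 7L)
    if (geographic) {
      ll <- albers_inverse(tr$x, tr$y, proj)
      tr$lon <- ll$lon
      tr$lat <- ll$lat
      tr <- tr[, c("animal_id", "timestamp", "lon", "lat", "fix_type", "hdop",
                   "altitude_m", "defect")]
    }
    truth_fixes[[i]] <- tr[, c("animal_id", "timestamp", "defect")]
    tr$defect <- NULL
    fixes[[i]] <- tr
  }
  list(fixes = do.call(rbind, fixes),
       morpho = morpho,
       truth = data.frame(animal_id = morpho$animal_id, sex = morpho$sex,
                          true_area_km2 = area, sigma_m = sigma,
                          stringsAsFactors = FALSE),
       truth_fixes = do.call(rbind, truth_fixes))
}

#' Write a fixes table to CSV in the documented column layout
#' @param fixes data.frame from [simulate_population()].
#' @param path output file.
#' @export
write_fixes_csv <- function(fixes, path) {
  cols <- c("animal_id", "timestamp", "lon", "lat", "fix_type", "hdop", "altitude_m")
  stopifnot(all(cols %in% names(fixes)))
  out <- fixes[, cols]
  names(out)[1] <- "AnimalID"
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a morphometric table to CSV
#' @param morpho data.frame from [simulate_morphometrics()].
#' @param path output file.
#' @export
write_morpho_csv <- function(morpho, path) {
  out <- morpho
  names(out)[names(out) == "animal_id"] <- "AnimalID"
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
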