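# GPS fix quality control: the filter cascade that removes unreliable
# positions before home-range estimation. Order: missing coordinates ->
# fix type -> HDOP -> altitude -> movement rules (coordinate jump, speed,
# step-length percentile), with the movement rules iterated to convergence
# because removing a fix merges its neighbouring steps.

#' Quality-control configuration
#'
#' Thresholds follow standard large-mammal telemetry practice: HDOP > 5
#' discarded (strict inequality), speeds above 10 km/h sustained over
#' intervals of 30 min or more, step lengths above `step_multiplier` times
#' the individual's 99th-percentile step, and coordinate jumps over 1 km
#' within 5 min or less.
#'
#' @param hdop_max maximum accepted HDOP (strictly greater is dropped).
#' @param speed_max km/h; strictly greater is dropped when the interval
#'   condition holds.
#' @param speed_min_interval minutes; the speed rule applies to intervals
#'   `>=` this value.
#' @param step_pctl percentile of the individual's step lengths (default 99).
#' @param step_multiplier multiple of that percentile above which the step's
#'   destination fix is dropped; admissible range 2-3.
#' @param jump_dist_km coordinate-jump distance threshold (km, strict).
#' @param jump_max_interval minutes; the jump rule applies to intervals `<=`
#'   this value.
#' @param altitude_range plausible altitude band (m); fixes with a present
#'   altitude outside it are dropped (missing altitude is tolerated).
#' @param allowed_fix_types retained fix-type codes.
#' @export
qc_config <- function(hdop_max = 5, speed_max = 10, speed_min_interval = 30,
                      step_pctl = 99, step_multiplier = 2.5,
                      jump_dist_km = 1, jump_max_interval = 5,
                      altitude_range = c(1000, 3500),
                      allowed_fix_types = c("3D", "2D-high")) {
  if (step_multiplier < 2 || step_multiplier > 3)
    stop("step_multiplier must lie in [2, 3]", call. = FALSE)
  stopifnot(hdop_max > 0, speed_max > 0, speed_min_interval > 0,
            jump_dist_km > 0, jump_max_interval > 0)
  structure(list(hdop_max = hdop_max, speed_max = speed_max,
                 speed_min_interval = speed_min_interval,
                 step_pctl = step_pctl, step_multiplier = step_multiplier,
                 jump_dist_km = jump_dist_km, jump_max_interval = jump_max_interval,
                 altitude_range = altitude_range,
                 allowed_fix_types = allowed_fix_types),
            class = "qc_config")
}

#' Parse a fixes CSV into per-animal trajectories
#'
#' Rows are sorted chronologically per animal; duplicate (animal, timestamp)
#' rows collapse to the first; rows without a parseable timestamp are dropped
#' and counted. Rows with missing coordinates are retained at parse and left
#' to the filter stage.
#'
#' @param path CSV with columns `AnimalID, timestamp, lon, lat, fix_type,
#'   hdop, altitude_m`.
#' @return named list of per-animal data.frames; attribute `parse_report`
#'   counts dropped/deduplicated rows.
#' @export
parse_fixes <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(AnimalID = "character"))
  required <- c("AnimalID", "timestamp", "lon", "lat", "fix_type", "hdop", "altitude_m")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("fixes file lacks mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  ts <- parse_timestamp(raw$timestamp)
  bad_ts <- is.na(ts)
  raw <- raw[!bad_ts, , drop = FALSE]
  ts <- ts[!bad_ts]
  raw$timestamp <- ts
  names(raw)[names(raw) == "AnimalID"] <- "animal_id"
  raw$lon <- suppressWarnings(as.numeric(raw$lon))
  raw$lat <- suppressWarnings(as.numeric(raw$lat))
  raw$hdop <- suppressWarnings(as.numeric(raw$hdop))
  raw$altitude_m <- suppressWarnings(as.numeric(raw$altitude_m))
  raw <- raw[order(raw$animal_id, raw$timestamp), , drop = FALSE]
  dup <- duplicated(raw[, c("animal_id", "timestamp")])
  n_dup <- sum(dup)
  raw <- raw[!dup, , drop = FALSE]
  out <- split(raw, raw$animal_id)
  attr(out, "parse_report") <- list(dropped_no_timestamp = sum(bad_ts),
                                    deduplicated = n_dup)
  out
}

parse_timestamp <- function(x) {
  fmts <- c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
            "%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M")
  ts <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (f in fmts) {
    todo <- is.na(ts)
    if (!any(todo)) break
    ts[todo] <- as.POSIXct(strptime(x[todo], f, tz = "UTC"), tz = "UTC")
  }
  ts
}

#' Step metrics between consecutive fixes with coordinates
#'
#' @param traj trajectory with `lon`, `lat`, `timestamp`.
#' @return data.frame: `from, to` (row indices into `traj`), `step_m`
#'   (haversine, mean Earth radius 6,371,000 m), `interval_min`, `speed_kmh`.
#' @export
step_metrics <- function(traj) {
  usable <- which(!is.na(traj$lon) & !is.na(traj$lat))
  if (length(usable) < 2)
    return(data.frame(from = integer(), to = integer(), step_m = numeric(),
                      interval_min = numeric(), speed_kmh = numeric()))
  i <- usable[-length(usable)]
  j <- usable[-1]
  d <- geosphere::distHaversine(cbind(traj$lon[i], traj$lat[i]),
                                cbind(traj$lon[j], traj$lat[j]), r = 6371000)
  dt <- as.numeric(difftime(traj$timestamp[j], traj$timestamp[i], units = "mins"))
  data.frame(from = i, to = j, step_m = d, interval_min = dt,
             speed_kmh = ifelse(dt > 0, (d / 1000) / (dt / 60), Inf))
}

#' Apply the quality-control filter cascade to one trajectory
#'
#' Rules, in order: (1) missing coordinates; (2) disallowed fix types;
#' (3) HDOP missing or above `hdop_max`; (4) altitude present but outside
#' `altitude_range`; then, iterating to convergence with steps recomputed
#' after each removal pass: (5) coordinate jumps (> `jump_dist_km` within
#' `<= jump_max_interval` min), (6) unrealistic speeds (> `speed_max` km/h
#' over `>= speed_min_interval` min), (7) steps above `step_multiplier`
#' times the individual's `step_pctl` percentile (linear-interpolation
#' percentile). The later fix (destination) of a failing step is dropped.
#'
#' @param traj parsed trajectory.
#' @param cfg a [qc_config()].
#' @return list: `clean` (retained fixes), `report` (per-rule removal counts,
#'   retained count, per-fix removal reasons).
#' @export
filter_fixes <- function(traj, cfg = qc_config()) {
  n0 <- nrow(traj)
  reason <- rep(NA_character_, n0)
  alive <- rep(TRUE, n0)

  mark <- function(idx, why) {
    idx <- idx[alive[idx]]
    reason[idx] <<- why
    alive[idx] <<- FALSE
    length(idx)
  }

  counts <- c(missing_coord = 0, fix_type = 0, hdop = 0, altitude = 0,
              jump = 0, speed = 0, step_length = 0)
  counts["missing_coord"] <- mark(which(is.na(traj$lon) | is.na(traj$lat)), "missing_coord")
  counts["fix_type"] <- mark(which(alive & !(traj$fix_type %in% cfg$allowed_fix_types)), "fix_type")
  counts["hdop"] <- mark(which(alive & (is.na(traj$hdop) | traj$hdop > cfg$hdop_max)), "hdop")
  counts["altitude"] <- mark(which(alive & !is.na(traj$altitude_m) &
                                     (traj$altitude_m < cfg$altitude_range[1] |
                                        traj$altitude_m > cfg$altitude_range[2])), "altitude")

  repeat {
    removed_this_cycle <- 0L
    for (rule in c("jump", "speed", "step_length")) {
      sm <- step_metrics(traj[alive, , drop = FALSE])
      if (nrow(sm) == 0) break
      live_idx <- which(alive)
      bad <- switch(rule,
        jump = sm$step_m > cfg$jump_dist_km * 1000 & sm$interval_min <= cfg$jump_max_interval,
        speed = sm$speed_kmh > cfg$speed_max & sm$interval_min >= cfg$speed_min_interval,
        step_length = {
          thr <- cfg$step_multiplier *
            stats::quantile(sm$step_m, cfg$step_pctl / 100, type = 7, names = FALSE)
          sm$step_m > thr
        })
      if (any(bad)) {
        # a bad step whose origin is itself being removed this pass is an
        # artefact of the origin (e.g. the return step out of a teleport):
        # drop the origin only and re-evaluate next pass
        bad_idx <- which(bad)
        doomed_from <- logical(max(sm$to))
        keep <- logical(length(bad_idx))
        for (q in seq_along(bad_idx)) {
          i <- bad_idx[q]
          if (!doomed_from[sm$from[i]]) {
            keep[q] <- TRUE
            doomed_from[sm$to[i]] <- TRUE
          }
        }
        bad_idx <- bad_idx[keep]
        k <- mark(live_idx[sm$to[bad_idx]], rule)
        counts[if (rule == "step_length") "step_length" else rule] <-
          counts[if (rule == "step_length") "step_length" else rule] + k
        removed_this_cycle <- removed_this_cycle + k
      }
    }
    if (removed_this_cycle == 0L) break
  }

  clean <- traj[alive, , drop = FALSE]
  removed <- which(!alive)
  list(clean = clean,
       report = list(animal_id = if (n0) traj$animal_id[1] else NA_character_,
                     counts = counts,
                     retained = nrow(clean),
                     input = n0,
                     reasons = data.frame(row = removed, reason = reason[removed],
                                          stringsAsFactors = FALSE)))
}

#' Run QC over a list of trajectories
#'
#' @param trajectories output of [parse_fixes()] or a list of data.frames.
#' @param cfg a [qc_config()].
#' @return list: `clean` (list of cleaned trajectories), `reports` (per-animal
#'   QC reports, `{animal_id: {rule: count}}` shaped).
#' @export
qc_trajectories <- function(trajectories, cfg = qc_config()) {
  res <- lapply(trajectories, filter_fixes, cfg = cfg)
  list(clean = lapply(res, `[[`, "clean"),
       reports = lapply(res, `[[`, "report"))
}
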