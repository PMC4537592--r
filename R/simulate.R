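#' Simulation configuration for the synthetic telemetry study
#'
#' Defaults state the emulated study system: 19 adults and 9 juveniles, a
#' five-station coastal array, an ocean stage (island to coast) and a
#' coastal stage, layered winds on a 32 km / 3 h lattice, age-dependent
#' departure choosiness (adults wait for a tailwind component of at least
#' +2 m/s at the departure sampling level; juveniles take the first
#' evening), wind-triangle groundspeeds with full drift compensation, and
#' an ocean-stage climb to the cruising altitude that diverts part of the
#' airspeed into vertical movement. Airspeed 12 m/s is a plausible
#' passerine value, not an observed one; climb rate 1.5 m/s sits inside
#' the 1-2 m/s range small songbirds achieve; cruising altitude 800 m.
#'
#' @param ... Overrides for any default listed below.
#' @return A `sim_config` list.
#' @export
sim_config <- function(...) {
  lv <- default_levels()
  nl <- nrow(lv)
  # mean wind: slow, WSW-ward air at low levels veering/strengthening with
  # altitude so the coastal cruising level offers more support
  speeds <- c(2, 2.5, 3, 3.5, 4, 5, 5.5, 6, 6.5, 7, 7.5, 8, 8.5)
  dirs <- c(230, 230, 232, 238, 244, 250, 252, 254, 256, 258, 260, 262, 264)
  cfg <- list(
    n_adults = 19, n_juveniles = 9,
    n_nest_pairs = 8,                       # parent-offspring shared nests
    airspeed_ms = 12,
    climb_rate_ms = 1.5,
    climb_airspeed_fraction = 0.75,
    cruise_altitude_m = 800,
    adult_tailwind_threshold = 2,
    juvenile_tailwind_threshold = -Inf,
    departure_level = "1000mb",             # level sampled when deciding
    ocean_level = "1000mb",                 # winds actually flown in
    coast_level = "925mb",
    n_evenings = 40,
    departure_mean_evening = 20,            # date spread: Oct 03 +/- 9 d
    departure_sd_evenings = 9,
    evening_departure_s = 82800,            # 23:00 UTC
    pulse_rate_s = 2,
    spurious_rate_per_hour = 0,
    duration_noise_sd_min = 2,
    p_coast_detected = 20 / 28,             # birds seen at the far station
    pattern_probs_idh = c(first_antenna_only = 25 / 28, both = 2 / 28,
                          second_antenna_only = 1 / 28),
    pattern_probs_pm = c(first_antenna_only = 0.3, both = 0.4,
                         second_antenna_only = 0.3),
    level_ids = lv$level_id,
    level_wind_speed = setNames(speeds, lv$level_id),
    level_wind_dir_to = setNames(dirs, lv$level_id),
    level_altitude_m = setNames(lv$nominal_altitude_m, lv$level_id),
    altitude_evening_sd_m = 45,             # evening-to-evening height noise
    wind_shared_sd = 1,                     # synoptic noise common to levels
    wind_level_sd = 4.5,                    # per-level, per-evening noise
    wind_node_sd = 0.5,                     # lattice micro-noise
    lat_range = c(44.0, 45.2),
    lon_range = c(-68.6, -66.2),
    signal_peak = 100, signal_sd_s = 150, signal_floor = 15)
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown))
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(override)] <- override
  structure(cfg, class = "sim_config")
}

#' Simulate a layered wind field on the reanalysis lattice
#'
#' One table row per (level, lattice node, time). Each level's u/v wind is
#' its configured mean vector plus an evening-scale synoptic component
#' shared by all levels, a per-level per-evening component, and lattice
#' micro-noise; pressure-level geopotential heights are drawn around their
#' climatological defaults with evening-to-evening noise. Times cover
#' 18:00 to 06:00 UTC in 3-h steps for every evening.
#'
#' @param config A [sim_config()].
#' @return Wind table (see [read_winds()] for the column contract).
#' @export
simulate_wind_field <- function(config) {
  lat_step <- 32 / 111.195
  mid_lat <- mean(config$lat_range)
  lon_step <- 32 / (111.195 * cos(.deg2rad(mid_lat)))
  lats <- seq(config$lat_range[1], config$lat_range[2], by = lat_step)
  lons <- seq(config$lon_range[1], config$lon_range[2], by = lon_step)
  times_per_evening <- seq(18 * 3600, 30 * 3600, by = 3 * 3600)
  ev <- seq_len(config$n_evenings) - 1
  times <- as.vector(outer(times_per_evening, ev * 86400, `+`))
  evening_of <- rep(ev, each = length(times_per_evening))
  nodes <- expand.grid(lat = lats, lon = lons, KEEP.OUT.ATTRS = FALSE)
  nn <- nrow(nodes); nt <- length(times)
  shared_u <- stats::rnorm(config$n_evenings, 0, config$wind_shared_sd)
  shared_v <- stats::rnorm(config$n_evenings, 0, config$wind_shared_sd)
  out <- vector("list", length(config$level_ids))
  for (i in seq_along(config$level_ids)) {
    l <- config$level_ids[i]
    base <- wind_to_uv(config$level_wind_speed[[l]],
                       config$level_wind_dir_to[[l]])
    lev_u <- stats::rnorm(config$n_evenings, 0, config$wind_level_sd)
    lev_v <- stats::rnorm(config$n_evenings, 0, config$wind_level_sd)
    u <- base$u + rep(shared_u[evening_of + 1] + lev_u[evening_of + 1],
                      each = nn) +
      stats::rnorm(nn * nt, 0, config$wind_node_sd)
    v <- base$v + rep(shared_v[evening_of + 1] + lev_v[evening_of + 1],
                      each = nn) +
      stats::rnorm(nn * nt, 0, config$wind_node_sd)
    w <- uv_to_wind(u, v)
    is_pressure <- grepl("mb$", l)
    gph <- if (is_pressure)
      rep(config$level_altitude_m[[l]] +
            stats::rnorm(config$n_evenings, 0,
                         config$altitude_evening_sd_m)[evening_of + 1],
          each = nn)
    else rep(NA_real_, nn * nt)
    out[[i]] <- data.frame(
      level_id = l,
      lat = rep(nodes$lat, times = nt),
      lon = rep(nodes$lon, times = nt),
      time = rep(times, each = nn),
      wind_speed_ms = w$wind_speed,
      wind_dir_to_deg = w$wind_dir_to,
      geopotential_height_m = gph,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

.sim_birds <- function(config) {
  n <- config$n_adults + config$n_juveniles
  age <- c(rep("adult", config$n_adults),
           rep("juvenile", config$n_juveniles))
  tag <- sprintf("tag%02d", seq_len(n))
  # parent-offspring pairs share a nest: pair adult i with juvenile i
  nest <- sprintf("nest%02d", seq_len(n))
  np <- min(config$n_nest_pairs, config$n_adults, config$n_juveniles)
  if (np > 0)
    nest[config$n_adults + seq_len(np)] <- nest[seq_len(np)]
  data.frame(tag_id = tag, age = age, nest_id = nest,
             individual_id = tag, stringsAsFactors = FALSE)
}

#' Simulate age-dependent departure timing
#'
#' Each bird becomes ready to migrate on a bird-specific evening (normal
#' around the configured mean with the observed day-to-day spread of
#' departure dates) and then departs on the first ready evening whose
#' tailwind component along the ocean track (wind sampled at the
#' departure level over the island at the evening departure hour) exceeds
#' its age-specific threshold; the juvenile default threshold of -Inf
#' makes juveniles take their readiness evening regardless of wind.
#'
#' @param config A [sim_config()].
#' @param winds Wind table from [simulate_wind_field()].
#' @param birds Bird metadata (internal default: the configured cohort).
#' @return Bird table with `departure_evening` (NA when no evening
#'   qualifies; such birds are reported in a warning) and
#'   `departure_time` (s).
#' @export
simulate_departures <- function(config, winds, birds = NULL) {
  if (is.null(birds)) birds <- .sim_birds(config)
  stations <- default_array()
  kent <- stations$KentIs1
  idh <- stations$IDH
  track <- initial_bearing(kent$lat, kent$lon, idh$lat, idh$lon)
  wl <- winds[winds$level_id == config$departure_level, , drop = FALSE]
  ev_tw <- vapply(seq_len(config$n_evenings) - 1, function(e) {
    t0 <- e * 86400 + config$evening_departure_s
    wv <- idw_interpolate(wl, kent$lat, kent$lon, t0, k_nearest = 16)
    wind_components(wv$wind_speed, wv$wind_dir_to, track)$tailwind
  }, 0)
  thr <- ifelse(birds$age == "adult", config$adult_tailwind_threshold,
                config$juvenile_tailwind_threshold)
  ready <- pmin(pmax(round(stats::rnorm(nrow(birds),
                                        config$departure_mean_evening,
                                        config$departure_sd_evenings)),
                     1), config$n_evenings)
  dep <- vapply(seq_along(thr), function(i) {
    j <- which(ev_tw > thr[i] & seq_along(ev_tw) >= ready[i])
    if (length(j)) j[1] else NA_integer_
  }, 1L)
  if (anyNA(dep))
    warning(sum(is.na(dep)), " bird(s) found no qualifying evening and did",
            " not depart", call. = FALSE)
  birds$departure_evening <- dep
  birds$departure_time <- (dep - 1) * 86400 + config$evening_departure_s +
    stats::runif(nrow(birds), 0, 3600)
  birds$departure_tailwind <- ev_tw[dep]
  birds
}

.stage_groundspeed <- function(tailwind, crosswind, airspeed, climb_rate,
                               climb_alt_m, distance_m,
                               climb_fraction = 1) {
  # full drift compensation: along-track speed = tw + sqrt(Va_h^2 - cw^2).
  # While the climb penalty is active the horizontal airspeed loses the
  # vector component of the climb rate and, additionally, the configured
  # climb_airspeed_fraction of what remains - a stand-in for the
  # energetic cost of climb-and-search flight over the ocean, which the
  # pure vector term (0.1 m/s at the defaults) cannot represent.
  va_h <- climb_fraction * sqrt(airspeed^2 - climb_rate^2)
  if (abs(crosswind) >= va_h) return(NULL)   # cannot hold track
  gs_climb <- tailwind + sqrt(va_h^2 - crosswind^2)
  gs_cruise <- tailwind + sqrt(airspeed^2 - crosswind^2)
  if (gs_climb <= 0) return(NULL)
  t_climb <- if (climb_rate > 0) climb_alt_m / climb_rate else 0
  d_climb <- gs_climb * t_climb
  t <- if (d_climb >= distance_m) distance_m / gs_climb
  else t_climb + (distance_m - d_climb) / gs_cruise
  list(duration_s = t, groundspeed_ms = distance_m / t)
}

.segment_wind <- function(winds, level, lat1, lon1, lat2, lon2, t_mid) {
  m <- great_circle_midpoint(lat1, lon1, lat2, lon2)
  wl <- winds[winds$level_id == level, , drop = FALSE]
  idw_interpolate(wl, m$lat, m$lon, t_mid, k_nearest = 16)
}

#' Simulate the true two-stage flight of one bird
#'
#' The ocean stage runs from the island to a crossing point at the first
#' coastal station (antenna pattern drawn from the configured mix); the
#' coastal stage continues to a crossing at the second station. Along each
#' stage the bird holds its track with full drift compensation; the
#' along-track groundspeed follows the wind triangle from the tailwind and
#' crosswind at the stage's flight level, with the ocean-stage climb
#' flown at a reduced horizontal airspeed until the cruising altitude is
#' reached. Gaussian noise is added to the stage durations.
#'
#' @param bird One row of the [simulate_departures()] output.
#' @param winds Wind table.
#' @param config A [sim_config()].
#' @param stations Station list (default [default_array()]).
#' @return A `true_flight` list (NULL when the bird cannot hold track),
#'   with per-stage origins, crossing patterns, true winds, durations and
#'   groundspeeds; the coastal stage may be absent.
#' @export
simulate_flight <- function(bird, winds, config,
                            stations = default_array()) {
  if (is.na(bird$departure_evening)) return(NULL)
  kent <- stations$KentIs1; idh <- stations$IDH; pm <- stations$PetitManan
  dep_t <- bird$departure_time

  pat1 <- sample(names(config$pattern_probs_idh), 1,
                 prob = config$pattern_probs_idh)
  x1 <- classify_crossing(pat1, idh)
  d1 <- haversine_distance(kent$lat, kent$lon, x1$lat, x1$lon) * 1000
  trk1 <- initial_bearing(kent$lat, kent$lon, x1$lat, x1$lon)
  wv1 <- .segment_wind(winds, config$ocean_level, kent$lat, kent$lon,
                       x1$lat, x1$lon, dep_t + 1800)
  wc1 <- wind_components(wv1$wind_speed, wv1$wind_dir_to, trk1)
  climb_on <- config$climb_rate_ms > 0
  g1 <- .stage_groundspeed(
    wc1$tailwind, wc1$crosswind, config$airspeed_ms,
    config$climb_rate_ms,
    # climbing-and-searching spans the ocean crossing when the penalty is
    # on: the bird has reached cruise altitude only by the coast
    if (climb_on) Inf else 0, d1,
    climb_fraction = if (climb_on) config$climb_airspeed_fraction else 1)
  if (is.null(g1)) {
    warning("bird ", bird$tag_id, " cannot hold its ocean track; flight",
            " aborted", call. = FALSE)
    return(NULL)
  }
  dur1 <- g1$duration_s +
    60 * stats::rnorm(1, 0, config$duration_noise_sd_min)
  dur1 <- max(dur1, 0.25 * g1$duration_s)
  t_idh <- dep_t + dur1

  fl <- list(tag_id = bird$tag_id, age = bird$age, nest_id = bird$nest_id,
             individual_id = bird$individual_id,
             departure_time = dep_t,
             ocean = list(origin = list(lat = kent$lat, lon = kent$lon,
                                        time = dep_t),
                          pattern = pat1,
                          crossing = list(lat = x1$lat, lon = x1$lon,
                                          time = t_idh),
                          track_deg = trk1, distance_km = d1 / 1000,
                          tailwind = wc1$tailwind,
                          crosswind = wc1$crosswind,
                          duration_min = dur1 / 60,
                          groundspeed_ms = d1 / dur1),
             coast = NULL)

  if (stats::runif(1) < config$p_coast_detected) {
    pat2 <- sample(names(config$pattern_probs_pm), 1,
                   prob = config$pattern_probs_pm)
    x2 <- classify_crossing(pat2, pm)
    d2 <- haversine_distance(x1$lat, x1$lon, x2$lat, x2$lon) * 1000
    trk2 <- initial_bearing(x1$lat, x1$lon, x2$lat, x2$lon)
    wv2 <- .segment_wind(winds, config$coast_level, x1$lat, x1$lon,
                         x2$lat, x2$lon, t_idh + 1800)
    wc2 <- wind_components(wv2$wind_speed, wv2$wind_dir_to, trk2)
    g2 <- .stage_groundspeed(wc2$tailwind, wc2$crosswind,
                             config$airspeed_ms, 0, 0, d2)
    if (!is.null(g2)) {
      dur2 <- g2$duration_s +
        60 * stats::rnorm(1, 0, config$duration_noise_sd_min)
      dur2 <- max(dur2, 0.25 * g2$duration_s)
      fl$coast <- list(origin = fl$ocean$crossing, pattern = pat2,
                       crossing = list(lat = x2$lat, lon = x2$lon,
                                       time = t_idh + dur2),
                       track_deg = trk2, distance_km = d2 / 1000,
                       tailwind = wc2$tailwind, crosswind = wc2$crosswind,
                       duration_min = dur2 / 60,
                       groundspeed_ms = d2 / dur2)
    }
  }
  structure(fl, class = "true_flight")
}

.passage_detections <- function(tag, station_name, antennas, peak_time,
                                scan_on, scan_period, pulse_rate,
                                peak, sd_s, floor_s) {
  # pulses at the transmitter rate, heard only inside scan-on windows,
  # with a Gaussian (in receiver units) passage curve around closest
  # approach
  span <- sd_s * sqrt(2 * log(peak / floor_s))
  tt <- seq(peak_time - span, peak_time + span, by = pulse_rate)
  if (!length(tt)) return(NULL)
  on_window <- (tt %% scan_period) < scan_on
  tt <- tt[on_window]
  if (!length(tt)) return(NULL)
  strength <- peak * exp(-(tt - peak_time)^2 / (2 * sd_s^2))
  keep <- strength >= floor_s
  if (!any(keep)) return(NULL)
  do.call(rbind, lapply(antennas, function(a)
    data.frame(tag_id = tag, station = station_name, antenna_index = a,
               time = tt[keep], signal_strength = strength[keep],
               stringsAsFactors = FALSE)))
}

.pattern_antennas <- function(pattern)
  switch(pattern, first_antenna_only = 1L, both = c(1L, 2L),
         second_antenna_only = 2L)

#' Render detection tables from true flights
#'
#' Emits pulse-level detections with signal-strength passage curves peaked
#' at the true event times, sampled only inside each station's scan-on
#' windows; stations farther than the detection range from the bird's
#' track produce nothing. Spurious detections (uniform random times,
#' random strengths) are injected at the configured hourly rate per
#' occupied station for exercising the pulse-rate filter.
#'
#' @param flights List of [simulate_flight()] results.
#' @param config A [sim_config()].
#' @param stations Station list.
#' @return Detection data.frame (see [read_detections()]).
#' @export
render_detections <- function(flights, config,
                              stations = default_array()) {
  rows <- list()
  for (fl in flights) {
    if (is.null(fl)) next
    # island: departure curve on the first island station, all antennas
    kent <- stations$KentIs1
    rows[[length(rows) + 1]] <- .passage_detections(
      fl$tag_id, kent$name, seq_along(kent$antennas), fl$departure_time,
      kent$scan_on, kent$scan_period, config$pulse_rate_s,
      config$signal_peak, config$signal_sd_s, config$signal_floor)
    idh <- stations$IDH
    if (haversine_distance(idh$lat, idh$lon, fl$ocean$crossing$lat,
                           fl$ocean$crossing$lon) <=
        idh$detection_range_km) {
      rows[[length(rows) + 1]] <- .passage_detections(
        fl$tag_id, idh$name, .pattern_antennas(fl$ocean$pattern),
        fl$ocean$crossing$time, idh$scan_on, idh$scan_period,
        config$pulse_rate_s, config$signal_peak, config$signal_sd_s,
        config$signal_floor)
    }
    if (!is.null(fl$coast)) {
      pm <- stations$PetitManan
      if (haversine_distance(pm$lat, pm$lon, fl$coast$crossing$lat,
                             fl$coast$crossing$lon) <=
          pm$detection_range_km) {
        rows[[length(rows) + 1]] <- .passage_detections(
          fl$tag_id, pm$name, .pattern_antennas(fl$coast$pattern),
          fl$coast$crossing$time, pm$scan_on, pm$scan_period,
          config$pulse_rate_s, config$signal_peak, config$signal_sd_s,
          config$signal_floor)
      }
    }
  }
  det <- do.call(rbind, rows)
  if (config$spurious_rate_per_hour > 0 && !is.null(det)) {
    # false positives cluster around each bird-station passage window and
    # carry marginal signal strengths (well below the passage peak), as
    # real interference-induced decodes do
    grp <- split(det, paste(det$tag_id, det$station))
    spur <- lapply(grp, function(d) {
      t0 <- min(d$time) - 1800; t1 <- max(d$time) + 1800
      nsp <- stats::rpois(1, config$spurious_rate_per_hour *
                            (t1 - t0) / 3600)
      if (!nsp) return(NULL)
      data.frame(tag_id = d$tag_id[1], station = d$station[1],
                 antenna_index = sample(unique(d$antenna_index), nsp,
                                        replace = TRUE),
                 time = stats::runif(nsp, t0, t1),
                 signal_strength = stats::runif(nsp, config$signal_floor,
                                                0.5 * config$signal_peak),
                 stringsAsFactors = FALSE)
    })
    det <- rbind(det, do.call(rbind, unname(spur)))
  }
  det <- det[order(det$tag_id, det$station, det$time), , drop = FALSE]
  rownames(det) <- NULL
  det
}

#' Generate a complete paired synthetic dataset
#'
#' Runs the whole generator under one seed: wind field, departures, true
#' flights, detections, and the ground-truth tables needed by the recovery
#' tests. Regenerating with the same seed reproduces identical tables.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with `config`, `seed`, `stations`, `winds`, `birds`,
#'   `detections`, `truth` (per-stage true segment table) and `flights`
#'   (the raw `true_flight` list).
#' @export
generate_dataset <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  stations <- default_array()
  winds <- simulate_wind_field(config)
  birds <- simulate_departures(config, winds)
  flights <- lapply(seq_len(nrow(birds)), function(i)
    simulate_flight(birds[i, ], winds, config, stations))
  detections <- render_detections(flights, config, stations)
  truth <- do.call(rbind, lapply(flights, function(fl) {
    if (is.null(fl)) return(NULL)
    row <- function(st, s) data.frame(
      tag_id = fl$tag_id, stage = st, age = fl$age, nest_id = fl$nest_id,
      individual_id = fl$individual_id, pattern = s$pattern,
      origin_lat = s$origin$lat, origin_lon = s$origin$lon,
      dest_lat = s$crossing$lat, dest_lon = s$crossing$lon,
      origin_time = s$origin$time, dest_time = s$crossing$time,
      track_deg = s$track_deg, distance_km = s$distance_km,
      duration_min = s$duration_min, groundspeed_ms = s$groundspeed_ms,
      tailwind_ms = s$tailwind, crosswind_ms = s$crosswind,
      stringsAsFactors = FALSE)
    rbind(row("ocean", fl$ocean),
          if (!is.null(fl$coast)) row("coast", fl$coast))
  }))
  list(config = config, seed = seed, stations = stations, winds = winds,
       birds = birds, detections = detections, truth = truth,
       flights = flights)
}

#' Lightweight per-segment wind generator for altitude-recovery studies
#'
#' Bypasses detection rendering: draws, for each of `n` flight segments,
#' correlated per-level tailwind/crosswind annotations (a synoptic
#' component shared across levels plus independent per-level noise) and a
#' flight duration driven linearly by the tailwind at one generating
#' level. Output feeds [altitude_scan()] directly.
#'
#' @param n Number of segments.
#' @param generating_level Level whose tailwind drives duration.
#' @param stage Stage label for the output tables.
#' @param slope_min_per_ms Duration change per m/s of tailwind
#'   (default -6 min, the scale of the observed duration-tailwind
#'   relationship).
#' @param base_duration_min Mean duration at zero tailwind.
#' @param noise_sd_min Residual duration noise.
#' @param shared_sd,level_sd Wind-component noise structure (m/s).
#' @param config A [sim_config()] supplying level means.
#' @return List with `segments` and `annotations` data.frames.
#' @export
simulate_stage_winds <- function(n = 20, generating_level = "925mb",
                                 stage = "coast",
                                 slope_min_per_ms = -6,
                                 base_duration_min = 70,
                                 noise_sd_min = 8,
                                 shared_sd = 3, level_sd = 2,
                                 config = sim_config()) {
  track <- 249
  lv <- config$level_ids
  shared_u <- stats::rnorm(n, 0, shared_sd)
  shared_v <- stats::rnorm(n, 0, shared_sd)
  ann <- do.call(rbind, lapply(lv, function(l) {
    base <- wind_to_uv(config$level_wind_speed[[l]],
                       config$level_wind_dir_to[[l]])
    u <- base$u + shared_u + stats::rnorm(n, 0, level_sd)
    v <- base$v + shared_v + stats::rnorm(n, 0, level_sd)
    w <- uv_to_wind(u, v)
    wc <- wind_components(w$wind_speed, w$wind_dir_to, track)
    data.frame(tag_id = sprintf("tag%03d", seq_len(n)), stage = stage,
               level_id = l,
               level_altitude_m = config$level_altitude_m[[l]],
               wind_speed_ms = w$wind_speed, beta_deg = wc$beta,
               tailwind_ms = wc$tailwind, crosswind_ms = wc$crosswind,
               stringsAsFactors = FALSE)
  }))
  tw_gen <- ann$tailwind_ms[ann$level_id == generating_level]
  dur <- base_duration_min + slope_min_per_ms * tw_gen +
    stats::rnorm(n, 0, noise_sd_min)
  dur <- pmax(dur, 10)
  seg <- data.frame(
    tag_id = sprintf("tag%03d", seq_len(n)), stage = stage,
    age = sample(c("adult", "juvenile"), n, replace = TRUE),
    nest_id = sprintf("nest%03d", seq_len(n)),
    individual_id = sprintf("tag%03d", seq_len(n)),
    duration_min = dur,
    stringsAsFactors = FALSE)
  list(segments = seg, annotations = ann)
}

#' Simulate standardized data from the structural flight-performance model
#'
#' Draws data directly from the standardized structural equations used by
#' the path models: age and stage indicators, tailwind generated from age
#' and stage, crosswind as pure noise, and the response generated from the
#' configured coefficients, with nest and individual random intercepts.
#' Defaults are the published standardized estimates, so recovering them
#' doubles as a plausibility check on the inference stack.
#'
#' @param n_individuals Number of birds; each contributes an ocean and a
#'   coastal row (n = 2 * n_individuals).
#' @param response Response node name.
#' @param coef_tailwind Named vector: intercept, age, stage effects on
#'   tailwind.
#' @param coef_response Named vector of effects on the response
#'   (intercept, tailwind, tailwind_sq, stage, age; missing names mean 0).
#' @param nest_sd,individual_sd,resid_sd Random-effect and residual SDs.
#' @param p_adult Probability a bird is an adult.
#' @return Standardized-style analysis table ready for [fit_path()] /
#'   [backward_eliminate()].
#' @export
simulate_path_data <- function(n_individuals = 100,
                               response = "flight_duration",
                               coef_tailwind = c(intercept = -0.13,
                                                 age = 0.80,
                                                 stage = -0.70),
                               coef_response = c(intercept = -0.23,
                                                 tailwind = -0.69,
                                                 tailwind_sq = 0.23),
                               nest_sd = 0.3, individual_sd = 0.3,
                               resid_sd = 0.5, p_adult = 19 / 28) {
  ni <- n_individuals
  ind <- sprintf("bird%03d", seq_len(ni))
  age_i <- stats::rbinom(ni, 1, p_adult)
  nest_i <- sprintf("nest%03d", c(seq_len(ceiling(ni / 2)),
                                  seq_len(floor(ni / 2))))
  u_nest <- stats::rnorm(length(unique(nest_i)), 0, nest_sd)
  names(u_nest) <- unique(nest_i)
  u_ind <- stats::rnorm(ni, 0, individual_sd)
  d <- data.frame(
    individual_id = rep(ind, each = 2),
    nest_id = rep(nest_i, each = 2),
    age = rep(age_i, each = 2),
    stage = rep(c(1, 0), times = ni),   # ocean then coast
    stringsAsFactors = FALSE)
  n <- nrow(d)
  re <- u_nest[d$nest_id] + rep(u_ind, each = 2)
  cf <- function(v, nm) if (nm %in% names(v)) v[[nm]] else 0
  d$tailwind <- cf(coef_tailwind, "intercept") +
    cf(coef_tailwind, "age") * d$age +
    cf(coef_tailwind, "stage") * d$stage +
    re + stats::rnorm(n, 0, resid_sd)
  d$crosswind <- stats::rnorm(n, 0, 1)
  tw_sq <- d$tailwind^2
  d$tailwind_sq <- (tw_sq - mean(tw_sq)) / stats::sd(tw_sq)
  # response-equation random effects are independent of the tailwind
  # equation's: shared group effects would act as a hidden common cause
  # of tailwind and the response, and conditioning on tailwind (a
  # collider) would then open a genuine age-response dependence that the
  # d-separation machinery rightly detects
  u_nest2 <- stats::rnorm(length(unique(nest_i)), 0, nest_sd)
  names(u_nest2) <- unique(nest_i)
  re2 <- u_nest2[d$nest_id] + rep(stats::rnorm(ni, 0, individual_sd),
                                  each = 2)
  d[[response]] <- cf(coef_response, "intercept") +
    cf(coef_response, "tailwind") * d$tailwind +
    cf(coef_response, "tailwind_sq") * d$tailwind_sq +
    cf(coef_response, "stage") * d$stage +
    cf(coef_response, "age") * d$age +
    cf(coef_response, "crosswind") * d$crosswind +
    re2 + stats::rnorm(n, 0, resid_sd)
  d
}
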