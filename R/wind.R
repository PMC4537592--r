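#' Winds-aloft annotation
#'
#' Tools to turn layered reanalysis-style wind tables (32 km / 3 h lattice
#' by default) into per-segment tailwind and crosswind components at the
#' space-time midpoint of each flight segment, one annotation per
#' atmospheric level.
#'
#' Internally wind direction is always the direction TOWARD which the air
#' moves (vector heading, degrees clockwise from geographic north), so that
#' a wind blowing along the track yields a positive tailwind. Files using
#' the meteorological direction-FROM convention are converted on read.
#'
#' @name wind
#' @keywords internal
NULL

#' Default atmospheric level set
#'
#' Two fixed heights (10 m, 30 m) plus pressure levels from 1000 mbar to
#' 750 mbar in 25-mbar steps; `nominal_altitude_m` carries approximate
#' climatological geopotential heights used as defaults by the simulator
#' and as altitude labels when a wind table has no geopotential column.
#'
#' @return data.frame with `level_id` and `nominal_altitude_m`, ordered by
#'   increasing altitude.
#' @export
default_levels <- function() {
  pl <- seq(1000, 750, by = -25)
  alt <- c(160, 376, 595, 820, 1050, 1290, 1530, 1780, 2040, 2300, 2560)
  data.frame(
    level_id = c("10m", "30m", paste0(pl, "mb")),
    nominal_altitude_m = c(10, 30, alt),
    stringsAsFactors = FALSE)
}

.wrap180 <- function(x) {
  # wrap an angle to (-180, 180]
  y <- ((x + 180) %% 360) - 180
  ifelse(y == -180, 180, y)
}

#' Tailwind and crosswind components of a wind vector on a track
#'
#' With beta the angular difference between the wind heading (direction-to)
#' and the track direction, the tailwind component is `Vw * cos(beta)`
#' (positive when the wind increases groundspeed along the track) and the
#' crosswind component `Vw * sin(beta)` (perpendicular to the track).
#'
#' @param wind_speed Wind speed Vw, m/s (>= 0).
#' @param wind_dir_to Direction toward which the wind blows, degrees
#'   clockwise from geographic north.
#' @param track_dir Track direction, degrees clockwise from north.
#' @return List with `tailwind`, `crosswind` (m/s) and `beta` (degrees,
#'   wrapped to (-180, 180]). Vectorised.
#' @export
wind_components <- function(wind_speed, wind_dir_to, track_dir) {
  if (any(wind_speed < 0)) stop("wind speed must be >= 0", call. = FALSE)
  beta <- .wrap180(wind_dir_to - track_dir)
  br <- .deg2rad(beta)
  list(tailwind = wind_speed * cos(br),
       crosswind = wind_speed * sin(br),
       beta = beta)
}

#' Convert between wind speed/direction and u/v components
#'
#' `u` is the eastward and `v` the northward component of air motion;
#' direction is the heading the air moves toward.
#'
#' @param wind_speed,wind_dir_to Speed (m/s) and heading (degrees).
#' @return `wind_to_uv`: list with `u`, `v`; `uv_to_wind`: list with
#'   `wind_speed`, `wind_dir_to`.
#' @export
wind_to_uv <- function(wind_speed, wind_dir_to) {
  th <- .deg2rad(wind_dir_to)
  list(u = wind_speed * sin(th), v = wind_speed * cos(th))
}

#' @param u,v Eastward and northward wind components, m/s.
#' @rdname wind_to_uv
#' @export
uv_to_wind <- function(u, v) {
  list(wind_speed = sqrt(u^2 + v^2),
       wind_dir_to = ifelse(u == 0 & v == 0, 0, .rad2deg(atan2(u, v)) %% 360))
}

#' Inverse-distance-weighted space-time wind interpolation
#'
#' Interpolates the wind vector (u/v components, never the circular
#' direction) at a query point from samples on one atmospheric level.
#' The combined space-time distance is
#' `sqrt((d_space / space_scale_km)^2 + (d_time / time_scale_s)^2)` with
#' the lattice resolutions (32 km, 3 h) as default scalings; weights are
#' `1 / d^power`. A query coinciding with a sample returns that sample's
#' wind exactly.
#'
#' @param samples data.frame with columns `lat`, `lon`, `time` (numeric
#'   seconds), `wind_speed_ms`, `wind_dir_to_deg` (one level).
#' @param lat,lon,time Query point.
#' @param power IDW exponent (default 1).
#' @param space_scale_km,time_scale_s Distance scalings.
#' @param k_nearest If set, interpolate from only the k nearest samples in
#'   scaled space-time distance. Track annotation interpolates locally
#'   (the surrounding lattice cells); with a low power and an unbounded
#'   sample cloud, the mass of far samples would otherwise drag every
#'   value toward the field mean.
#' @return List with `u`, `v`, `wind_speed`, `wind_dir_to`.
#' @export
idw_interpolate <- function(samples, lat, lon, time, power = 1,
                            space_scale_km = 32, time_scale_s = 3 * 3600,
                            k_nearest = NULL) {
  if (!nrow(samples)) stop("no wind samples to interpolate", call. = FALSE)
  ds <- haversine_distance(samples$lat, samples$lon, lat, lon)
  dt <- abs(as.numeric(samples$time) - as.numeric(time))
  d <- sqrt((ds / space_scale_km)^2 + (dt / time_scale_s)^2)
  if (!is.null(k_nearest) && k_nearest < length(d)) {
    keep <- order(d)[seq_len(k_nearest)]
    samples <- samples[keep, , drop = FALSE]
    d <- d[keep]
  }
  uv <- wind_to_uv(samples$wind_speed_ms, samples$wind_dir_to_deg)
  hit <- d < 1e-12
  if (any(hit)) {
    i <- which(hit)[1]
    out <- list(u = uv$u[i], v = uv$v[i])
  } else {
    w <- 1 / d^power
    out <- list(u = sum(w * uv$u) / sum(w), v = sum(w * uv$v) / sum(w))
  }
  c(out, uv_to_wind(out$u, out$v))
}

#' Space-time midpoint of a flight segment
#'
#' @param segment A [build_flight_segment()] result or any list with
#'   `origin_lat/lon`, `dest_lat/lon`, `origin_time`, `dest_time`.
#' @return List with `lat`, `lon` (great-circle midpoint) and `time`
#'   (temporal midpoint, numeric seconds).
#' @export
segment_midpoint <- function(segment) {
  if (segment$dest_time <= segment$origin_time)
    stop("destination time must follow origin time", call. = FALSE)
  m <- great_circle_midpoint(segment$origin_lat, segment$origin_lon,
                             segment$dest_lat, segment$dest_lon)
  list(lat = m$lat, lon = m$lon,
       time = (segment$origin_time + segment$dest_time) / 2)
}

#' Mean altitude of a pressure level across departure evenings
#'
#' @param heights Geopotential heights (m) of one pressure level, one per
#'   departure evening.
#' @return List with `mean_m` and `sd_m` (sample sd; 0 for a single value).
#' @export
level_mean_altitude <- function(heights) {
  if (!length(heights)) stop("no geopotential heights", call. = FALSE)
  s <- if (length(heights) > 1) stats::sd(heights) else 0
  list(mean_m = mean(heights), sd_m = s)
}

#' Altitude labels for every level in a wind table
#'
#' Pressure levels are labelled by the mean geopotential height across the
#' table (the departure evenings); fixed-height levels and levels without a
#' geopotential column fall back to [default_levels()] nominal altitudes.
#'
#' @param winds Wind table (see [read_winds()]).
#' @return data.frame `level_id`, `altitude_m`, `altitude_sd_m`.
#' @export
level_altitudes <- function(winds) {
  lv <- unique(winds$level_id)
  nom <- default_levels()
  out <- lapply(lv, function(l) {
    g <- winds$geopotential_height_m[winds$level_id == l]
    g <- g[is.finite(g)]
    if (length(g)) {
      a <- level_mean_altitude(g)
      data.frame(level_id = l, altitude_m = a$mean_m, altitude_sd_m = a$sd_m)
    } else {
      data.frame(level_id = l,
                 altitude_m = nom$nominal_altitude_m[match(l, nom$level_id)],
                 altitude_sd_m = NA_real_)
    }
  })
  do.call(rbind, out)
}

#' Annotate a flight segment with per-level wind components
#'
#' Interpolates the wind at the segment's space-time midpoint on every
#' available level and projects it on the segment's track direction.
#' Levels listed in `levels` but absent from the wind table are skipped
#' with a warning.
#'
#' @param segment A [build_flight_segment()] result.
#' @param winds Wind table with a `level_id` column (see [read_winds()]).
#' @param levels Level ids to annotate (default: all present in `winds`).
#' @param power,space_scale_km,time_scale_s,k_nearest Passed to
#'   [idw_interpolate()]; by default the 16 nearest lattice samples (the
#'   local space-time neighbourhood) carry the interpolation.
#' @return data.frame with one row per level: `tag_id`, `stage`,
#'   `level_id`, `level_altitude_m`, `wind_speed_ms`, `beta_deg`,
#'   `tailwind_ms`, `crosswind_ms`.
#' @export
annotate_segment <- function(segment, winds, levels = NULL, power = 1,
                             space_scale_km = 32, time_scale_s = 3 * 3600,
                             k_nearest = 16) {
  if (is.null(levels)) levels <- unique(winds$level_id)
  missing_lv <- setdiff(levels, unique(winds$level_id))
  if (length(missing_lv)) {
    warning("wind level(s) missing, skipped: ",
            paste(missing_lv, collapse = ", "), call. = FALSE)
    levels <- setdiff(levels, missing_lv)
  }
  mid <- segment_midpoint(segment)
  alts <- level_altitudes(winds)
  rows <- lapply(levels, function(l) {
    s <- winds[winds$level_id == l, , drop = FALSE]
    wv <- idw_interpolate(s, mid$lat, mid$lon, mid$time, power = power,
                          space_scale_km = space_scale_km,
                          time_scale_s = time_scale_s,
                          k_nearest = k_nearest)
    wc <- wind_components(wv$wind_speed, wv$wind_dir_to, segment$track_deg)
    data.frame(tag_id = segment$tag_id, stage = segment$stage,
               level_id = l,
               level_altitude_m = alts$altitude_m[match(l, alts$level_id)],
               wind_speed_ms = wv$wind_speed, beta_deg = wc$beta,
               tailwind_ms = wc$tailwind, crosswind_ms = wc$crosswind,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Annotate many segments at once
#'
#' @param segments data.frame of segments (see [segments_table()]).
#' @inheritParams annotate_segment
#' @return Row-bound annotation data.frame.
#' @export
annotate_segments <- function(segments, winds, levels = NULL, power = 1,
                              space_scale_km = 32, time_scale_s = 3 * 3600,
                              k_nearest = 16) {
  do.call(rbind, lapply(seq_len(nrow(segments)), function(i)
    annotate_segment(as.list(segments[i, , drop = FALSE]), winds,
                     levels = levels, power = power,
                     space_scale_km = space_scale_km,
                     time_scale_s = time_scale_s, k_nearest = k_nearest)))
}
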