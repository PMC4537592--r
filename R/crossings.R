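#' Classify a crossing point from the antenna detection pattern
#'
#' At a two-antenna coastal station with back-to-back boresights, the set
#' of antennas that detected a passing bird locates its crossing of the
#' antenna axis: detection on both antennas places the crossing directly
#' over the station (offset 0); detection on a single antenna places it at
#' half the detection range along that antenna's boresight (7.5 km at the
#' default 15 km range). The signed offset is measured along the first
#' antenna's boresight axis.
#'
#' @param pattern One of `"first_antenna_only"`, `"both"`,
#'   `"second_antenna_only"` (antenna order as listed in the station spec).
#' @param station A [station_spec()] with exactly two antennas.
#' @param time Event time at the station (passed through).
#' @return An object of class `crossing_event`: station name, pattern,
#'   `lat`/`lon` of the crossing point, `offset_km` signed along the first
#'   antenna's boresight, and `time`.
#' @export
classify_crossing <- function(pattern, station, time = NA_real_) {
  pattern <- match.arg(pattern,
                       c("first_antenna_only", "both", "second_antenna_only"))
  if (length(station$antennas) != 2)
    stop("crossing classification requires a two-antenna station",
         call. = FALSE)
  half <- station$detection_range_km / 2
  if (pattern == "both") {
    lat <- station$lat; lon <- station$lon; off <- 0
  } else {
    idx <- if (pattern == "first_antenna_only") 1L else 2L
    p <- destination_point(station$lat, station$lon,
                           station$antennas[[idx]]$boresight, half)
    lat <- p$lat; lon <- p$lon
    off <- if (idx == 1L) half else -half
  }
  structure(list(station = station$name, pattern = pattern,
                 lat = lat, lon = lon, offset_km = off, time = time),
            class = "crossing_event")
}

#' Build a flight segment between two events
#'
#' A flight segment joins a departure (or upstream crossing) event to a
#' downstream crossing event for one bird and one flight stage. Distance is
#' the great-circle distance between the event locations, duration the time
#' difference in minutes, groundspeed their ratio in m/s, and track
#' direction the initial great-circle bearing.
#'
#' @param origin,destination Lists/`crossing_event`s with `lat`, `lon`,
#'   `time` (numeric seconds UTC).
#' @param tag_id,stage,age,nest_id,individual_id Segment metadata; `stage`
#'   is `"ocean"` or `"coast"`, `age` `"adult"` or `"juvenile"`.
#' @return An object of class `flight_segment` (a one-row list).
#' @export
build_flight_segment <- function(origin, destination, tag_id,
                                 stage = c("ocean", "coast"),
                                 age = c("adult", "juvenile"),
                                 nest_id = NA_character_,
                                 individual_id = tag_id) {
  stage <- match.arg(stage)
  age <- match.arg(age)
  dur_s <- as.numeric(destination$time) - as.numeric(origin$time)
  if (!is.finite(dur_s) || dur_s <= 0)
    stop("destination time must follow origin time", call. = FALSE)
  dist_km <- haversine_distance(origin$lat, origin$lon,
                                destination$lat, destination$lon)
  if (dist_km <= 0)
    stop("degenerate track: zero distance", call. = FALSE)
  duration_min <- dur_s / 60
  structure(list(
    tag_id = tag_id, stage = stage, age = age,
    nest_id = nest_id, individual_id = individual_id,
    origin_lat = origin$lat, origin_lon = origin$lon,
    dest_lat = destination$lat, dest_lon = destination$lon,
    origin_time = as.numeric(origin$time),
    dest_time = as.numeric(destination$time),
    track_deg = initial_bearing(origin$lat, origin$lon,
                                destination$lat, destination$lon),
    distance_km = dist_km,
    duration_min = duration_min,
    groundspeed_ms = dist_km * 1000 / (duration_min * 60)),
    class = "flight_segment")
}

#' Collect flight segments into a data frame
#'
#' @param segments List of [build_flight_segment()] results.
#' @return data.frame with one row per segment.
#' @export
segments_table <- function(segments) {
  if (!length(segments)) {
    cols <- c("tag_id", "stage", "age", "nest_id", "individual_id",
              "origin_lat", "origin_lon", "dest_lat", "dest_lon",
              "origin_time", "dest_time", "track_deg", "distance_km",
              "duration_min", "groundspeed_ms")
    out <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
    return(out)
  }
  do.call(rbind, lapply(segments, function(s)
    as.data.frame(unclass(s), stringsAsFactors = FALSE)))
}
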