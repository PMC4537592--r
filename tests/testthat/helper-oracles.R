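# Independent oracles used to derive expected values. These deliberately
# use different formulations than the package code paths they check.

# spherical law of cosines distance (vs the package's haversine)
oracle_distance_km <- function(lat1, lon1, lat2, lon2, R = 6371) {
  r <- pi / 180
  ca <- sin(lat1 * r) * sin(lat2 * r) +
    cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
  R * acos(pmin(1, pmax(-1, ca)))
}

# local flat-earth destination (valid to <10 m at tens of km)
oracle_destination_flat <- function(lat, lon, bearing, d_km) {
  r <- pi / 180
  dlat <- d_km * cos(bearing * r) / 111.195
  dlon <- d_km * sin(bearing * r) / (111.195 * cos(lat * r))
  c(lat = lat + dlat, lon = lon + dlon)
}

# 3D-vector great-circle midpoint (vs the package's trig form)
oracle_midpoint <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  v <- function(lat, lon)
    c(cos(lat * r) * cos(lon * r), cos(lat * r) * sin(lon * r), sin(lat * r))
  m <- v(lat1, lon1) + v(lat2, lon2)
  m <- m / sqrt(sum(m^2))
  c(lat = asin(m[3]) / r, lon = atan2(m[2], m[1]) / r)
}

# brute-force run scan for the pulse-rate filter, written recursively and
# independently of the package loop: runs grow from the earliest
# unassigned detection, absorbing every later unassigned detection whose
# offset from the run tail is a near-positive-multiple of the pulse rate;
# runs of one are false positives
oracle_pulse_filter_keep <- function(times, pulse_rate, tol) {
  times <- sort(times)
  near_mult <- function(dt)
    round(dt / pulse_rate) >= 1 &
      abs(dt - round(dt / pulse_rate) * pulse_rate) <= tol
  grow <- function(tail_t, pool) {
    hit <- pool[near_mult(pool - tail_t)]
    if (!length(hit)) return(numeric(0))
    c(hit[1], grow(hit[1], pool[pool > hit[1]]))
  }
  pool <- times
  kept <- numeric(0)
  while (length(pool)) {
    run <- c(pool[1], grow(pool[1], pool[-1]))
    if (length(run) >= 2) kept <- c(kept, run)
    pool <- setdiff(pool, c(run[1], run))
  }
  times %in% kept
}

make_series <- function(times, strengths = NULL, tag = "t1", station = "S",
                        antenna = 1L) {
  n <- length(times)
  detection_series(data.frame(
    tag_id = rep(tag, n), station = rep(station, n),
    antenna_index = rep(antenna, n), time = times,
    signal_strength = if (is.null(strengths)) rep(1, n) else strengths))
}

# printed study coordinates (arc-minutes)
KENT <- c(lat = 44 + 35 / 60, lon = -(66 + 45 / 60))
IDH_LOC <- c(lat = 44 + 36 / 60, lon = -(67 + 16 / 60))
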