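#' Detection series utilities
#'
#' A detection series is the ordered set of detections of one tag at one
#' station: columns `tag_id`, `station`, `antenna_index`, `time` (numeric
#' seconds UTC or POSIXct) and `signal_strength` (receiver units, arbitrary
#' but monotone in received power).
#'
#' @param df data.frame with the columns above.
#' @return A validated, time-sorted `detection_series` data.frame.
#' @export
detection_series <- function(df) {
  need <- c("tag_id", "station", "antenna_index", "time", "signal_strength")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing detection columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df)) {
    if (any(!is.finite(as.numeric(df$time))))
      stop("non-finite detection time", call. = FALSE)
    if (any(!is.finite(df$signal_strength)))
      stop("non-finite signal strength", call. = FALSE)
    df <- df[order(df$time), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("detection_series", "data.frame")
  df
}

#' Remove false-positive detections by the pulse-rate rule
#'
#' Digitally coded transmitters emit pulses at a fixed rate, so genuine
#' consecutive detections are separated by (near-)integer multiples of the
#' pulse rate. Detections are grouped into maximal runs: a run extends
#' from its most recent member to the next detection whose interval from
#' that member is within `tolerance` seconds of a positive integer
#' multiple of `pulse_rate`, skipping (but not consuming) incompatible
#' detections; skipped detections may anchor later runs. Singleton runs
#' (points with no pulse-rate-consistent partner) are discarded as false
#' positives. The filter is idempotent.
#'
#' @param series A [detection_series()].
#' @param pulse_rate Transmitter pulse rate, seconds (> 0).
#' @param tolerance Allowed deviation from an exact multiple, seconds
#'   (default 0.25).
#' @return Filtered `detection_series` (empty input passes through).
#' @export
filter_false_positives <- function(series, pulse_rate, tolerance = 0.25) {
  stopifnot(pulse_rate > 0, tolerance >= 0)
  n <- nrow(series)
  if (n <= 1) {
    # a lone detection has no neighbour to validate it
    return(series[integer(0), , drop = FALSE])
  }
  tt <- as.numeric(series$time)
  compatible <- function(a, b) {
    dt <- b - a
    k <- round(dt / pulse_rate)
    k >= 1 && abs(dt - k * pulse_rate) <= tolerance
  }
  assigned <- logical(n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (assigned[i]) next
    run <- i
    last <- i
    j <- i + 1
    while (j <= n) {
      if (!assigned[j] && compatible(tt[last], tt[j])) {
        run <- c(run, j)
        last <- j
      }
      j <- j + 1
    }
    if (length(run) >= 2) {
      assigned[run] <- TRUE
      keep[run] <- TRUE
    } else {
      assigned[i] <- TRUE
    }
  }
  out <- series[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Event time from the signal-strength peak
#'
#' Departure and arrival times are defined as the time of maximum signal
#' strength on the passage curve; ties are broken by the earliest time.
#'
#' @param series A nonempty [detection_series()].
#' @return The event timestamp (same type as `series$time`).
#' @export
event_time_from_peak <- function(series) {
  if (!nrow(series)) stop("no detections: cannot locate event", call. = FALSE)
  series$time[which.max(series$signal_strength)]
}
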