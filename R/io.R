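#' CSV readers and writers for the pipeline's external formats
#'
#' All files are plain CSV with documented headers; timestamps are
#' ISO-8601 UTC on disk and numeric seconds in memory; wind direction is
#' converted to the direction-to convention on read. Parse failures
#' report the offending line number.
#'
#' @name io
#' @keywords internal
NULL

.parse_times <- function(x, file, lines) {
  if (is.numeric(x)) return(as.numeric(x))
  s <- trimws(as.character(x))
  s <- sub("Z$", "", s)
  s <- sub("T", " ", s, fixed = TRUE)
  out <- as.POSIXct(strptime(s, "%Y-%m-%d %H:%M:%OS", tz = "UTC"),
                    tz = "UTC")
  short <- is.na(out)
  if (any(short))   # rows without a seconds field
    out[short] <- as.POSIXct(strptime(s[short], "%Y-%m-%d %H:%M",
                                      tz = "UTC"), tz = "UTC")
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    stop(file, ": unparseable timestamp at data line ",
         lines[bad[1]], ": '", x[bad[1]], "'", call. = FALSE)
  as.numeric(out)
}

.fmt_time <- function(t)
  format(as.POSIXct(t, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%OS1Z")

#' Parse a latitude or longitude, decimal or degree-arcminute
#'
#' Accepts decimal degrees (`-67.2667`) and degree-minute strings as
#' printed in field reports (`"44°36' N"`, `"67 16 W"`); west and
#' south are negative.
#'
#' @param x Character or numeric vector.
#' @return Numeric decimal degrees.
#' @export
parse_coordinate <- function(x) {
  if (is.numeric(x)) return(x)
  vapply(x, function(s) {
    s0 <- trimws(s)
    num <- suppressWarnings(as.numeric(s0))
    if (!is.na(num)) return(num)
    hemi <- regmatches(s0, regexpr("[NSEWnsew]", s0))
    parts <- regmatches(s0, gregexpr("[0-9]+\\.?[0-9]*", s0))[[1]]
    if (!length(parts)) stop("unparseable coordinate: ", s, call. = FALSE)
    deg <- as.numeric(parts[1])
    if (length(parts) >= 2) deg <- deg + as.numeric(parts[2]) / 60
    if (length(parts) >= 3) deg <- deg + as.numeric(parts[3]) / 3600
    if (length(hemi) && toupper(hemi) %in% c("S", "W")) deg <- -deg
    deg
  }, 0, USE.NAMES = FALSE)
}

.require_cols <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(file, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
}

#' Read a detection table
#'
#' Columns: `tag_id`, `station`, `antenna_index`, `timestamp_utc`
#' (ISO-8601; a numeric `time` column in seconds is also accepted) and
#' `signal_strength`.
#'
#' @param path CSV path.
#' @return data.frame with numeric `time` seconds, sorted by tag, station,
#'   time.
#' @export
read_detections <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lines <- seq_len(nrow(df))
  tcol <- if ("timestamp_utc" %in% names(df)) "timestamp_utc" else "time"
  .require_cols(df, c("tag_id", "station", "antenna_index", tcol,
                      "signal_strength"), path)
  df$time <- .parse_times(df[[tcol]], path, lines)
  bad <- which(!is.finite(df$signal_strength))
  if (length(bad))
    stop(path, ": non-finite signal strength at data line ", bad[1],
         call. = FALSE)
  df <- df[order(df$tag_id, df$station, df$time),
           c("tag_id", "station", "antenna_index", "time",
             "signal_strength")]
  rownames(df) <- NULL
  df
}

#' @param detections Detection data.frame.
#' @rdname read_detections
#' @export
write_detections <- function(detections, path) {
  out <- detections
  out$timestamp_utc <- .fmt_time(out$time)
  utils::write.csv(out[, c("tag_id", "station", "antenna_index",
                           "timestamp_utc", "signal_strength")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a layered wind table
#'
#' Columns: `level_id`, `lat`, `lon`, `timestamp_utc` (or numeric `time`),
#' `wind_speed_ms`, `wind_dir_deg`, `dir_convention` (`"to"` or `"from"`;
#' meteorological direction-from values are converted to direction-to by
#' adding 180 degrees) and optional `geopotential_height_m`.
#'
#' @param path CSV path.
#' @return data.frame with internal columns including `wind_dir_to_deg`.
#' @export
read_winds <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tcol <- if ("timestamp_utc" %in% names(df)) "timestamp_utc" else "time"
  .require_cols(df, c("level_id", "lat", "lon", tcol, "wind_speed_ms"),
                path)
  df$time <- .parse_times(df[[tcol]], path, seq_len(nrow(df)))
  if ("wind_dir_to_deg" %in% names(df)) {
    dirs <- df$wind_dir_to_deg
  } else {
    .require_cols(df, c("wind_dir_deg", "dir_convention"), path)
    bad <- which(!df$dir_convention %in% c("to", "from"))
    if (length(bad))
      stop(path, ": dir_convention must be 'to' or 'from' (data line ",
           bad[1], ")", call. = FALSE)
    dirs <- ifelse(df$dir_convention == "from",
                   (df$wind_dir_deg + 180) %% 360, df$wind_dir_deg %% 360)
  }
  df$lat <- parse_coordinate(df$lat)
  df$lon <- parse_coordinate(df$lon)
  bad <- which(df$lat < -90 | df$lat > 90 | df$lon < -180 | df$lon > 180 |
                 df$wind_speed_ms < 0)
  if (length(bad))
    stop(path, ": out-of-range coordinate or wind speed at data line ",
         bad[1], call. = FALSE)
  df$wind_dir_to_deg <- dirs
  if (!"geopotential_height_m" %in% names(df))
    df$geopotential_height_m <- NA_real_
  df[, c("level_id", "lat", "lon", "time", "wind_speed_ms",
         "wind_dir_to_deg", "geopotential_height_m")]
}

#' @param winds Wind data.frame (internal form).
#' @rdname read_winds
#' @export
write_winds <- function(winds, path) {
  out <- winds
  out$timestamp_utc <- .fmt_time(out$time)
  out$wind_dir_deg <- out$wind_dir_to_deg
  out$dir_convention <- "to"
  utils::write.csv(out[, c("level_id", "lat", "lon", "timestamp_utc",
                           "wind_speed_ms", "wind_dir_deg",
                           "dir_convention", "geopotential_height_m")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read bird metadata
#'
#' Columns: `tag_id`, `age` ("adult"/"juvenile"), `nest_id`, optional
#' `individual_id` (defaults to the tag) and `body_mass_g`.
#'
#' @param path CSV path.
#' @return Validated data.frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("tag_id", "age", "nest_id"), path)
  bad <- which(!df$age %in% c("adult", "juvenile"))
  if (length(bad))
    stop(path, ": age must be 'adult' or 'juvenile' (data line ", bad[1],
         ")", call. = FALSE)
  if (!"individual_id" %in% names(df)) df$individual_id <- df$tag_id
  df
}

#' Write and read flight-segment tables
#'
#' @param segments Segment data.frame ([segments_table()]).
#' @param path CSV path.
#' @export
write_segments <- function(segments, path) {
  utils::write.csv(segments, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("tag_id", "stage", "distance_km", "duration_min",
                      "groundspeed_ms"), path)
  df
}

#' Write a path-model selection table
#'
#' Columns `model_equations`, `K`, `AICc`, `dAICc`, `W`, `cumW`,
#' `fishers_C`, sorted ascending by AICc, numeric columns rounded to 2
#' decimal places in the style of published selection tables.
#'
#' @param x A [model_selection_table()] data.frame or a list of
#'   `path_fit`s.
#' @param path CSV path.
#' @export
write_selection_table <- function(x, path) {
  tab <- if (is.data.frame(x)) x else model_selection_table(x)
  for (cl in c("AICc", "dAICc", "W", "cumW", "fishers_C"))
    tab[[cl]] <- round(tab[[cl]], 2)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
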