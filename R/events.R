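# Tag event streams: one row per observation a tag produced.  Columns:
#   tag_id, product_id, timestamp (POSIXct UTC), location_id,
#   temperature_c (NA for non-reading events), event_type.

#' An empty, correctly-typed event table
#'
#' @return A zero-row tibble with the event-stream schema.
#' @export
empty_events <- function() {
  tibble::tibble(
    tag_id = character(),
    product_id = character(),
    timestamp = as.POSIXct(character(), tz = "UTC"),
    location_id = character(),
    temperature_c = numeric(),
    event_type = character()
  )
}

# Validate an in-memory event table against the schema and the facility map.
validate_events <- function(events, facility) {
  needed <- c("tag_id", "product_id", "timestamp", "location_id",
              "temperature_c", "event_type")
  missing_cols <- setdiff(needed, names(events))
  if (length(missing_cols) > 0) {
    stop("event table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_type <- setdiff(unique(events$event_type), EVENT_TYPES)
  if (length(bad_type) > 0) {
    stop("unknown event_type: ", paste(bad_type, collapse = ", "), call. = FALSE)
  }
  check_locations(events$location_id, facility)
  temp <- events$temperature_c
  bad_range <- !is.na(temp) & (temp < -10 | temp > 45)
  if (any(bad_range)) {
    stop("temperature_c outside the sensor range [-10, 45] in row(s) ",
         paste(utils::head(which(bad_range), 5), collapse = ", "), call. = FALSE)
  }
  no_temp <- events$event_type %in% c("stopbox_drop", "deactivation")
  if (any(no_temp & !is.na(temp))) {
    stop("stopbox_drop/deactivation events must not carry a temperature",
         call. = FALSE)
  }
  invisible(events)
}

parse_timestamps <- function(x) {
  x <- trimws(x)
  # Zulu-suffixed ISO-8601 is the canonical on-disk form; a bare
  # "YYYY-mm-dd HH:MM:SS" (or "T"-separated) datetime is taken as local time
  # and normalised to UTC.
  zulu <- grepl("Z$", x)
  out <- rep(as.POSIXct(NA, tz = "UTC"), length(x))
  if (any(zulu)) {
    out[zulu] <- as.POSIXct(x[zulu], format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
  if (any(!zulu)) {
    local <- gsub("T", " ", x[!zulu], fixed = TRUE)
    parsed <- as.POSIXct(local, format = "%Y-%m-%d %H:%M:%S", tz = "")
    out[!zulu] <- as.POSIXct(format(parsed, tz = "UTC"), tz = "UTC")
  }
  out
}

format_timestamps <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' Read a tag event stream from CSV
#'
#' Parses a `tag_id,product_id,timestamp,location_id,temperature_c,event_type`
#' CSV (ISO-8601 timestamps; the temperature field is empty for events that do
#' not carry one), checks every location against the facility map, and returns
#' the rows time-sorted within each tag.
#'
#' @param path Path to the CSV file.
#' @param facility A [facility_map()] used to resolve `location_id`s.
#' @return A tibble of tag events.
#' @export
read_events <- function(path, facility) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  needed <- c("tag_id", "product_id", "timestamp", "location_id",
              "temperature_c", "event_type")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("event CSV header is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) return(empty_events())
  ts <- parse_timestamps(raw$timestamp)
  if (anyNA(ts)) {
    stop("unparseable timestamp at row ", which(is.na(ts))[1],
         ", column 'timestamp': '", raw$timestamp[which(is.na(ts))[1]], "'",
         call. = FALSE)
  }
  temp_chr <- trimws(raw$temperature_c)
  temp <- suppressWarnings(as.numeric(temp_chr))
  bad_temp <- temp_chr != "" & is.na(temp)
  if (any(bad_temp)) {
    stop("unparseable temperature at row ", which(bad_temp)[1],
         ", column 'temperature_c': '", temp_chr[which(bad_temp)[1]], "'",
         call. = FALSE)
  }
  events <- tibble::tibble(
    tag_id = raw$tag_id,
    product_id = raw$product_id,
    timestamp = ts,
    location_id = raw$location_id,
    temperature_c = temp,
    event_type = raw$event_type
  )
  validate_events(events, facility)
  dplyr::arrange(events, .data$tag_id, .data$timestamp)
}

#' Write a tag event stream to CSV
#'
#' Inverse of [read_events()]: timestamps are written as Zulu ISO-8601 to
#' one-second precision and temperatures to 0.1 degC (the declared storage
#' precision), so a write/read round trip is lossless for data at that
#' precision.
#'
#' @param events An event tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- data.frame(
    tag_id = events$tag_id,
    product_id = events$product_id,
    timestamp = format_timestamps(events$timestamp),
    location_id = events$location_id,
    temperature_c = ifelse(is.na(events$temperature_c), "",
                           sprintf("%.1f", events$temperature_c)),
    event_type = events$event_type,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
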