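# Journey segmentation: split a product trace into storage / transport /
# transfusion phases and derive the timestamps the guidelines need.

#' Segment a product trace into storage, transport and transfusion phases
#'
#' Room occupancy is reconstructed from the event stream: a `gateway_pass`
#' marks the instant of a room transition; where a gateway read was missed,
#' the boundary falls at the midpoint between the last event in the old room
#' and the first in the new one.  Phases follow room function - the BTL and
#' storage rooms are `storage` (products inside a storage room are assumed to
#' be in its refrigerator), everything else is `transport` - except that for a
#' transfused product everything after its final exit from a storage-capable
#' room is the `transfusion` phase (transfusion data run from leaving storage
#' to the stop-box drop).  A transfused product whose stop box sits inside the
#' storage room has no transfusion phase and is flagged not separable.
#'
#' Derived timestamps: `btl_departure_time` (first exit from the BTL),
#' `cooling_exit_time` (last exit from a validated-cooler room before the end
#' of the journey), `transfusion_time` (stop-box drop) and `return_time`
#' (deactivation at the BTL).
#'
#' @param trace A `product_trace` with at least one reading.
#' @param facility A [facility_map()].
#' @return An object of class `segmented_trace`: the segment table (`phase`,
#'   `location_id`, `start_time`, `end_time`, `n_readings`), the readings
#'   annotated with their segment and phase, the derived timestamps, and the
#'   `separable` flag.
#' @export
segment_trace <- function(trace, facility) {
  stopifnot(inherits(trace, "product_trace"))
  if (nrow(trace$readings) == 0) {
    stop("cannot segment a trace with zero readings (product ",
         trace$product_id, ")", call. = FALSE)
  }
  ev <- trace$events
  check_locations(ev$location_id, facility, "trace")
  n <- nrow(ev)
  ts <- ev$timestamp
  rooms <- ev$location_id

  change <- which(rooms[-1] != rooms[-n]) + 1L
  b_time <- as.POSIXct(numeric(0), origin = "1970-01-01", tz = "UTC")
  if (length(change) > 0) {
    b_time <- ts[change]
    mid <- ev$event_type[change] != "gateway_pass"
    if (any(mid)) {
      b_time[mid] <- ts[change[mid] - 1L] + (ts[change[mid]] - ts[change[mid] - 1L]) / 2
    }
  }
  starts <- c(ts[1], b_time)
  ends <- c(b_time, ts[n])
  seg_rooms <- rooms[c(1L, change)]
  keep <- as.numeric(ends) > as.numeric(starts)
  # zero-length intervals can arise from coincident boundaries; drop them but
  # keep the overall tiling intact
  starts <- starts[keep]; ends <- ends[keep]; seg_rooms <- seg_rooms[keep]

  storage_capable <- is_storage_capable(facility, seg_rooms)
  phase <- ifelse(storage_capable, "storage", "transport")

  disposition <- trace$disposition
  separable <- TRUE
  if (disposition == "transfused") {
    if (storage_capable[length(seg_rooms)]) {
      # the stop-box drop happened inside a storage room: storage and
      # transfusion data cannot be split
      separable <- FALSE
    } else {
      stor <- which(storage_capable)
      last_storage <- if (length(stor) > 0) max(stor) else 0L
      phase[(last_storage + 1L):length(seg_rooms)] <- "transfusion"
    }
  }

  segments <- tibble::tibble(
    phase = phase, location_id = seg_rooms,
    start_time = starts, end_time = ends
  )
  rd <- trace$readings
  seg_idx <- findInterval(as.numeric(rd$timestamp), as.numeric(starts))
  seg_idx[seg_idx < 1L] <- 1L
  rd$segment <- seg_idx
  rd$phase <- segments$phase[seg_idx]
  segments$n_readings <- tabulate(seg_idx, nbins = nrow(segments))

  trace_end <- ends[length(ends)]
  btl <- btl_id(facility)
  btl_departure <- if (seg_rooms[1] == btl && length(seg_rooms) > 1) {
    ends[1]
  } else {
    as.POSIXct(NA, tz = "UTC")
  }
  validated <- storage_capable &
    room_field(facility, seg_rooms, "has_validated_cooler")
  cool_idx <- which(validated & as.numeric(ends) < as.numeric(trace_end))
  cooling_exit <- if (length(cool_idx) > 0) ends[max(cool_idx)] else
    as.POSIXct(NA, tz = "UTC")

  transfusion_time <- return_time <- as.POSIXct(NA, tz = "UTC")
  if (!is.null(trace$terminal)) {
    if (trace$terminal$type == "stopbox_drop") transfusion_time <- trace$terminal$time
    if (trace$terminal$type == "deactivation" && trace$terminal$location_id == btl) {
      return_time <- trace$terminal$time
    }
  }

  structure(
    list(
      product_id = trace$product_id,
      disposition = disposition,
      activation_time = trace$activation_time,
      segments = segments,
      readings = rd,
      btl_departure_time = btl_departure,
      cooling_exit_time = cooling_exit,
      transfusion_time = transfusion_time,
      return_time = return_time,
      separable = separable
    ),
    class = "segmented_trace"
  )
}

#' Last exit from validated cooling
#'
#' The end of the last storage segment spent in a room with a validated
#' cooling system, before the end of the journey; `NA` if the product never
#' left such a room mid-journey.  Guideline 2 measures its 1-hour window from
#' this instant.
#'
#' @param seg A `segmented_trace`.
#' @return A POSIXct timestamp, or `NA`.
#' @export
cooling_exit_time <- function(seg) {
  stopifnot(inherits(seg, "segmented_trace"))
  seg$cooling_exit_time
}

#' First recorded temperature breach
#'
#' The timestamp of the earliest eligible reading at or above the
#' noncompliance value (11 degC by default), which is the evidence threshold
#' for the 10 degC limit of guideline 3.
#'
#' @param readings A readings tibble (typically the eligible readings from
#'   [clean_temperatures()]).
#' @param thresholds A [guideline_thresholds()].
#' @return A POSIXct timestamp, or `NA` if no reading breaches.
#' @export
first_breach_time <- function(readings, thresholds = guideline_thresholds()) {
  hot <- !is.na(readings$temperature_c) &
    readings$temperature_c >= thresholds$breach_noncompliant_c
  if (!any(hot)) return(as.POSIXct(NA, tz = "UTC"))
  min(readings$timestamp[hot])
}

#' @export
print.segmented_trace <- function(x, ...) {
  cat(sprintf("<segmented_trace %s> %s, %d segments%s\n", x$product_id,
              x$disposition, nrow(x$segments),
              if (x$separable) "" else " (not separable)"))
  print(x$segments)
  invisible(x)
}
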