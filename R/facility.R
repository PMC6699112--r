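#' Build a facility map
#'
#' The facility map lists every room a tag can report, its type, whether it
#' holds an officially validated refrigerator, whether a stop box is mounted in
#' it, and its ambient temperature (the latter is used only by the simulator).
#'
#' Exactly one room must be the blood transfusion laboratory (`BTL`).  Only the
#' BTL and storage rooms may carry a validated cooler; corridors never do.
#'
#' @param rooms A data frame with columns `location_id`, `room_type` (one of
#'   `BTL`, `storage_room`, `or_theatre`, `icu_bay`, `corridor`),
#'   `has_validated_cooler`, `has_stopbox`, `ambient_c`.
#' @return An object of class `facility_map`.
#' @export
#' @examples
#' fac <- default_facility()
#' fac$rooms
facility_map <- function(rooms) {
  rooms <- tibble::as_tibble(rooms)
  needed <- c("location_id", "room_type", "has_validated_cooler", "has_stopbox",
              "ambient_c")
  missing_cols <- setdiff(needed, names(rooms))
  if (length(missing_cols) > 0) {
    stop("facility map is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  rooms$location_id <- as.character(rooms$location_id)
  rooms$room_type <- as.character(rooms$room_type)
  rooms$has_validated_cooler <- as.logical(rooms$has_validated_cooler)
  rooms$has_stopbox <- as.logical(rooms$has_stopbox)
  rooms$ambient_c <- as.numeric(rooms$ambient_c)
  if (anyDuplicated(rooms$location_id)) {
    stop("duplicate location_id in facility map", call. = FALSE)
  }
  bad_type <- setdiff(unique(rooms$room_type), ROOM_TYPES)
  if (length(bad_type) > 0) {
    stop("unknown room_type: ", paste(bad_type, collapse = ", "), call. = FALSE)
  }
  if (sum(rooms$room_type == "BTL") != 1) {
    stop("facility map must contain exactly one BTL room", call. = FALSE)
  }
  bad_cooler <- rooms$has_validated_cooler &
    !(rooms$room_type %in% c("BTL", "storage_room"))
  if (any(bad_cooler)) {
    stop("only the BTL and storage rooms may hold a validated cooler: ",
         paste(rooms$location_id[bad_cooler], collapse = ", "), call. = FALSE)
  }
  structure(list(rooms = rooms), class = "facility_map")
}

#' Default facility layout
#'
#' A compact floor plan with the rooms a tagged product can visit on its way
#' from the blood transfusion laboratory to an operating theatre or intensive
#' care unit: the BTL, a connecting corridor, a validated storage room and a
#' theatre at the operating-room complex, and a validated storage room (with
#' the stop box mounted inside it) plus a patient bay at the ICU.  Refrigerated
#' rooms default to a 4 degC ambient, everything else to 22 degC.
#'
#' @param cold_c,warm_c Ambient temperatures (degC) for refrigerated and
#'   unrefrigerated rooms.
#' @return A `facility_map`.
#' @export
default_facility <- function(cold_c = 4.0, warm_c = 22.0) {
  facility_map(tibble::tribble(
    ~location_id,  ~room_type,     ~has_validated_cooler, ~has_stopbox, ~ambient_c,
    "btl",         "BTL",          TRUE,                  FALSE,        cold_c,
    "corridor",    "corridor",     FALSE,                 FALSE,        warm_c,
    "or_storage",  "storage_room", TRUE,                  TRUE,         cold_c,
    "or_theatre",  "or_theatre",   FALSE,                 TRUE,         warm_c,
    "icu_storage", "storage_room", TRUE,                  TRUE,         cold_c,
    "icu_bay",     "icu_bay",      FALSE,                 FALSE,        warm_c
  ))
}

#' Read a facility map from YAML or JSON
#'
#' Expects a top-level `rooms` list whose entries carry the columns documented
#' in [facility_map()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `facility_map`.
#' @export
read_facility_map <- function(path) {
  vals <- read_config_file(path)
  if (is.null(vals$rooms)) {
    stop("facility file must have a top-level 'rooms' entry", call. = FALSE)
  }
  rooms <- vals$rooms
  if (!is.data.frame(rooms)) {
    rooms <- dplyr::bind_rows(lapply(rooms, tibble::as_tibble))
  }
  facility_map(rooms)
}

# Fast lookups ---------------------------------------------------------------

room_field <- function(facility, location_id, field) {
  idx <- match(location_id, facility$rooms$location_id)
  facility$rooms[[field]][idx]
}

btl_id <- function(facility) {
  facility$rooms$location_id[facility$rooms$room_type == "BTL"]
}

is_storage_capable <- function(facility, location_id) {
  room_field(facility, location_id, "room_type") %in% c("BTL", "storage_room")
}

check_locations <- function(location_id, facility, what = "event") {
  unknown <- setdiff(unique(location_id), facility$rooms$location_id)
  if (length(unknown) > 0) {
    stop("unknown location_id in ", what, ": ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.facility_map <- function(x, ...) {
  cat(sprintf("Facility map: %d rooms (BTL: %s)\n", nrow(x$rooms), btl_id(x)))
  print(x$rooms)
  invisible(x)
}
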