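# Journey templates: room itineraries with log-normal dwell-time
# distributions, covering every fate a tagged product can meet.

new_journey_template <- function(name, steps, terminal) {
  steps <- tibble::as_tibble(steps)
  if (!all(c("location_id", "meanlog", "sdlog", "offset_min") %in% names(steps))) {
    stop("template steps need location_id, meanlog, sdlog, offset_min", call. = FALSE)
  }
  if (!terminal %in% c("deactivation", "stopbox", "none")) {
    stop("terminal must be deactivation, stopbox or none", call. = FALSE)
  }
  structure(list(name = name, steps = steps, terminal = terminal),
            class = "journey_template")
}

step_row <- function(location_id, median_min, sdlog, offset_min = 0) {
  tibble::tibble(location_id = location_id, meanlog = log(median_min),
                 sdlog = sdlog, offset_min = offset_min)
}

#' Default journey templates
#'
#' Six itineraries through the floor plan of [default_facility()], one per fate
#' a tagged product can meet.  Dwell times are log-normal (always positive,
#' right-skewed), in minutes:
#'
#' * `never_left` - issued but never dispatched; deactivated at the BTL.
#' * `lost_in_transit` - the tag falls silent shortly after entering the
#'   corridor; no terminal event.
#' * `or_transfusion` - BTL, corridor, operating-room storage, theatre;
#'   the tag is dropped in the theatre stop box at transfusion.  The theatre
#'   dwell is the time the product spends outside validated cooling, sized so
#'   its mean matches the observed 3.74 h.
#' * `icu_transfusion_unseparable` - transfused at the ICU, where the stop box
#'   sits inside the storage room, so storage and transfusion data cannot be
#'   separated.
#' * `or_return` / `icu_return` - unused products held at the ward and brought
#'   back to the BTL.  Ward dwell is a ~23 h base hold plus a log-normal
#'   excess, reproducing both the observed group means (28.8 h / 46.2 h
#'   outside the BTL) and the rarity of returns inside the 24-h limit.
#'
#' Templates are keyed to location ids of the supplied facility; the default
#' names match [default_facility()].
#'
#' @param facility A [facility_map()] whose room ids the templates reference.
#' @return A named list of `journey_template` objects.
#' @export
journey_templates <- function(facility = default_facility()) {
  check <- function(tmpl) {
    check_locations(tmpl$steps$location_id, facility, paste0("template ", tmpl$name))
    tmpl
  }
  # Return wards hold products for roughly a day before sending them back;
  # modelled as a fixed base hold plus log-normal excess (see vignette).
  or_hold <- step_row("or_storage", exp(log(342) - 0.5), 1.0,
                      offset_min = 23.1 * 60 - 16)
  icu_hold <- step_row("icu_storage", exp(log(1386) - 0.5), 1.0,
                       offset_min = 23.1 * 60 - 20)
  templates <- list(
    never_left = new_journey_template(
      "never_left",
      step_row("btl", 240, 0.5),
      terminal = "deactivation"
    ),
    lost_in_transit = new_journey_template(
      "lost_in_transit",
      dplyr::bind_rows(
        step_row("btl", 120, 0.5),
        step_row("corridor", 8, 0.3)
      ),
      terminal = "none"
    ),
    or_transfusion = new_journey_template(
      "or_transfusion",
      dplyr::bind_rows(
        step_row("btl", 120, 0.5),
        step_row("corridor", 8, 0.3),
        step_row("or_storage", 180, 0.6),
        # time outside validated cooling before transfusion; mean ~224 min
        step_row("or_theatre", exp(log(224) - 0.45^2 / 2), 0.45)
      ),
      terminal = "stopbox"
    ),
    icu_transfusion_unseparable = new_journey_template(
      "icu_transfusion_unseparable",
      dplyr::bind_rows(
        step_row("btl", 120, 0.5),
        step_row("corridor", 8, 0.3),
        step_row("icu_storage", 360, 0.6)
      ),
      terminal = "stopbox"
    ),
    or_return = new_journey_template(
      "or_return",
      dplyr::bind_rows(
        step_row("btl", 120, 0.5),
        step_row("corridor", 8, 0.3),
        or_hold,
        step_row("corridor", 8, 0.3),
        step_row("btl", 20, 0.4)
      ),
      terminal = "deactivation"
    ),
    icu_return = new_journey_template(
      "icu_return",
      dplyr::bind_rows(
        step_row("btl", 120, 0.5),
        step_row("corridor", 10, 0.3),
        icu_hold,
        step_row("corridor", 10, 0.3),
        step_row("btl", 20, 0.4)
      ),
      terminal = "deactivation"
    )
  )
  lapply(templates, check)
}
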