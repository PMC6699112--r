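# Hand-built fixtures: event streams with known segment boundaries, so
# expected verdicts can be computed by straight-line arithmetic in the tests.

t_base <- as.POSIXct("2018-03-01 08:00:00", tz = "UTC")

mk_time <- function(minutes) t_base + minutes * 60

# One event row with defaults.
ev_row <- function(min, location, type, temp = NA_real_, tag = "T1",
                   product = "P1") {
  tibble::tibble(tag_id = tag, product_id = product, timestamp = mk_time(min),
                 location_id = location, temperature_c = temp,
                 event_type = type)
}

ev_bind <- function(...) dplyr::bind_rows(...)

# A transfused operating-room journey with known boundaries:
#   btl [0, 120] -> corridor [120, 130] -> or_storage [130, 240]
#   -> or_theatre [240, 330], stop-box drop at 330.
# Storage/transport readings after the first hour: btl 64..112 at 5.0,
# corridor 124 at 8.0, or_storage 140..230 at 4.5.  Expected: G1 noncompliant
# (max 8.0), G2 noncompliant (1.5 h outside cooling), G3 compliant (no
# reading reaches 11).
or_journey_events <- function(tag = "T1", product = "P1") {
  ev_bind(
    ev_row(0, "btl", "activation", tag = tag, product = product),
    ev_row(seq(8, 112, by = 8), "btl", "reading", 5.0, tag, product),
    ev_row(120, "corridor", "gateway_pass", tag = tag, product = product),
    ev_row(124, "corridor", "reading", 8.0, tag, product),
    ev_row(130, "or_storage", "gateway_pass", tag = tag, product = product),
    ev_row(seq(140, 230, by = 10), "or_storage", "reading", 4.5, tag, product),
    ev_row(240, "or_theatre", "gateway_pass", tag = tag, product = product),
    ev_row(c(250, 300), "or_theatre", "reading", c(10.0, 15.0), tag, product),
    ev_row(330, "or_theatre", "stopbox_drop", tag = tag, product = product)
  )
}

# A returned journey: btl [0, 60] -> corridor [60, 70] -> or_storage
# [70, 1500] -> corridor [1500, 1510] -> btl [1510, 1530], deactivated at
# 1530.  Departure at 60, return at 1530: 24.5 h outside, G4 noncompliant.
return_journey_events <- function(tag = "T2", product = "P2",
                                  hold_end_min = 1500, temp_c = 4.5) {
  ev_bind(
    ev_row(0, "btl", "activation", tag = tag, product = product),
    ev_row(seq(8, 56, by = 8), "btl", "reading", temp_c, tag, product),
    ev_row(60, "corridor", "gateway_pass", tag = tag, product = product),
    ev_row(70, "or_storage", "gateway_pass", tag = tag, product = product),
    ev_row(seq(80, hold_end_min - 10, by = 8), "or_storage", "reading", temp_c,
           tag, product),
    ev_row(hold_end_min, "corridor", "gateway_pass", tag = tag, product = product),
    ev_row(hold_end_min + 10, "btl", "gateway_pass", tag = tag, product = product),
    ev_row(hold_end_min + 15, "btl", "reading", temp_c, tag, product),
    ev_row(hold_end_min + 30, "btl", "deactivation", tag = tag, product = product)
  )
}

# An ICU transfusion where the stop box sits inside the storage room:
# btl [0, 60] -> corridor [60, 70] -> icu_storage [70, 400], drop at 400.
icu_unseparable_events <- function(tag = "T3", product = "P3") {
  ev_bind(
    ev_row(0, "btl", "activation", tag = tag, product = product),
    ev_row(seq(8, 56, by = 8), "btl", "reading", 4.5, tag, product),
    ev_row(60, "corridor", "gateway_pass", tag = tag, product = product),
    ev_row(70, "icu_storage", "gateway_pass", tag = tag, product = product),
    ev_row(seq(80, 390, by = 8), "icu_storage", "reading", 4.5, tag, product),
    ev_row(400, "icu_storage", "stopbox_drop", tag = tag, product = product)
  )
}

# Products that never left the laboratory.
never_left_events <- function(tag = "T4", product = "P4") {
  ev_bind(
    ev_row(0, "btl", "activation", tag = tag, product = product),
    ev_row(seq(8, 232, by = 8), "btl", "reading", 4.5, tag, product),
    ev_row(240, "btl", "deactivation", tag = tag, product = product)
  )
}

# A tag that fell silent in the corridor.
lost_events <- function(tag = "T5", product = "P5") {
  ev_bind(
    ev_row(0, "btl", "activation", tag = tag, product = product),
    ev_row(seq(8, 112, by = 8), "btl", "reading", 4.5, tag, product),
    ev_row(120, "corridor", "gateway_pass", tag = tag, product = product),
    ev_row(126, "corridor", "reading", 7.0, tag, product)
  )
}

one_trace <- function(events, facility = default_facility()) {
  build_traces(events, facility)[[1]]
}

one_segmented <- function(events, facility = default_facility()) {
  segment_trace(one_trace(events, facility), facility)
}

# Minimal segmented-trace stub for evaluator arithmetic tests.
seg_stub <- function(disposition = "transfused",
                     btl_departure_h = NA, cooling_exit_h = NA,
                     transfusion_h = NA, return_h = NA) {
  as_t <- function(h) if (is.na(h)) as.POSIXct(NA, tz = "UTC") else mk_time(h * 60)
  structure(list(
    product_id = "S1", disposition = disposition, activation_time = t_base,
    segments = tibble::tibble(), readings = tibble::tibble(),
    btl_departure_time = as_t(btl_departure_h),
    cooling_exit_time = as_t(cooling_exit_h),
    transfusion_time = as_t(transfusion_h),
    return_time = as_t(return_h), separable = TRUE
  ), class = "segmented_trace")
}

# The published per-disposition verdict tallies, as patterns for
# records_from_verdicts(): 4 returned products compliant to both applicable
# guidelines; 5 compliant to G4 only and 10 to G1 only; 99 compliant to
# neither; 49 transfused products noncompliant to G1 and G2 but compliant to
# G3; 15 with missing data (12 unregistered returns, 3 unregistered
# transfusion times).
study_verdict_patterns <- function() {
  tibble::tibble(
    disposition = c("returned", "returned", "returned", "returned",
                    "transfused", "returned", "transfused"),
    g1 = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE),
    g2 = c(NA, NA, NA, NA, FALSE, NA, NA),
    g3 = c(NA, NA, NA, NA, TRUE, NA, TRUE),
    g4 = c(TRUE, TRUE, FALSE, FALSE, NA, NA, NA),
    n = c(4L, 5L, 10L, 99L, 49L, 12L, 3L)
  )
}
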