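# Missingness injection: transmission dropout and stop-box misuse.

#' Inject field-realistic missingness into a simulated event stream
#'
#' Two corruption modes:
#'
#' * transmission dropout - every `reading` and `gateway_pass` event is lost
#'   independently with probability `dropout_p` (lifecycle events survive);
#' * stop-box misuse - a staff member pockets the tag at transfusion instead
#'   of dropping it: the `stopbox_drop` is delayed by a uniform draw from
#'   `delay_days`, body-adjacent pocket-temperature readings are appended in
#'   between, and with probability `wrong_box_p` the drop lands in a different
#'   room's stop box.
#'
#' Uses the session RNG; seed beforehand for reproducibility (the simulator
#' does this for you).
#'
#' @param events Event tibble.
#' @param truth Truth tibble from [simulate_cohort()]; its `corrupted` column
#'   records which products were misused.
#' @param dropout_p Per-event loss probability.
#' @param stopbox_misuse `NULL`, or a list with `misuse_p`, `delay_days`
#'   (length-2 range), `wrong_box_p` and `pocket_c`.
#' @param thermal A [thermal_params()] (pocket readings follow the thermal
#'   model toward `pocket_c`).
#' @param facility A [facility_map()] (locates alternative stop boxes).
#' @return A list with the corrupted `events` and the updated `truth`.
#' @export
inject_missingness <- function(events, truth, dropout_p = 0,
                               stopbox_misuse = NULL,
                               thermal = thermal_params(),
                               facility = default_facility()) {
  if (dropout_p < 0 || dropout_p > 1) {
    stop("dropout_p must lie in [0, 1]", call. = FALSE)
  }

  if (!is.null(stopbox_misuse) && stopbox_misuse$misuse_p > 0) {
    candidates <- which(truth$disposition == "transfused" &
                          truth$template == "or_transfusion" &
                          truth$corrupted == "")
    chosen <- candidates[runif(length(candidates)) < stopbox_misuse$misuse_p]
    for (i in chosen) {
      pieces <- delay_stopbox(events, truth$product_id[i], stopbox_misuse,
                              thermal, facility)
      events <- pieces$events
      truth$corrupted[i] <- "stopbox_misuse"
    }
  }

  if (dropout_p > 0 && nrow(events) > 0) {
    droppable <- events$event_type %in% c("reading", "gateway_pass")
    lose <- droppable & runif(nrow(events)) < dropout_p
    events <- events[!lose, , drop = FALSE]
  }

  list(events = dplyr::arrange(events, .data$tag_id, .data$timestamp),
       truth = truth)
}

# Delay one product's stop-box drop and append pocket readings.
delay_stopbox <- function(events, product_id, misuse, thermal, facility) {
  idx <- which(events$product_id == product_id &
                 events$event_type == "stopbox_drop")
  if (length(idx) != 1) return(list(events = events))
  drop_time <- events$timestamp[idx]
  drop_loc <- events$location_id[idx]
  delay_s <- round(runif(1, misuse$delay_days[1], misuse$delay_days[2]) * 86400)
  new_time <- drop_time + delay_s

  # pocket readings: tag warms from its last recorded value toward pocket_c
  prod_reads <- events$product_id == product_id & events$event_type == "reading"
  last_c <- if (any(prod_reads)) {
    events$temperature_c[which(prod_reads)[sum(prod_reads)]]
  } else {
    thermal$initial_tag_c
  }
  step_s <- thermal$sampling_interval_min * 60
  n_new <- floor((delay_s - 1) / step_s)
  if (n_new > 0) {
    t_new <- drop_time + step_s * seq_len(n_new)
    temps <- tag_temperature_step(last_c, misuse$pocket_c,
                                  thermal$rate_constant_per_min,
                                  step_s * seq_len(n_new) / 60)
    temps <- quantize_temp(temps + thermal$sensor_bias_c, thermal$quantization_c)
    temps <- pmin(temps, 45) # sensor ceiling
    events <- dplyr::bind_rows(events, tibble::tibble(
      tag_id = events$tag_id[idx], product_id = product_id,
      timestamp = t_new, location_id = drop_loc,
      temperature_c = temps, event_type = "reading"
    ))
    idx <- which(events$product_id == product_id &
                   events$event_type == "stopbox_drop")
  }
  events$timestamp[idx] <- new_time
  if (runif(1) < misuse$wrong_box_p) {
    boxes <- setdiff(facility$rooms$location_id[facility$rooms$has_stopbox],
                     drop_loc)
    if (length(boxes) > 0) events$location_id[idx] <- sample(boxes, 1)
  }
  list(events = events)
}
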