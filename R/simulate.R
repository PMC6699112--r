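# Discrete-event cohort simulator: tagged products move through the facility
# along sampled journey templates; the tag temperature follows the first-order
# thermal model through each room's ambient; recorded values carry sensor bias
# and quantization; missingness modes mirror what field telemetry suffers.

#' Simulation configuration
#'
#' @param n_products Number of tagged products to simulate.
#' @param template_mix Named probabilities over the templates in `templates`
#'   (must sum to 1).  Ignored when `template_counts` is given.
#' @param template_counts Named integer counts per template (summing to
#'   `n_products`); gives an exact, shuffled template assignment.
#' @param thermal A [thermal_params()] object.
#' @param facility A [facility_map()].
#' @param thresholds A [guideline_thresholds()] object (used to label ground
#'   truth).
#' @param templates Journey templates, as from [journey_templates()].
#' @param dropout_p Probability that any individual reading or gateway event
#'   is lost in transmission.
#' @param stopbox_misuse_p Probability that a transfused (operating-room)
#'   product's tag is pocketed by staff and dropped into the stop box only
#'   days later, with pocket-temperature readings in between.
#' @param stopbox_delay_days Range (days) of the late-drop delay.
#' @param wrong_box_p Probability a misused tag is dropped in a different
#'   room's stop box.
#' @param pocket_c Ambient temperature of a pocketed tag, degC.
#' @param return_registration_fail_p Probability that a returned product's
#'   deactivation at the BTL is never registered.
#' @param incomplete_p Probability that a dispatched product's readings are
#'   almost entirely lost (no usable sub-dataset); `n_incomplete` overrides
#'   with an exact count.
#' @param n_incomplete Exact number of such products, or `NULL`.
#' @param start_time Start of the issue window (POSIXct, UTC).
#' @param issue_window_days Activations are spread uniformly over this window.
#' @param lost_visible_min A lost tag stays visible in the corridor for
#'   8 to `lost_visible_min` minutes before falling silent.
#' @param seed Integer seed; identical configurations (including the seed)
#'   produce byte-identical event streams.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_products,
                              template_mix = NULL,
                              template_counts = NULL,
                              thermal = thermal_params(),
                              facility = default_facility(),
                              thresholds = guideline_thresholds(),
                              templates = journey_templates(facility),
                              dropout_p = 0.02,
                              stopbox_misuse_p = 0,
                              stopbox_delay_days = c(4, 6),
                              wrong_box_p = 0,
                              pocket_c = 30.0,
                              return_registration_fail_p = 0,
                              incomplete_p = 0,
                              n_incomplete = NULL,
                              start_time = as.POSIXct("2018-03-01 06:00:00", tz = "UTC"),
                              issue_window_days = 60,
                              lost_visible_min = 15,
                              seed = 1L) {
  if (n_products < 0) stop("n_products must be non-negative", call. = FALSE)
  if (is.null(template_mix) && is.null(template_counts)) {
    template_mix <- setNames(rep(1 / length(templates), length(templates)),
                             names(templates))
  }
  if (!is.null(template_counts)) {
    bad <- setdiff(names(template_counts), names(templates))
    if (length(bad) > 0) stop("unknown template(s): ", paste(bad, collapse = ", "),
                              call. = FALSE)
    if (sum(template_counts) != n_products) {
      stop("template_counts must sum to n_products", call. = FALSE)
    }
  } else {
    bad <- setdiff(names(template_mix), names(templates))
    if (length(bad) > 0) stop("unknown template(s): ", paste(bad, collapse = ", "),
                              call. = FALSE)
    if (any(template_mix < 0) || any(template_mix > 1)) {
      stop("template_mix probabilities must lie in [0, 1]", call. = FALSE)
    }
    if (abs(sum(template_mix) - 1) > 1e-8) {
      stop("template_mix must sum to 1 (got ", sum(template_mix), ")", call. = FALSE)
    }
  }
  probs <- c(dropout_p, stopbox_misuse_p, wrong_box_p,
             return_registration_fail_p, incomplete_p)
  if (any(probs < 0) || any(probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      n_products = as.integer(n_products),
      template_mix = template_mix,
      template_counts = template_counts,
      thermal = thermal,
      facility = facility,
      thresholds = thresholds,
      templates = templates,
      dropout_p = dropout_p,
      stopbox_misuse_p = stopbox_misuse_p,
      stopbox_delay_days = stopbox_delay_days,
      wrong_box_p = wrong_box_p,
      pocket_c = pocket_c,
      return_registration_fail_p = return_registration_fail_p,
      incomplete_p = incomplete_p,
      n_incomplete = n_incomplete,
      start_time = start_time,
      issue_window_days = issue_window_days,
      lost_visible_min = lost_visible_min,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Study-cohort configuration
#'
#' A 243-product cohort with the observed fate tallies: 7 never left the BTL,
#' 13 were lost after leaving it, 40 were transfused at the ICU where storage
#' and transfusion data cannot be separated, 52 were transfused at the
#' operating room, 131 returned unused (66 from the OR, 65 from the ICU; the
#' OR/ICU split of returns is not reported and is an even split here), and one
#' product's readings are unusable in every sub-dataset.  Misuse and
#' registration-failure rates reproduce the observed per-guideline
#' completeness (3 of 52 transfusion records dropped late; 12 of 130 returns
#' unregistered).
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [simulation_config()].
#' @return A `simulation_config`.
#' @export
paper_cohort_config <- function(seed = 1L, ...) {
  args <- list(
    n_products = 243,
    template_counts = c(never_left = 7, lost_in_transit = 13,
                        icu_transfusion_unseparable = 40, or_transfusion = 52,
                        or_return = 66, icu_return = 65),
    n_incomplete = 1,
    stopbox_misuse_p = 3 / 52,
    return_registration_fail_p = 12 / 130,
    dropout_p = 0.02,
    seed = seed
  )
  args <- utils::modifyList(args, list(...))
  do.call(simulation_config, args)
}

#' Strip all noise sources from a configuration
#'
#' Sets sensor bias, quantization, dropout, stop-box misuse, registration
#' failures and incomplete-record corruption to zero, so recorded values equal
#' the true tag temperature and every event is observed.
#'
#' @param config A `simulation_config`.
#' @return The noiseless configuration.
#' @export
noiseless <- function(config) {
  config$thermal$sensor_bias_c <- 0
  config$thermal$quantization_c <- 0
  config$dropout_p <- 0
  config$stopbox_misuse_p <- 0
  config$wrong_box_p <- 0
  config$return_registration_fail_p <- 0
  config$incomplete_p <- 0
  config$n_incomplete <- NULL
  config
}

empty_truth <- function() {
  tibble::tibble(
    product_id = character(), tag_id = character(), template = character(),
    disposition = character(), activation_time = as.POSIXct(character(), tz = "UTC"),
    btl_departure_time = as.POSIXct(character(), tz = "UTC"),
    cooling_exit_time = as.POSIXct(character(), tz = "UTC"),
    final_storage_exit = as.POSIXct(character(), tz = "UTC"),
    transfusion_time = as.POSIXct(character(), tz = "UTC"),
    return_time = as.POSIXct(character(), tz = "UTC"),
    g1_compliant = logical(), g2_compliant = logical(), g3_compliant = logical(),
    g4_compliant = logical(), category = character(),
    exclusion_reason = character(), corrupted = character(),
    n_readings = integer(), itinerary = list()
  )
}

#' Simulate a cohort of tagged blood products
#'
#' Every product follows a journey sampled from the configured templates; the
#' tag temperature evolves by the first-order thermal model through each
#' room's ambient; recorded readings are true tag temperature plus sensor
#' bias, quantized, every `sampling_interval_min` minutes; `gateway_pass`
#' events mark each room transition; journeys end in a stop-box drop
#' (transfusion), a deactivation at the BTL (return), or silence (lost).
#' Missingness modes (reading dropout, stop-box misuse, unregistered returns,
#' unusable records) are then injected per the configuration.
#'
#' @param config A [simulation_config()].
#' @return A list with `events` (tag event tibble) and `truth` (one row per
#'   product: true journey times, true per-guideline verdicts on the noiseless
#'   tag signal, the decision-tree category implied by them, the expected
#'   exclusion reason, and which corruption - if any - was injected).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_products
  if (n == 0) return(list(events = empty_events(), truth = empty_truth()))

  if (!is.null(config$template_counts)) {
    assigned <- sample(rep(names(config$template_counts), config$template_counts))
  } else {
    assigned <- sample(names(config$template_mix), n, replace = TRUE,
                       prob = config$template_mix)
  }
  ids <- sprintf("P%04d", seq_len(n))
  tags <- sprintf("T%04d", seq_len(n))

  sims <- vector("list", n)
  for (i in seq_len(n)) {
    sims[[i]] <- simulate_product(ids[i], tags[i], config$templates[[assigned[i]]],
                                  config)
  }
  events <- dplyr::bind_rows(lapply(sims, `[[`, "events"))
  truth <- dplyr::bind_rows(lapply(sims, `[[`, "truth"))
  truth$itinerary <- lapply(sims, `[[`, "itinerary")

  # Unusable-record corruption: keep only the first few post-activation
  # readings so no phase retains a usable reading series.
  candidates <- which(!(truth$template %in%
                          c("never_left", "lost_in_transit",
                            "icu_transfusion_unseparable")))
  n_inc <- if (!is.null(config$n_incomplete)) {
    min(config$n_incomplete, length(candidates))
  } else {
    sum(runif(length(candidates)) < config$incomplete_p)
  }
  if (n_inc > 0) {
    corrupt <- sample(candidates, n_inc)
    for (i in corrupt) {
      keep_until <- truth$activation_time[i] + 16 * 60
      drop <- events$product_id == truth$product_id[i] &
        events$event_type == "reading" & events$timestamp > keep_until
      events <- events[!drop, , drop = FALSE]
      truth$corrupted[i] <- "incomplete"
      truth$exclusion_reason[i] <- "incomplete_all_subsets"
    }
  }

  # Unregistered returns: the BTL deactivation never makes it to the database.
  returned <- which(truth$disposition == "returned" &
                      truth$template != "never_left" & truth$corrupted == "")
  fail <- returned[runif(length(returned)) < config$return_registration_fail_p]
  if (length(fail) > 0) {
    drop <- events$product_id %in% truth$product_id[fail] &
      events$event_type == "deactivation"
    events <- events[!drop, , drop = FALSE]
    truth$corrupted[fail] <- "return_unregistered"
  }

  # Stop-box misuse and transmission dropout.
  misuse <- NULL
  if (config$stopbox_misuse_p > 0) {
    misuse <- list(misuse_p = config$stopbox_misuse_p,
                   delay_days = config$stopbox_delay_days,
                   wrong_box_p = config$wrong_box_p,
                   pocket_c = config$pocket_c)
  }
  inj <- inject_missingness(events, truth, dropout_p = config$dropout_p,
                            stopbox_misuse = misuse, thermal = config$thermal,
                            facility = config$facility)
  events <- dplyr::arrange(inj$events, .data$tag_id, .data$timestamp)
  list(events = events, truth = inj$truth)
}

# One product's journey: itinerary, thermal curves, events, truth labels.
simulate_product <- function(product_id, tag_id, tmpl, config) {
  th <- config$thermal
  fac <- config$facility
  steps <- tmpl$steps
  m <- nrow(steps)

  activation <- config$start_time +
    round(runif(1, 0, config$issue_window_days * 86400))
  dwell_s <- round((steps$offset_min +
                      rlnorm(m, steps$meanlog, steps$sdlog)) * 60)
  dwell_s <- pmax(dwell_s, 60) # at least a minute per room
  entry <- activation + c(0, cumsum(dwell_s))[seq_len(m)]
  exits <- entry + dwell_s
  end_time <- exits[m]
  if (tmpl$terminal == "none") {
    # tag falls silent shortly after entering the last room (>= 8 min in,
    # so at least one reading lands there)
    end_time <- entry[m] + round(runif(1, 8, config$lost_visible_min) * 60)
  }

  amb <- room_field(fac, steps$location_id, "ambient_c")
  k_tag <- th$rate_constant_per_min
  k_prod <- k_tag * th$product_rate_ratio
  tag_entry <- prod_entry <- numeric(m)
  tag_entry[1] <- th$initial_tag_c
  prod_entry[1] <- amb[1] # products come out of the issue refrigerator
  if (m > 1) {
    for (j in 2:m) {
      dt <- dwell_s[j - 1] / 60
      tag_entry[j] <- tag_temperature_step(tag_entry[j - 1], amb[j - 1], k_tag, dt)
      prod_entry[j] <- tag_temperature_step(prod_entry[j - 1], amb[j - 1], k_prod, dt)
    }
  }

  step_s <- th$sampling_interval_min * 60
  n_reads <- max(0, floor((as.numeric(end_time) - as.numeric(activation) - 1) / step_s))
  read_t <- activation + step_s * seq_len(n_reads)
  seg <- findInterval(as.numeric(read_t), as.numeric(entry))
  dt_min <- (as.numeric(read_t) - as.numeric(entry[seg])) / 60
  true_tag <- tag_temperature_step(tag_entry[seg], amb[seg], k_tag, dt_min)
  true_prod <- tag_temperature_step(prod_entry[seg], amb[seg], k_prod, dt_min)
  recorded <- quantize_temp(true_tag + th$sensor_bias_c, th$quantization_c)

  rows <- list(
    tibble::tibble(tag_id = tag_id, product_id = product_id,
                   timestamp = activation, location_id = steps$location_id[1],
                   temperature_c = NA_real_, event_type = "activation")
  )
  if (m > 1) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      tag_id = tag_id, product_id = product_id, timestamp = entry[-1],
      location_id = steps$location_id[-1], temperature_c = NA_real_,
      event_type = "gateway_pass"
    )
  }
  if (n_reads > 0) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      tag_id = tag_id, product_id = product_id, timestamp = read_t,
      location_id = steps$location_id[seg], temperature_c = recorded,
      event_type = "reading"
    )
  }
  if (tmpl$terminal != "none") {
    rows[[length(rows) + 1]] <- tibble::tibble(
      tag_id = tag_id, product_id = product_id, timestamp = end_time,
      location_id = steps$location_id[m], temperature_c = NA_real_,
      event_type = if (tmpl$terminal == "stopbox") "stopbox_drop" else "deactivation"
    )
  }
  events <- dplyr::arrange(dplyr::bind_rows(rows), .data$timestamp)
  # drop any gateway/reading at or after the terminal instant
  if (tmpl$terminal == "none") {
    events <- events[events$timestamp <= end_time, , drop = FALSE]
  }

  truth <- label_truth(product_id, tag_id, tmpl, steps, entry, exits, end_time,
                       activation, read_t, true_tag, fac, config$thresholds)
  truth$n_readings <- n_reads
  list(events = events, truth = truth,
       itinerary = tibble::tibble(location_id = steps$location_id,
                                  entry = entry, exit = exits,
                                  true_tag_entry_c = tag_entry,
                                  true_product_entry_c = prod_entry))
}

# True per-guideline verdicts on the noiseless tag signal, plus the category
# they imply.  This is deliberately straight-line arithmetic on the known
# journey times, independent of the event-stream reconstruction path.
label_truth <- function(product_id, tag_id, tmpl, steps, entry, exits, end_time,
                        activation, read_t, true_tag, fac, th) {
  m <- nrow(steps)
  storage_capable <- is_storage_capable(fac, steps$location_id)
  validated <- storage_capable & room_field(fac, steps$location_id, "has_validated_cooler")
  btl <- btl_id(fac)

  disposition <- switch(tmpl$terminal,
    none = "lost",
    stopbox = "transfused",
    deactivation = if (m == 1) "never_left" else "returned"
  )
  departure <- if (m > 1) exits[1] else as.POSIXct(NA, tz = "UTC")
  transfusion <- if (disposition == "transfused") end_time else as.POSIXct(NA, tz = "UTC")
  return_time <- if (disposition == "returned") end_time else as.POSIXct(NA, tz = "UTC")

  # last exit from a validated-cooler room strictly before the journey end
  cool_idx <- which(validated & exits < end_time)
  cooling_exit <- if (length(cool_idx) > 0) exits[max(cool_idx)] else as.POSIXct(NA, tz = "UTC")
  # A product dropped in a storage room's own stop box has no transfusion
  # phase; otherwise the phase starts at the final exit from any
  # storage-capable room.
  separable <- !(disposition == "transfused" && storage_capable[m])
  stor_idx <- which(storage_capable & exits < end_time)
  final_storage_exit <- if (disposition == "transfused" && separable &&
                              length(stor_idx) > 0) {
    exits[max(stor_idx)]
  } else {
    as.POSIXct(NA, tz = "UTC")
  }

  g1 <- g2 <- g3 <- g4 <- NA
  excl <- switch(disposition,
    never_left = "never_left_btl",
    lost = "lost_after_btl",
    transfused = if (!separable) "unseparable_icu" else "none",
    returned = "none"
  )
  if (excl == "none") {
    elig <- read_t > activation + th$min_allocation_hours * 3600
    if (disposition == "transfused") elig <- elig & read_t < final_storage_exit
    elig_t <- read_t[elig]
    elig_temp <- true_tag[elig]
    if (length(elig_temp) > 0) {
      g1 <- all(elig_temp >= th$compliant_lo_c & elig_temp <= th$compliant_hi_c)
    }
    if (disposition == "transfused") {
      g2 <- as.numeric(difftime(transfusion, cooling_exit, units = "hours")) <=
        th$transfusion_max_hours
      breach <- elig_t[elig_temp >= th$breach_noncompliant_c]
      g3 <- if (length(breach) == 0) TRUE else {
        anchor <- if (th$g3_anchor == "breach") breach[1] else departure
        as.numeric(difftime(transfusion, anchor, units = "hours")) <=
          th$breach_transfuse_within_hours
      }
    }
    if (disposition == "returned") {
      g4 <- as.numeric(difftime(return_time, departure, units = "hours")) <=
        th$return_within_hours
    }
  }

  verdicts <- if (disposition == "transfused") c(g1, g2, g3) else
    if (disposition == "returned") c(g1, g4) else NA
  category <- if (excl != "none") {
    NA_character_
  } else if (anyNA(verdicts)) {
    "excluded_missing_data"
  } else {
    n_bad <- sum(!verdicts)
    if (n_bad == 0) "compliant_all" else if (n_bad == 1) "noncompliant_one" else
      "noncompliant_two_or_more"
  }

  tibble::tibble(
    product_id = product_id, tag_id = tag_id, template = tmpl$name,
    disposition = disposition, activation_time = activation,
    btl_departure_time = departure, cooling_exit_time = cooling_exit,
    final_storage_exit = final_storage_exit, transfusion_time = transfusion,
    return_time = return_time,
    g1_compliant = g1, g2_compliant = g2, g3_compliant = g3, g4_compliant = g4,
    category = category, exclusion_reason = excl, corrupted = "",
    n_readings = NA_integer_
  )
}
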