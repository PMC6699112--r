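# Guideline evaluation and decision-tree classification.
#
# All boundaries are compliant-inclusive: an interval of exactly 1 h (G2) or
# 24 h (G3/G4) and a recorded 6.5 degC (G1) still comply.  Inclusive limits
# favour the product and match the printed compliant ranges.

guideline_result <- function(guideline_id, applicable, assessable = NA,
                             compliant = NA, evidence = list()) {
  list(guideline_id = guideline_id, applicable = applicable,
       assessable = assessable, compliant = compliant, evidence = evidence)
}

#' Evaluate guideline 1: storage temperature
#'
#' Products must be kept between 2 and 6 degC; recorded values are judged
#' against the sensor-widened window (1.5 to 6.5 degC by default).  Compliant
#' iff every eligible reading lies inside the window.
#'
#' @param eligible Eligible readings, from [clean_temperatures()].
#' @param thresholds A [guideline_thresholds()].
#' @return A guideline result: `applicable`, `assessable`, `compliant`, and
#'   evidence `min_temp_c` / `max_temp_c`.
#' @export
eval_g1 <- function(eligible, thresholds = guideline_thresholds()) {
  if (nrow(eligible) == 0) {
    return(guideline_result(1L, TRUE, assessable = FALSE))
  }
  temps <- eligible$temperature_c
  guideline_result(
    1L, TRUE, assessable = TRUE,
    compliant = all(temps >= thresholds$compliant_lo_c &
                      temps <= thresholds$compliant_hi_c),
    evidence = list(min_temp_c = min(temps), max_temp_c = max(temps))
  )
}

#' Evaluate guideline 2: time outside validated cooling before transfusion
#'
#' Transfusion must happen within 1 hour of leaving a validated cooling
#' system.  Compliant iff `transfusion_time - cooling_exit_time` is at most
#' `transfusion_max_hours`.
#'
#' @param seg A `segmented_trace` of a transfused product.
#' @param thresholds A [guideline_thresholds()].
#' @return A guideline result with evidence `hours_outside_cooling`.
#' @export
eval_g2 <- function(seg, thresholds = guideline_thresholds()) {
  if (is.na(seg$transfusion_time) || is.na(seg$cooling_exit_time)) {
    return(guideline_result(2L, TRUE, assessable = FALSE))
  }
  hours <- as.numeric(difftime(seg$transfusion_time, seg$cooling_exit_time,
                               units = "hours"))
  guideline_result(
    2L, TRUE, assessable = TRUE,
    compliant = hours <= thresholds$transfusion_max_hours,
    evidence = list(hours_outside_cooling = hours)
  )
}

#' Evaluate guideline 3: transfusion deadline after a temperature breach
#'
#' A product that reaches a temperature above 10 degC (recorded value at or
#' above 11 degC) must be transfused within 24 hours.  If no eligible reading
#' breaches, the guideline is vacuously complied with.  The 24-hour window is
#' anchored at the first recorded breach by default; set
#' `g3_anchor = "departure"` in the thresholds to measure it from BTL
#' departure instead.
#'
#' @param seg A `segmented_trace` of a transfused product.
#' @param eligible Eligible readings, from [clean_temperatures()].
#' @param thresholds A [guideline_thresholds()].
#' @return A guideline result with evidence `min_temp_c`, `max_temp_c`,
#'   `breach_time`, `hours_to_transfusion`.
#' @export
eval_g3 <- function(seg, eligible, thresholds = guideline_thresholds()) {
  if (is.na(seg$transfusion_time) || nrow(eligible) == 0) {
    return(guideline_result(3L, TRUE, assessable = FALSE))
  }
  breach <- first_breach_time(eligible, thresholds)
  temps <- eligible$temperature_c
  if (is.na(breach)) {
    return(guideline_result(
      3L, TRUE, assessable = TRUE, compliant = TRUE,
      evidence = list(min_temp_c = min(temps), max_temp_c = max(temps),
                      breach_time = as.POSIXct(NA, tz = "UTC"),
                      hours_to_transfusion = NA_real_)
    ))
  }
  anchor <- if (thresholds$g3_anchor == "breach") breach else seg$btl_departure_time
  hours <- as.numeric(difftime(seg$transfusion_time, anchor, units = "hours"))
  guideline_result(
    3L, TRUE, assessable = TRUE,
    compliant = hours <= thresholds$breach_transfuse_within_hours,
    evidence = list(min_temp_c = min(temps), max_temp_c = max(temps),
                    breach_time = breach, hours_to_transfusion = hours)
  )
}

#' Evaluate guideline 4: return deadline for unused products
#'
#' Unused products must be back at the blood transfusion laboratory within
#' 24 hours of leaving it.  Compliant iff `return_time - btl_departure_time`
#' is at most `return_within_hours`.
#'
#' @param seg A `segmented_trace` of a returned product.
#' @param thresholds A [guideline_thresholds()].
#' @return A guideline result with evidence `hours_to_return`.
#' @export
eval_g4 <- function(seg, thresholds = guideline_thresholds()) {
  if (is.na(seg$btl_departure_time) || is.na(seg$return_time)) {
    return(guideline_result(4L, TRUE, assessable = FALSE))
  }
  hours <- as.numeric(difftime(seg$return_time, seg$btl_departure_time,
                               units = "hours"))
  guideline_result(
    4L, TRUE, assessable = TRUE,
    compliant = hours <= thresholds$return_within_hours,
    evidence = list(hours_to_return = hours)
  )
}

#' Decision-tree category from per-guideline results
#'
#' The applicable set is guidelines 1 and 4 for returned products and 1, 2
#' and 3 for transfused ones.  If any applicable guideline could not be
#' assessed the product is `excluded_missing_data`; otherwise the count of
#' noncompliant applicable guidelines maps 0 to `compliant_all`, 1 to
#' `noncompliant_one`, and 2 or more to `noncompliant_two_or_more`.
#'
#' @param results List of guideline results (as from the `eval_g*` functions)
#'   for the applicable guidelines.
#' @return One of the four category strings.
#' @export
classify <- function(results) {
  applicable <- results[vapply(results, `[[`, logical(1), "applicable")]
  assessable <- vapply(applicable, function(r) isTRUE(r$assessable), logical(1))
  if (!all(assessable)) return("excluded_missing_data")
  n_bad <- sum(!vapply(applicable, `[[`, logical(1), "compliant"))
  if (n_bad == 0) "compliant_all"
  else if (n_bad == 1) "noncompliant_one"
  else "noncompliant_two_or_more"
}

#' Evaluate all applicable guidelines for one product
#'
#' @param seg A `segmented_trace`.
#' @param thresholds A [guideline_thresholds()].
#' @return A one-row tibble in the compliance-record schema (see
#'   [assess_cohort()]).
#' @export
assess_product <- function(seg, thresholds = guideline_thresholds()) {
  stopifnot(inherits(seg, "segmented_trace"))
  eligible <- clean_temperatures(seg, thresholds)
  transfused <- seg$disposition == "transfused"
  returned <- seg$disposition == "returned"

  with_completeness <- function(res) {
    # an evaluator may find its inputs formally present while the
    # completeness rules (gaps, plausibility) still veto assessment
    comp <- assess_completeness(seg, res$guideline_id, thresholds)
    if (isTRUE(res$assessable) && !comp$assessable) {
      res$assessable <- FALSE
      res$compliant <- NA
      res$evidence <- list()
    }
    res
  }
  g1 <- with_completeness(eval_g1(eligible, thresholds))
  g2 <- if (transfused) with_completeness(eval_g2(seg, thresholds)) else
    guideline_result(2L, FALSE)
  g3 <- if (transfused) with_completeness(eval_g3(seg, eligible, thresholds)) else
    guideline_result(3L, FALSE)
  g4 <- if (returned) with_completeness(eval_g4(seg, thresholds)) else
    guideline_result(4L, FALSE)

  ev <- function(res, field) {
    v <- res$evidence[[field]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  breach <- g3$evidence[["breach_time"]]
  tibble::tibble(
    product_id = seg$product_id,
    disposition = seg$disposition,
    category = classify(list(g1, g2, g3, g4)),
    g1_applicable = g1$applicable, g1_assessable = isTRUE(g1$assessable),
    g1_compliant = if (isTRUE(g1$assessable)) g1$compliant else NA,
    g1_min_c = ev(g1, "min_temp_c"), g1_max_c = ev(g1, "max_temp_c"),
    g2_applicable = g2$applicable, g2_assessable = isTRUE(g2$assessable),
    g2_compliant = if (isTRUE(g2$assessable)) g2$compliant else NA,
    g2_hours_outside_cooling = ev(g2, "hours_outside_cooling"),
    g3_applicable = g3$applicable, g3_assessable = isTRUE(g3$assessable),
    g3_compliant = if (isTRUE(g3$assessable)) g3$compliant else NA,
    g3_min_c = ev(g3, "min_temp_c"), g3_max_c = ev(g3, "max_temp_c"),
    g3_breach_time = if (is.null(breach)) as.POSIXct(NA, tz = "UTC") else breach,
    g3_hours_to_transfusion = ev(g3, "hours_to_transfusion"),
    g4_applicable = g4$applicable, g4_assessable = isTRUE(g4$assessable),
    g4_compliant = if (isTRUE(g4$assessable)) g4$compliant else NA,
    g4_hours_to_return = ev(g4, "hours_to_return")
  )
}

#' Run the full audit pipeline over a cohort
#'
#' Builds traces from the event stream, segments them, applies the inclusion
#' rules, and evaluates and classifies every included product.
#'
#' @param events Event tibble (see [read_events()]).
#' @param facility A [facility_map()].
#' @param thresholds A [guideline_thresholds()].
#' @return A list with `records` (compliance records of included products,
#'   one row each), `inclusion` (every product's inclusion decision),
#'   `assessability` (per product x guideline), `traces` and `segmented`
#'   (the intermediate objects, keyed by product id).
#' @export
assess_cohort <- function(events, facility = default_facility(),
                          thresholds = guideline_thresholds()) {
  traces <- build_traces(events, facility)
  segmented <- lapply(traces, function(tr) {
    if (nrow(tr$readings) == 0) NULL else segment_trace(tr, facility)
  })
  inclusion <- apply_inclusion_rules(traces, segmented, thresholds)
  keep <- inclusion$decisions$included
  records <- dplyr::bind_rows(lapply(segmented[keep], assess_product,
                                     thresholds = thresholds))
  assessability <- assessability_report(segmented[keep], thresholds)
  list(records = records, inclusion = inclusion$decisions,
       assessability = assessability, traces = traces, segmented = segmented)
}

# Results I/O ----------------------------------------------------------------

record_to_json_list <- function(row) {
  num <- function(x) if (is.na(x)) NULL else as.numeric(x)
  lgl <- function(x) if (is.na(x)) NULL else as.logical(x)
  tim <- function(x) if (is.na(x)) NULL else format_timestamps(x)
  list(
    product_id = row$product_id,
    disposition = row$disposition,
    category = row$category,
    guidelines = list(
      g1 = list(applicable = row$g1_applicable, assessable = row$g1_assessable,
                compliant = lgl(row$g1_compliant),
                evidence = list(min_temp_c = num(row$g1_min_c),
                                max_temp_c = num(row$g1_max_c))),
      g2 = list(applicable = row$g2_applicable, assessable = row$g2_assessable,
                compliant = lgl(row$g2_compliant),
                evidence = list(hours_outside_cooling = num(row$g2_hours_outside_cooling))),
      g3 = list(applicable = row$g3_applicable, assessable = row$g3_assessable,
                compliant = lgl(row$g3_compliant),
                evidence = list(min_temp_c = num(row$g3_min_c),
                                max_temp_c = num(row$g3_max_c),
                                breach_time = tim(row$g3_breach_time),
                                hours_to_transfusion = num(row$g3_hours_to_transfusion))),
      g4 = list(applicable = row$g4_applicable, assessable = row$g4_assessable,
                compliant = lgl(row$g4_compliant),
                evidence = list(hours_to_return = num(row$g4_hours_to_return)))
    )
  )
}

#' Write compliance records as JSON lines
#'
#' One JSON object per product, with nested per-guideline verdicts and
#' evidence; re-readable with [read_results()].
#'
#' @param records Compliance-record tibble (see [assess_cohort()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(records) > 0) {
    for (i in seq_len(nrow(records))) {
      line <- jsonlite::toJSON(record_to_json_list(records[i, , drop = FALSE]),
                               auto_unbox = TRUE, null = "null", digits = NA)
      writeLines(line, con)
    }
  }
  invisible(path)
}

#' Read compliance records from JSON lines
#'
#' @param path Path written by [write_results()].
#' @return A compliance-record tibble.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(dplyr::bind_rows(list()))
  }
  rows <- lapply(lines, function(line) {
    x <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    g <- x$guidelines
    pick_n <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
    pick_l <- function(v) if (is.null(v)) NA else as.logical(v)
    pick_t <- function(v) {
      if (is.null(v)) as.POSIXct(NA, tz = "UTC") else parse_timestamps(v)
    }
    tibble::tibble(
      product_id = x$product_id, disposition = x$disposition,
      category = x$category,
      g1_applicable = g$g1$applicable, g1_assessable = g$g1$assessable,
      g1_compliant = pick_l(g$g1$compliant),
      g1_min_c = pick_n(g$g1$evidence$min_temp_c),
      g1_max_c = pick_n(g$g1$evidence$max_temp_c),
      g2_applicable = g$g2$applicable, g2_assessable = g$g2$assessable,
      g2_compliant = pick_l(g$g2$compliant),
      g2_hours_outside_cooling = pick_n(g$g2$evidence$hours_outside_cooling),
      g3_applicable = g$g3$applicable, g3_assessable = g$g3$assessable,
      g3_compliant = pick_l(g$g3$compliant),
      g3_min_c = pick_n(g$g3$evidence$min_temp_c),
      g3_max_c = pick_n(g$g3$evidence$max_temp_c),
      g3_breach_time = pick_t(g$g3$evidence$breach_time),
      g3_hours_to_transfusion = pick_n(g$g3$evidence$hours_to_transfusion),
      g4_applicable = g$g4$applicable, g4_assessable = g$g4$assessable,
      g4_compliant = pick_l(g$g4$compliant),
      g4_hours_to_return = pick_n(g$g4$evidence$hours_to_return)
    )
  })
  dplyr::bind_rows(rows)
}
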