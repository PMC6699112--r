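# Data-quality rules: dataset inclusion, temperature eligibility, and
# per-guideline assessability.

# Per-phase reading coverage: for each phase, the number of readings and the
# largest gap (minutes) between consecutive readings within any one segment,
# counting the stretch from a segment boundary to its nearest reading.
phase_coverage <- function(seg) {
  s <- seg$segments
  rd <- seg$readings
  out <- lapply(unique(s$phase), function(ph) {
    idx <- which(s$phase == ph)
    max_gap <- 0
    n_reads <- 0L
    for (i in idx) {
      t_r <- sort(rd$timestamp[rd$segment == i])
      n_reads <- n_reads + length(t_r)
      bounds <- c(as.numeric(s$start_time[i]), as.numeric(t_r),
                  as.numeric(s$end_time[i]))
      max_gap <- max(max_gap, max(diff(bounds)) / 60)
    }
    tibble::tibble(phase = ph, n_readings = n_reads, max_gap_min = max_gap)
  })
  dplyr::bind_rows(out)
}

# A phase is usable when it holds at least one reading and no within-segment
# gap exceeds the limit.
usable_phases <- function(seg, gap_limit_min) {
  cov <- phase_coverage(seg)
  cov$phase[cov$n_readings > 0 & cov$max_gap_min <= gap_limit_min]
}

#' Apply the dataset inclusion rules
#'
#' A product's dataset enters the analysis cohort unless (in this precedence
#' order) the product never left the BTL, was lost after leaving it, was
#' transfused where the stop box sits inside the storage room so storage and
#' transfusion data cannot be separated, or no sub-dataset (phase) retains a
#' usable reading series.
#'
#' @param traces List of `product_trace` objects.
#' @param segmented List of matching `segmented_trace` objects (same order).
#' @param thresholds A [guideline_thresholds()]; supplies the reading-gap
#'   limit.
#' @return A list with `included` (character vector of product ids) and
#'   `decisions` (tibble: `product_id`, `included`, `exclusion_reason`).
#' @export
apply_inclusion_rules <- function(traces, segmented,
                                  thresholds = guideline_thresholds()) {
  decisions <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    seg <- segmented[[i]]
    reason <- if (tr$disposition == "never_left") {
      "never_left_btl"
    } else if (tr$disposition == "lost") {
      "lost_after_btl"
    } else if (!is.null(seg) && !seg$separable) {
      "unseparable_icu"
    } else if (is.null(seg) ||
                 length(usable_phases(seg, thresholds$gap_limit_min)) == 0) {
      # a trace with no readings at all cannot be segmented, let alone used
      "incomplete_all_subsets"
    } else {
      "none"
    }
    tibble::tibble(product_id = tr$product_id, included = reason == "none",
                   exclusion_reason = reason)
  })
  decisions <- dplyr::bind_rows(decisions)
  list(included = decisions$product_id[decisions$included],
       decisions = decisions)
}

#' Select the temperature readings eligible for guideline evaluation
#'
#' Applies the temperature data-quality criteria: readings taken within the
#' first `min_allocation_hours` after tag activation are dropped (the tag is
#' still equilibrating from handling temperature), and transfusion-phase
#' readings are dropped (products are deliberately warmed just before
#' transfusion).  What remains - storage and transport readings from an
#' equilibrated tag - is what guidelines 1 and 3 are scored on.
#'
#' @param seg A `segmented_trace`.
#' @param thresholds A [guideline_thresholds()].
#' @return A tibble of eligible readings (possibly empty).
#' @export
clean_temperatures <- function(seg, thresholds = guideline_thresholds()) {
  stopifnot(inherits(seg, "segmented_trace"))
  rd <- seg$readings
  keep <- rd$phase %in% c("storage", "transport") &
    rd$timestamp > seg$activation_time + thresholds$min_allocation_hours * 3600 &
    !is.na(rd$temperature_c)
  rd[keep, , drop = FALSE]
}

#' Assess whether a guideline can be evaluated on a product's data
#'
#' A guideline is assessable when every boundary timestamp it needs exists and
#' the reading series it relies on has no gap beyond the limit:
#'
#' * guideline 1 - at least one eligible reading, and no storage/transport
#'   gap beyond `gap_limit_min`;
#' * guideline 2 - cooling-exit and transfusion timestamps present, and the
#'   interval between them plausible (a stop-box drop days after cooling exit
#'   is a registration failure, not a transfusion time);
#' * guideline 3 - transfusion timestamp present and plausible, plus the
#'   guideline-1 reading-series requirements (breaches must be detectable);
#' * guideline 4 - BTL departure and return timestamps present.
#'
#' @param seg A `segmented_trace`.
#' @param guideline_id Integer 1-4.
#' @param thresholds A [guideline_thresholds()].
#' @return A list with `assessable` (flag) and `cause` (`"ok"` or the missing
#'   ingredient).
#' @export
assess_completeness <- function(seg, guideline_id,
                                thresholds = guideline_thresholds()) {
  stopifnot(inherits(seg, "segmented_trace"))
  if (!guideline_id %in% 1:4) {
    stop("unknown guideline id: ", guideline_id, call. = FALSE)
  }
  eligible_ok <- function() {
    elig <- clean_temperatures(seg, thresholds)
    if (nrow(elig) == 0) return("no_eligible_readings")
    cov <- phase_coverage(seg)
    cov <- cov[cov$phase %in% c("storage", "transport"), , drop = FALSE]
    if (any(cov$max_gap_min > thresholds$gap_limit_min)) return("reading_gap")
    "ok"
  }
  transfusion_ok <- function() {
    if (is.na(seg$transfusion_time)) return("missing_transfusion_time")
    if (is.na(seg$cooling_exit_time)) return("missing_cooling_exit")
    hours <- as.numeric(difftime(seg$transfusion_time, seg$cooling_exit_time,
                                 units = "hours"))
    if (hours < 0) return("transfusion_before_cooling_exit")
    if (hours > thresholds$max_plausible_transfusion_hours) {
      return("implausible_transfusion_delay")
    }
    "ok"
  }
  cause <- switch(as.character(guideline_id),
    "1" = eligible_ok(),
    "2" = transfusion_ok(),
    "3" = {
      c1 <- transfusion_ok()
      if (c1 != "ok") c1 else eligible_ok()
    },
    "4" = {
      if (is.na(seg$btl_departure_time)) "missing_departure"
      else if (is.na(seg$return_time)) "missing_return_registration"
      else "ok"
    }
  )
  list(assessable = cause == "ok", cause = cause)
}

#' Per-product, per-guideline assessability report
#'
#' Which guidelines apply to a product follows its disposition (guideline 1
#' always; 2 and 3 only for transfused products; 4 only for returned ones);
#' whether an applicable guideline can actually be evaluated follows
#' [assess_completeness()].
#'
#' @param segmented List of `segmented_trace` objects.
#' @param thresholds A [guideline_thresholds()].
#' @return A tibble with one row per product x guideline: `product_id`,
#'   `guideline_id`, `applicable`, `assessable`, `cause`.
#' @export
assessability_report <- function(segmented, thresholds = guideline_thresholds()) {
  rows <- lapply(segmented, function(seg) {
    applicable <- c(TRUE,
                    seg$disposition == "transfused",
                    seg$disposition == "transfused",
                    seg$disposition == "returned")
    res <- lapply(1:4, function(g) {
      if (!applicable[g]) {
        list(assessable = NA, cause = "not_applicable")
      } else {
        assess_completeness(seg, g, thresholds)
      }
    })
    tibble::tibble(
      product_id = seg$product_id,
      guideline_id = 1:4,
      applicable = applicable,
      assessable = vapply(res, `[[`, logical(1), "assessable"),
      cause = vapply(res, `[[`, character(1), "cause")
    )
  })
  dplyr::bind_rows(rows)
}
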