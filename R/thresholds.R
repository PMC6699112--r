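#' Guideline thresholds
#'
#' Bundles the numeric constraints behind the four intrahospital guidelines on
#' storage, transport and distribution of red-cell concentrates, together with
#' the data-quality constants used when applying them to tag telemetry.
#'
#' The four guidelines are: (1) products must be kept between `storage_lo_c`
#' and `storage_hi_c`; (2) transfusion must happen within
#' `transfusion_max_hours` of leaving a validated cooling system; (3) a product
#' whose recorded temperature reaches `breach_noncompliant_c` must be
#' transfused within `breach_transfuse_within_hours`; (4) unused products must
#' be back at the blood transfusion laboratory within `return_within_hours` of
#' leaving it.
#'
#' Because the tag sensor reads slightly high, recorded values are judged
#' against the storage window widened by `tolerance_c` on both sides
#' (so 1.5-6.5 degC by default), and a recorded value of
#' `breach_noncompliant_c` (11 degC) scores as a breach of the 10 degC limit.
#' Readings taken within `min_allocation_hours` of tag activation are ignored
#' (the tag is still equilibrating from room temperature).
#'
#' @param storage_lo_c,storage_hi_c Storage window, degrees Celsius.
#' @param tolerance_c Sensor allowance added to each side of the window.
#' @param breach_c Temperature limit above which a product may not be restored.
#' @param breach_noncompliant_c Recorded value treated as evidence of a breach.
#' @param transfusion_max_hours Allowed hours outside validated cooling before
#'   transfusion.
#' @param breach_transfuse_within_hours Allowed hours between a breach and
#'   transfusion.
#' @param return_within_hours Allowed hours between leaving and re-entering the
#'   blood transfusion laboratory for unused products.
#' @param min_allocation_hours Readings earlier than this after activation are
#'   not eligible.
#' @param gap_limit_min Largest tolerated gap (minutes) between consecutive
#'   readings within a segment before the segment counts as incomplete; three
#'   missed 8-minute samples by default.
#' @param max_plausible_transfusion_hours Cooling-exit to stop-box intervals
#'   longer than this are treated as registration failures (late stop-box
#'   drops), not real transfusion times.
#' @param g3_anchor Whether the 24-hour window of guideline 3 is measured from
#'   the first recorded breach (`"breach"`, default) or from departure from the
#'   blood transfusion laboratory (`"departure"`).
#'
#' @return An object of class `guideline_thresholds` (a named list with the
#'   derived `compliant_lo_c` / `compliant_hi_c` window).
#' @export
#' @examples
#' th <- guideline_thresholds()
#' c(th$compliant_lo_c, th$compliant_hi_c)
guideline_thresholds <- function(storage_lo_c = 2.0,
                                 storage_hi_c = 6.0,
                                 tolerance_c = 0.5,
                                 breach_c = 10.0,
                                 breach_noncompliant_c = 11.0,
                                 transfusion_max_hours = 1.0,
                                 breach_transfuse_within_hours = 24.0,
                                 return_within_hours = 24.0,
                                 min_allocation_hours = 1.0,
                                 gap_limit_min = 24.0,
                                 max_plausible_transfusion_hours = 24.0,
                                 g3_anchor = c("breach", "departure")) {
  g3_anchor <- match.arg(g3_anchor)
  if (!(storage_lo_c < storage_hi_c)) {
    stop("storage_lo_c must be below storage_hi_c", call. = FALSE)
  }
  if (!(breach_c > storage_hi_c)) {
    stop("breach_c must exceed storage_hi_c", call. = FALSE)
  }
  durations <- c(transfusion_max_hours, breach_transfuse_within_hours,
                 return_within_hours, min_allocation_hours, gap_limit_min,
                 max_plausible_transfusion_hours)
  if (any(!is.finite(durations)) || any(durations <= 0)) {
    stop("all duration thresholds must be positive", call. = FALSE)
  }
  out <- list(
    storage_lo_c = storage_lo_c,
    storage_hi_c = storage_hi_c,
    tolerance_c = tolerance_c,
    breach_c = breach_c,
    breach_noncompliant_c = breach_noncompliant_c,
    transfusion_max_hours = transfusion_max_hours,
    breach_transfuse_within_hours = breach_transfuse_within_hours,
    return_within_hours = return_within_hours,
    min_allocation_hours = min_allocation_hours,
    gap_limit_min = gap_limit_min,
    max_plausible_transfusion_hours = max_plausible_transfusion_hours,
    g3_anchor = g3_anchor,
    compliant_lo_c = storage_lo_c - tolerance_c,
    compliant_hi_c = storage_hi_c + tolerance_c
  )
  structure(out, class = "guideline_thresholds")
}

#' Read guideline thresholds from a YAML or JSON file
#'
#' The file holds any subset of the arguments of [guideline_thresholds()];
#' missing fields take their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `guideline_thresholds` object.
#' @export
read_thresholds <- function(path) {
  vals <- read_config_file(path)
  known <- names(formals(guideline_thresholds))
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0) {
    stop("unknown threshold field(s): ", paste(extra, collapse = ", "), call. = FALSE)
  }
  do.call(guideline_thresholds, vals)
}

# Shared YAML/JSON loader (extension-dispatched).
read_config_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: .", ext, " (use YAML or JSON)", call. = FALSE)
  }
}

#' @export
print.guideline_thresholds <- function(x, ...) {
  cat("Guideline thresholds\n")
  cat(sprintf("  storage window: %.1f-%.1f degC (compliant recorded: %.1f-%.1f)\n",
              x$storage_lo_c, x$storage_hi_c, x$compliant_lo_c, x$compliant_hi_c))
  cat(sprintf("  breach: > %.1f degC (recorded >= %.1f); transfuse within %g h of breach\n",
              x$breach_c, x$breach_noncompliant_c, x$breach_transfuse_within_hours))
  cat(sprintf("  transfuse within %g h of cooling exit; return within %g h\n",
              x$transfusion_max_hours, x$return_within_hours))
  invisible(x)
}
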