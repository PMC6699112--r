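# Summary outputs: the category table, per-group statistics, and histogram
# exports.

#' Percentage rounded half-up to one decimal
#'
#' @param numerator,denominator Counts; the denominator must be positive.
#' @return `100 * numerator / denominator`, rounded half-up to one decimal.
#' @export
#' @examples
#' percent_round(4, 182) # 2.2
percent_round <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive", call. = FALSE)
  floor(1000 * numerator / denominator + 0.5) / 10
}

#' Mean / min / max summary of a group of values
#'
#' @param values Non-empty numeric vector (degC or hours, as appropriate).
#' @return A one-row tibble: `n`, `mean`, `min`, `max`.
#' @export
summarize_group <- function(values) {
  if (length(values) == 0) stop("cannot summarize an empty group", call. = FALSE)
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  tibble::tibble(n = length(values), mean = mean(values),
                 min = min(values), max = max(values))
}

#' Category table over a classified cohort
#'
#' Counts and half-up one-decimal percentages of the four decision-tree
#' categories; the denominator is the cohort size.
#'
#' @param records Compliance-record tibble (see [assess_cohort()]).
#' @return A tibble with `category`, `n`, `pct`, plus a `denominator`
#'   attribute.
#' @export
category_table <- function(records) {
  n_total <- nrow(records)
  counts <- unname(vapply(CATEGORIES, function(cat) sum(records$category == cat),
                          integer(1)))
  out <- tibble::tibble(
    category = CATEGORIES,
    n = as.integer(counts),
    pct = if (n_total > 0) percent_round(counts, n_total) else rep(0, 4)
  )
  attr(out, "denominator") <- n_total
  out
}

# Left-closed binned counts of a numeric vector.
bin_counts <- function(values, width) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    return(tibble::tibble(bin_lo = numeric(), bin_hi = numeric(),
                          count = integer()))
  }
  lo <- floor(values / width) * width
  tab <- table(lo)
  bin_lo <- as.numeric(names(tab))
  tibble::tibble(bin_lo = bin_lo, bin_hi = bin_lo + width,
                 count = as.integer(tab))
}

#' Export evidence distributions as histogram CSVs
#'
#' Writes binned counts, per disposition group, of the minimum and maximum
#' eligible temperatures (guidelines 1/3 evidence), the hours outside
#' validated cooling before transfusion (guideline 2), and the hours until
#' return to the BTL (guideline 4).
#'
#' @param records Compliance-record tibble.
#' @param out_dir Output directory (created if missing).
#' @param temp_bin_c,time_bin_h Bin widths (0.5 degC and 1 h by default).
#' @return Invisibly, a named list of the histogram tibbles (also written as
#'   `hist_*.csv`).
#' @export
export_distributions <- function(records, out_dir, temp_bin_c = 0.5,
                                 time_bin_h = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  by_group <- function(field, width) {
    parts <- lapply(split(records, records$disposition), function(grp) {
      out <- bin_counts(grp[[field]], width)
      if (nrow(out) > 0) out$group <- grp$disposition[1]
      out
    })
    dplyr::bind_rows(parts)
  }
  hists <- list(
    min_temp = by_group("g1_min_c", temp_bin_c),
    max_temp = by_group("g1_max_c", temp_bin_c),
    hours_outside_cooling = by_group("g2_hours_outside_cooling", time_bin_h),
    hours_to_return = by_group("g4_hours_to_return", time_bin_h)
  )
  for (name in names(hists)) {
    utils::write.csv(hists[[name]],
                     file.path(out_dir, paste0("hist_", name, ".csv")),
                     row.names = FALSE)
  }
  invisible(hists)
}

#' Build compliance records from per-disposition verdict patterns
#'
#' Expands a table of verdict patterns into individual compliance records and
#' classifies each with the decision tree.  This is how published cohort
#' tallies (so many returned products compliant to guideline 1 but not 4, and
#' so on) are encoded for cross-tabulation: each row gives a disposition, the
#' four per-guideline verdicts (`TRUE`/`FALSE`; `NA` means the guideline was
#' applicable but not assessable; guidelines that do not apply to the
#' disposition are ignored), and how many products share that pattern.
#'
#' @param patterns A data frame with columns `disposition`, `g1`, `g2`, `g3`,
#'   `g4` (logical) and `n` (count).
#' @return A compliance-record tibble with one row per product.
#' @export
#' @examples
#' records_from_verdicts(tibble::tibble(
#'   disposition = "returned", g1 = TRUE, g2 = NA, g3 = NA, g4 = TRUE, n = 4
#' ))
records_from_verdicts <- function(patterns) {
  patterns <- tibble::as_tibble(patterns)
  rows <- vector("list", nrow(patterns))
  counter <- 0L
  for (i in seq_len(nrow(patterns))) {
    p <- patterns[i, ]
    transfused <- p$disposition == "transfused"
    returned <- p$disposition == "returned"
    mk <- function(id, applicable, verdict) {
      guideline_result(id, applicable,
                       assessable = if (applicable) !is.na(verdict) else NA,
                       compliant = if (applicable && !is.na(verdict)) verdict else NA)
    }
    results <- list(mk(1L, TRUE, p$g1),
                    mk(2L, transfused, p$g2),
                    mk(3L, transfused, p$g3),
                    mk(4L, returned, p$g4))
    category <- classify(results)
    idx <- counter + seq_len(p$n)
    counter <- counter + p$n
    rows[[i]] <- tibble::tibble(
      product_id = sprintf("F%04d", idx),
      disposition = p$disposition,
      category = category,
      g1_applicable = TRUE, g1_assessable = !is.na(p$g1), g1_compliant = p$g1,
      g2_applicable = transfused,
      g2_assessable = if (transfused) !is.na(p$g2) else FALSE,
      g2_compliant = if (transfused) p$g2 else NA,
      g3_applicable = transfused,
      g3_assessable = if (transfused) !is.na(p$g3) else FALSE,
      g3_compliant = if (transfused) p$g3 else NA,
      g4_applicable = returned,
      g4_assessable = if (returned) !is.na(p$g4) else FALSE,
      g4_compliant = if (returned) p$g4 else NA
    )
  }
  dplyr::bind_rows(rows)
}
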