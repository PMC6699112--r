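segment_all <- function(traces, fac) {
  lapply(traces, function(tr) {
    if (nrow(tr$readings) == 0) NULL else segment_trace(tr, fac)
  })
}

test_that("the study's fate tallies reproduce its inclusion count", {
  cfg <- paper_cohort_config(seed = 3, dropout_p = 0)
  sim <- simulate_cohort(cfg)
  traces <- build_traces(sim$events, cfg$facility)
  segmented <- segment_all(traces, cfg$facility)
  inc <- apply_inclusion_rules(traces, segmented, cfg$thresholds)
  tab <- table(inc$decisions$exclusion_reason)
  expect_equal(length(inc$included), 182)
  expect_equal(as.integer(tab[["never_left_btl"]]), 7)
  expect_equal(as.integer(tab[["lost_after_btl"]]), 13)
  expect_equal(as.integer(tab[["unseparable_icu"]]), 40)
  expect_equal(as.integer(tab[["incomplete_all_subsets"]]), 1)
  expect_equal(percent_round(length(inc$included), cfg$n_products), 74.9)
})

test_that("an all-complete cohort has zero exclusions and reasons partition", {
  fac <- default_facility()
  events <- ev_bind(or_journey_events("T1", "P1"),
                    return_journey_events("T2", "P2"))
  traces <- build_traces(events, fac)
  segmented <- segment_all(traces, fac)
  inc <- apply_inclusion_rules(traces, segmented)
  expect_setequal(inc$included, c("P1", "P2"))
  expect_true(all(inc$decisions$included == (inc$decisions$exclusion_reason == "none")))
})

test_that("exclusion reasons follow the precedence order", {
  fac <- default_facility()
  # unseparable AND all-subsets-incomplete: the earlier reason wins
  ev <- icu_unseparable_events()
  thin <- ev[ev$event_type != "reading" | ev$timestamp <= mk_time(16), ]
  traces <- build_traces(thin, fac)
  inc <- apply_inclusion_rules(traces, segment_all(traces, fac))
  expect_equal(inc$decisions$exclusion_reason, "unseparable_icu")

  # never-left trumps incompleteness too
  ev2 <- never_left_events()
  thin2 <- ev2[ev2$event_type != "reading" | ev2$timestamp <= mk_time(16), ]
  traces2 <- build_traces(thin2, fac)
  inc2 <- apply_inclusion_rules(traces2, segment_all(traces2, fac))
  expect_equal(inc2$decisions$exclusion_reason, "never_left_btl")
})

test_that("a product with no usable phase is excluded as incomplete", {
  fac <- default_facility()
  ev <- return_journey_events()
  thin <- ev[ev$event_type != "reading" | ev$timestamp <= mk_time(16), ]
  traces <- build_traces(thin, fac)
  inc <- apply_inclusion_rules(traces, segment_all(traces, fac))
  expect_equal(inc$decisions$exclusion_reason, "incomplete_all_subsets")
})

test_that("temperature cleaning drops early and transfusion-phase readings", {
  seg <- one_segmented(or_journey_events())
  elig <- clean_temperatures(seg)
  # nothing within the first hour after activation
  expect_true(all(elig$timestamp > mk_time(60)))
  # the 30-minute reading is excluded
  expect_false(mk_time(32) %in% elig$timestamp)
  # theatre (transfusion-phase) warm-up readings are excluded
  expect_true(all(elig$phase %in% c("storage", "transport")))
  expect_equal(max(elig$temperature_c), 8.0) # corridor, not the 15.0 theatre value
})

test_that("a trace with no post-allocation readings is unassessable for guideline 1", {
  fac <- default_facility()
  ev <- ev_bind(
    ev_row(0, "btl", "activation"),
    ev_row(c(8, 16, 24), "btl", "reading", 4.5),
    ev_row(40, "btl", "deactivation")
  )
  seg <- segment_trace(one_trace(ev, fac), fac)
  expect_equal(nrow(clean_temperatures(seg)), 0)
  comp <- assess_completeness(seg, 1)
  expect_false(comp$assessable)
  expect_equal(comp$cause, "no_eligible_readings")
})

test_that("guideline assessability needs its boundary timestamps", {
  fac <- default_facility()
  # unregistered return: G4 unassessable, G1 untouched
  ev <- return_journey_events()
  ev <- ev[ev$event_type != "deactivation", ]
  seg <- segment_trace(one_trace(ev, fac), fac)
  g4 <- assess_completeness(seg, 4)
  expect_false(g4$assessable)
  expect_equal(g4$cause, "missing_return_registration")
  expect_true(assess_completeness(seg, 1)$assessable)

  # a stop-box drop days after cooling exit is not a plausible transfusion time
  late <- or_journey_events()
  late$timestamp[late$event_type == "stopbox_drop"] <-
    late$timestamp[late$event_type == "stopbox_drop"] + 5 * 86400
  seg_late <- segment_trace(one_trace(late, fac), fac)
  g2 <- assess_completeness(seg_late, 2)
  expect_false(g2$assessable)
  expect_equal(g2$cause, "implausible_transfusion_delay")
  expect_false(assess_completeness(seg_late, 3)$assessable)

  expect_error(assess_completeness(seg, 7), "unknown guideline")
})

test_that("adding readings back never flips a guideline to unassessable", {
  fac <- default_facility()
  th <- guideline_thresholds()
  set.seed(31)
  for (rep in 1:8) {
    ev <- if (rep %% 2 == 0) or_journey_events() else return_journey_events()
    is_reading <- which(ev$event_type == "reading")
    drop <- sample(is_reading, size = floor(length(is_reading) * runif(1, 0.2, 0.8)))
    thin <- ev[-drop, ]
    seg_full <- segment_trace(one_trace(ev, fac), fac)
    seg_thin <- segment_trace(one_trace(thin, fac), fac)
    for (g in 1:4) {
      thin_ok <- assess_completeness(seg_thin, g, th)$assessable
      full_ok <- assess_completeness(seg_full, g, th)$assessable
      expect_false(thin_ok && !full_ok)
    }
  }
})

test_that("missing-data products on the study mix are about 15 of 182", {
  cfg <- paper_cohort_config(seed = 17)
  sim <- simulate_cohort(cfg)
  res <- assess_cohort(sim$events, cfg$facility, cfg$thresholds)
  n_excluded <- sum(res$records$category == "excluded_missing_data")
  # expectation 15 (3 late stop-box drops + 12 unregistered returns);
  # allow ~4 binomial standard deviations
  expect_true(abs(n_excluded - 15) <= 4 * sqrt(15))
})
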