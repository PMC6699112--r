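test_that("a trace that stayed in the laboratory is one storage segment", {
  seg <- one_segmented(never_left_events())
  expect_equal(nrow(seg$segments), 1)
  expect_equal(seg$segments$phase, "storage")
  expect_true(seg$separable)
  expect_true(is.na(seg$btl_departure_time))
  expect_true(is.na(seg$cooling_exit_time))
})

test_that("an operating-room journey splits into the four expected phases", {
  seg <- one_segmented(or_journey_events())
  expect_equal(seg$segments$phase,
               c("storage", "transport", "storage", "transfusion"))
  expect_equal(seg$segments$location_id,
               c("btl", "corridor", "or_storage", "or_theatre"))
  expect_equal(seg$segments$start_time, mk_time(c(0, 120, 130, 240)))
  expect_equal(seg$segments$end_time, mk_time(c(120, 130, 240, 330)))
  expect_equal(seg$btl_departure_time, mk_time(120))
  # latest validated-cooler exit wins: or_storage, not the BTL
  expect_equal(seg$cooling_exit_time, mk_time(240))
  expect_equal(cooling_exit_time(seg), mk_time(240))
  expect_equal(seg$transfusion_time, mk_time(330))
})

test_that("a stop box inside the ICU storage room makes the trace unseparable", {
  seg <- one_segmented(icu_unseparable_events())
  expect_false(seg$separable)
  expect_false("transfusion" %in% seg$segments$phase)
})

test_that("missing gateways fall back to midpoint boundaries", {
  fac <- default_facility()
  ev <- or_journey_events()
  ev <- ev[ev$event_type != "gateway_pass", ]
  seg <- segment_trace(one_trace(ev, fac), fac)
  # last btl reading 112, first corridor reading 124 -> boundary at 118
  expect_equal(seg$segments$end_time[1], mk_time(118))
  # corridor 124 -> or_storage 140: boundary at 132
  expect_equal(seg$segments$end_time[2], mk_time(132))
})

test_that("segmentation tiles the trace and assigns each reading once", {
  fac <- default_facility()
  for (ev in list(or_journey_events(), return_journey_events(),
                  icu_unseparable_events(), never_left_events())) {
    tr <- one_trace(ev, fac)
    seg <- segment_trace(tr, fac)
    total <- sum(as.numeric(seg$segments$end_time) -
                   as.numeric(seg$segments$start_time))
    span <- as.numeric(max(tr$events$timestamp)) -
      as.numeric(min(tr$events$timestamp))
    expect_equal(total, span)
    expect_equal(sum(seg$segments$n_readings), nrow(tr$readings))
    expect_true(all(diff(as.numeric(seg$segments$start_time)) > 0))
  }
})

test_that("segmentation is idempotent", {
  fac <- default_facility()
  tr <- one_trace(return_journey_events(), fac)
  s1 <- segment_trace(tr, fac)
  s2 <- segment_trace(tr, fac)
  expect_identical(s1$segments, s2$segments)
})

test_that("a trace without readings cannot be segmented", {
  fac <- default_facility()
  ev <- never_left_events()
  ev <- ev[ev$event_type != "reading", ]
  expect_error(segment_trace(one_trace(ev, fac), fac), "zero readings")
})

test_that("first breach is the earliest hot reading, whatever the row order", {
  th <- guideline_thresholds()
  rd <- tibble::tibble(timestamp = mk_time(c(10, 20, 30)),
                       temperature_c = c(4.0, 11.0, 12.5))
  expect_equal(first_breach_time(rd, th), mk_time(20))
  cool <- tibble::tibble(timestamp = mk_time(c(10, 20)),
                         temperature_c = c(4.0, 6.5))
  expect_true(is.na(first_breach_time(cool, th)))
  # permutation oracle: the answer only depends on the (time, temp) multiset
  set.seed(42)
  rd_big <- tibble::tibble(timestamp = mk_time(sample(1:200, 50)),
                           temperature_c = runif(50, 3, 14))
  ref <- first_breach_time(dplyr::arrange(rd_big, timestamp), th)
  for (i in 1:5) {
    perm <- rd_big[sample(nrow(rd_big)), ]
    expect_equal(first_breach_time(perm, th), ref)
  }
})

test_that("noiseless simulated boundaries match the true itinerary exactly", {
  cfg <- noiseless(simulation_config(
    n_products = 12, seed = 5, dropout_p = 0,
    template_mix = c(or_transfusion = 0.5, or_return = 0.5)))
  sim <- simulate_cohort(cfg)
  traces <- build_traces(sim$events, cfg$facility)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- traces[[sim$truth$product_id[i]]]
    seg <- segment_trace(tr, cfg$facility)
    itin <- sim$truth$itinerary[[i]]
    expect_equal(seg$segments$location_id, itin$location_id)
    expect_equal(as.numeric(seg$segments$start_time), as.numeric(itin$entry))
    # interior boundaries are gateway-anchored and exact; the final segment
    # ends at the terminal event
    n <- nrow(itin)
    expect_equal(as.numeric(seg$segments$end_time[-n]),
                 as.numeric(itin$exit[-n]))
  }
})
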