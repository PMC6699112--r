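test_that("identical configurations produce identical event streams", {
  cfg <- simulation_config(n_products = 30, seed = 99,
                           stopbox_misuse_p = 0.2,
                           return_registration_fail_p = 0.2)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$events, b$events)
  expect_identical(a$truth[setdiff(names(a$truth), "itinerary")],
                   b$truth[setdiff(names(b$truth), "itinerary")])
  c <- simulate_cohort(simulation_config(n_products = 30, seed = 100))
  expect_false(identical(a$events, c$events))
})

test_that("an empty cohort yields empty events and truth", {
  sim <- simulate_cohort(simulation_config(n_products = 0))
  expect_equal(nrow(sim$events), 0)
  expect_equal(nrow(sim$truth), 0)
})

test_that("a cohort of stay-at-home templates never leaves the laboratory", {
  cfg <- simulation_config(n_products = 15, seed = 4,
                           template_mix = c(never_left = 1))
  sim <- simulate_cohort(cfg)
  traces <- build_traces(sim$events, cfg$facility)
  disp <- vapply(traces, `[[`, character(1), "disposition")
  expect_true(all(disp == "never_left"))
})

test_that("template mixes must be valid probabilities", {
  expect_error(simulation_config(10, template_mix = c(never_left = 0.4)),
               "sum to 1")
  expect_error(simulation_config(10, template_mix = c(foo = 1)),
               "unknown template")
  expect_error(simulation_config(10, template_counts = c(never_left = 3)),
               "sum to n_products")
  expect_error(simulation_config(10, dropout_p = 1.5), "\\[0, 1\\]")
})

test_that("recorded temperatures settle at ambient plus bias within quantization", {
  cfg <- simulation_config(n_products = 10, seed = 21, dropout_p = 0,
                           template_mix = c(or_return = 1))
  sim <- simulate_cohort(cfg)
  th <- cfg$thermal
  for (i in seq_len(nrow(sim$truth))) {
    itin <- sim$truth$itinerary[[i]]
    hold <- itin[itin$location_id == "or_storage", ]
    ev <- sim$events[sim$events$product_id == sim$truth$product_id[i] &
                       sim$events$event_type == "reading", ]
    settled <- ev$temperature_c[ev$timestamp >= hold$entry + 2 * 3600 &
                                  ev$timestamp < hold$exit]
    expect_true(length(settled) > 0)
    expect_true(all(abs(settled - (4.0 + th$sensor_bias_c)) <=
                      th$quantization_c / 2 + 1e-9))
  }
})

test_that("exclusion counts on the study mix stay within binomial error", {
  cfg <- simulation_config(
    n_products = 243, seed = 8, dropout_p = 0,
    template_mix = c(never_left = 7, lost_in_transit = 13,
                     icu_transfusion_unseparable = 40, or_transfusion = 52,
                     or_return = 66, icu_return = 65) / 243,
    incomplete_p = 1 / 183)
  sim <- simulate_cohort(cfg)
  res <- assess_cohort(sim$events, cfg$facility, cfg$thresholds)
  tab <- table(factor(res$inclusion$exclusion_reason,
                      levels = c("never_left_btl", "lost_after_btl",
                                 "unseparable_icu", "incomplete_all_subsets",
                                 "none")))
  tol <- function(n, p) 4 * sqrt(243 * p * (1 - p)) # ~4 sd
  expect_true(abs(tab[["never_left_btl"]] - 7) <= tol(243, 7 / 243))
  expect_true(abs(tab[["lost_after_btl"]] - 13) <= tol(243, 13 / 243))
  expect_true(abs(tab[["unseparable_icu"]] - 40) <= tol(243, 40 / 243))
  expect_true(tab[["incomplete_all_subsets"]] <= 6)
})

test_that("missingness injection is the identity when switched off", {
  cfg <- noiseless(simulation_config(n_products = 8, seed = 13))
  sim <- simulate_cohort(cfg)
  out <- inject_missingness(sim$events, sim$truth, dropout_p = 0,
                            stopbox_misuse = NULL)
  expect_identical(dplyr::arrange(out$events, tag_id, timestamp),
                   dplyr::arrange(sim$events, tag_id, timestamp))
})

test_that("full dropout leaves only lifecycle events", {
  cfg <- noiseless(simulation_config(n_products = 8, seed = 13))
  sim <- simulate_cohort(cfg)
  set.seed(1)
  out <- inject_missingness(sim$events, sim$truth, dropout_p = 1)
  expect_true(all(out$events$event_type %in%
                    c("activation", "deactivation", "stopbox_drop")))
})

test_that("a pocketed tag shifts the apparent transfusion by days and fails QC", {
  cfg <- noiseless(simulation_config(n_products = 6, seed = 55,
                                     template_mix = c(or_transfusion = 1)))
  sim <- simulate_cohort(cfg)
  set.seed(2)
  out <- inject_missingness(sim$events, sim$truth, dropout_p = 0,
                            stopbox_misuse = list(misuse_p = 1,
                                                  delay_days = c(5, 5),
                                                  wrong_box_p = 0,
                                                  pocket_c = 30),
                            thermal = cfg$thermal, facility = cfg$facility)
  expect_true(all(out$truth$corrupted == "stopbox_misuse"))
  res <- assess_cohort(out$events, cfg$facility, cfg$thresholds)
  expect_true(all(res$records$category == "excluded_missing_data"))
  expect_false(any(res$records$g2_assessable))
  # the apparent transfusion time sits ~5 days after the true one
  seg <- res$segmented[[res$records$product_id[1]]]
  true_t <- out$truth$transfusion_time[out$truth$product_id == seg$product_id]
  shift_h <- as.numeric(difftime(seg$transfusion_time, true_t, units = "hours"))
  expect_equal(shift_h, 120, tolerance = 0.01)
  # pocket readings approach body-adjacent temperature
  pocket <- out$events[out$events$product_id == seg$product_id &
                         out$events$event_type == "reading" &
                         out$events$timestamp > true_t + 86400, ]
  expect_true(all(pocket$temperature_c > 25))
})

test_that("ground-truth verdicts are internally consistent with the decision tree", {
  cfg <- noiseless(simulation_config(n_products = 60, seed = 77))
  truth <- simulate_cohort(cfg)$truth
  ok <- truth$exclusion_reason == "none"
  for (i in which(ok)) {
    verdicts <- if (truth$disposition[i] == "transfused") {
      c(truth$g1_compliant[i], truth$g2_compliant[i], truth$g3_compliant[i])
    } else {
      c(truth$g1_compliant[i], truth$g4_compliant[i])
    }
    expected <- if (anyNA(verdicts)) "excluded_missing_data" else
      switch(as.character(sum(!verdicts)), "0" = "compliant_all",
             "1" = "noncompliant_one", "noncompliant_two_or_more")
    expect_equal(truth$category[i], expected)
  }
})
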