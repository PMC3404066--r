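test_that("house positivity ranges and cumulative follow the definitions", {
  # house A pupae-positive at survey 1 only; house B never positive
  vol <- rbind(A1 = c(50, 50, 50), B1 = c(50, 50, 50))
  pup <- rbind(A1 = c(3, 0, 0), B1 = c(0, 0, 0))
  ds <- make_dataset(vol, pup, households = c("HA", "HB"))
  ps <- positivity_summary(ds)
  hp <- ps[ps$stage == "pupae" & ps$unit == "house", ]
  expect_equal(hp$range_min, 0)
  expect_equal(hp$range_max, 50)
  expect_equal(hp$cumulative, 50)
  expect_equal(hp$always_negative, 50)
})

test_that("an all-negative dataset is 100% always-negative", {
  vol <- rbind(A = c(50, 50), B = c(40, 40))
  ps <- positivity_summary(make_dataset(vol))
  expect_true(all(ps$range_min == 0 & ps$range_max == 0))
  expect_true(all(ps$cumulative == 0))
  expect_true(all(ps$always_negative == 100))
  all_neg <- attr(ps, "all_stages_always_negative")
  expect_equal(unname(all_neg["container"]), 100)
})

test_that("cumulative and always-negative sum to 100 for every row", {
  ds <- make_fixture("study", seed = 2)
  ps <- positivity_summary(ds)
  expect_true(all(abs(ps$cumulative + ps$always_negative - 100) < 0.11))
  expect_true(all(ps$cumulative >= ps$range_max - 0.11))
})

test_that("adding a positive record never lowers cumulative positivity", {
  ds <- make_fixture("tiny", seed = 9)
  base <- positivity_summary(ds)
  wet_rows <- which(ds$records$wet & ds$records$pupae == 0)
  for (i in wet_rows[c(1, 5, 9)]) {
    ds2 <- ds
    ds2$records$pupae[i] <- 4L
    ps2 <- positivity_summary(ds2)
    expect_true(all(ps2$cumulative >= base$cumulative - 1e-9))
  }
})

test_that("mean pupae per house matches the survey arithmetic", {
  n_house <- 41
  vol <- matrix(50, n_house, 2,
                dimnames = list(sprintf("C%02d", 1:n_house), NULL))
  pup <- matrix(0L, n_house, 2, dimnames = dimnames(vol))
  pup[1, 1] <- 77L     # 77 pupae on day 1
  pup[1, 2] <- 517L    # 517 pupae on day 29
  ds <- make_dataset(vol, pup)
  expect_equal(mean_pupae_per_house(ds, 1), 1.9)
  expect_equal(mean_pupae_per_house(ds, 2), 12.6)
  pup[] <- 0L
  expect_equal(mean_pupae_per_house(make_dataset(vol, pup), 1), 0)
  expect_error(mean_pupae_per_house(ds, 99), "unknown survey")
})

test_that("fold changes reproduce the reported rises", {
  expect_equal(fold_change(12.6, 1.9), 6.6)
  expect_equal(fold_change(12.6, 5.6), 2.3)
  expect_equal(fold_change(4.2, 4.2), 1.0)
  expect_error(fold_change(1, 0), "undefined")
})

test_that("daily flux probability is events per container-day", {
  # 10 containers x 15 surveys; 7 containers get one +25 jump each
  vol <- matrix(50, 10, 15, dimnames = list(sprintf("C%02d", 1:10), NULL))
  for (i in 1:7) vol[i, (i + 1):15] <- 75
  ds <- make_dataset(vol, capacity = 2000)
  expect_equal(daily_flux_probability(ds, "large", "increase"),
               7 / (10 * 14 * 2))
  expect_equal(daily_flux_probability(ds, "large", "decrease"), 0)
  # the rate times the exposure recovers the integer event count
  p <- daily_flux_probability(ds, "large", "increase")
  expect_equal(p * 10 * 14 * 2, 7, tolerance = 1e-12)
  # geometric conversion is close at these magnitudes
  pg <- daily_flux_probability(ds, "large", "increase", method = "geometric")
  expect_lt(abs(pg - p), 0.005)
  expect_error(daily_flux_probability(ds, "small", "increase"), "no complete")
})

test_that("flux event tallies and the percent-fewer statistic", {
  vol <- rbind(A = c(50, 75, 50, 50))   # +25, -25, 0
  fc <- flux_event_counts(make_dataset(vol))
  expect_equal(unname(fc$total), c(1, 1, 1))
  # reported comparison of filling vs draw-down events
  expect_equal(pct_fewer(304, 410), 26)
  vol2 <- rbind(A = c(50, 50, 50), B = c(40, 40, 40))
  fc2 <- flux_event_counts(make_dataset(vol2))
  expect_equal(unname(fc2$total), c(0, 0, 4))
  expect_true(is.na(fc2$pct_fewer_filling))
  expect_error(pct_fewer(3, 0), "no draw-down")
})

test_that("wet fraction is the percentage of wet containers", {
  vol <- rbind(A = c(50, 50), B = c(30, 0), C = c(20, 0), D = c(10, 10))
  ds <- make_dataset(vol)
  expect_equal(wet_fraction(ds, 1), 100)
  expect_equal(wet_fraction(ds, 2), 50)
  expect_equal(wet_fraction(ds), c(100, 50))
  expect_error(wet_fraction(ds, 7), "unknown survey")
})

test_that("survey means table is internally consistent", {
  ds <- make_fixture("tiny", seed = 4)
  sm <- survey_means(ds)
  expect_equal(nrow(sm), ds$n_surveys)
  expect_equal(sm$day, 1 + 2 * (sm$survey_index - 1))
  k <- 2
  expect_equal(sm$total_pupae[k],
               sum(ds$records$pupae[ds$records$survey_index == k]))
})
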