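test_that("monthly aggregation counts unique patients, not events", {
  ev <- data.frame(
    patient_id = c("p1", "p1", "p1", "p2", "p1"),
    code = "401.9",
    date = as.Date(c("2001-03-02", "2001-03-15", "2001-03-28",
                     "2001-03-10", "2001-04-01")))
  mc <- aggregate_monthly(ev)
  # p1's three March visits count once; both patients in March, p1 in April
  expect_equal(unname(mc$values[1, ]), c(2L, 1L))
  expect_equal(format(mc$months, "%Y-%m"), c("2001-03", "2001-04"))
})

test_that("aggregation matches a brute-force oracle on a simulated fixture", {
  cfg <- sim_config(n_codes = 4, months = 30, start = "2000-01",
                    baseline_rates = 5, growth_rate = 0,
                    total_season_amplitude = 0, seed = 11)
  sim <- simulate_counts(cfg)
  mc <- aggregate_monthly(sim$events)
  expect_equal(mc$values, sim$counts$values)
  oracle <- brute_force_aggregate(sim$events, sim$counts$codes,
                                  sim$counts$months)
  expect_equal(mc$values, oracle)
  # invariant to event ordering and idempotent on deduplicated input
  shuf <- sim$events[sample(nrow(sim$events)), ]
  expect_equal(aggregate_monthly(shuf)$values, mc$values)
})

test_that("same-month repeat visits never inflate counts", {
  cfg <- sim_config(n_codes = 3, months = 30, start = "2000-01",
                    baseline_rates = 8, growth_rate = 0,
                    total_season_amplitude = 0,
                    extra_visit_prob = 0.5, seed = 12)
  sim <- simulate_counts(cfg)
  expect_gt(nrow(sim$events), sum(sim$counts$values))  # duplicates exist
  expect_equal(aggregate_monthly(sim$events)$values, sim$counts$values)
})

test_that("time axis is mid-month decimal years, evenly spaced", {
  ev <- data.frame(patient_id = "p", code = "x",
                   date = as.Date(c("1997-01-15", "1997-06-02")))
  mc <- aggregate_monthly(ev)
  expect_equal(mc$time_axis[1], 1997 + 0.5 / 12, tolerance = 1e-10)
  expect_equal(diff(mc$time_axis), rep(1 / 12, 5), tolerance = 1 / 365)
})

test_that("malformed input is rejected with informative errors", {
  bad <- data.frame(patient_id = "p", code = "x", date = "not-a-date")
  expect_error(aggregate_monthly(bad), "unparseable")
  expect_warning(
    aggregate_monthly(data.frame(patient_id = character(0),
                                 code = character(0),
                                 date = character(0))),
    "no events")
})

test_that("filter_codes keeps totals strictly greater than min_cases", {
  m <- month_seq("2000-01-01", 12)
  vals <- rbind(c(rep(42L, 11), 37L),   # total 499
                c(rep(42L, 11), 38L),   # total 500: "more than 500" fails
                c(rep(42L, 11), 39L),   # total 501
                rep(900L, 12))          # total 10800
  mc <- monthly_counts(vals, c("a", "b", "c", "d"), m)
  kept <- filter_codes(mc, min_cases = 500)
  expect_equal(kept$codes, c("c", "d"))
  expect_equal(filter_codes(mc, min_cases = 0)$codes, mc$codes)
})

test_that("restrict_period selects whole calendar years", {
  m <- month_seq("1995-01-01", 16 * 12)  # 1995..2010
  mc <- monthly_counts(matrix(1L, 2, length(m)), c("a", "b"), m)
  r <- restrict_period(mc, 1997, 2009)
  expect_equal(length(r$months), 156)  # 13 years x 12
  expect_equal(format(r$months[1], "%Y-%m"), "1997-01")
  expect_equal(format(r$months[156], "%Y-%m"), "2009-12")
  expect_error(restrict_period(mc, 2020, 2021), "no months")
  # no-op restriction is the identity
  expect_equal(restrict_period(mc, 1995, 2010)$values, mc$values)
})

test_that("events and counts round-trip through delimited text", {
  cfg <- sim_config(n_codes = 3, months = 26, start = "2002-01",
                    baseline_rates = 6, seed = 13)
  sim <- simulate_counts(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  ev <- read_events(file.path(dir, "events.csv"))
  expect_equal(aggregate_monthly(ev)$values, sim$counts$values)
  cp <- file.path(dir, "counts.csv")
  write_counts(sim$counts, cp, header_comment = "v0 test")
  rt <- read_counts(cp)
  expect_equal(rt$values, sim$counts$values)
  expect_equal(rt$months, sim$counts$months)
})
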