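test_that("published case-control ratios reproduce from the printed counts", {
  tb <- load_table1()
  r <- incidence_ratio(tb$a, tb$n1, tb$b, tb$n2)
  dec <- printed_decimals(tb$ratio)
  for (i in seq_len(nrow(tb))) {
    if (tb$b[i] == 0) {
      expect_identical(r[i], -1)
    } else {
      expect_lt(abs(r[i] - tb$ratio[i]), 0.5000001 * 10^(-dec[i]))
    }
  }
  # the printed column is the incidence (risk) ratio, not the
  # cross-product odds ratio: for the top row OR would be ~59.5
  or <- (9 / (204 - 9)) / (2 / (2582 - 2))
  expect_equal(or, 59.5, tolerance = 0.01)
  expect_gt(abs(or - tb$ratio[1]), 2)
})

test_that("two-sided Fisher matches the published p column for 40/41 rows", {
  tb <- load_table1()
  p <- comorbidity_test(tb$a, tb$n1, tb$b, tb$n2)
  rel <- abs(p - tb$p) / tb$p
  expect_gte(sum(rel < 0.02), 40)
})

test_that("cohorts use first-occurrence index dates and exclusion", {
  ev <- data.frame(
    patient_id = c("p1", "p1", "p1", "p2", "p3", "p3"),
    code = c("Q", "Q", "C", "C", "Q", "X"),
    date = as.Date(c("2004-05-10", "2003-02-01", "2004-01-01",
                     "2004-06-01", "2005-01-01", "2004-12-20")))
  co <- build_cohorts(ev, "Q", "C")
  expect_equal(co$case$index_date[co$case$patient_id == "p1"],
               as.Date("2003-02-01"))                  # earliest Q event
  expect_false("p1" %in% co$controls[["C"]]$patient_id)  # case wins
  expect_equal(co$controls[["C"]]$patient_id, "p2")
  expect_error(build_cohorts(ev, "Q", "ZZZ"), "ZZZ")
})

test_that("the 60-day window is half-open: [index-60, index)", {
  ev <- data.frame(
    patient_id = c("c1", "c2", "c3", "k1", "c1", "c2", "c3"),
    code = c("Q", "Q", "Q", "C", "X", "X", "X"),
    date = as.Date(c("2005-03-01", "2005-03-01", "2005-03-01", "2005-01-01",
                     "2005-03-01",   # on the index day: excluded
                     "2005-02-28",   # 1 day before: included
                     "2004-12-31"))) # 60 days before: included
  co <- build_cohorts(ev, "Q", "C")
  res <- screen(ev, co$case, co$controls[["C"]], exclude = c("Q", "C"))
  expect_equal(res$a[res$condition == "X"], 2L)
})

test_that("screen recovers exactly planted co-occurrence counts", {
  ev <- simulate_comorbidity_cohort(
    204, 2582, conditions = c("354.0", "599.0", "null1"),
    case_incidence = c(9 / 204, 26 / 204, 0),
    control_incidence = c(2 / 2582, 76 / 2582, 0),
    exact = TRUE, query_code = "358.01", control_code = "487.1", seed = 51)
  truth <- attr(ev, "truth")
  expect_equal(truth$a, c(9L, 26L, 0L))  # deterministic assignment
  co <- build_cohorts(ev, "358.01", "487.1")
  expect_equal(nrow(co$case), 204)
  expect_equal(nrow(co$controls[[1]]), 2582)
  res <- screen(ev, co$case, co$controls[[1]],
                exclude = c("358.01", "487.1"))
  row <- res[res$condition == "354.0", ]
  expect_equal(row$a, 9L)
  expect_equal(row$b, 2L)
  expect_equal(row$ratio, 56.96, tolerance = 1e-3)
  expect_equal(res$ratio[res$condition == "599.0"], 4.33, tolerance = 1e-3)
  expect_false("null1" %in% res$condition)  # zero-probability condition
})

test_that("intersection keeps only conditions significant vs every control", {
  r1 <- data.frame(condition = c("x", "y", "z"), a = 5, n1 = 100,
                   inc_case = 0.05, b = 1, n2 = 1000, inc_ctrl = 0.001,
                   ratio = 50, p = c(0.001, 0.2, 0.01), q = NA)
  r2 <- r1
  r2$p <- c(0.002, 0.001, 0.3)
  out <- intersect_controls(list(flu = r1, hip = r2), p_threshold = 0.05)
  expect_equal(out$condition, "x")   # y fails control 1, z fails control 2
  expect_equal(out$p, 0.001)         # statistics of the first control
  r2$p <- c(0.9, 0.9, 0.9)
  expect_warning(out2 <- intersect_controls(list(r1, r2)), "no condition")
  expect_equal(nrow(out2), 0)
})

test_that("the screen is calibrated under equal incidences", {
  ev <- simulate_comorbidity_cohort(
    300, 1500, conditions = sprintf("c%02d", 1:40),
    case_incidence = 0.05, control_incidence = 0.05, seed = 52)
  res <- comorbidity_screen(ev, "Q", "CTRL", p_threshold = 0.05)
  frac <- nrow(res$intersection) / 40
  expect_lte(frac, 0.07)
})
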