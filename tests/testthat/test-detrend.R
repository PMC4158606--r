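test_that("kernel smoother is exact on constants and matches the NW oracle", {
  sm <- smooth_series(rep(7, 60))
  expect_equal(sm$trend, rep(7, 60), tolerance = 1e-12)

  # linear ramp: smoother output equals the independently coded
  # Nadaraya-Watson formula everywhere, and tracks the ramp in the interior
  y <- 10 + 2 * (0:119)
  sm2 <- smooth_series(y, bandwidth = 9)
  expect_equal(sm2$trend, nw_oracle(y, 9), tolerance = 1e-10)
  interior <- 19:101
  expect_lt(max(abs(sm2$trend[interior] - y[interior])) / diff(range(y)),
            0.05)
})

test_that("automatic bandwidth is Silverman's rule with a floor", {
  # massive counts push the Silverman bandwidth below the floor
  sm <- smooth_series(rpois(120, 5000))
  expect_equal(sm$bandwidth, 9)
  # all-zero series: zero trend, sentinel bandwidth
  z <- smooth_series(rep(0, 48))
  expect_equal(z$trend, rep(0, 48))
  expect_true(is.na(z$bandwidth))
  expect_error(smooth_series(rep(1, 10)), "24 months")
})

test_that("the smoother passes seasonal signal (closed-form attenuation)", {
  # a cosine of period T survives Gaussian smoothing with factor
  # exp(-(2*pi*h/T)^2/2); at h = 12, T = 12 the trend absorbs ~0%, so the
  # detrended series must retain >= 80% of the amplitude
  t <- 0:119
  y <- 100 + 10 * cos(2 * pi * t / 12)
  a <- detrend_series(y, 1997 + (t + 0.5) / 12, "sin12", bandwidth = 12)
  tm <- (a$time - 1997) * 12 - 0.5
  fit <- stats::lm(a$detrended ~ cos(2 * pi * tm / 12) + sin(2 * pi * tm / 12))
  amp <- sqrt(sum(stats::coef(fit)[2:3]^2))
  atten <- exp(-(2 * pi * 12 / 12)^2 / 2)
  expect_gt(amp / 10, 0.8)
  expect_equal(amp / 10, 1 - atten, tolerance = 0.02)
})

test_that("detrending trims 2 bandwidths and centers the residual", {
  t <- 0:119
  axis <- 1997 + (t + 0.5) / 12
  expect_equal(detrend_series(rep(5, 120), axis, bandwidth = 6)$detrended,
               rep(0, 96), tolerance = 1e-10)
  a <- detrend_series(stats::rpois(120, 60) + 2 * t, axis, bandwidth = 6)
  expect_equal(a$trim, 12)          # ceil(2 * 6)
  expect_equal(length(a$time), 96)  # 120 - 2 * 12
  # residual mean ~ 0: within 2 standard errors under Poisson noise
  se <- sqrt(60 / length(a$detrended))
  expect_lt(abs(mean(a$detrended)), 2 * se)
  expect_error(detrend_series(rep(2, 50), 1:50 / 12, bandwidth = 9), "24")
})

test_that("detrending strips low-frequency (secular) power", {
  set.seed(21)
  t <- 0:155
  y <- 200 + 3 * t + stats::rpois(156, 50)
  axis <- 1997 + (t + 0.5) / 12
  a <- detrend_series(y, axis, "ramp")
  tm <- (a$time - a$time[1]) * 12
  slow <- 1 / seq(61, 120, by = 6)  # periods beyond 5 years
  p_raw <- lomb_scargle(a$raw, tm, slow)
  p_det <- lomb_scargle(a$detrended, tm, slow)
  expect_gt(max(p_raw) / max(p_det), 10)
})

test_that("shared seasonal component has symmetric scales and a 6-month peak", {
  set.seed(22)
  t <- 0:155
  months <- month_seq("1997-01-01", 156)
  total <- 2000 * (1 + t / 150) * (1 + 0.05 * cos(2 * pi * t / 6))
  two <- monthly_counts(rbind(round(total), round(total)), c("a", "b"), months)
  sh <- build_shared_seasonal(two)
  expect_equal(unname(sh$scale), c(0.5, 0.5), tolerance = 1e-12)
  g <- ls_grid(length(sh$time) - 1)
  pw <- lomb_scargle(sh$total_detrended, (sh$time - sh$time[1]) * 12,
                     g$frequencies)
  expect_equal(g$periods[which.max(pw)], 6, tolerance = 0.2)
  one <- monthly_counts(matrix(round(total), 1), "a", months)
  expect_error(build_shared_seasonal(one), ">= 2 codes")
})

test_that("de-totaling cancels exact fixed-proportion codes", {
  t <- 0:155
  months <- month_seq("1997-01-01", 156)
  total <- 10000 * (1 + t / 150) * (1 + 0.05 * cos(2 * pi * t / 6))
  vals <- round(rbind(0.2 * total, 0.3 * total, 0.5 * total))
  mc <- monthly_counts(vals, c("a", "b", "c"), months)
  adj <- adjust_all(mc)
  for (a in adj)
    expect_lt(max(abs(a$detotaled)), 0.01 * mean(a$raw))
})

test_that("de-totaling preserves a code's own independent signal", {
  # noiseless: one 12-month seasonal code beside two flat codes; the total
  # is dominated by the flat codes, so de-totaling must keep >= 90% of the
  # code's 12-month periodogram power
  t <- 0:155
  months <- month_seq("1997-01-01", 156)
  sig <- 500 * (1 + 0.3 * cos(2 * pi * t / 12))
  vals <- round(rbind(sig, rep(8000, 156), rep(7000, 156)))
  mc <- monthly_counts(vals, c("s", "f1", "f2"), months)
  adj <- adjust_all(mc)
  tm <- (adj[["s"]]$time - adj[["s"]]$time[1]) * 12
  f12 <- 1 / 12
  p_before <- lomb_scargle(adj[["s"]]$detrended, tm, f12)
  p_after <- lomb_scargle(adj[["s"]]$detotaled, tm, f12)
  expect_gt(p_after / p_before, 0.9)
})

test_that("de-totaling degenerates correctly", {
  t <- 0:119
  months <- month_seq("1997-01-01", 120)
  set.seed(23)
  vals <- matrix(stats::rpois(240, 100), 2)
  mc <- monthly_counts(vals, c("a", "b"), months)
  sh <- build_shared_seasonal(mc)
  a <- detrend_series(vals[1, ], mc$time_axis, "a")
  # zero shared component -> detotaled == detrended
  sh0 <- sh
  sh0$total_detrended[] <- 0
  expect_equal(detotal_series(a, sh0)$detotaled, a$detrended)
  # misaligned axes -> error
  bad <- a
  bad$time <- bad$time + 1
  expect_error(detotal_series(bad, sh), "align")
})
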