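trace_ms <- function(n, dt = 10) (seq_len(n) - 1) * dt

test_that("gap interpolation recovers affine and constant signals exactly", {
  t <- trace_ms(100)
  d <- 3 + 0.0005 * t                     # exactly linear
  gap <- 41:55
  dg <- d; dg[gap] <- NA
  filled <- interpolate_gaps(pupil_trace(t, dg))
  expect_equal(filled$d[gap], d[gap], tolerance = 1e-9)
  expect_equal(filled$mask[gap], rep("interpolated", length(gap)))

  dc <- rep(3.5, 100); dc[30:40] <- NA
  filled_c <- interpolate_gaps(pupil_trace(t, dc))
  expect_equal(filled_c$d[30:40], rep(3.5, 11), tolerance = 1e-12)
})

test_that("filled values follow the 20-flanking-point slope rule on a curved signal", {
  t <- trace_ms(120)
  d <- 3 + 1e-6 * (t - 500)^2 / 100       # gently quadratic
  gap <- 61:68
  dg <- d; dg[gap] <- NA
  filled <- interpolate_gaps(pupil_trace(t, dg), half_window = 10)
  # independent re-derivation: least-squares slope through the 10 valid
  # points on each side, line anchored at the last pre-gap point
  pts <- c(51:60, 69:78)
  slope <- unname(stats::coef(stats::lm(d[pts] ~ t[pts]))[2])
  expected <- d[60] + slope * (t[gap] - t[60])
  expect_equal(filled$d[gap], expected, tolerance = 1e-9)
})

test_that("extreme, oversized and flank-poor gaps are left missing", {
  t <- trace_ms(60)
  d <- rep(3.5, 60)
  d[1:5] <- NA                            # leading gap
  d[56:60] <- NA                          # trailing gap
  filled <- interpolate_gaps(pupil_trace(t, d))
  expect_equal(filled$mask[1:5], rep("missing", 5))
  expect_equal(filled$mask[56:60], rep("missing", 5))

  d2 <- rep(3.5, 200); d2[50:120] <- NA   # 710 ms gap > 500 ms default
  filled2 <- interpolate_gaps(pupil_trace(trace_ms(200), d2))
  expect_true(all(filled2$mask[50:120] == "missing"))

  d3 <- rep(3.5, 30); d3[6:10] <- NA      # only 5 valid points before the gap
  expect_warning(filled3 <- interpolate_gaps(pupil_trace(trace_ms(30), d3)),
                 "left missing")
  expect_true(all(filled3$mask[6:10] == "missing"))
})

test_that("measured points are never altered by interpolation", {
  set.seed(601)
  t <- trace_ms(200)
  d <- 3.5 + 0.2 * sin(t / 300) + rnorm(200, 0, 0.02)
  d[c(30:40, 100:112)] <- NA
  tr <- pupil_trace(t, d)
  filled <- interpolate_gaps(tr)
  meas <- tr$mask == "measured"
  expect_identical(filled$d[meas], tr$d[meas])
  expect_identical(filled$mask[meas], tr$mask[meas])
})

test_that("Savitzky-Golay smoothing reproduces polynomials up to its order", {
  t <- trace_ms(200)
  const <- pupil_trace(t, rep(3.5, 200), stage = "filled")
  expect_equal(smooth_sg(const)$d, rep(3.5, 200), tolerance = 1e-12)

  # cubic signal, order-3 filter: reproduced everywhere including edges
  u <- (t - 1000) / 1000
  cubic <- 3.5 + 0.3 * u + 0.2 * u^2 - 0.1 * u^3
  sm <- smooth_sg(pupil_trace(t, cubic, stage = "filled"), window = 21, polyorder = 3)
  expect_equal(sm$d, cubic, tolerance = 1e-9)
})

test_that("window-5 order-2 smoothing equals the closed-form kernel on interior points", {
  set.seed(602)
  t <- trace_ms(60)
  d <- 3.5 + rnorm(60, 0, 0.1)
  sm <- smooth_sg(pupil_trace(t, d, stage = "filled"), window = 5, polyorder = 2)
  kernel <- c(-3, 12, 17, 12, -3) / 35
  expected <- as.numeric(stats::filter(d, kernel, sides = 2))
  interior <- 3:58
  expect_equal(sm$d[interior], expected[interior], tolerance = 1e-9)
})

test_that("smoothing propagates missing spans and validates parameters", {
  t <- trace_ms(100)
  d <- rep(3.5, 100); d[40:60] <- NA
  sm <- smooth_sg(pupil_trace(t, d, stage = "filled"))
  expect_true(all(sm$mask[40:60] == "missing"))
  expect_true(all(is.na(sm$d[40:60])))
  expect_true(all(!is.na(sm$d[-(40:60)])))
  expect_error(smooth_sg(pupil_trace(trace_ms(10), rep(3, 10), stage = "filled"),
                         window = 21), "trace length")
  expect_error(smooth_sg(pupil_trace(t, d, stage = "filled"), window = 20),
               "odd")
})

test_that("binocular averaging covers the three presence cases", {
  t <- trace_ms(5)
  l <- pupil_trace(t, c(3.0, NA, 3.0, NA, 3.2), stage = "smoothed")
  r <- pupil_trace(t, c(4.0, 4.0, NA, NA, 3.4), stage = "smoothed")
  avg <- average_binocular(l, r)
  expect_equal(avg$d, c(3.5, 4.0, 3.0, NA, 3.3))
  expect_equal(avg$mask, c("measured", "measured", "measured", "missing", "measured"))

  set.seed(603)
  dl <- ifelse(runif(200) < 0.2, NA, 3 + rnorm(200, 0, 0.1))
  dr <- ifelse(runif(200) < 0.2, NA, 3 + rnorm(200, 0, 0.1))
  got <- average_binocular(pupil_trace(trace_ms(200), dl, stage = "smoothed"),
                           pupil_trace(trace_ms(200), dr, stage = "smoothed"))
  expected <- ifelse(!is.na(dl) & !is.na(dr), (dl + dr) / 2,
                     ifelse(!is.na(dl), dl, dr))
  expect_equal(got$d, expected)

  expect_error(
    average_binocular(pupil_trace(trace_ms(5), rep(3, 5), stage = "smoothed"),
                      pupil_trace(trace_ms(6), rep(3, 6), stage = "smoothed")),
    "alignment")
})

test_that("baseline adjustment and normalization follow hand arithmetic", {
  t <- trace_ms(1000)
  const <- pupil_trace(t, rep(3.5, 1000), stage = "averaged")
  bl <- baseline_normalize(const, c(0, 5000))
  expect_equal(bl$d, rep(0, 1000), tolerance = 1e-12)
  expect_equal(attr(bl, "baseline_mm"), 3.5)

  d <- rep(3.0, 1000)
  d[600:700] <- 3.3                        # +0.3 mm bump after the baseline window
  bl2 <- baseline_normalize(pupil_trace(t, d, stage = "averaged"), c(0, 5000))
  expect_equal(max(bl2$d), 0.3, tolerance = 1e-12)
  expect_equal(max(bl2$d_norm), 0.1, tolerance = 1e-12)

  # translation invariance of the baselined series
  bl3 <- baseline_normalize(pupil_trace(t, d + 1.25, stage = "averaged"), c(0, 5000))
  expect_equal(bl3$d, bl2$d, tolerance = 1e-12)

  expect_error(baseline_normalize(pupil_trace(t, d, stage = "averaged"),
                                  c(-2000, 0)), "empty baseline")
})

test_that("the full pupillogram recovers the injected dilation bump", {
  sc <- test_scenario()
  sim <- simulate_recording(default_profiles()$expert, sc, seed = 31)
  pp <- pupillogram(sim$recording)
  expect_identical(attr(pp, "stages"),
                   c("raw", "filled", "smoothed", "averaged", "normalized"))
  # bump location: centroid of the above-half-maximum region, on the
  # recovered trace and on the noise-free truth
  locate <- function(t, d) {
    keep <- !is.na(d)
    t <- t[keep]; d <- d[keep]
    top <- d > max(d) / 2
    sum(t[top] * d[top]) / sum(d[top])
  }
  got <- locate(pp$t_ms, pp$d)
  truth <- locate(sim$truth$pupil$t_ms,
                  sim$truth$pupil$d - min(sim$truth$pupil$d))
  expect_lt(abs(got - truth), 1000)

  # determinism: identical recordings give identical pupillograms
  sim2 <- simulate_recording(default_profiles()$expert, sc, seed = 31)
  expect_identical(pp$d, pupillogram(sim2$recording)$d)

  # no pupil data at all -> error
  s <- sim$recording$samples[1:1000, ]
  s$pupil_l <- NA_real_; s$pupil_r <- NA_real_
  rec_np <- gaze_recording(s, rate_hz = 300, screen = c(1920, 1080))
  expect_error(pupillogram(rec_np), "no pupil data")
})

test_that("binocular averaging of the simulated eyes halves the noise variance", {
  sc <- test_scenario()
  sim <- simulate_recording(default_profiles()$novice, sc, seed = 32)
  s <- sim$recording$samples
  ok <- !is.na(s$pupil_l) & !is.na(s$pupil_r)
  latent <- sim$truth$pupil$d[ok]
  v_single <- stats::var(s$pupil_l[ok] - latent)
  v_avg <- stats::var((s$pupil_l[ok] + s$pupil_r[ok]) / 2 - latent)
  expect_equal(v_avg / v_single, 0.5, tolerance = 0.1)
})
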