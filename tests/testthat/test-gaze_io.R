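test_that("a well-formed gaze table parses with the rate inferred", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("t_ms\tgaze_x\tgaze_y\tpupil_l\tpupil_r\tvalid_l\tvalid_r",
               "0\t100\t200\t3.1\t3.3\t1\t1",
               "10\t101\t201\t3.2\t3.2\t1\t1",
               "20\t102\t202\t3.1\t3.4\t1\t1"), path)
  rec <- read_gaze_table(path)
  expect_s3_class(rec, "gaze_recording")
  expect_equal(nrow(rec$samples), 3)
  expect_equal(rec$rate_hz, 100)           # 10 ms median interval
  expect_equal(rec$samples$x, c(100, 101, 102))
})

test_that("blank pupil fields become missing values with invalid flags", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("t_ms\tgaze_x\tgaze_y\tpupil_l\tpupil_r\tvalid_l\tvalid_r",
               "0\t100\t200\t3.1\t3.3\t1\t1",
               "10\t101\t201\t\t\t1\t1",
               "20\t102\t202\t3.1\t3.4\t1\t1"), path)
  rec <- read_gaze_table(path)
  expect_true(is.na(rec$samples$pupil_l[2]))
  expect_true(is.na(rec$samples$pupil_r[2]))
  expect_false(rec$samples$valid_l[2])
  expect_false(rec$samples$valid_r[2])
  expect_true(all(rec$samples$valid_l[c(1, 3)]))
})

test_that("device sentinel pupil codes map to missing via the dialect", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,px,py,dl,dr,okl,okr",
               "0,100,200,-1,3.3,1,1",
               "10,101,201,3.2,0,1,1"), path)
  d <- gaze_dialect(sep = ",",
                    columns = c(t_ms = "time", gaze_x = "px", gaze_y = "py",
                                pupil_l = "dl", pupil_r = "dr",
                                valid_l = "okl", valid_r = "okr"))
  rec <- read_gaze_table(path, dialect = d)
  expect_true(is.na(rec$samples$pupil_l[1]))
  expect_true(is.na(rec$samples$pupil_r[2]))
  expect_true(rec$samples$valid_r[1])      # other eye still measured
  expect_true(rec$samples$valid_l[2])
})

test_that("unparseable timestamps are rejected with a reported count", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("t_ms\tgaze_x\tgaze_y\tpupil_l\tpupil_r\tvalid_l\tvalid_r",
               "0\t100\t200\t3.1\t3.3\t1\t1",
               "oops\t101\t201\t3.2\t3.2\t1\t1",
               "20\t102\t202\t3.1\t3.4\t1\t1"), path)
  expect_message(rec <- read_gaze_table(path), "rejected 1 row")
  expect_equal(nrow(rec$samples), 2)
})

test_that("format and validation errors name the offending column or row", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("t_ms\tgaze_x\tpupil_l\tpupil_r\tvalid_l\tvalid_r",
               "0\t100\t3.1\t3.3\t1\t1"), path)
  expect_error(read_gaze_table(path), "gaze_y")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("t_ms\tgaze_x\tgaze_y\tpupil_l\tpupil_r\tvalid_l\tvalid_r",
               "0\t100\t200\t3.1\t3.3\t1\t1",
               "20\t101\t201\t3.2\t3.2\t1\t1",
               "10\t102\t202\t3.1\t3.4\t1\t1"), path2)
  expect_error(read_gaze_table(path2), "strictly increasing.*row 3")
})

test_that("a simulated recording round-trips through write/read field-for-field", {
  sc <- test_scenario()
  sim <- simulate_recording(default_profiles()$novice, sc, seed = 11)
  # down-sample to keep the fixture small; structure is unchanged
  rec <- sim$recording
  rec$samples <- rec$samples[rec$samples$t_ms < 5000, ]
  rec <- gaze_recording(rec$samples, rate_hz = rec$rate_hz,
                        screen = c(rec$screen_w, rec$screen_h))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gaze_table(rec, path)
  back <- read_gaze_table(path, screen = c(rec$screen_w, rec$screen_h))
  expect_equal(back$samples$t_ms, rec$samples$t_ms, tolerance = 1e-9)
  expect_equal(back$samples$x, rec$samples$x, tolerance = 1e-9)
  expect_equal(back$samples$y, rec$samples$y, tolerance = 1e-9)
  expect_equal(back$samples$pupil_l, rec$samples$pupil_l, tolerance = 1e-9)
  expect_equal(back$samples$pupil_r, rec$samples$pupil_r, tolerance = 1e-9)
  expect_equal(back$samples$valid_l, rec$samples$valid_l)
  expect_equal(back$samples$valid_r, rec$samples$valid_r)
})

test_that("AOI configs parse, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("screen:", "  w: 1920", "  h: 1080",
               "aois:",
               "  - {name: AOI II, x0: 100, y0: 100, x1: 500, y1: 500}",
               "  - {name: AOI III, x0: 600, y0: 100, x1: 900, y1: 500}"), path)
  scheme <- read_aoi_config(path)
  expect_s3_class(scheme, "aoi_scheme")
  expect_equal(scheme$aois$name, c("AOI II", "AOI III"))
  expect_equal(scheme$complement_name, "AOI I")

  out <- withr::local_tempfile(fileext = ".yaml")
  write_aoi_config(scheme, out)
  back <- read_aoi_config(out)
  expect_equal(back$aois, scheme$aois)
  expect_equal(back$complement_name, scheme$complement_name)

  # scenario config emitted by the simulator's default scenario
  out2 <- withr::local_tempfile(fileext = ".json")
  write_aoi_config(default_scenario()$scheme, out2)
  back2 <- read_aoi_config(out2)
  expect_equal(nrow(back2$aois), 2)
  expect_equal(back2$complement_name, "AOI I")
})

test_that("overlapping or out-of-bounds AOI rectangles are rejected by name", {
  expect_error(
    aoi_scheme(data.frame(name = c("A", "B"),
                          x0 = c(0, 50), y0 = c(0, 50),
                          x1 = c(100, 150), y1 = c(100, 150)),
               screen = c(1920, 1080)),
    "overlap: A and B")
  expect_error(
    aoi_scheme(data.frame(name = "A", x0 = 1800, y0 = 0, x1 = 2000, y1 = 100),
               screen = c(1920, 1080)),
    "outside")
  # touching edges are fine under half-open rectangles
  expect_s3_class(
    aoi_scheme(data.frame(name = c("A", "B"),
                          x0 = c(0, 100), y0 = c(0, 0),
                          x1 = c(100, 200), y1 = c(100, 100)),
               screen = c(1920, 1080)),
    "aoi_scheme")
})

test_that("output tables round-trip at 3-decimal precision", {
  rec <- make_recording(seq(0, 2000, by = 10),
                        x = c(rep(100, 100), rep(500.1234, 101)),
                        y = c(rep(100, 100), rep(300.5678, 101)))
  fx <- detect_fixations_ivt(rec)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fixation_table(fx, path)
  back <- read_fixation_table(path)
  expect_equal(back$onset_ms, round(fx$onset_ms, 3))
  expect_equal(back$cx, round(fx$cx, 3))

  # empty fixation list -> header-only file
  empty <- fx[0, ]
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_fixation_table(empty, path2)
  expect_length(readLines(path2), 1)
  expect_equal(nrow(read_fixation_table(path2)), 0)

  scheme <- default_scenario()$scheme
  m <- percent_metrics(fx, scheme, participant_id = "p1")
  path3 <- withr::local_tempfile(fileext = ".tsv")
  write_metrics_table(m, path3)
  back3 <- read_metrics_table(path3)
  expect_equal(back3$pct_duration, round(m$pct_duration, 3))
  expect_equal(back3$aoi, m$aoi)
})

test_that("comparison tables use the conventional post-hoc column layout", {
  comp <- dunn_pairwise(list(`AOI II` = c(1, 2), `AOI III` = c(3, 4),
                             `AOI I` = c(5, 6)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_comparison_table(comp, path)
  back <- read_comparison_table(path)
  expect_identical(names(back),
                   c("pair", "test_statistic", "std_error",
                     "std_test_statistic", "sig", "adj_sig"))
  expect_equal(back$test_statistic, round(comp$rank_diff, 3))
  expect_equal(back$std_test_statistic, round(comp$z, 3))
})
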