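# Interchange schema, validation, and stance-grid resampling.

test_that("write_cohort / read_cohort round-trips a cohort losslessly", {
  cohort <- make_cohort(2L, moment_offsets = c(0.05, 0.2))
  # second subject gets a right side too: 2 subjects x 2 sides later
  cohort <- c(cohort, list(make_record("S01", "right", moment_offset = 0.1),
                           make_record("S02", "right")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_length(back, 4L)

  # records come back sorted by (subject_id, side); compare curve-by-curve
  ids <- vapply(back, function(r) paste(r$subject_id, r$side), character(1))
  expect_identical(ids, c("S01 left", "S01 right", "S02 left", "S02 right"))
  orig <- cohort[order(record_ids <- vapply(cohort, function(r)
    paste(r$subject_id, r$side), character(1)))]
  for (i in seq_along(back)) {
    # variables come back in canonical order; values must be bit-identical
    expect_identical(back[[i]]$kinematics[names(orig[[i]]$kinematics)],
                     orig[[i]]$kinematics)
    expect_identical(back[[i]]$measured_moments[names(orig[[i]]$measured_moments)],
                     orig[[i]]$measured_moments)
    expect_identical(back[[i]]$predicted_moments[names(orig[[i]]$predicted_moments)],
                     orig[[i]]$predicted_moments)
  }

  # write-read-write is byte-identical (deterministic formatting)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("json mirror round-trips identically to the csv route", {
  cohort <- make_cohort(2L, moment_offsets = c(0, 0.15))
  pj <- withr::local_tempfile(fileext = ".json")
  write_cohort(cohort, pj, format = "json")
  back <- read_cohort(pj, format = "json")
  expect_length(back, 2L)
  expect_equal(back[[1]]$kinematics, cohort[[1]]$kinematics)
  expect_equal(back[[2]]$predicted_moments, cohort[[2]]$predicted_moments)
})

test_that("empty cohort writes a header-only file", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(list(), path)
  expect_identical(readLines(path),
                   "subject_id,side,variable,sample_index,value")
})

test_that("validation errors name the offender", {
  cohort <- make_cohort(2L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  long <- read.csv(path, colClasses = c(subject_id = "character"))

  # drop KneeFlx for S02 -> error naming subject and variable
  broken <- long[!(long$subject_id == "S02" & long$variable == "KneeFlx"), ]
  pb <- withr::local_tempfile(fileext = ".csv")
  write.csv(broken, pb, row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(pb), "S02.*KneeFlx")

  # non-finite value -> error with a row index
  broken2 <- long
  broken2$value[123] <- NA
  pb2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(broken2, pb2, row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(pb2), "non-finite.*123")

  expect_error(read_cohort("/nonexistent/file.csv"), "not found")
})

test_that("severity survives the metadata side-car", {
  rec <- make_record()
  rec$severity <- 0.75
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(list(rec), path)
  back <- read_cohort(path)
  expect_equal(back[[1]]$severity, 0.75)
})

test_that("resample_stance matches the piecewise-linear oracle", {
  # hand-computed at parameters k/6 over knots (0, 1/3, 2/3, 1)
  expect_equal(resample_stance(c(0, 1, 4, 9), n_points = 7),
               c(0, 0.5, 1, 2.5, 4, 6.5, 9))
  # linear ramp stays linear
  expect_equal(resample_stance(c(0, 10), n_points = 60),
               seq(0, 10, length.out = 60))
})

test_that("resample_stance is the identity at target length and bounded", {
  set.seed(42)
  for (rep in 1:20) {
    raw <- rnorm(sample(5:200, 1))
    expect_identical(resample_stance(raw, length(raw)), as.numeric(raw))
    y <- resample_stance(raw, 60)
    # endpoints exact, interior within the convex hull of the input
    expect_identical(y[c(1, 60)], as.numeric(raw[c(1, length(raw))]))
    expect_true(min(y) >= min(raw) - 1e-12 && max(y) <= max(raw) + 1e-12)
    # idempotent at the target length
    expect_identical(resample_stance(y, 60), y)
  }
  expect_error(resample_stance(numeric(1)), "at least 2")
  expect_error(resample_stance(c(1, NA, 3)), "non-finite")
})
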