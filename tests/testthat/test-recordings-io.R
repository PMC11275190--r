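test_that("traces round-trip through CSV", {
  tr <- trace(sin(1:50 / 5) + 0.1, dt = 2, unit = "mV", label = "rt")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  back <- read_trace_csv(path, unit = "mV", label = "rt")
  expect_equal(back$values, tr$values)
  expect_equal(back$dt, tr$dt)
  expect_equal(back$t0, tr$t0)
  expect_identical(back$unit, "mV")
})

test_that("a hand-written trace file parses by inspection", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,value", "0,0.1", "1,0.2", "2,0.3"), path)
  tr <- read_trace_csv(path, unit = "mV")
  expect_equal(tr$dt, 1)
  expect_equal(tr$values, c(0.1, 0.2, 0.3))
})

test_that("malformed trace files raise distinct errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,value", "2,0.1", "0,0.2", "1,0.3"), path)
  expect_error(read_trace_csv(path), class = "trace_nonmonotone")
  writeLines(c("time_s,value", "0,0.1", "1,0.2", "2.5,0.3"), path)
  expect_error(read_trace_csv(path), class = "trace_nonuniform")
  writeLines(c("time_s,value", "0,0.1", "1,abc", "2,0.3"), path)
  expect_error(read_trace_csv(path), class = "trace_nonnumeric")
  expect_error(read_trace_csv(file.path(tempdir(), "absent.csv")),
               class = "io_missing_file")
})

test_that("metrics tables render with the documented layout and precision", {
  row <- metrics_row("Control", mean = 0.895, sd = 0.419, max = 1.909,
                     min = 0.361, kurtosis = 3.91, skewness = 1.37)
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_table(row, path)
  lines <- readLines(path)
  expect_identical(lines[1],
                   "Condition,Mean,StdDev,Max,Min,Kurtosis,Skewness")
  expect_identical(lines[2], "Control,0.895,0.419,1.909,0.361,3.91,1.37")
  back <- read_metrics_table(path)
  expect_equal(back$Mean, 0.895)
  expect_equal(back$Skewness, 1.37)
})

test_that("metrics rows enforce their invariants and export to JSON", {
  expect_error(metrics_row("x", mean = 2, sd = 1, max = 1.5, min = 0,
                           kurtosis = 3, skewness = 0),
               class = "metrics_invalid")
  expect_error(metrics_row("x", mean = 1, sd = -1, max = 2, min = 0,
                           kurtosis = 3, skewness = 0),
               class = "metrics_invalid")
  rows <- rbind(
    metrics_row("a", 1, 0.1, 2, 0.5, 3, 0),
    metrics_row("b", 2, 0.2, 3, 1.0, 3, 1))
  path <- withr::local_tempfile(fileext = ".json")
  metrics_to_json(rows, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$Mean, c(1, 2))
  expect_error(write_metrics_table(rows[0, ], tempfile()),
               class = "metrics_invalid")
})
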