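test_that("QC removal rules match the sensor-cleaning contract", {
  raw <- make_series(c(10, 26, 8, 9, 7))
  raw$do_mgl[4] <- 0.0          # nonpositive DO
  raw$ph[5] <- -0.1             # nonpositive pH
  qc <- apply_qc_filters(raw)
  expect_equal(qc$report$rows_removed_by_rule$do_gt_25, 1)
  expect_equal(qc$report$rows_removed_by_rule$nonpositive_value, 2)
  expect_equal(qc$report$rows_out, 2)
  expect_equal(qc$data$do_mgl, c(10, 8))
  expect_true(all(qc$data$do_mgl > 0 & qc$data$do_mgl <= 25))
  # passing row retained unchanged
  expect_equal(qc$data$do_mgl[1], 10)
})

test_that("conductivity unit conversion multiplies mS/cm rows by 1000", {
  raw <- make_series(c(10, 9))
  raw$cond_uscm <- c(0.5, 0.62)
  qc <- apply_qc_filters(raw, cond_unit = "ms/cm")
  expect_equal(qc$data$cond_uscm, c(500, 620))
  expect_equal(qc$report$unit_conversions, 2)
})

test_that("exclusion intervals and duplicate timestamps are removed and counted", {
  raw <- make_series(rep(9, 8))
  raw$timestamp[5] <- raw$timestamp[4]   # duplicate
  excl <- tibble::tibble(start = raw$timestamp[7], end = raw$timestamp[8],
                         reason = "oxygenation episode")
  qc <- apply_qc_filters(raw, exclusion_intervals = excl)
  expect_equal(qc$report$rows_removed_by_rule$duplicate_timestamp, 1)
  expect_equal(qc$report$rows_removed_by_rule$excluded_interval, 2)
  expect_true(all(diff(qc$data$timestamp) > 0))
})

test_that("QC is idempotent, conserves row counts, and never passes bound violations", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      n <- 200
      raw <- make_series(runif(n, -2, 30))
      raw$cond_uscm <- runif(n, -100, 1000)
      raw$ph <- runif(n, -1, 14)
      raw$turbidity_ntu <- runif(n, -5, 50)
      qc <- apply_qc_filters(raw)
      rep1 <- qc$report
      expect_equal(rep1$rows_in - sum(unlist(rep1$rows_removed_by_rule)),
                   rep1$rows_out)
      with(qc$data, {
        expect_true(all(do_mgl > 0 & do_mgl <= 25))
        expect_true(all(cond_uscm > 0) && all(ph > 0) && all(turbidity_ntu > 0))
      })
      # idempotence: second pass removes nothing
      qc2 <- apply_qc_filters(qc$data)
      expect_equal(qc2$data, qc$data)
      expect_equal(sum(unlist(qc2$report$rows_removed_by_rule)), 0)
      # timestamps that survive are untouched
      expect_true(all(qc$data$timestamp %in% raw$timestamp))
    }
  })
})

test_that("missing timestamp or DO column is a hard error", {
  expect_error(apply_qc_filters(tibble::tibble(do_mgl = 1)), "timestamp")
  expect_error(apply_qc_filters(tibble::tibble(timestamp = Sys.time())),
               "do_mgl")
})

test_that("rainfall pairing broadcasts by calendar date and never fabricates zeros", {
  s <- make_series(rep(9, 96 * 2))    # two full days
  rain <- tibble::tibble(date = as.Date("2021-03-01"), rainfall_mm = 3.2)
  out <- pair_rainfall(s, rain)
  d1 <- as.Date(out$timestamp, tz = "UTC") == as.Date("2021-03-01")
  expect_equal(sum(d1), 96)
  expect_true(all(out$rainfall_mm[d1] == 3.2))
  expect_true(all(is.na(out$rainfall_mm[!d1])))   # absent date -> missing
  rain_dup <- tibble::tibble(date = as.Date(c("2021-03-01", "2021-03-01")),
                             rainfall_mm = c(1, 2))
  expect_error(pair_rainfall(s, rain_dup), "duplicate")
})

test_that("sensor CSV reading applies the column mapping and reports round-trips", {
  tmp <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    TIME = format(as.POSIXct("2021-03-01", tz = "UTC") + 900 * 0:3,
                  "%Y-%m-%dT%H:%M:%SZ"),
    `DOO-MGL` = c(10, 9, 8, 7)
  ), tmp)
  x <- read_sensor_csv(tmp, col_map = c(timestamp = "TIME", do_mgl = "DOO-MGL"))
  expect_s3_class(x$timestamp, "POSIXct")
  expect_equal(x$do_mgl, c(10, 9, 8, 7))
  expect_error(read_sensor_csv(tmp, col_map = c(timestamp = "NOPE")),
               "not found")
  rep_path <- tempfile(fileext = ".json")
  qc <- apply_qc_filters(x)
  write_qc_report(qc$report, rep_path)
  parsed <- jsonlite::read_json(rep_path)
  expect_equal(parsed$rows_in, 4)
})
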