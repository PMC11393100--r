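test_that("moving average preserves constants and linear ramps, kills full-period tones", {
  expect_equal(moving_average_trend(rep(3, 100), 6), rep(3, 100))
  n <- 2000; t <- seq_len(n)
  # 6-h window at 15-min sampling = 24 samples: a 24-sample-period sine
  # sums to zero over any full window
  tone <- sin(2 * pi * t / 24)
  tr <- moving_average_trend(tone, 6)
  expect_lt(max(abs(tr[50:(n - 50)])), 1e-8)
  ramp <- 0.3 * t
  tr2 <- moving_average_trend(ramp, 6)
  expect_equal(tr2[50:(n - 50)], ramp[50:(n - 50)], tolerance = 1e-10)
  expect_error(moving_average_trend(rep(1, 10), 6), "longer")
})

test_that("seasonal detrending satisfies its reconstruction and ratio contracts", {
  withr::with_seed(3, {
    n <- 1500; t <- seq_len(n)
    y <- 9 + 2 * sin(2 * pi * t / 960) + 0.5 * sin(2 * pi * t / 48) +
      0.1 * rnorm(n)
    da <- seasonal_detrend(y, 6, "additive")
    expect_lt(max(abs(reconstruct(da) - y) / abs(y)), 1e-10)
    dm <- seasonal_detrend(y, 6, "multiplicative")
    expect_lt(max(abs(reconstruct(dm) - y) / abs(y)), 1e-10)
    # constant series: multiplicative fluctuation is identically one
    dc <- seasonal_detrend(rep(5, 200), 6, "multiplicative")
    expect_equal(dc$fluctuation, rep(1, 200))
    # slow trend + fast seasonal: fluctuation recovers the fast part
    slow <- 10 + 0.001 * t; fast <- 0.3 * sin(2 * pi * t / 8)
    df <- seasonal_detrend(slow + fast, 6, "additive")
    int <- 100:(n - 100)
    expect_gt(cor(df$fluctuation[int], fast[int]), 0.99)
    expect_error(seasonal_detrend(c(1, -1, 2), 6, "multiplicative"),
                 "positive")
  })
})

test_that("multiplicative detrending equals exp of additive detrending of the log", {
  withr::with_seed(5, {
    n <- 1200; t <- seq_len(n)
    y <- exp(2 + 0.3 * sin(2 * pi * t / 600) + 0.05 * rnorm(n))
    for (method in c("seasonal", "emd")) {
      dm <- detrend(y, method, "multiplicative", f_hours = 6, m_dropped = 2)
      dl <- detrend(log(y), method, "additive", f_hours = 6, m_dropped = 2)
      expect_equal(dm$fluctuation, exp(dl$fluctuation), tolerance = 1e-12)
      expect_equal(dm$trend, exp(dl$trend), tolerance = 1e-12)
    }
  })
})

test_that("shift and scale invariances of the two modes hold", {
  withr::with_seed(8, {
    n <- 900
    y <- 9 + sin(2 * pi * seq_len(n) / 48) + 0.1 * rnorm(n)
    a <- seasonal_detrend(y, 6, "additive")
    a_shift <- seasonal_detrend(y + 5, 6, "additive")
    expect_equal(a_shift$trend, a$trend + 5, tolerance = 1e-10)
    expect_equal(a_shift$fluctuation, a$fluctuation, tolerance = 1e-10)
    m <- seasonal_detrend(y, 6, "multiplicative")
    m_scale <- seasonal_detrend(3 * y, 6, "multiplicative")
    expect_equal(m_scale$trend, 3 * m$trend, tolerance = 1e-10)
    expect_equal(m_scale$fluctuation, m$fluctuation, tolerance = 1e-10)
  })
})

test_that("EMD detrending splits modes per the dropped-mode count", {
  withr::with_seed(13, {
    n <- 2048; t <- seq_len(n)
    slow <- 2 * sin(2 * pi * t / 1000); fast <- 0.3 * sin(2 * pi * t / 20)
    y <- 9 + slow + fast
    d <- emd_detrend(y, m_dropped = 1, mode = "additive")
    int <- 100:(n - 100)
    expect_gt(cor(d$fluctuation[int], fast[int]), 0.95)
    expect_lt(max(abs(reconstruct(d) - y)), 1e-8)
    # boundary case: dropping all modes leaves the residue as trend
    N <- d$params$n_imfs
    db <- emd_detrend(y, m_dropped = N, mode = "additive")
    expect_equal(db$trend, db$imf_set$residue)
    all_imfs <- Reduce(`+`, db$imf_set$imfs, rep(0, n))
    expect_equal(db$fluctuation, all_imfs)
    expect_error(emd_detrend(y, m_dropped = N + 1), "m_dropped")
    # literal residue-to-fluctuation reading still reconstructs
    dr <- emd_detrend(y, m_dropped = 1, residue_to = "fluctuation")
    expect_lt(max(abs(reconstruct(dr) - y)), 1e-8)
  })
})

test_that("multiplicative EMD recovers an injected multiplicative tone", {
  n <- 2048; t <- seq_len(n)
  fast <- 0.05 * sin(2 * pi * t / 20)
  y <- exp(2 + 0.3 * sin(2 * pi * t / 1000) + fast)
  d <- emd_detrend(y, m_dropped = 1, mode = "multiplicative")
  int <- 100:(n - 100)
  expect_gt(cor(log(d$fluctuation)[int], fast[int]), 0.95)
  expect_lt(max(abs(reconstruct(d) - y) / y), 1e-10)
})

test_that("automatic mode selection drops exactly the modes faster than the cutoff", {
  withr::with_seed(17, {
    n <- 4096; t <- seq_len(n)
    # 12-h tone (48 samples) + fast noise: the tone must stay in the trend
    y <- 9 + cos(2 * pi * t / 48) + 0.2 * rnorm(n)
    d <- emd_detrend(y, m_dropped = "auto", cutoff_hours = 6)
    # fluctuation carries no substantial 12-h component
    pw <- Mod(stats::fft(d$fluctuation - mean(d$fluctuation)))^2
    bin_12h <- n / 48 + 1
    expect_lt(pw[bin_12h] / sum(pw[2:(n / 2)]), 0.05)
    expect_gte(d$params$m_dropped, 1L)
  })
})
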