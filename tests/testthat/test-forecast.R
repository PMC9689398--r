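test_that("supervised window construction counts and aligns correctly", {
  s <- seq_len(100)
  sup <- make_supervised(s, 10)
  expect_equal(nrow(sup$x), 90)
  expect_equal(sup$y[1], s[11])
  expect_equal(sup$x[1, ], s[1:10])
  expect_equal(sup$x[90, ], s[90:99])
  expect_error(make_supervised(seq_len(10), 10), "exceed")
  expect_error(make_supervised(s, 0), ">= 1")
})

test_that("chronological split holds out the final 480 samples", {
  s <- seq_len(10000)
  sp <- split_series(s, 480)
  expect_length(sp$validation, 480)
  expect_length(sp$train, 7616)
  expect_length(sp$test, 1904)
  expect_equal(sp$validation, 9521:10000)
  expect_equal(tail(sp$train, 1) + 1, sp$test[1])
  expect_error(split_series(seq_len(500), 480, lookback = 100), "too short")
})

test_that("forecaster specs validate their stack", {
  expect_error(forecaster_spec(lookback = 0), ">= 1")
  expect_error(forecaster_spec(64, dropout = 1), "\\[0, 1\\)")
  expect_error(forecaster_spec(64, dense = c(2, 3)), "single output")
  pres <- forecaster_presets()
  expect_equal(vapply(pres, function(p) p$lookback, 1L),
               c(fhr_acidotic = 1500L, uc_acidotic = 2000L,
                 fhr_non_acidotic = 1000L, uc_non_acidotic = 800L))
  expect_equal(pres$fhr_acidotic$dense, c(2L, 1L))
  expect_equal(pres$fhr_non_acidotic$dropout, 0)
  fast <- forecaster_presets(fast = TRUE)
  expect_true(all(vapply(fast, function(p) p$lookback, 1L) == 64L))
})

test_that("rmse and mae match hand arithmetic and obey Jensen", {
  expect_equal(unname(rmse_mae(1:5, 1:5)), c(0, 0))
  expect_equal(unname(rmse_mae(c(1, -1), c(0, 0))), c(1, 1))
  expect_equal(unname(rmse_mae(c(0, 2), c(0, 0))), c(sqrt(2), 1))
  set.seed(1)
  for (i in 1:50) {
    r <- rmse_mae(rnorm(20), rnorm(20))
    expect_gte(r["rmse"], r["mae"])
  }
  expect_error(rmse_mae(1:3, 1:4), "equal length")
})

test_that("gate activations respect their ranges and the cell recurrence", {
  set.seed(3)
  n_draws <- 0
  for (s in 1:20) {
    params <- ctgforesee:::cpp_lstm_init(6, c(1L), s)
    ## random weight scales beyond the initializer's range
    params$W <- params$W * runif(1, 0.5, 4)
    params$U <- params$U * runif(1, 0.5, 4)
    tr <- ctgforesee:::cpp_lstm_trace(params, rnorm(50, 0, 2))
    expect_true(all(tr$f > 0 & tr$f < 1))
    expect_true(all(tr$i > 0 & tr$i < 1))
    expect_true(all(tr$o > 0 & tr$o < 1))
    expect_true(all(tr$g > -1 & tr$g < 1))
    ## C_t = f_t C_{t-1} + i_t g_t and y_t = o_t tanh(C_t)
    Cprev <- rbind(0, tr$C[-nrow(tr$C), , drop = FALSE])
    expect_equal(tr$C, tr$f * Cprev + tr$i * tr$g, tolerance = 1e-12)
    expect_equal(tr$y, tr$o * tanh(tr$C), tolerance = 1e-12)
    n_draws <- n_draws + length(tr$f) * 3 + length(tr$g)
  }
  expect_gte(n_draws, 1000)
})

test_that("the compiled forward pass matches a plain-R reimplementation", {
  set.seed(9)
  for (s in 1:5) {
    params <- ctgforesee:::cpp_lstm_init(5, c(3L, 1L), s)
    win <- rnorm(30)
    got <- ctgforesee:::cpp_lstm_predict(params, matrix(win, 1))
    expect_equal(got, oracle_lstm_forward(params, win), tolerance = 1e-12)
  }
  ## a zero-weight model outputs exactly zero
  z <- ctgforesee:::cpp_lstm_init(4, c(1L), 1)
  z$U[] <- 0; z$W[] <- 0; z$b[] <- 0
  z$dense_W[[1]][] <- 0; z$dense_b[[1]][] <- 0
  expect_equal(ctgforesee:::cpp_lstm_predict(z, matrix(rnorm(16), 1)), 0)
})

test_that("training is reproducible and reports errors in original units", {
  set.seed(12)
  x <- 140 + rnorm(4000, 0, 0.5)
  spec <- forecaster_spec(lookback = 16, units = 8, dropout = 0.1, dense = 1,
                          epochs = 5, seed = 7)
  m1 <- train_forecaster(x, spec, smooth_window_s = 0)
  m2 <- train_forecaster(x, spec, smooth_window_s = 0)
  expect_identical(m1$report, m2$report)
  expect_identical(m1$params, m2$params)
  expect_gte(m1$report$testing_rmse, m1$report$testing_mae)
  expect_gte(m1$report$validation_rmse, m1$report$validation_mae)
  ## near-constant series: forecast error bounded by the noise floor
  expect_lte(m1$report$validation_rmse, 2 * 0.5)
  expect_error(train_forecaster(c(x[1:100], NA), spec), "missing")
})

test_that("recursive forecasts of a constant-trained model stay put", {
  x <- rep(25, 3000)
  spec <- forecaster_spec(lookback = 16, units = 6, dropout = 0, dense = 1,
                          epochs = 3, seed = 2)
  m <- train_forecaster(x, spec, smooth_window_s = 0)
  fc <- forecast_recursive(m, x, 480)
  expect_length(fc, 480)
  expect_true(all(abs(fc - 25) < 1))
  expect_error(forecast_recursive(m, x, 0), "positive")
  expect_error(forecast_recursive(m, x[1:4], 10), "lookback")
})
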