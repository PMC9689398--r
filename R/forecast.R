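#' Sliding-window supervised pairs for one-step forecasting
#'
#' Pair `i` couples the window of `lookback` consecutive samples starting at
#' `i` with the next sample as the prediction target, preserving
#' chronological order.
#'
#' @param series numeric series.
#' @param lookback window length in samples (>= 1).
#' @return List with matrix `x` (`length(series) - lookback` rows of
#'   `lookback` columns) and target vector `y`.
#' @export
make_supervised <- function(series, lookback) {
  n <- length(series)
  if (lookback < 1) stop("make_supervised: lookback must be >= 1",
                         call. = FALSE)
  if (n <= lookback)
    stop("make_supervised: series length (", n,
         ") must exceed lookback (", lookback, ")", call. = FALSE)
  m <- n - lookback
  x <- matrix(NA_real_, m, lookback)
  for (j in seq_len(lookback)) x[, j] <- series[j:(j + m - 1L)]
  list(x = x, y = series[(lookback + 1L):n])
}

#' Chronological train/test/validation split of a series
#'
#' The final `validation_steps` samples are held out for recursive
#' multi-step validation; the remaining prefix is split 80/20 in time order
#' into training and testing. Nothing is shuffled across the boundaries.
#'
#' @param series numeric series.
#' @param validation_steps samples held out at the end (default 480 = 2 min
#'   at 4 Hz).
#' @param train_frac fraction of the prefix used for training.
#' @param lookback optional lookback used only for the feasibility check.
#' @return List with `train`, `test`, `validation` numeric vectors.
#' @export
split_series <- function(series, validation_steps = 480L, train_frac = 0.8,
                         lookback = 0L) {
  n <- length(series)
  if (n <= validation_steps + lookback + 10)
    stop("split_series: series too short for a ", validation_steps,
         "-step validation hold-out", call. = FALSE)
  rest <- n - validation_steps
  n_train <- floor(train_frac * rest)
  list(train = series[seq_len(n_train)],
       test = series[(n_train + 1L):rest],
       validation = series[(rest + 1L):n])
}

#' Forecaster architecture and training hyperparameters
#'
#' Describes one LSTM forecaster: the lookback window, the LSTM width, an
#' optional dropout layer on the LSTM output, a stack of linear dense layers
#' ending in the single forecast unit, and the SGD training setup
#' (mean-squared-error loss throughout).
#'
#' @param lookback window length in samples.
#' @param units LSTM cells.
#' @param dropout dropout rate on the LSTM output in \[0, 1) (0 = no layer).
#' @param dense widths of the dense stack; the last must be 1.
#' @param lr,momentum SGD learning rate and momentum.
#' @param clip global gradient-norm clip (0 disables).
#' @param epochs,batch_size,patience training length, minibatch size and
#'   early-stopping patience on the monitored test metric.
#' @param monitor early-stopping/selection metric: `"recursive"` (default)
#'   tracks a recursive rollout over the tail of the test split, which
#'   selects weights that stay stable when fed their own predictions;
#'   `"one_step"` tracks the plain one-step test loss.
#' @param validation_steps recursive validation horizon (480 = 2 min).
#' @param seed RNG seed for init, shuffling and dropout.
#' @return Object of class `forecaster_spec`.
#' @export
forecaster_spec <- function(lookback, units = 10L, dropout = 0.1,
                            dense = c(1L), lr = 0.05, momentum = 0.9,
                            clip = 1, epochs = 30L, batch_size = 64L,
                            patience = 5L, validation_steps = 480L,
                            monitor = c("recursive", "one_step"),
                            seed = 1L) {
  monitor <- match.arg(monitor)
  if (lookback < 1) stop("forecaster_spec: lookback must be >= 1",
                         call. = FALSE)
  if (dropout < 0 || dropout >= 1)
    stop("forecaster_spec: dropout must lie in [0, 1)", call. = FALSE)
  dense <- as.integer(dense)
  if (length(dense) < 1L || dense[length(dense)] != 1L)
    stop("forecaster_spec: the dense stack must end in a single output unit",
         call. = FALSE)
  if (any(dense < 1L))
    stop("forecaster_spec: dense widths must be positive", call. = FALSE)
  structure(list(lookback = as.integer(lookback), units = as.integer(units),
                 dropout = dropout, dense = dense, lr = lr,
                 momentum = momentum, clip = clip,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 validation_steps = as.integer(validation_steps),
                 monitor = monitor,
                 seed = as.integer(seed)),
            class = "forecaster_spec")
}

#' @export
print.forecaster_spec <- function(x, ...) {
  cat(sprintf("LSTM forecaster spec: lookback %d, %d cells%s, dense [%s]\n",
              x$lookback, x$units,
              if (x$dropout > 0) sprintf(", dropout %.2f", x$dropout) else "",
              paste(x$dense, collapse = ", ")))
  cat(sprintf("  SGD lr=%g momentum=%g, batch %d, up to %d epochs (patience %d)\n",
              x$lr, x$momentum, x$batch_size, x$epochs, x$patience))
  invisible(x)
}

#' Stock per-channel forecaster architectures
#'
#' The four single-series architectures used for the two showcase tracings:
#' FHR/acidotic (lookback 1500, dropout, dense 2+1), UC/acidotic (lookback
#' 2000, dropout), FHR/non-acidotic (lookback 1000, no dropout) and
#' UC/non-acidotic (lookback 800, dropout). With `fast = TRUE` the lookback
#' shrinks to 64 samples so a desk-scale run finishes in minutes; the layer
#' stacks are unchanged.
#'
#' @param fast use the desk-scale lookback.
#' @param ... overrides forwarded to every [forecaster_spec()].
#' @return Named list of four `forecaster_spec`s.
#' @export
forecaster_presets <- function(fast = FALSE, ...) {
  lb <- function(full) if (fast) 64L else full
  list(
    fhr_acidotic = forecaster_spec(lookback = lb(1500L), units = 10L,
                                   dropout = 0.1, dense = c(2L, 1L), ...),
    uc_acidotic = forecaster_spec(lookback = lb(2000L), units = 10L,
                                  dropout = 0.1, dense = 1L, ...),
    fhr_non_acidotic = forecaster_spec(lookback = lb(1000L), units = 10L,
                                       dropout = 0, dense = 1L, ...),
    uc_non_acidotic = forecaster_spec(lookback = lb(800L), units = 10L,
                                      dropout = 0.1, dense = 1L, ...))
}

#' Root-mean-square and mean absolute error
#'
#' @param predicted,actual equal-length numeric vectors.
#' @return Named vector `c(rmse, mae)`; RMSE >= MAE always (Jensen).
#' @export
rmse_mae <- function(predicted, actual) {
  if (length(predicted) != length(actual) || !length(predicted))
    stop("rmse_mae: inputs must be nonempty and of equal length",
         call. = FALSE)
  r <- predicted - actual
  out <- c(rmse = sqrt(mean(r^2)), mae = mean(abs(r)))
  stopifnot(out["rmse"] >= out["mae"] - 1e-12)
  out
}

#' Train an LSTM forecaster on one signal channel
#'
#' Applies the standard conditioning (moving-average smoothing, then
#' z-scoring with statistics from the training split only), builds sliding
#' windows over the pre-validation portion of the series (a window belongs
#' to the train or test split according to its target sample), trains the
#' LSTM stack with minibatch SGD on the mean-squared error, restores the
#' best-test-loss weights, and reports one-step test errors plus recursive
#' multi-step validation errors, all in original signal units.
#'
#' @param series numeric series at 4 Hz (bpm or UC units), no missing values
#'   (repair gaps first, see [interpolate_gaps()]).
#' @param spec a [forecaster_spec()].
#' @param smooth_window_s smoothing window (seconds); 0 disables.
#' @return Object of class `ctg_forecaster` with the trained weights, the
#'   conditioning parameters, loss history and a `report` containing
#'   `testing_rmse`, `testing_mae`, `validation_rmse`, `validation_mae`.
#' @export
train_forecaster <- function(series, spec, smooth_window_s = 4) {
  stopifnot(inherits(spec, "forecaster_spec"))
  if (anyNA(series))
    stop("train_forecaster: series contains missing samples", call. = FALSE)
  cond <- if (smooth_window_s > 0) smooth_ma(series, smooth_window_s) else
    as.numeric(series)
  sp <- split_series(cond, spec$validation_steps, lookback = spec$lookback)
  mu <- mean(sp$train)
  sdv <- sd(sp$train)
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  z <- standardize(cond, mu, sdv)
  n_pre <- length(sp$train) + length(sp$test)
  sup <- make_supervised(z[seq_len(n_pre)], spec$lookback)
  ## split pairs by target index (chronological, no leakage)
  tgt <- (spec$lookback + 1L):n_pre
  in_train <- tgt <= length(sp$train)
  if (!any(in_train) || !any(!in_train))
    stop("train_forecaster: series too short for the 80/20 window split",
         call. = FALSE)
  fit0 <- cpp_lstm_init(spec$units, spec$dense, spec$seed)
  fit <- cpp_lstm_train(fit0,
                        sup$x[in_train, , drop = FALSE], sup$y[in_train],
                        sup$x[!in_train, , drop = FALSE], sup$y[!in_train],
                        spec$lr, spec$momentum, spec$clip, spec$epochs,
                        spec$batch_size, spec$patience, spec$dropout,
                        spec$seed,
                        if (identical(spec$monitor, "recursive"))
                          spec$validation_steps else 0L)
  model <- structure(list(spec = spec, params = fit$params, mean = mu,
                          sd = sdv, smooth_window_s = smooth_window_s,
                          history = list(train = fit$train_loss,
                                         monitor = fit$monitor_loss,
                                         best_epoch = fit$best_epoch),
                          series = cond),
                     class = "ctg_forecaster")
  ## one-step test errors, original units
  pred_te <- destandardize(
    cpp_lstm_predict(fit$params, sup$x[!in_train, , drop = FALSE]), mu, sdv)
  act_te <- destandardize(sup$y[!in_train], mu, sdv)
  te <- rmse_mae(pred_te, act_te)
  ## recursive validation over the held-out tail
  fc <- forecast_recursive(model, cond[seq_len(n_pre)],
                           length(sp$validation))
  va <- rmse_mae(fc, sp$validation)
  model$report <- list(testing_rmse = unname(te["rmse"]),
                       testing_mae = unname(te["mae"]),
                       validation_rmse = unname(va["rmse"]),
                       validation_mae = unname(va["mae"]))
  model
}

#' @export
print.ctg_forecaster <- function(x, ...) {
  cat("Trained LSTM forecaster\n")
  print(x$spec)
  r <- x$report
  cat(sprintf("  one-step test RMSE %.4f / MAE %.4f; recursive %d-step validation RMSE %.4f / MAE %.4f (original units)\n",
              r$testing_rmse, r$testing_mae, x$spec$validation_steps,
              r$validation_rmse, r$validation_mae))
  invisible(x)
}

#' @export
summary.ctg_forecaster <- function(object, ...) {
  h <- object$history
  cat("Trained LSTM forecaster\n")
  print(object$spec)
  cat(sprintf("  trained %d epochs (best epoch %d), final train MSE %.5g (standardized units)\n",
              length(h$train), h$best_epoch, tail(h$train, 1)))
  r <- object$report
  cat(sprintf("  test RMSE %.4f, MAE %.4f | validation RMSE %.4f, MAE %.4f\n",
              r$testing_rmse, r$testing_mae, r$validation_rmse,
              r$validation_mae))
  invisible(object)
}

#' Recursive multi-step forecast
#'
#' Iterates the one-step forecaster: each prediction is appended to the
#' window and fed back, `horizon` times (480 steps = 2 min at 4 Hz, 960 =
#' 4 min). The history is standardized with the model's training statistics
#' and the forecast is returned in original units.
#'
#' @param model a trained [train_forecaster()] object.
#' @param history recent conditioned samples (length >= lookback), original
#'   units; defaults to the series the model was trained on.
#' @param horizon number of steps ahead (> 0).
#' @return Numeric vector of length `horizon`.
#' @export
forecast_recursive <- function(model, history = NULL, horizon = 480L) {
  stopifnot(inherits(model, "ctg_forecaster"))
  if (horizon <= 0)
    stop("forecast_recursive: horizon must be positive", call. = FALSE)
  if (is.null(history)) history <- model$series
  L <- model$spec$lookback
  if (length(history) < L)
    stop("forecast_recursive: history shorter than the lookback",
         call. = FALSE)
  win <- standardize(tail(history, L), model$mean, model$sd)
  out <- numeric(horizon)
  for (h in seq_len(horizon)) {
    p <- cpp_lstm_predict(model$params, matrix(win, nrow = 1L))
    out[h] <- p
    win <- c(win[-1L], p)
  }
  destandardize(out, model$mean, model$sd)
}

#' @export
predict.ctg_forecaster <- function(object, horizon = 480L, history = NULL,
                                   ...) {
  forecast_recursive(object, history = history, horizon = horizon)
}

# Activation trace of one window (gates, cell state, hidden output per time
# step) in standardized units; used by the cell-invariant tests.
lstm_trace <- function(model_or_params, window) {
  params <- if (inherits(model_or_params, "ctg_forecaster"))
    model_or_params$params else model_or_params
  cpp_lstm_trace(params, as.numeric(window))
}
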