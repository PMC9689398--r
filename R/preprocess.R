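#' Centered moving-average smoothing
#'
#' Smooths a 4 Hz sample series with a centered moving average. The window is
#' given in seconds and rounded to an odd number of samples so it is
#' symmetric; at the series edges the window shrinks so the output has the
#' same length as the input. Missing samples (`NA`) are ignored inside the
#' window; a window containing only missing samples yields `NA`.
#'
#' The default 4 s window suppresses beat-to-beat jitter while preserving the
#' 15 s-and-longer events that matter for FIGO-style feature extraction.
#'
#' @param x numeric series at 4 Hz (may contain `NA`).
#' @param window_s window length in seconds (default 4).
#' @param fs sampling rate, samples/second.
#' @return Smoothed series, same length as `x`.
#' @export
smooth_ma <- function(x, window_s = 4, fs = CTG_HZ) {
  if (!is.numeric(window_s) || window_s <= 0)
    stop("smooth_ma: window_s must be positive", call. = FALSE)
  w <- round(window_s * fs)
  if (w < 1L) w <- 1L
  if (w %% 2L == 0L) w <- w + 1L
  n <- length(x)
  if (w > n)
    stop("smooth_ma: window (", w, " samples) longer than series (", n, ")",
         call. = FALSE)
  h <- (w - 1L) %/% 2L
  good <- !is.na(x)
  xz <- ifelse(good, x, 0)
  cs <- cumsum(c(0, xz))
  cn <- cumsum(c(0, as.numeric(good)))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  s <- cs[hi + 1L] - cs[lo]
  m <- cn[hi + 1L] - cn[lo]
  out <- ifelse(m > 0, s / m, NA_real_)
  out
}

#' Repair short signal-loss gaps by linear interpolation
#'
#' Missing runs no longer than `max_gap_s` that are flanked by observed
#' samples are filled with a linear ramp between the flanking values and
#' unmasked. Longer runs, and runs touching either end of the recording, stay
#' masked. Observed samples are never altered. The 15 s default means a
#' repaired gap can never fabricate a qualifying 15 s event on its own.
#'
#' @param record a [ctg_record()].
#' @param max_gap_s longest gap (seconds) that is repaired.
#' @return A repaired [ctg_record()].
#' @export
interpolate_gaps <- function(record, max_gap_s = 15) {
  stopifnot(inherits(record, "ctg_record"))
  mask <- record$missing_mask
  if (all(mask))
    stop("interpolate_gaps: record '", record$record_id,
         "' is entirely missing (unrecoverable signal)", call. = FALSE)
  if (!any(mask)) return(record)
  fill_channel <- function(x) {
    r <- rle(is.na(x))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      a <- starts[k]; b <- ends[k]
      if (a == 1L || b == length(x)) next            # edge gap: no anchors
      if (r$lengths[k] > max_gap_s * CTG_HZ) next    # too long to trust
      x[a:b] <- x[a - 1L] +
        (x[b + 1L] - x[a - 1L]) * seq_len(b - a + 1L) / (b - a + 2L)
    }
    x
  }
  fhr <- fill_channel(record$fhr)
  uc <- fill_channel(record$uc)
  out <- record
  out$fhr <- fhr
  out$uc <- pmax(uc, 0)
  out$missing_mask <- is.na(fhr)
  out
}

#' Standardize / de-standardize a series
#'
#' `standardize()` applies the z-score transform `(x - mean) / std`;
#' `destandardize()` inverts it exactly. Used to put signals on the unit
#' scale the forecaster trains on, with statistics always taken from the
#' training split only.
#'
#' @param x numeric series.
#' @param mean,std transform parameters; `std` must be > 0.
#' @return Transformed series.
#' @export
standardize <- function(x, mean, std) {
  if (!is.numeric(std) || length(std) != 1L || is.na(std) || std <= 0)
    stop("standardize: std must be a positive number", call. = FALSE)
  (x - mean) / std
}

#' @rdname standardize
#' @export
destandardize <- function(x, mean, std) {
  if (!is.numeric(std) || length(std) != 1L || is.na(std) || std <= 0)
    stop("destandardize: std must be a positive number", call. = FALSE)
  x * std + mean
}
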