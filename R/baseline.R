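#' Iterative FHR baseline estimation
#'
#' Estimates the fetal-heart-rate baseline by the FIGO-style iterative
#' procedure: the initial baseline `M` is the mean of all (non-missing)
#' samples; accelerations and decelerations are detected against `M`, a new
#' mean `N` is computed over the event-free samples, and the loop repeats
#' with `M <- N` while the two differ by more than `tol`. Convergence (or
#' hitting `max_iter`) is reported honestly in the returned object.
#'
#' The input should already be smoothed (see [smooth_ma()]); event detection
#' during the iteration uses preliminary, untyped excursions.
#'
#' @param fhr smoothed FHR series at 4 Hz (`NA` = missing).
#' @param tol convergence tolerance in bpm (default 0.5).
#' @param max_iter iteration cap; non-convergence is flagged, not an error.
#' @param fs sampling rate.
#' @return An object of class `fhr_baseline` with fields `M` (final
#'   baseline), `N` (last re-estimate), `iterations`, `converged` and
#'   `event_free_mask`.
#' @export
estimate_baseline <- function(fhr, tol = 0.5, max_iter = 50L, fs = CTG_HZ) {
  good <- !is.na(fhr)
  if (sum(good) < 120 * fs)
    stop("estimate_baseline: fewer than 2 min of non-missing signal ",
         "(unrecoverable)", call. = FALSE)
  M <- mean(fhr[good])
  iterations <- 0L
  converged <- FALSE
  event_free <- good
  N <- M
  repeat {
    iterations <- iterations + 1L
    ev <- detect_events(fhr, M, fs = fs)
    event_free <- good
    if (nrow(ev))
      for (k in seq_len(nrow(ev)))
        event_free[ev$onset[k]:(ev$offset[k] - 1L)] <- FALSE
    if (!any(event_free)) {
      ## pathological: events cover everything; fall back to all samples
      N <- mean(fhr[good])
    } else {
      N <- mean(fhr[event_free])
    }
    if (abs(N - M) <= tol) {
      converged <- TRUE
      M <- N
      break
    }
    M <- N
    if (iterations >= max_iter) break
  }
  structure(list(M = M, N = N, iterations = iterations,
                 converged = converged, event_free_mask = event_free),
            class = "fhr_baseline")
}

#' @export
print.fhr_baseline <- function(x, ...) {
  cat(sprintf("FHR baseline: %.2f bpm (%s after %d iteration%s)\n",
              x$M, if (x$converged) "converged" else "NOT converged",
              x$iterations, if (x$iterations == 1L) "" else "s"))
  invisible(x)
}

#' Detect baseline excursions (candidate accelerations/decelerations)
#'
#' An event is a maximal run of samples strictly on one side of the baseline
#' whose peak deviation reaches at least 15 bpm and whose duration is at
#' least 15 s. Runs are broken by missing samples. Returned events are
#' untyped (`deceleration_unspecified` / `acceleration`-signed); use
#' [classify_events()] for the duration- and contraction-based taxonomy.
#'
#' @param fhr smoothed FHR series.
#' @param baseline baseline level in bpm (finite scalar).
#' @param min_peak_bpm,min_dur_s qualification thresholds (15 bpm, 15 s).
#' @param fs sampling rate.
#' @return Data frame with columns `type` (`"unspecified"`), `onset`,
#'   `offset` (sample indices, half-open), `peak_deviation_bpm`, `peak_index`.
#' @export
detect_events <- function(fhr, baseline, min_peak_bpm = 15, min_dur_s = 15,
                          fs = CTG_HZ) {
  stopifnot(is.finite(baseline))
  dev <- fhr - baseline
  s <- sign(dev)
  s[is.na(s)] <- 0
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_len <- min_dur_s * fs
  out <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k] == 0) next
    if (r$lengths[k] < min_len) next
    idx <- starts[k]:ends[k]
    pk <- idx[which.max(abs(dev[idx]))]
    if (abs(dev[pk]) < min_peak_bpm) next
    out[[length(out) + 1L]] <- data.frame(
      type = "unspecified", onset = starts[k], offset = ends[k] + 1L,
      peak_deviation_bpm = dev[pk], peak_index = pk)
  }
  if (!length(out))
    return(data.frame(type = character(), onset = integer(),
                      offset = integer(), peak_deviation_bpm = numeric(),
                      peak_index = integer()))
  do.call(rbind, out)
}

#' Detect uterine contractions
#'
#' The resting uterine tone is estimated as a rolling 10-minute 10th
#' percentile of the UC series (evaluated on a coarse grid and linearly
#' interpolated). Maximal runs where the signal exceeds tone + 10 units and
#' lasts between 20 s and 240 s are reported as contractions, with the
#' in-run argmax as the peak.
#'
#' @param uc smoothed UC series.
#' @param min_amp amplitude threshold above tone (units, default 10).
#' @param min_dur_s,max_dur_s duration band in seconds (20, 240).
#' @param tone_window_s window for the rolling tone quantile (600 s).
#' @param fs sampling rate.
#' @return Data frame with columns `onset`, `peak`, `offset` (samples,
#'   half-open) and `amplitude_above_tone`.
#' @export
detect_contractions <- function(uc, min_amp = 10, min_dur_s = 20,
                                max_dur_s = 240, tone_window_s = 600,
                                fs = CTG_HZ) {
  n <- length(uc)
  half <- round(tone_window_s * fs / 2)
  grid <- unique(c(seq(1L, n, by = 30L * fs), n))
  tone_grid <- vapply(grid, function(i) {
    w <- uc[max(1L, i - half):min(n, i + half)]
    w <- w[!is.na(w)]
    if (!length(w)) return(NA_real_)
    quantile(w, 0.10, names = FALSE)
  }, 1.0)
  tone <- approx(grid, tone_grid, xout = seq_len(n), rule = 2)$y
  over <- !is.na(uc) & (uc - tone > min_amp)
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    len <- r$lengths[k]
    if (len < min_dur_s * fs || len > max_dur_s * fs) next
    idx <- starts[k]:ends[k]
    pk <- idx[which.max(uc[idx] - tone[idx])]
    out[[length(out) + 1L]] <- data.frame(
      onset = starts[k], peak = pk, offset = ends[k] + 1L,
      amplitude_above_tone = uc[pk] - tone[pk])
  }
  if (!length(out))
    return(data.frame(onset = integer(), peak = integer(),
                      offset = integer(), amplitude_above_tone = numeric()))
  do.call(rbind, out)
}

#' Type detected FHR events by the FIGO duration and contraction rules
#'
#' Positive excursions lasting 15 s to 2 min are accelerations; 2 min and
#' longer are prolonged accelerations. Negative excursions are typed in
#' strict precedence order: duration over 5 min gives a severe deceleration;
#' 2--5 min a prolonged deceleration; otherwise, if the deceleration's onset
#' falls after the peak and before the end of its paired contraction (the
#' contraction with maximal overlap) it is a late deceleration; otherwise a
#' drop from onset to nadir within 30 s makes it a variable deceleration;
#' anything left is a light deceleration. The precedence makes the subtype
#' partition exhaustive and deterministic.
#'
#' @param events data frame from [detect_events()].
#' @param contractions data frame from [detect_contractions()].
#' @param fs sampling rate.
#' @return `events` with `type` filled in and a `paired_contraction` column
#'   (row index into `contractions`, `NA` when unpaired).
#' @export
classify_events <- function(events, contractions, fs = CTG_HZ) {
  if (!nrow(events)) {
    events$paired_contraction <- integer(0)
    return(events)
  }
  events$paired_contraction <- NA_integer_
  for (k in seq_len(nrow(events))) {
    dur_s <- (events$offset[k] - events$onset[k]) / fs
    if (events$peak_deviation_bpm[k] > 0) {
      events$type[k] <- if (dur_s < 120) "acceleration" else
        "prolonged_acceleration"
      next
    }
    ## deceleration taxonomy, in precedence order
    if (dur_s > 300) { events$type[k] <- "severe_deceleration"; next }
    if (dur_s >= 120) { events$type[k] <- "prolonged_deceleration"; next }
    paired <- NA_integer_
    if (nrow(contractions)) {
      ov <- pmin(events$offset[k], contractions$offset) -
        pmax(events$onset[k], contractions$onset)
      if (any(ov > 0)) paired <- which.max(ov)
    }
    events$paired_contraction[k] <- paired
    if (!is.na(paired) &&
        events$onset[k] > contractions$peak[paired] &&
        events$onset[k] < contractions$offset[paired] &&
        dur_s > 15) {
      events$type[k] <- "late_deceleration"
      next
    }
    nadir_s <- (events$peak_index[k] - events$onset[k]) / fs
    events$type[k] <- if (nadir_s <= 30) "variable_deceleration" else
      "light_deceleration"
  }
  events
}
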