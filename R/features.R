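FEATURE_NAMES <- c(
  "baseline_bpm", "n_accelerations", "n_decelerations", "n_contractions",
  "n_variable_decel", "n_severe_decel", "n_late_decel", "n_prolonged_decel",
  "n_prolonged_accel", "n_light_decel", "hist_width_bpm", "hist_min_bpm",
  "hist_max_bpm", "hist_n_peaks", "hist_mean", "hist_median", "hist_mode",
  "variability_bpm")

#' FHR histogram features
#'
#' Bins the non-missing FHR samples into 1 bpm bins and reports the
#' min/max/width of the observed values, mean and median, the mode (centre
#' of the most populated bin, lowest on ties), and the number of histogram
#' peaks: local maxima of the 3-bin-smoothed counts holding at least 5% of
#' the total mass.
#'
#' @param fhr FHR series (bpm), `NA` allowed.
#' @return Named numeric vector with elements `width`, `min`, `max`,
#'   `n_peaks`, `mean`, `median`, `mode`.
#' @export
histogram_features <- function(fhr) {
  x <- fhr[!is.na(fhr)]
  if (!length(x))
    stop("histogram_features: no non-missing samples (unrecoverable)",
         call. = FALSE)
  lo <- min(x); hi <- max(x)
  centers <- seq(floor(lo), ceiling(hi), by = 1)
  counts <- tabulate(pmin(pmax(round(x - centers[1L]) + 1L, 1L),
                          length(centers)), nbins = length(centers))
  mode <- centers[which.max(counts)]
  ## 3-bin smoothing then prominence-floored local maxima
  cs <- counts
  if (length(counts) >= 3L)
    cs <- as.numeric(stats::filter(counts, rep(1 / 3, 3), sides = 2))
  cs[is.na(cs)] <- counts[is.na(cs)]
  floor_mass <- 0.05 * sum(counts)
  n_peaks <- 0L
  nb <- length(cs)
  if (nb == 1L) {
    n_peaks <- 1L
  } else {
    for (i in seq_len(nb)) {
      left <- if (i > 1L) cs[i - 1L] else -Inf
      right <- if (i < nb) cs[i + 1L] else -Inf
      if (cs[i] > left && cs[i] >= right && cs[i] >= floor_mass)
        n_peaks <- n_peaks + 1L
    }
    if (n_peaks == 0L) n_peaks <- 1L
  }
  c(width = hi - lo, min = lo, max = hi, n_peaks = as.numeric(n_peaks),
    mean = mean(x), median = median(x), mode = mode)
}

#' Short-term FHR variability
#'
#' Mean absolute successive difference of the (gap-repaired, unsmoothed)
#' FHR over event-free samples — the event-free mask comes from the
#' baseline estimate so accelerations and decelerations do not inflate the
#' statistic. Zero for a constant trace; equivariant under amplitude
#' scaling of the deviations.
#'
#' @param fhr FHR series in bpm (unsmoothed, gaps repaired).
#' @param baseline an `fhr_baseline` object (for the event-free mask).
#' @return Variability in bpm.
#' @export
fhr_variability <- function(fhr, baseline) {
  stopifnot(inherits(baseline, "fhr_baseline"))
  keep <- baseline$event_free_mask & !is.na(fhr)
  ok <- keep[-length(keep)] & keep[-1L]
  if (!any(ok))
    stop("fhr_variability: no event-free sample pairs (undefined)",
         call. = FALSE)
  d <- diff(fhr)
  mean(abs(d[ok]))
}

#' pH-based acidosis label
#'
#' Cord pH below the threshold (default 7.2) is acidotic (1); the threshold
#' itself and anything above is non-acidotic (0).
#'
#' @param ph cord pH value(s).
#' @param threshold decision threshold, in (6.5, 7.6).
#' @return Integer vector of 0/1 labels.
#' @export
label_from_ph <- function(ph, threshold = 7.2) {
  if (threshold <= 6.5 || threshold >= 7.6)
    stop("label_from_ph: threshold must lie in (6.5, 7.6)", call. = FALSE)
  if (!is.numeric(ph) || any(is.na(ph)))
    stop("label_from_ph: pH must be numeric and non-missing", call. = FALSE)
  as.integer(ph < threshold)
}

#' Extract the FIGO-style feature vector from a CTG record
#'
#' Runs the full single-record pipeline: gap repair, moving-average
#' smoothing, iterative baseline estimation, event detection and typing,
#' contraction detection, histogram features and short-term variability.
#'
#' @param record a [ctg_record()], at least 2 min of usable signal
#'   (10 min or more recommended).
#' @param smooth_window_s smoothing window in seconds.
#' @param max_gap_s longest signal-loss gap repaired by interpolation.
#' @return An object of class `ctg_features`: list with `features` (named
#'   numeric vector of the 18 features), `baseline` (`fhr_baseline`),
#'   `events`, `contractions`, `record_id`, `ph` and `label` (`NA` when the
#'   record has no pH).
#' @export
extract_features <- function(record, smooth_window_s = 4, max_gap_s = 15) {
  stopifnot(inherits(record, "ctg_record"))
  rec <- interpolate_gaps(record, max_gap_s)
  fhr_s <- smooth_ma(rec$fhr, smooth_window_s)
  uc_s <- smooth_ma(rec$uc, smooth_window_s)
  bl <- estimate_baseline(fhr_s)
  ev <- detect_events(fhr_s, bl$M)
  contr <- detect_contractions(uc_s)
  ev <- classify_events(ev, contr)
  hist_f <- histogram_features(rec$fhr)
  var_bpm <- fhr_variability(rec$fhr, bl)
  cnt <- function(ty) sum(ev$type == ty)
  decel_types <- c("light_deceleration", "variable_deceleration",
                   "late_deceleration", "prolonged_deceleration",
                   "severe_deceleration")
  feats <- c(
    baseline_bpm = bl$M,
    n_accelerations = cnt("acceleration"),
    n_decelerations = sum(ev$type %in% decel_types),
    n_contractions = nrow(contr),
    n_variable_decel = cnt("variable_deceleration"),
    n_severe_decel = cnt("severe_deceleration"),
    n_late_decel = cnt("late_deceleration"),
    n_prolonged_decel = cnt("prolonged_deceleration"),
    n_prolonged_accel = cnt("prolonged_acceleration"),
    n_light_decel = cnt("light_deceleration"),
    hist_width_bpm = unname(hist_f["width"]),
    hist_min_bpm = unname(hist_f["min"]),
    hist_max_bpm = unname(hist_f["max"]),
    hist_n_peaks = unname(hist_f["n_peaks"]),
    hist_mean = unname(hist_f["mean"]),
    hist_median = unname(hist_f["median"]),
    hist_mode = unname(hist_f["mode"]),
    variability_bpm = var_bpm)
  structure(list(features = feats, baseline = bl, events = ev,
                 contractions = contr, record_id = record$record_id,
                 ph = record$ph,
                 label = if (is.na(record$ph)) NA_integer_ else
                   label_from_ph(record$ph)),
            class = "ctg_features")
}

#' @export
print.ctg_features <- function(x, ...) {
  cat("CTG features for '", x$record_id, "'\n", sep = "")
  f <- x$features
  cat(sprintf("  baseline %.1f bpm, variability %.2f bpm\n",
              f["baseline_bpm"], f["variability_bpm"]))
  cat(sprintf("  events: %d accel / %d decel (%d late, %d variable, %d light, %d prolonged, %d severe), %d contractions\n",
              f["n_accelerations"], f["n_decelerations"], f["n_late_decel"],
              f["n_variable_decel"], f["n_light_decel"],
              f["n_prolonged_decel"], f["n_severe_decel"],
              f["n_contractions"]))
  if (!is.na(x$ph))
    cat(sprintf("  pH %.2f -> label %d\n", x$ph, x$label))
  invisible(x)
}

#' @export
as.data.frame.ctg_features <- function(x, ...) {
  out <- as.data.frame(as.list(x$features))
  out <- cbind(data.frame(record_id = x$record_id, stringsAsFactors = FALSE),
               out, data.frame(ph = x$ph, label = x$label))
  out
}

#' Feature table for a cohort
#'
#' Applies [extract_features()] to each generated or loaded record and binds
#' the results into one data frame with `record_id`, the 18 features, `ph`
#' and `label` columns.
#'
#' @param records list of [ctg_record()]s, or of `list(record=, truth=)`
#'   pairs as produced by [generate_cohort()].
#' @param ... passed to [extract_features()].
#' @return Data frame, one row per record.
#' @export
cohort_features <- function(records, ...) {
  rows <- lapply(records, function(r) {
    rec <- if (inherits(r, "ctg_record")) r else r$record
    as.data.frame(extract_features(rec, ...))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation matrix of a feature table
#'
#' Constant columns have undefined correlations; they are reported as `NA`
#' and named in the `"constant_features"` attribute rather than silently
#' zero-filled.
#'
#' @param table data frame of numeric feature columns (non-numeric columns
#'   such as `record_id` are dropped).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
feature_correlation <- function(table) {
  num <- table[vapply(table, is.numeric, TRUE)]
  if (nrow(num) < 2L)
    stop("feature_correlation: need at least 2 rows", call. = FALSE)
  sds <- vapply(num, sd, 1.0)
  const <- names(num)[sds == 0 | is.na(sds)]
  m <- suppressWarnings(cor(as.matrix(num)))
  diag(m) <- 1
  attr(m, "constant_features") <- const
  m
}

#' Drop count features with too little support
#'
#' Count-valued features that are nonzero in fewer than `min_support`
#' records carry no class information at cohort scale and are removed, with
#' a report of what was dropped.
#'
#' @param table feature data frame.
#' @param min_support minimum number of rows with a nonzero count.
#' @param count_cols columns treated as counts; default: every `n_*` column.
#' @return List with `table` (reduced) and `dropped` (character vector).
#' @export
prune_rare_features <- function(table, min_support = 3,
                                count_cols = grep("^n_", names(table),
                                                  value = TRUE)) {
  support <- vapply(count_cols, function(cn) sum(table[[cn]] != 0), 1L)
  dropped <- count_cols[support < min_support]
  list(table = table[setdiff(names(table), dropped)], dropped = dropped)
}
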