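test_that("baseline of a constant trace is the constant, in one iteration", {
  bl <- estimate_baseline(rep(140, 10 * 60 * fs))
  expect_equal(bl$M, 140)
  expect_equal(bl$iterations, 1L)
  expect_true(bl$converged)
  expect_error(estimate_baseline(rep(NA_real_, 4000)), "unrecoverable")
  expect_error(estimate_baseline(rep(140, 100)), "2 min")
})

test_that("iterative baseline matches the hand-iterated loop on event traces", {
  ## one acceleration
  x <- add_hump(rep(140, 2400), at_s = 200, dur_s = 60, amp = 30)
  bl <- estimate_baseline(x)
  or <- oracle_baseline(x)
  expect_lt(abs(bl$M - 140), 0.5)
  expect_lt(abs(bl$M - or$M), 1e-9)
  expect_lte(bl$iterations, 5L)
  ## acceleration + deceleration, asymmetric
  y <- add_hump(add_hump(rep(132, 4800), 100, 90, 25), 700, 45, -20)
  bl2 <- estimate_baseline(y)
  or2 <- oracle_baseline(y)
  expect_lt(abs(bl2$M - or2$M), 1e-9)
  expect_lt(abs(bl2$M - 132), 0.5)
  expect_lte(bl2$iterations, 5L)
  ## idempotence: re-running from the converged value barely moves
  bl3 <- estimate_baseline(y)
  expect_lte(abs(bl3$N - bl2$M), 0.5)
})

test_that("event detection applies the 15 bpm / 15 s rules", {
  x <- add_hump(rep(140, 1200), 100, 30, 20)
  ev <- detect_events(x, 140)
  expect_equal(nrow(ev), 1L)
  expect_gt(ev$peak_deviation_bpm, 0)
  ## 10 s hump: too short
  expect_equal(nrow(detect_events(add_hump(rep(140, 1200), 100, 10, 20), 140)),
               0L)
  ## 12 bpm hump: too shallow
  expect_equal(nrow(detect_events(add_hump(rep(140, 1200), 100, 30, 12), 140)),
               0L)
  expect_equal(nrow(detect_events(rep(140, 1200), 140)), 0L)
})

test_that("event detection equals the brute-force interval scan on 5-min traces", {
  for (s in 1:20) {
    set.seed(s)
    x <- rep(140, 5 * 60 * fs)
    for (h in seq_len(sample(1:4, 1)))
      x <- add_hump(x, runif(1, 10, 240), runif(1, 8, 50),
                    sample(c(-1, 1), 1) * runif(1, 8, 30))
    x <- x + rnorm(length(x), 0, 0.5)
    xs <- smooth_ma(x, 4)
    got <- detect_events(xs, 140)
    want <- oracle_detect_events(xs, 140)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$onset, unname(want[, "onset"]))
      expect_equal(got$offset, unname(want[, "offset"]))
    }
  }
})

test_that("deceleration taxonomy follows the duration and contraction rules", {
  contr <- data.frame(onset = 100, peak = 220, offset = 400,
                      amplitude_above_tone = 25)
  mk <- function(onset, dur_s, nadir_frac = 0.5, dev = -30) {
    data.frame(type = "unspecified", onset = onset,
               offset = onset + dur_s * fs,
               peak_deviation_bpm = dev,
               peak_index = onset + round(nadir_frac * dur_s * fs))
  }
  ## 180 s dip, no contraction pairing -> prolonged
  ev <- classify_events(mk(1000, 180), contr)
  expect_equal(ev$type, "prolonged_deceleration")
  ## > 5 min -> severe
  expect_equal(classify_events(mk(1000, 330), contr)$type,
               "severe_deceleration")
  ## onset 10 s after the contraction peak, 40 s -> late
  expect_equal(classify_events(mk(260, 40), contr)$type, "late_deceleration")
  ## onset before the peak, gradual (nadir at 60 s) -> light
  expect_equal(classify_events(mk(150, 90, nadir_frac = 2 / 3), contr)$type,
               "light_deceleration")
  ## abrupt drop (nadir at 10 s), away from the contraction -> variable
  expect_equal(classify_events(mk(900, 40, nadir_frac = 0.25), contr)$type,
               "variable_deceleration")
  ## positive events: 2-5 min band mirrors to prolonged acceleration
  acc <- mk(1000, 150, dev = +25)
  expect_equal(classify_events(acc, contr)$type, "prolonged_acceleration")
  expect_equal(classify_events(mk(1000, 60, dev = +25), contr)$type,
               "acceleration")
})

test_that("every deceleration gets exactly one subtype", {
  decel_types <- c("light_deceleration", "variable_deceleration",
                   "late_deceleration", "prolonged_deceleration",
                   "severe_deceleration")
  for (s in 1:10) {
    g <- generate_record(regime_defaults("acidotic", duration_s = 1200,
                                         seed = 100 + s))
    fv <- extract_features(g$record)
    ev <- fv$events
    neg <- ev[ev$peak_deviation_bpm < 0, ]
    expect_true(all(neg$type %in% decel_types))
    expect_equal(unname(fv$features["n_decelerations"]),
                 sum(unname(fv$features[c("n_variable_decel", "n_severe_decel",
                                          "n_late_decel", "n_prolonged_decel",
                                          "n_light_decel")])))
  }
})

test_that("contraction detection applies the 10-unit / 20-240 s rule", {
  uc <- rep(8, 1200)
  uc <- add_hump(uc, 100, 60, 15)
  ctr <- detect_contractions(uc)
  expect_equal(nrow(ctr), 1L)
  expect_equal(ctr$peak, which.max(uc))
  ## 10 s bump: below the duration floor
  expect_equal(nrow(detect_contractions(add_hump(rep(8, 1200), 100, 10, 15))),
               0L)
  ## shallow bump never crosses tone + 10
  expect_equal(nrow(detect_contractions(add_hump(rep(8, 1200), 100, 60, 9))),
               0L)
  expect_equal(nrow(detect_contractions(rep(8, 1200))), 0L)
})

test_that("histogram features match direct binning", {
  h <- histogram_features(rep(140, 500))
  expect_equal(unname(h[c("width", "mean", "median", "mode", "n_peaks")]),
               c(0, 140, 140, 140, 1))
  bimodal <- c(rep(120, 500), rep(160, 500))
  hb <- histogram_features(bimodal)
  expect_equal(unname(hb["width"]), 40)
  expect_equal(unname(hb["n_peaks"]), 2)
  ramp <- seq(120, 160, length.out = 4000)
  hr <- histogram_features(ramp)
  expect_equal(unname(hr["width"]), 40)
  expect_equal(unname(hr["mean"]), 140)
  expect_error(histogram_features(rep(NA_real_, 10)), "unrecoverable")
})

test_that("variability is the mean absolute successive difference off events", {
  const <- rep(140, 2400)
  bl <- estimate_baseline(const)
  expect_equal(fhr_variability(const, bl), 0)
  alt <- 140 + rep_len(c(2, -2), 2400)
  bl_alt <- estimate_baseline(smooth_ma(alt, 4))
  expect_equal(fhr_variability(alt, bl_alt), 4)
  ## event samples are excluded: variability equals that of the quiet part
  x <- add_hump(alt, 200, 60, 30)
  bl_x <- estimate_baseline(smooth_ma(x, 4))
  quiet <- bl_x$event_free_mask
  d_ok <- quiet[-length(quiet)] & quiet[-1]
  expect_equal(fhr_variability(x, bl_x), mean(abs(diff(x))[d_ok]))
  expect_lt(abs(fhr_variability(x, bl_x) - 4), 0.2)
})

test_that("feature extraction composes the pipeline deterministically", {
  p <- clean_params("acidotic", seed = 17, n_accel = 2, n_decel = 1,
                    decel_type_mix = c(light = 0, variable = 0, late = 1,
                                       prolonged = 0, severe = 0))
  g <- generate_record(p)
  fv <- extract_features(g$record)
  expect_equal(unname(fv$features["n_accelerations"]), 2)
  expect_equal(unname(fv$features["n_late_decel"]), 1)
  expect_equal(unname(fv$features["n_contractions"]),
               nrow(g$truth$contractions))
  expect_identical(fv$features, extract_features(g$record)$features)
  ## flat record: no events, baseline recovered
  fv_flat <- extract_features(flat_record())
  cnts <- fv_flat$features[grep("^n_", names(fv_flat$features))]
  expect_true(all(cnts[setdiff(names(cnts), "hist_n_peaks")] == 0))
  expect_equal(unname(fv_flat$features["baseline_bpm"]), 140)
  expect_error(extract_features(flat_record(minutes = 1)), "2 min")
})

test_that("adding a constant shifts level features and nothing else", {
  g <- generate_record(regime_defaults("acidotic", duration_s = 1200,
                                       seed = 31))
  f1 <- extract_features(g$record)$features
  shifted <- g$record
  shifted$fhr <- shifted$fhr + 10
  f2 <- extract_features(shifted)$features
  level <- c("baseline_bpm", "hist_min_bpm", "hist_max_bpm", "hist_mean",
             "hist_median", "hist_mode")
  expect_equal(f2[level], f1[level] + 10)
  rest <- setdiff(names(f1), level)
  expect_equal(f2[rest], f1[rest], tolerance = 1e-10)
})

test_that("pH labeling uses a strict threshold at 7.2", {
  expect_identical(label_from_ph(7.19), 1L)
  expect_identical(label_from_ph(7.20), 0L)
  expect_identical(label_from_ph(7.35), 0L)
  expect_identical(label_from_ph(c(6.9, 7.2, 7.5)), c(1L, 0L, 0L))
  expect_error(label_from_ph(NaN), "numeric")
  expect_error(label_from_ph(7.0, threshold = 6.4), "6.5")
})

test_that("feature correlations flag constants instead of zero-filling", {
  set.seed(8)
  tab <- data.frame(a = rnorm(1000), b = rnorm(1000))
  tab$c <- 2 * tab$a + 3
  tab$d <- 1
  m <- feature_correlation(tab)
  expect_equal(diag(m), setNames(rep(1, 4), c("a", "b", "c", "d")))
  expect_equal(m["a", "c"], 1)
  expect_lt(abs(m["a", "b"]), 0.1)
  expect_true(is.na(m["a", "d"]))
  expect_equal(attr(m, "constant_features"), "d")
  expect_error(feature_correlation(tab[1, ]), "2 rows")
})

test_that("rare count features are pruned with a report", {
  tab <- data.frame(baseline_bpm = rnorm(94, 140),
                    n_late_decel = rpois(94, 2),
                    n_prolonged_accel = c(1, 2, rep(0, 92)))
  pr <- prune_rare_features(tab, min_support = 3)
  expect_equal(pr$dropped, "n_prolonged_accel")
  expect_false("n_prolonged_accel" %in% names(pr$table))
  expect_true("n_late_decel" %in% names(pr$table))
  tab2 <- data.frame(n_accelerations = rpois(20, 5) + 1)
  pr2 <- prune_rare_features(tab2)
  expect_identical(pr2$table, tab2)
  expect_length(pr2$dropped, 0)
})
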