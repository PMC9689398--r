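test_that("record construction enforces the signal invariants", {
  r <- ctg_record(c(140, 0, 150, NA), c(10, 12, 11, 9), ph = 7.15)
  expect_equal(r$missing_mask, c(FALSE, TRUE, FALSE, TRUE))
  expect_true(all(is.na(r$fhr[r$missing_mask])))
  expect_error(ctg_record(numeric(0), numeric(0)), "empty")
  expect_error(ctg_record(c(140, 150), 10), "equal length")
  expect_error(ctg_record(c(140, 300), c(10, 10)), "\\[30, 250\\]")
  expect_error(ctg_record(c(140, 140), c(10, -1)), "negative UC")
})

test_that("write/read round-trips records exactly, including pH and gaps", {
  tmp <- withr::local_tempdir()
  for (s in 1:20) {
    g <- generate_record(regime_defaults(
      if (s %% 2) "acidotic" else "non_acidotic",
      duration_s = 300, seed = s))
    path <- file.path(tmp, paste0("r", s, ".csv"))
    write_ctg(g$record, path)
    back <- read_ctg(path)
    expect_equal(back$fhr, g$record$fhr)
    expect_equal(back$uc, g$record$uc)
    expect_equal(back$missing_mask, g$record$missing_mask)
    expect_equal(back$ph, g$record$ph)
    expect_equal(back$record_id, g$record$record_id)
  }
})

test_that("reader flags malformed input with a useful error", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "bad.csv")
  writeLines("time_s,fhr,uc", p)
  expect_error(read_ctg(p), "no data rows")
  writeLines(c("time_s,fhr,uc", "0,140,10", "0.25,150"), p)
  expect_error(read_ctg(p), "malformed row at line 3")
  writeLines(c("a,b", "1,2"), p)
  expect_error(read_ctg(p), "'fhr' and 'uc'")
  expect_error(read_ctg(file.path(tmp, "absent.csv")), "no such file")
})

test_that("annotation sidecars round-trip", {
  tmp <- withr::local_tempdir()
  ann <- data.frame(record_id = "r1", channel = c("fhr", "uc"),
                    type = c("acceleration", "contraction"),
                    onset_s = c(10, 40), offset_s = c(40, 100),
                    peak_s = c(25, 70))
  p <- file.path(tmp, "ann.csv")
  write_annotations(ann, p)
  expect_equal(read_annotations(p), ann)
})

test_that("moving-average smoothing matches hand-computed averages", {
  expect_equal(smooth_ma(rep(140, 100), 4), rep(140, 100))
  x <- c(0, 0, 0, 4, 0, 0, 0)
  expect_equal(smooth_ma(x, 1.25)[4], 0.8)   # 5-sample centred mean
  alt <- rep(c(130, 150), 10)
  sm <- smooth_ma(alt, 0.5)                  # 2 samples rounds up to 3
  inner <- sm[2:19]
  expect_true(all(abs(inner - 140) < abs(alt[2:19] - 140)))
  expect_error(smooth_ma(1:5, 4), "longer than series")
})

test_that("smoothing never leaves the data range and ignores missing", {
  for (s in 1:25) {
    set.seed(s)
    x <- 140 + cumsum(rnorm(400))
    x[sample(400, 20)] <- NA
    sm <- smooth_ma(x, runif(1, 0.5, 10))
    expect_true(all(sm >= min(x, na.rm = TRUE) - 1e-12, na.rm = TRUE))
    expect_true(all(sm <= max(x, na.rm = TRUE) + 1e-12, na.rm = TRUE))
  }
})

test_that("gap interpolation repairs short gaps linearly and leaves long ones", {
  fhr <- rep(140, 400)
  fhr[101:108] <- 0                       # 2 s gap
  fhr[301:302] <- 142                     # anchor a ramp target
  fhr[200:320] <- NA                      # 30 s gap (> 15 s)
  fhr[300:320] <- 140
  rec <- ctg_record(fhr, rep(8, 400))
  rep_rec <- interpolate_gaps(rec, 15)
  expect_false(any(rep_rec$missing_mask[101:108]))
  expect_equal(rep_rec$fhr[101:108], rep(140, 8))   # flat anchors -> flat fill
  expect_true(all(rep_rec$missing_mask[200:299]))   # long gap stays masked
  ## non-missing samples untouched
  expect_equal(rep_rec$fhr[!rec$missing_mask], rec$fhr[!rec$missing_mask])
  ## ramp is linear and monotone between its anchors
  fhr2 <- rep(140, 400); fhr2[51:58] <- NA; fhr2[59:400] <- 142
  rec2 <- interpolate_gaps(ctg_record(fhr2, rep(8, 400)), 15)
  expect_true(all(diff(rec2$fhr[50:59]) > 0))
  expect_true(all(rec2$fhr[51:58] > 140 & rec2$fhr[51:58] < 142))
  ## identity when nothing is missing
  clean <- ctg_record(rep(140, 100), rep(8, 100))
  expect_identical(interpolate_gaps(clean, 15), clean)
  allmiss <- ctg_record(rep(0, 100), rep(8, 100))
  expect_error(interpolate_gaps(allmiss, 15), "unrecoverable")
})

test_that("standardize is the exact z-transform and inverts", {
  expect_equal(standardize(rep(5, 4), 5, 2), rep(0, 4))
  expect_equal(standardize(c(140, 150), 140, 10), c(0, 1))
  x <- rnorm(50, 140, 7)
  expect_equal(destandardize(standardize(x, 140, 7), 140, 7), x)
  expect_error(standardize(1:3, 0, 0), "positive")
})
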