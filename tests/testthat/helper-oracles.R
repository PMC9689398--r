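# Independent oracles and fixture builders used across the test files.
# These deliberately use different algorithms from the package internals.

fs <- 4

# A flat record: constant FHR and resting-tone UC.
flat_record <- function(minutes = 10, fhr = 140, uc = 8) {
  n <- minutes * 60 * fs
  ctg_record(rep(fhr, n), rep(uc, n), record_id = "flat")
}

# Add a raised-cosine hump of `amp` bpm and `dur_s` seconds at `at_s`.
add_hump <- function(x, at_s, dur_s, amp) {
  m <- round(dur_s * fs)
  i <- round(at_s * fs) + seq_len(m)
  x[i] <- x[i] + amp * 0.5 * (1 - cos(2 * pi * (seq_len(m) - 0.5) / m))
  x
}

# Brute-force event-detection oracle: enumerate maximal same-sign runs of
# (x - baseline) with a split/which approach (the package uses rle), then
# apply the 15 bpm / 15 s thresholds.
oracle_detect_events <- function(x, baseline) {
  dev <- x - baseline
  sgn <- sign(dev)
  sgn[is.na(sgn)] <- 0
  out <- list()
  i <- 1L
  n <- length(x)
  while (i <= n) {
    if (sgn[i] == 0) { i <- i + 1L; next }
    j <- i
    while (j < n && sgn[j + 1L] == sgn[i]) j <- j + 1L
    if ((j - i + 1L) >= 15 * fs && max(abs(dev[i:j])) >= 15)
      out[[length(out) + 1L]] <- c(onset = i, offset = j + 1L)
    i <- j + 1L
  }
  if (!length(out)) return(matrix(numeric(0), ncol = 2,
                                  dimnames = list(NULL, c("onset", "offset"))))
  do.call(rbind, out)
}

# Hand-iterated baseline loop (the flowchart executed literally, using the
# oracle event scan rather than the package detector).
oracle_baseline <- function(x, tol = 0.5, max_iter = 50) {
  good <- !is.na(x)
  M <- mean(x[good])
  for (it in seq_len(max_iter)) {
    ev <- oracle_detect_events(x, M)
    keep <- good
    if (nrow(ev))
      for (k in seq_len(nrow(ev))) keep[ev[k, 1]:(ev[k, 2] - 1L)] <- FALSE
    N <- if (any(keep)) mean(x[keep]) else M
    if (abs(N - M) <= tol) return(list(M = N, iterations = it))
    M <- N
  }
  list(M = M, iterations = max_iter)
}

# All-pairs dominance oracle for the Pareto front.
oracle_pareto <- function(points) {
  keep <- rep(TRUE, nrow(points))
  for (i in seq_len(nrow(points))) {
    if (is.na(points$accuracy[i])) { keep[i] <- FALSE; next }
    for (j in seq_len(nrow(points))) {
      if (i == j || is.na(points$accuracy[j])) next
      if (points$n_classified[j] >= points$n_classified[i] &&
          points$accuracy[j] >= points$accuracy[i] &&
          (points$n_classified[j] > points$n_classified[i] ||
           points$accuracy[j] > points$accuracy[i])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  points[keep, , drop = FALSE]
}

# Plain-R LSTM forward pass over one window (independent of the compiled
# implementation).
oracle_lstm_forward <- function(params, window) {
  H <- nrow(params$W)
  sig <- function(z) 1 / (1 + exp(-z))
  y <- rep(0, H)
  C <- rep(0, H)
  for (x_t in window) {
    a <- as.numeric(x_t * params$U + y %*% params$W + params$b)
    i <- sig(a[1:H]); f <- sig(a[(H + 1):(2 * H)])
    g <- tanh(a[(2 * H + 1):(3 * H)]); o <- sig(a[(3 * H + 1):(4 * H)])
    C <- f * C + i * g
    y <- o * tanh(C)
  }
  z <- y
  for (k in seq_along(params$dense_W))
    z <- as.numeric(z %*% params$dense_W[[k]] + params$dense_b[[k]])
  z
}

# Noise-free generator settings for morphology studies.
clean_params <- function(class_label, seed, duration_s = 1200, ...) {
  regime_defaults(class_label, noise_sd_bpm = 0, dropout_rate_per_hr = 0,
                  baseline_drift_sd = 0, baseline_sd_between = 0,
                  variability_sd_between = 0, duration_s = duration_s,
                  seed = seed, ...)
}

# Two well-separated Gaussian blobs in two features with pure labels.
make_blobs <- function(n = 40, sep = 8, seed = 1) {
  set.seed(seed)
  half <- n / 2
  x <- rbind(cbind(rnorm(half), rnorm(half)),
             cbind(rnorm(half) + sep, rnorm(half) + sep))
  colnames(x) <- c("f1", "f2")
  list(x = as.data.frame(x), labels = rep(c(0L, 1L), each = half))
}

type_counts <- function(types, levels) table(factor(types, levels = levels))
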