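# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so generation never perturbs session randomness.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Truncated-normal draw via inverse-CDF (exact and cheap for our ranges).
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  p <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(p, mean, sd)
}

# Raised-cosine hump of `m` samples peaking at `amp` (signed).
raised_cosine <- function(m, amp) {
  amp * 0.5 * (1 - cos(2 * pi * (seq_len(m) - 0.5) / m))
}

# Variable-deceleration shape: steep linear drop to the nadir within
# `drop_s` seconds, a short nadir plateau, then linear recovery.
variable_dip <- function(m, amp, drop_s, fs = CTG_HZ) {
  t <- (seq_len(m) - 0.5) / fs
  dur <- m / fs
  knots_t <- c(0, drop_s, 0.6 * dur, dur)
  knots_v <- c(0, -abs(amp), -abs(amp), 0)
  approx(knots_t, knots_v, xout = t, rule = 2)$y
}

#' Parameters for the synthetic CTG generator
#'
#' Bundles every tunable of [generate_record()]. The two stock regimes
#' returned by [regime_defaults()] encode the clinical contrast the
#' classifier must learn: acidotic tracings have fewer accelerations, more
#' (and more often late/variable) decelerations, and reduced short-term
#' variability.
#'
#' @param duration_s recording length in seconds (default 1800 = 30 min).
#' @param baseline_bpm resting FHR level, beats/min (100--170).
#' @param baseline_drift_sd sd (bpm) of the slow baseline wander.
#' @param accel_rate_per_hr,decel_rate_per_hr expected event rates per hour
#'   (counts drawn Poisson unless `n_accel`/`n_decel` fix them).
#' @param decel_type_mix named probabilities over
#'   `light, variable, late, prolonged, severe`; must sum to 1.
#' @param contraction_period_s,contraction_jitter_sd contraction cadence.
#' @param contraction_amp peak amplitude above resting tone (units, > 10).
#' @param contraction_tone resting uterine tone (units).
#' @param noise_sd_bpm Gaussian sensor-noise sd on FHR (UC noise is half).
#' @param dropout_rate_per_hr expected signal-loss gaps per hour.
#' @param variability_bpm short-term variability: beat-to-beat alternation
#'   whose mean absolute successive difference equals this value.
#' @param ph_mean,ph_sd class-conditional cord-pH distribution (truncated to
#'   the class side of the 7.2 threshold).
#' @param baseline_sd_between,variability_sd_between between-record sd of the
#'   baseline level and of the variability: each generated record draws its
#'   own values around the regime means, so a cohort is heterogeneous the
#'   way real patients are and the classes overlap rather than separating
#'   trivially. Set to 0 for exactly reproducible event morphology studies.
#' @param class_label `"acidotic"` or `"non_acidotic"`.
#' @param n_accel,n_decel optional exact event counts (override the rates).
#' @param seed integer RNG seed.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(duration_s = 1800,
                         baseline_bpm = 140,
                         baseline_drift_sd = 2,
                         accel_rate_per_hr = 12,
                         decel_rate_per_hr = 2,
                         decel_type_mix = c(light = 0.7, variable = 0.15,
                                            late = 0.1, prolonged = 0.05,
                                            severe = 0),
                         contraction_period_s = 180,
                         contraction_jitter_sd = 20,
                         contraction_amp = 30,
                         contraction_tone = 8,
                         noise_sd_bpm = 2,
                         dropout_rate_per_hr = 6,
                         variability_bpm = 10,
                         ph_mean = 7.3,
                         ph_sd = 0.06,
                         baseline_sd_between = 4,
                         variability_sd_between = 2.5,
                         class_label = c("non_acidotic", "acidotic"),
                         n_accel = NULL,
                         n_decel = NULL,
                         seed = 1L) {
  class_label <- match.arg(class_label)
  mix_names <- c("light", "variable", "late", "prolonged", "severe")
  decel_type_mix <- decel_type_mix[mix_names]
  names(decel_type_mix) <- mix_names
  decel_type_mix[is.na(decel_type_mix)] <- 0
  if (abs(sum(decel_type_mix) - 1) > 1e-9)
    stop("synth_params: decel_type_mix must sum to 1", call. = FALSE)
  if (any(decel_type_mix < 0) || accel_rate_per_hr < 0 || decel_rate_per_hr < 0 ||
      dropout_rate_per_hr < 0 || noise_sd_bpm < 0 || variability_bpm < 0)
    stop("synth_params: rates and noise levels must be nonnegative", call. = FALSE)
  if (duration_s <= 0) stop("synth_params: duration_s must be positive", call. = FALSE)
  if (baseline_bpm < 100 || baseline_bpm > 170)
    stop("synth_params: baseline_bpm must lie in [100, 170]", call. = FALSE)
  if (contraction_amp <= 10)
    stop("synth_params: contraction_amp must exceed 10 units", call. = FALSE)
  structure(as.list(environment()), class = "synth_params")
}

#' Stock generator regimes for the two pH classes
#'
#' @param class_label `"acidotic"` or `"non_acidotic"`.
#' @param ... overrides passed on to [synth_params()].
#' @return A `synth_params` object.
#' @export
regime_defaults <- function(class_label = c("non_acidotic", "acidotic"), ...) {
  class_label <- match.arg(class_label)
  if (class_label == "non_acidotic") {
    synth_params(class_label = "non_acidotic", ...)
  } else {
    args <- list(baseline_bpm = 135, variability_bpm = 4,
                 accel_rate_per_hr = 2, decel_rate_per_hr = 8,
                 decel_type_mix = c(light = 0.15, variable = 0.30,
                                    late = 0.45, prolonged = 0.07,
                                    severe = 0.03),
                 ph_mean = 7.05, ph_sd = 0.08,
                 class_label = "acidotic")
    do.call(synth_params, utils::modifyList(args, list(...)))
  }
}

# Draw event blueprints (type, duration, amplitude) satisfying the FIGO
# thresholds with margin, so a correctly implemented detector recovers them
# exactly on noise-free tracings.
draw_event_specs <- function(n_accel, n_decel, mix) {
  specs <- list()
  if (n_accel > 0) {
    for (i in seq_len(n_accel))
      specs[[length(specs) + 1L]] <- list(
        type = "acceleration", shape = "cosine",
        dur_s = runif(1, 25, 100), amp = runif(1, 20, 30))
  }
  if (n_decel > 0) {
    types <- sample(names(mix), n_decel, replace = TRUE, prob = mix)
    for (ty in types) {
      specs[[length(specs) + 1L]] <- switch(ty,
        light = list(type = "light_deceleration", shape = "cosine",
                     dur_s = runif(1, 75, 110), amp = -runif(1, 20, 30)),
        variable = list(type = "variable_deceleration", shape = "variable",
                        dur_s = runif(1, 30, 60), amp = -runif(1, 20, 35),
                        drop_s = runif(1, 5, 12)),
        late = list(type = "late_deceleration", shape = "cosine",
                    dur_s = runif(1, 30, 60), amp = -runif(1, 20, 30)),
        prolonged = list(type = "prolonged_deceleration", shape = "cosine",
                         dur_s = runif(1, 140, 280), amp = -runif(1, 20, 30)),
        severe = list(type = "severe_deceleration", shape = "cosine",
                      dur_s = runif(1, 330, 420), amp = -runif(1, 20, 30)))
    }
  }
  specs
}

#' Generate one synthetic CTG record with ground truth
#'
#' Builds a 4 Hz FHR/UC pair from a slowly drifting baseline, planted
#' accelerations and decelerations of each subtype (raised-cosine humps, or a
#' steep piecewise-linear dip for variable decelerations), periodic
#' raised-cosine uterine contractions on a low resting tone, a beat-to-beat
#' variability alternation, Gaussian sensor noise and signal-loss gaps. Late
#' decelerations are planted with onset strictly after the paired
#' contraction's peak and before the end of its detectable (super-threshold)
#' interval. Cord pH is drawn from the class-conditional truncated normal.
#'
#' @param params a [synth_params()] object.
#' @return A list with elements `record` (a [ctg_record()]) and `truth`, the
#'   ground truth: `events` (type, onset, offset, peak_deviation_bpm; sample
#'   indices, half-open), `contractions` (onset, peak, offset, amplitude),
#'   and `ph`. Deterministic given `params$seed`.
#' @export
generate_record <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  with_seed(params$seed, generate_record_impl(params))
}

generate_record_impl <- function(p) {
  fs <- CTG_HZ
  n <- round(p$duration_s * fs)
  hours <- p$duration_s / 3600

  ## record-level draws around the regime means (patients differ)
  if (p$baseline_sd_between > 0)
    p$baseline_bpm <- rtruncnorm1(1, p$baseline_bpm, p$baseline_sd_between,
                                  100, 170)
  if (p$variability_sd_between > 0)
    p$variability_bpm <- rtruncnorm1(1, p$variability_bpm,
                                     p$variability_sd_between,
                                     0.5, 30)

  ## baseline wander: gaussian knots every 2 min, linearly interpolated
  k <- max(2L, ceiling(p$duration_s / 120) + 1L)
  knots <- rnorm(k, 0, p$baseline_drift_sd)
  drift <- approx(seq(0, n - 1, length.out = k), knots, xout = 0:(n - 1))$y
  base_curve <- p$baseline_bpm + drift

  ## uterine contractions
  uc <- rep(p$contraction_tone, n)
  contr <- list()
  t_next <- runif(1, 30, 90)
  while (TRUE) {
    dur <- runif(1, 60, 90)
    if ((t_next + dur + 10) * fs > n) break
    amp <- p$contraction_amp * runif(1, 0.95, 1.25)
    a <- round(t_next * fs) + 1L
    m <- round(dur * fs)
    uc[a:(a + m - 1L)] <- uc[a:(a + m - 1L)] + raised_cosine(m, amp)
    ## detectable (tone + 10) sub-interval of the bump
    th <- acos(1 - 2 * 10 / amp)                 # phase where bump crosses +10
    det_on <- a + ceiling(m * th / (2 * pi))
    det_off <- a + floor(m * (1 - th / (2 * pi)))
    contr[[length(contr) + 1L]] <- data.frame(
      onset = a, peak = a + (m %/% 2L), offset = a + m,
      det_onset = det_on, det_offset = det_off, amplitude = amp)
    t_next <- t_next + p$contraction_period_s +
      rnorm(1, 0, p$contraction_jitter_sd)
    if (t_next < 0) t_next <- p$contraction_period_s / 2
  }
  contractions <- if (length(contr)) do.call(rbind, contr) else
    data.frame(onset = integer(), peak = integer(), offset = integer(),
               det_onset = integer(), det_offset = integer(),
               amplitude = numeric())

  ## FHR events
  n_accel <- if (!is.null(p$n_accel)) p$n_accel else
    rpois(1, p$accel_rate_per_hr * hours)
  n_decel <- if (!is.null(p$n_decel)) p$n_decel else
    rpois(1, p$decel_rate_per_hr * hours)
  specs <- draw_event_specs(n_accel, n_decel, p$decel_type_mix)
  budget_s <- function(sp) sum(vapply(sp, `[[`, 1, "dur_s")) + 30 * length(sp)
  if (budget_s(specs) > 0.85 * p$duration_s) {
    if (!is.null(p$n_accel) || !is.null(p$n_decel))
      stop("generate_record: duration too short to host the requested ",
           "events (infeasible plan)", call. = FALSE)
    ## Poisson-drawn plan too busy for the recording: trim the longest
    ## events until it fits
    while (length(specs) && budget_s(specs) > 0.85 * p$duration_s) {
      durs <- vapply(specs, `[[`, 1, "dur_s")
      specs[[which.max(durs)]] <- NULL
    }
  }

  occupied <- data.frame(onset = integer(), offset = integer())  # FHR-axis
  gap <- 25 * fs                                     # inter-event guard
  free_ok <- function(a, b) {
    if (a < 60 * fs || b > n - 30 * fs) return(FALSE)
    !any(a < occupied$offset + gap & b > occupied$onset - gap)
  }
  ## forbidden onset zones for non-late decelerations: after a contraction's
  ## peak and before the end of its detectable interval. The guard band is
  ## generous (10 s) because a shallow deceleration's detected onset can
  ## drift a few seconds from the planted one.
  late_zone <- function(onset) {
    if (!nrow(contractions)) return(FALSE)
    any(onset > contractions$peak - 10 * fs &
          onset < contractions$det_offset + 10 * fs)
  }
  fhr_delta <- numeric(n)
  events <- list()
  used_contr <- rep(FALSE, nrow(contractions))
  for (sp in specs) {
    m <- round(sp$dur_s * fs)
    placed <- FALSE
    if (sp$type == "late_deceleration") {
      cand <- which(!used_contr)
      for (ci in cand) {
        peak <- contractions$peak[ci]
        hi <- contractions$det_offset[ci] - 5 * fs
        lo <- peak + 5 * fs
        if (hi <= lo) next
        for (try in 1:30) {
          a <- round(runif(1, lo, hi))
          if (free_ok(a, a + m)) {
            used_contr[ci] <- TRUE
            placed <- TRUE
            break
          }
        }
        if (placed) { paired <- ci; break }
      }
    } else {
      is_decel <- grepl("deceleration", sp$type)
      for (try in 1:500) {
        a <- round(runif(1, 60 * fs, n - 30 * fs - m))
        if (!free_ok(a, a + m)) next
        if (is_decel && late_zone(a)) next
        placed <- TRUE
        break
      }
      paired <- NA_integer_
    }
    if (!placed) {
      ## With exact requested counts an unplaceable event is an error; with
      ## Poisson-drawn counts the plan simply shrinks by one event (ground
      ## truth records what was actually planted).
      if (!is.null(p$n_accel) || !is.null(p$n_decel))
        stop("generate_record: could not place a ", sp$type,
             " (infeasible plan)", call. = FALSE)
      next
    }
    shape <- if (sp$shape == "variable")
      variable_dip(m, sp$amp, sp$drop_s) else raised_cosine(m, sp$amp)
    fhr_delta[a:(a + m - 1L)] <- fhr_delta[a:(a + m - 1L)] + shape
    occupied <- rbind(occupied, data.frame(onset = a, offset = a + m))
    events[[length(events) + 1L]] <- data.frame(
      type = sp$type, onset = a, offset = a + m,
      peak_deviation_bpm = if (sp$amp > 0) max(shape) else min(shape),
      paired_contraction = if (sp$type == "late_deceleration") paired
                           else NA_integer_)
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(type = character(), onset = integer(), offset = integer(),
               peak_deviation_bpm = numeric(), paired_contraction = integer())
  events <- events[order(events$onset), , drop = FALSE]
  rownames(events) <- NULL

  ## assemble FHR: baseline + events + variability alternation + noise
  altern <- rep_len(c(1, -1), n) * p$variability_bpm / 2
  fhr <- base_curve + fhr_delta + altern + rnorm(n, 0, p$noise_sd_bpm)
  uc <- uc + rnorm(n, 0, p$noise_sd_bpm / 2)
  fhr <- pmin(pmax(fhr, 30), 250)
  uc <- pmax(uc, 0)

  ## signal-loss gaps
  n_gaps <- rpois(1, p$dropout_rate_per_hr * hours)
  if (n_gaps > 0) {
    for (g in seq_len(n_gaps)) {
      len <- round(runif(1, 3, 20) * fs)
      a <- round(runif(1, 1, n - len))
      fhr[a:(a + len - 1L)] <- NA_real_
    }
    if (all(is.na(fhr))) fhr[1] <- p$baseline_bpm   # keep record recoverable
  }

  ## class-conditional cord pH, truncated to the class side of 7.2
  ph <- if (p$class_label == "acidotic")
    rtruncnorm1(1, p$ph_mean, p$ph_sd, 6.8, 7.199) else
    rtruncnorm1(1, p$ph_mean, p$ph_sd, 7.2, 7.5)

  record <- ctg_record(fhr = fhr, uc = uc, ph = ph,
                       record_id = paste0("synth_seed", p$seed))
  truth <- list(events = events,
                contractions = contractions[, c("onset", "peak", "offset",
                                                "amplitude")],
                ph = ph, class_label = p$class_label)
  list(record = record, truth = truth)
}

#' Generate a labeled cohort of synthetic CTG records
#'
#' Draws `round(n * acidotic_fraction)` records from the acidotic regime and
#' the remainder from the non-acidotic regime. Each record gets its own RNG
#' stream derived from `seed` and its cohort index, so cohorts are
#' reproducible and insensitive to generation order.
#'
#' @param n cohort size (>= 2).
#' @param acidotic_fraction fraction of acidotic records in \[0, 1\].
#' @param regimes list with `acidotic` and `non_acidotic` [synth_params()]
#'   templates; defaults to [regime_defaults()].
#' @param duration_s record length forwarded to both regimes.
#' @param seed root RNG seed.
#' @return List of `n` elements, each as returned by [generate_record()].
#' @export
generate_cohort <- function(n, acidotic_fraction = 0.5, regimes = NULL,
                            duration_s = 1800, seed = 1L) {
  if (n < 2) stop("generate_cohort: n must be at least 2", call. = FALSE)
  if (acidotic_fraction < 0 || acidotic_fraction > 1)
    stop("generate_cohort: acidotic_fraction must lie in [0, 1]", call. = FALSE)
  if (is.null(regimes))
    regimes <- list(acidotic = regime_defaults("acidotic",
                                               duration_s = duration_s),
                    non_acidotic = regime_defaults("non_acidotic",
                                                   duration_s = duration_s))
  n_acid <- round(n * acidotic_fraction)
  labels <- c(rep("acidotic", n_acid), rep("non_acidotic", n - n_acid))
  lapply(seq_len(n), function(i) {
    p <- regimes[[labels[i]]]
    p$seed <- (as.integer(seed) + 104729L * i) %% 2147483647L
    out <- generate_record(p)
    out$record$record_id <- sprintf("synth_%03d", i)
    out
  })
}
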