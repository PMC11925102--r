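#' Simulate one 24-h hypnogram
#'
#' Semi-Markov vigilance-state simulation on the scoring-epoch grid. Dwell
#' times are geometric at epoch resolution with phase-specific means;
#' conditional next states follow the configured transition matrices (REM is
#' entered only from NREM). On a rocking day the wake-to-NREM transition
#' hazard during light-period epochs is multiplied by
#' `1 + A * exp(-t / tau_within) * exp(-c / tau_across)`, where `t` is the
#' accumulated stimulation time in hours within the current cycle
#' (`(day - 1) * 12` plus hours since lights-on) and `c = cycle - 1`. The
#' dark period is simulated identically on rocking and non-rocking days.
#'
#' Hazards are held piecewise-constant over 30-min blocks; the geometric
#' dwell draw is truncated at block boundaries and resumed, which is exact
#' for a memoryless dwell process.
#'
#' @param config A [generator_config()].
#' @param day A [design_day()] stating whether rocking is scheduled and the
#'   cycle/day indices.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A 24-h [hypnogram()] starting at ZT0, with `rocking_on` set for
#'   light-period epochs of a rocking day.
#' @examples
#' hyp <- simulate_hypnogram(generator_config(), design_day(rocking = TRUE))
#' table(hyp$state)
#' @export
simulate_hypnogram <- function(config, day = design_day(), seed = NULL) {
  .assert(inherits(config, "generator_config"), "`config` must be a generator_config")
  .assert(inherits(day, "design_day"), "`day` must come from design_day()")
  seed <- seed %||% config$seed
  el <- config$epoch_len
  n_epochs <- as.integer(86400 / el)
  block_epochs <- as.integer(1800 / el)
  A <- config$rocking_gain

  states <- withr::with_seed(seed, {
    st <- integer(n_epochs)
    cur <- 1L # start awake at lights-on
    e <- 1L
    while (e <= n_epochs) {
      zt_h <- (e - 1L) * el / 3600
      phase <- if (zt_h < 12) "light" else "dark"
      p_exit <- el / config$mean_dwell[[phase]][[cur]]
      if (cur == 1L && day$rocking && phase == "light") {
        t_stim <- (day$day - 1) * 12 + zt_h
        g <- 1 + A * exp(-t_stim / config$tau_within) *
          exp(-(day$cycle - 1) / config$tau_across)
        p_exit <- min(1, p_exit * g)
      }
      d <- rgeom(1L, p_exit) + 1L
      block_end <- ((e - 1L) %/% block_epochs + 1L) * block_epochs
      m <- block_end - e + 1L
      if (d > m) { # bout continues into the next block; hazard re-evaluated
        st[e:(e + m - 1L)] <- cur
        e <- e + m
      } else {
        st[e:(e + d - 1L)] <- cur
        e <- e + d
        cur <- sample.int(3L, 1L,
                          prob = config$transitions[[phase]][cur, ])
      }
    }
    st
  })

  hyp <- hypnogram(.states[states], epoch_len = el, start_zt = 0)
  hyp$rocking_on <- day$rocking & hyp$phase == "light"
  hyp
}

# 1/f^a background noise for one or more epochs, band-limited to `band`.
# Returns an (n_samples x n_epochs) matrix. Power at frequency f is
# proportional to 1/f^a; total in-band variance per epoch is
# sum_f scale^2 / (2 f^a) over the 0.25-Hz frequency grid.
synth_background <- function(n_epochs, n_samples, sample_rate, exponent,
                             scale, band) {
  freqs <- seq_len(floor(n_samples / 2)) * sample_rate / n_samples
  keep <- freqs >= band[1] & freqs <= band[2]
  amp <- ifelse(keep, scale / freqs^(exponent / 2), 0)
  tt <- (seq_len(n_samples) - 1) / sample_rate
  x <- matrix(0, n_samples, n_epochs)
  active <- which(keep)
  # frequency-domain synthesis with random phases, per epoch
  phases <- matrix(runif(length(active) * n_epochs, 0, 2 * pi),
                   length(active), n_epochs)
  basis <- outer(tt, 2 * pi * freqs[active]) # n_samples x n_active
  for (j in seq_len(n_epochs)) {
    x[, j] <- cos(sweep(basis, 2, phases[, j], "+")) %*% amp[active]
  }
  x
}

#' Synthesize an EEG signal matching a hypnogram
#'
#' Each epoch's signal is a band-limited 1/f^a background plus a
#' state-dependent oscillation: NREM epochs carry a delta oscillation at
#' `delta_peak_base` Hz, replaced by `entrain_factor * rocking_freq` when the
#' epoch is rocking-on; REM epochs carry theta at `theta_freq`; wake is
#' low-amplitude background only. Oscillation phase is randomized per epoch
#' and amplitude continuity across epoch boundaries is not enforced (all
#' spectral metrics are epoch-local).
#'
#' @param hyp A [hypnogram()].
#' @param config A [generator_config()] (`sample_rate >= 64`).
#' @param seed Integer seed; defaults to `config$seed`.
#' @return An [eeg_record()] spanning the hypnogram, sample-aligned to its
#'   epoch grid.
#' @export
simulate_eeg <- function(hyp, config, seed = NULL) {
  .assert(inherits(config, "generator_config"), "`config` must be a generator_config")
  seed <- seed %||% config$seed
  fs <- config$sample_rate
  el <- epoch_len_of(hyp)
  nps <- as.integer(el * fs)
  n_epochs <- nrow(hyp)

  vals <- withr::with_seed(seed, {
    x <- synth_background(n_epochs, nps, fs, config$noise_exponent,
                          config$noise_scale, config$filter_band)
    tt <- (seq_len(nps) - 1) / fs
    f_osc <- rep(NA_real_, n_epochs)
    st <- as.character(hyp$state)
    f_osc[st == "NR"] <- ifelse(hyp$rocking_on[st == "NR"],
                                config$entrain_factor * config$rocking_freq,
                                config$delta_peak_base)
    f_osc[st == "R"] <- config$theta_freq
    amp <- config$osc_amplitude[st]
    ph <- runif(n_epochs, 0, 2 * pi)
    for (j in which(!is.na(f_osc) & amp > 0)) {
      x[, j] <- x[, j] + amp[j] * sin(2 * pi * f_osc[j] * tt + ph[j])
    }
    as.vector(x)
  })
  eeg_record(vals, sample_rate = fs, filter_band = config$filter_band,
             start_zt = hyp$zt_s[1])
}

# Enforce that quiet gaps inside [a, b] (run start/end boundaries included)
# never exceed `cap` seconds, given candidate event seconds `pts`.
cap_gaps <- function(a, b, pts, cap) {
  pts <- sort(unique(pts))
  out <- integer(0)
  prev <- a - 1L
  for (p in c(pts, b + 1L)) {
    while (p - prev > cap) {
      prev <- prev + as.integer(cap)
      if (prev <= b) out <- c(out, prev)
    }
    prev <- p
  }
  sort(unique(c(pts, out)))
}

#' Synthesize a motion-magnitude trace matching a hypnogram
#'
#' Wake epochs emit supra-threshold movement events at
#' `motion_rate_wake` events/min, with quiet gaps (including the run edges)
#' capped at `motion_gap_cap_wake` seconds so a wake bout can never satisfy
#' the 40-s immobility rule. Sleep (NREM or REM) emits sub-threshold sensor
#' noise plus occasional supra-threshold twitches at `twitch_rate_sleep`
#' events/min.
#'
#' @param hyp A [hypnogram()].
#' @param config A [generator_config()] (`motion_sample_rate >= 1`).
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A [motion_trace()] covering the hypnogram duration, with the
#'   configured movement threshold attached.
#' @export
simulate_motion <- function(hyp, config, seed = NULL) {
  .assert(inherits(config, "generator_config"), "`config` must be a generator_config")
  seed <- seed %||% config$seed
  sr <- config$motion_sample_rate
  el <- epoch_len_of(hyp)
  n_sec <- nrow(hyp) * el
  n_samp <- as.integer(n_sec * sr)

  mags <- withr::with_seed(seed, {
    mag <- abs(rnorm(n_samp, 0, 0.08)) # sub-threshold sensor noise
    sec_state <- rep(as.character(hyp$state), each = el)
    awake <- sec_state == "W"
    r <- rle(awake)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    rate_s <- config$motion_rate_wake / 60
    twitch_s <- config$twitch_rate_sleep / 60
    for (i in seq_along(r$values)) {
      a <- starts[i]; b <- ends[i]; len <- b - a + 1L
      if (r$values[i]) {
        n_ev <- rpois(1, len * rate_s)
        pts <- if (n_ev > 0) a - 1L + sample.int(len, min(n_ev, len)) else integer(0)
        pts <- cap_gaps(a, b, pts, config$motion_gap_cap_wake)
        idx <- as.integer((pts - 1L) * sr) + 1L
        mag[idx] <- 1 + abs(rnorm(length(idx), 0, 0.3))
      } else if (twitch_s > 0) {
        n_tw <- rpois(1, len * twitch_s)
        if (n_tw > 0) {
          pts <- a - 1L + sample.int(len, min(n_tw, len))
          idx <- as.integer((pts - 1L) * sr) + 1L
          mag[idx] <- 0.8 + abs(rnorm(length(idx), 0, 0.2))
        }
      }
    }
    mag
  })
  motion_trace(mags, sample_rate = sr, threshold = config$motion_threshold,
               start_zt = hyp$zt_s[1])
}

#' Simulate a cohort over a block design
#'
#' Draws one multiplicative (log-normal) dwell-parameter jitter per mouse,
#' then simulates each scheduled day's hypnogram (and optionally motion
#' trace). Control (`"S"`) cohorts follow the same schedule with the
#' platform off. Fully reproducible given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param config A [generator_config()].
#' @param motion Also synthesize motion traces? (Hypnograms only when
#'   `FALSE`; cheaper for large designs.)
#' @param include_rest_weeks Simulate the no-stimulation weeks as well?
#'   Day-by-cycle summaries only use baseline and stimulation weeks.
#' @return A tibble with one row per mouse x scheduled day: `mouse`, `group`,
#'   `sched_day`, `cycle`, `day`, `rocking`, `is_baseline`, and list-columns
#'   `hypnogram` (and `motion`).
#' @export
simulate_cohort <- function(spec, config, motion = TRUE,
                            include_rest_weeks = TRUE) {
  .assert(inherits(spec, "cohort_spec"), "`spec` must come from cohort_spec()")
  .assert(inherits(config, "generator_config"), "`config` must be a generator_config")
  design <- spec$design
  if (!include_rest_weeks) {
    design <- design[design$is_baseline | design$week == "stim", ]
  }
  jit <- withr::with_seed(spec$seed, {
    matrix(exp(rnorm(spec$n_mice * 2, 0, spec$between_mouse_sd)),
           spec$n_mice, 2, dimnames = list(NULL, c("light", "dark")))
  })
  grid <- tidyr::expand_grid(mouse = seq_len(spec$n_mice), design)
  rows <- purrr::pmap(grid, function(mouse, sched_day, cycle, day, rocking,
                                     is_baseline, week, ...) {
    cfg_m <- config
    for (ph in c("light", "dark")) {
      cfg_m$mean_dwell[[ph]] <- pmax(config$mean_dwell[[ph]] * jit[mouse, ph],
                                     config$epoch_len)
    }
    rock <- rocking && spec$group == "SE"
    dd <- design_day(rocking = rock,
                     cycle = if (is.na(cycle)) 1 else cycle,
                     day = if (is.na(day)) 1 else day)
    day_seed <- spec$seed + mouse * 100000L + sched_day * 100L
    hyp <- simulate_hypnogram(cfg_m, dd, seed = day_seed)
    out <- list(hypnogram = list(hyp))
    if (motion) {
      out$motion <- list(simulate_motion(hyp, cfg_m, seed = day_seed + 1L))
    }
    out
  })
  out <- dplyr::bind_cols(
    grid[, c("mouse", "sched_day", "cycle", "day", "rocking", "is_baseline")],
    dplyr::bind_rows(rows)
  )
  out$group <- spec$group
  out
}

#' Per-day sleep metrics for a simulated cohort
#'
#' Computes, for every mouse x day, light-period sleep minutes and the sleep
#' fragmentation index, either from the motion trace through the immobility
#' rule (as in the chronic experiments) or directly from the hypnogram.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param source `"motion"` (infer sleep from the trace via
#'   [infer_sleep()]) or `"hypnogram"` (NREM or REM counts as sleep).
#' @param period `"light"` or `"dark"`.
#' @param min_immobility_s Immobility threshold passed to [infer_sleep()].
#' @return A tibble keyed by (`mouse`, `sched_day`, `cycle`, `day`) with
#'   `sleep_min` and `frag_per_h`.
#' @export
cohort_sleep_metrics <- function(cohort, source = c("motion", "hypnogram"),
                                 period = "light", min_immobility_s = 40) {
  source <- match.arg(source)
  if (source == "motion") {
    .assert("motion" %in% names(cohort),
            "cohort has no motion traces; use source = \"hypnogram\"")
  }
  per_row <- purrr::pmap(cohort, function(hypnogram, motion = NULL, ...) {
    sw <- if (source == "motion") {
      infer_sleep(motion, min_immobility_s = min_immobility_s)
    } else {
      sleep_series(hypnogram)
    }
    tibble(sleep_min = sleep_amount(sw, period = period),
           frag_per_h = fragmentation_index(sw, period = period))
  })
  dplyr::bind_cols(
    cohort[, c("mouse", "sched_day", "cycle", "day", "rocking", "is_baseline")],
    dplyr::bind_rows(per_row)
  )
}
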