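#' Default conditional transition matrix for the vigilance-state chain
#'
#' Rows give the next-state distribution conditional on leaving each state.
#' Wake can only be followed by NREM; REM is entered exclusively from NREM
#' (probability `p_nrem_to_rem`) and always returns to wake.
#'
#' @param p_nrem_to_rem Probability that a terminating NREM bout is followed
#'   by REM rather than wake.
#' @return A 3x3 row-stochastic matrix with zero diagonal, states
#'   `W`, `NR`, `R` in rows and columns.
#' @export
default_transitions <- function(p_nrem_to_rem = 0.25) {
  .assert(p_nrem_to_rem >= 0 && p_nrem_to_rem <= 1,
          "`p_nrem_to_rem` must be in [0, 1]")
  m <- matrix(0, 3, 3, dimnames = list(.states, .states))
  m["W", "NR"] <- 1
  m["NR", "W"] <- 1 - p_nrem_to_rem
  m["NR", "R"] <- p_nrem_to_rem
  m["R", "W"] <- 1
  m
}

#' Configuration of the synthetic sleep-recording generator
#'
#' Bundles every parameter of the semi-Markov vigilance-state simulator, the
#' per-state EEG synthesis, and the motion-trace synthesis. Defaults encode
#' the study conditions the package emulates: 4-s scoring epochs, a 12h:12h
#' light/dark cycle with lights on at 20:00, cage rocking at 1.0 Hz during
#' the light period with the vestibular stimulus encoded by the brain at
#' about twice that frequency, and habituation of the sleep-promoting effect
#' within a stimulation week and across stimulation cycles.
#'
#' @param epoch_len Scoring epoch length in seconds.
#' @param lights_on Clock time of lights-on, `"HH:MM"` (metadata only; all
#'   simulated time is zeitgeber time, ZT0 = lights-on).
#' @param mean_dwell Named list with elements `light` and `dark`, each a named
#'   numeric vector of mean bout durations in seconds for states `W`, `NR`,
#'   `R`. Dwell times are geometric at epoch resolution with these means.
#' @param transitions Named list (`light`, `dark`) of 3x3 conditional
#'   next-state matrices (rows sum to 1, zero diagonal). REM must be
#'   reachable only from NREM.
#' @param rocking_gain Peak multiplicative gain `A` on the wake-to-NREM
#'   transition hazard at the start of a stimulation cycle (unitless, >= 0).
#' @param tau_within E-folding time (hours of accumulated stimulation within
#'   the current cycle) of the rocking gain.
#' @param tau_across E-folding constant of the gain across cycles
#'   (cycle index units).
#' @param rocking_freq Platform rocking frequency, Hz.
#' @param entrain_factor Ratio of the entrained brain oscillation frequency to
#'   `rocking_freq` (default 2: a 1 Hz platform entrains ~2 Hz NREM
#'   oscillations).
#' @param delta_peak_base Frequency (Hz) of the NREM delta oscillation when
#'   rocking is off.
#' @param theta_freq REM theta oscillation frequency, Hz.
#' @param sample_rate EEG sampling rate, Hz (>= 64).
#' @param noise_exponent Slope of the 1/f^a EEG background.
#' @param noise_scale Amplitude scale of the EEG background (arbitrary units).
#' @param osc_amplitude Named vector of state oscillation amplitudes
#'   (arbitrary units) for `W`, `NR`, `R`.
#' @param filter_band EEG band limits in Hz; background power is synthesized
#'   inside this band only.
#' @param motion_sample_rate Motion-trace sampling rate, Hz (>= 1).
#' @param motion_rate_wake Mean movement-event rate during wake, events/min.
#' @param motion_gap_cap_wake Longest quiet gap allowed inside a wake bout,
#'   seconds (must be < 40 so the immobility rule cannot misread wake).
#' @param twitch_rate_sleep Rate of brief supra-threshold twitches during
#'   sleep, events/min.
#' @param motion_threshold Magnitude above which a motion sample counts as
#'   movement.
#' @param seed Default integer seed used when a `simulate_*()` call does not
#'   supply one.
#' @return A list of class `generator_config`.
#' @examples
#' cfg <- generator_config()
#' cfg$rocking_freq * cfg$entrain_factor # entrained NREM frequency, Hz
#' @export
generator_config <- function(epoch_len = 4,
                             lights_on = "20:00",
                             mean_dwell = list(
                               light = c(W = 96, NR = 160, R = 64),
                               dark  = c(W = 400, NR = 128, R = 56)
                             ),
                             transitions = list(
                               light = default_transitions(0.25),
                               dark  = default_transitions(0.20)
                             ),
                             rocking_gain = 1.5,
                             tau_within = 18,
                             tau_across = 3,
                             rocking_freq = 1.0,
                             entrain_factor = 2,
                             delta_peak_base = 3.0,
                             theta_freq = 7.0,
                             sample_rate = 128,
                             noise_exponent = 1,
                             noise_scale = 1,
                             osc_amplitude = c(W = 0, NR = 8, R = 5),
                             filter_band = c(0.5, 40),
                             motion_sample_rate = 1,
                             motion_rate_wake = 6,
                             motion_gap_cap_wake = 20,
                             twitch_rate_sleep = 0.2,
                             motion_threshold = 0.5,
                             seed = 1L) {
  .assert(epoch_len > 0, "`epoch_len` must be > 0")
  .assert(is.list(mean_dwell) && all(c("light", "dark") %in% names(mean_dwell)),
          "`mean_dwell` needs `light` and `dark` elements")
  for (ph in c("light", "dark")) {
    dw <- mean_dwell[[ph]]
    .assert(all(.states %in% names(dw)) && all(dw[.states] > 0),
            sprintf("`mean_dwell$%s` must give positive means for W, NR, R", ph))
    .assert(all(dw[.states] >= epoch_len),
            sprintf("`mean_dwell$%s` must be >= epoch_len", ph))
    tr <- transitions[[ph]]
    .assert(is.matrix(tr) && all(dim(tr) == c(3, 3)) &&
              identical(rownames(tr), .states) &&
              identical(colnames(tr), .states),
            sprintf("`transitions$%s` must be a 3x3 W/NR/R matrix", ph))
    .assert(all(abs(rowSums(tr) - 1) < 1e-8),
            sprintf("`transitions$%s` rows must sum to 1", ph))
    .assert(all(diag(tr) == 0),
            sprintf("`transitions$%s` must have zero diagonal", ph))
    .assert(tr["W", "R"] == 0 && tr["R", "R"] == 0,
            "REM must be entered only from NREM")
  }
  .assert(rocking_gain >= 0, "`rocking_gain` must be >= 0")
  .assert(tau_within > 0 && tau_across > 0, "`tau_*` must be > 0")
  .assert(sample_rate >= 64, "`sample_rate` must be >= 64 Hz")
  .assert(sample_rate > 2 * filter_band[2],
          "`sample_rate` must exceed twice the upper filter edge")
  .assert(motion_sample_rate >= 1, "`motion_sample_rate` must be >= 1 Hz")
  .assert(motion_gap_cap_wake < 40,
          "`motion_gap_cap_wake` must be < 40 s (the immobility threshold)")
  .assert(motion_gap_cap_wake > 0, "`motion_gap_cap_wake` must be > 0")

  structure(
    list(
      epoch_len = epoch_len, lights_on = lights_on,
      mean_dwell = lapply(mean_dwell, function(x) x[.states]),
      transitions = transitions,
      rocking_gain = rocking_gain, tau_within = tau_within,
      tau_across = tau_across, rocking_freq = rocking_freq,
      entrain_factor = entrain_factor, delta_peak_base = delta_peak_base,
      theta_freq = theta_freq, sample_rate = sample_rate,
      noise_exponent = noise_exponent, noise_scale = noise_scale,
      osc_amplitude = osc_amplitude, filter_band = filter_band,
      motion_sample_rate = motion_sample_rate,
      motion_rate_wake = motion_rate_wake,
      motion_gap_cap_wake = motion_gap_cap_wake,
      twitch_rate_sleep = twitch_rate_sleep,
      motion_threshold = motion_threshold,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' Read a generator configuration from a YAML file
#'
#' The file may set any subset of [generator_config()] arguments; omitted
#' fields keep their defaults. `mean_dwell` and `transitions` are given as
#' nested maps (see the example file shipped in `inst/extdata/`).
#'
#' @param path Path to a YAML file.
#' @return A `generator_config` object.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$mean_dwell)) {
    raw$mean_dwell <- lapply(raw$mean_dwell, function(x) unlist(x)[.states])
  }
  if (!is.null(raw$transitions)) {
    raw$transitions <- lapply(raw$transitions, function(tr) {
      m <- matrix(0, 3, 3, dimnames = list(.states, .states))
      for (from in names(tr)) for (to in names(tr[[from]])) {
        m[from, to] <- tr[[from]][[to]]
      }
      m
    })
  }
  known <- names(formals(generator_config))
  extra <- setdiff(names(raw), known)
  .assert(length(extra) == 0,
          paste0("unknown config fields: ", paste(extra, collapse = ", ")))
  do.call(generator_config, raw)
}

#' Descriptor of a single simulated day
#'
#' @param rocking Is the rocking platform scheduled for this day's light
#'   period?
#' @param cycle 1-based stimulation cycle index (cycle 1 carries the full
#'   rocking gain).
#' @param day 1-based day within the stimulation week (habituation
#'   accumulates over `(day - 1) * 12` hours of prior stimulation).
#' @return A list of class `design_day`.
#' @export
design_day <- function(rocking = FALSE, cycle = 1, day = 1) {
  .assert(cycle >= 1 && day >= 1, "`cycle` and `day` are 1-based indices")
  structure(list(rocking = isTRUE(rocking), cycle = cycle, day = day),
            class = "design_day")
}

#' Block design of alternating stimulation and rest weeks
#'
#' Builds the day-level schedule of a block experiment: `baseline_days`
#' acclimation-end days first, then `n_cycles` cycles each consisting of one
#' stimulation week (`days_per_block` days, rocking on during the light
#' period) followed by one rest week of equal length.
#'
#' @param n_cycles Number of stimulation cycles.
#' @param days_per_block Days per stimulation (and rest) week.
#' @param baseline_days Number of baseline days preceding cycle 1.
#' @return A tibble with one row per scheduled day: `sched_day` (running
#'   index), `cycle` (NA for baseline), `day` (1..`days_per_block`, NA for
#'   baseline), `rocking`, `is_baseline`, `week` (`"stim"`/`"rest"`/
#'   `"baseline"`).
#' @examples
#' block_design(n_cycles = 2)
#' @export
block_design <- function(n_cycles, days_per_block = 7, baseline_days = 3) {
  .assert(n_cycles >= 1, "`n_cycles` must be >= 1")
  .assert(days_per_block >= 1, "`days_per_block` must be >= 1")
  .assert(baseline_days >= 0, "`baseline_days` must be >= 0")
  base <- if (baseline_days > 0) {
    tibble(cycle = NA_integer_, day = NA_integer_, rocking = FALSE,
           is_baseline = TRUE, week = "baseline", .rows = baseline_days)
  } else {
    tibble(cycle = integer(), day = integer(), rocking = logical(),
           is_baseline = logical(), week = character())
  }
  cyc <- tidyr::expand_grid(
    cycle = seq_len(n_cycles),
    week = c("stim", "rest"),
    day = seq_len(days_per_block)
  )
  cyc <- dplyr::mutate(cyc, rocking = .data$week == "stim",
                       is_baseline = FALSE)
  out <- dplyr::bind_rows(base, cyc[, names(base)])
  dplyr::mutate(out, sched_day = dplyr::row_number(),
                .before = 1)
}

#' Specification of a simulated cohort
#'
#' @param n_mice Number of mice (>= 1).
#' @param design Day schedule from [block_design()].
#' @param group Group label: `"SE"` (sleep enhancement; rocking follows the
#'   design schedule) or `"S"` (control; the platform never moves).
#' @param between_mouse_sd Between-mouse fractional (log-normal) variability
#'   applied once per mouse to all dwell means.
#' @param seed Integer seed for per-mouse parameter jitter and per-day
#'   simulation seeds.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mice, design, group = c("SE", "S"),
                        between_mouse_sd = 0.1, seed = 1L) {
  group <- match.arg(group)
  .assert(n_mice >= 1, "`n_mice` must be >= 1")
  .assert(between_mouse_sd >= 0, "`between_mouse_sd` must be >= 0")
  .assert(is.data.frame(design) &&
            all(c("sched_day", "cycle", "day", "rocking", "is_baseline")
                %in% names(design)),
          "`design` must come from block_design()")
  .assert(sum(design$is_baseline) >= 3,
          "design must include at least 3 baseline days")
  structure(list(n_mice = as.integer(n_mice), design = design, group = group,
                 between_mouse_sd = between_mouse_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}
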