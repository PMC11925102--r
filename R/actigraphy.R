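#' Construct a sleep/wake series
#'
#' @param asleep Logical vector on a regular grid.
#' @param sample_rate Grid rate, Hz.
#' @param provenance `"motion"` (inferred from a trace) or `"hypnogram"`.
#' @param start_zt Zeitgeber time of the first sample, seconds.
#' @return A tibble of class `sleep_wake` with `t_s` and `asleep`.
#' @export
sleep_wake_series <- function(asleep, sample_rate = 1,
                              provenance = c("motion", "hypnogram"),
                              start_zt = 0) {
  provenance <- match.arg(provenance)
  out <- tibble(t_s = (seq_along(asleep) - 1) / sample_rate,
                asleep = as.logical(asleep))
  structure(out, sample_rate = sample_rate, provenance = provenance,
            start_zt = start_zt,
            class = c("sleep_wake", class(tibble())))
}

#' Sleep/wake series derived from a hypnogram
#'
#' NREM and REM epochs both map to sleep (motion methods cannot separate
#' them); wake maps to wake. The series is expanded to a regular grid.
#'
#' @param hyp A [hypnogram()].
#' @param sample_rate Output grid rate, Hz.
#' @return A [sleep_wake_series()] with provenance `"hypnogram"`.
#' @export
sleep_series <- function(hyp, sample_rate = 1) {
  el <- epoch_len_of(hyp)
  per_epoch <- hyp$state != "W"
  sleep_wake_series(rep(per_epoch, each = as.integer(el * sample_rate)),
                    sample_rate = sample_rate, provenance = "hypnogram",
                    start_zt = hyp$zt_s[1])
}

#' Infer sleep from a motion trace by the immobility rule
#'
#' Every maximal run of sub-threshold samples lasting at least
#' `min_immobility_s` seconds is labelled sleep in full (including its first
#' 40 s under the default); all other samples are wake. This is the
#' motion-based definition "sleep = immobility lasting >= 40 s"; quiet
#' wakefulness longer than the threshold is inherently misread as sleep.
#'
#' @param trace A [motion_trace()] with its movement threshold attribute set
#'   (override with `threshold`).
#' @param min_immobility_s Immobility duration threshold, seconds.
#' @param threshold Optional movement threshold override.
#' @return A [sleep_wake_series()] on the trace's grid, provenance
#'   `"motion"`.
#' @export
infer_sleep <- function(trace, min_immobility_s = 40, threshold = NULL) {
  .assert(nrow(trace) > 0, "empty motion trace")
  thr <- threshold %||% attr(trace, "threshold")
  .assert(!is.null(thr), "no movement threshold set on the trace")
  sr <- attr(trace, "sample_rate")
  quiet <- trace$magnitude <= thr
  r <- rle(quiet)
  sleep_run <- r$values & (r$lengths / sr) >= min_immobility_s
  asleep <- rep(sleep_run, r$lengths)
  sleep_wake_series(asleep, sample_rate = sr, provenance = "motion",
                    start_zt = attr(trace, "start_zt") %||% 0)
}

sw_period_mask <- function(sw, period) {
  .assert(length(period) == 1 && period %in% c("24h", "light", "dark"),
          "`period` must be one of \"24h\", \"light\", \"dark\"")
  zt <- (attr(sw, "start_zt") %||% 0) + sw$t_s
  switch(period,
         "24h" = rep(TRUE, nrow(sw)),
         light = zt %% 86400 < 43200,
         dark = zt %% 86400 >= 43200)
}

#' Minutes asleep within a period
#'
#' @param sw A [sleep_wake_series()].
#' @param period `"24h"`, `"light"` or `"dark"` (zeitgeber-anchored).
#' @return Minutes asleep.
#' @export
sleep_amount <- function(sw, period = "24h") {
  sr <- attr(sw, "sample_rate")
  sum(sw$asleep & sw_period_mask(sw, period)) / sr / 60
}

#' Sleep fragmentation index
#'
#' Number of sleep-to-wake transitions per hour within the period.
#' Wake-to-sleep transitions are not counted; a transition is assigned to
#' the period containing its wake-onset sample.
#'
#' @param sw A [sleep_wake_series()].
#' @param period `"24h"`, `"light"` or `"dark"`.
#' @return Transitions per hour (count / period hours).
#' @export
fragmentation_index <- function(sw, period = "24h") {
  sr <- attr(sw, "sample_rate")
  keep <- sw_period_mask(sw, period)
  period_h <- sum(keep) / sr / 3600
  .assert(period_h > 0, "period has zero duration in this series")
  n <- nrow(sw)
  if (n < 2) return(0)
  trans <- sw$asleep[-n] & !sw$asleep[-1] # sleep at i, wake at i+1
  count <- sum(trans & keep[-1])
  count / period_h
}

#' Normalize per-day metric values to the baseline-day mean
#'
#' Each value is divided by the mean over baseline days, so the baseline
#' mean maps to exactly 1.0. Scaling all inputs by a constant leaves the
#' result unchanged.
#'
#' @param data A data frame with one row per day.
#' @param value Column of metric values (tidy-eval).
#' @param baseline Logical column (or expression) flagging baseline days.
#' @param out Name of the normalized output column.
#' @return `data` with the normalized column appended.
#' @examples
#' df <- tibble::tibble(day = 1:5, v = c(10, 10, 10, 12, 9),
#'                      bsl = c(TRUE, TRUE, TRUE, FALSE, FALSE))
#' normalize_to_baseline(df, v, bsl)
#' @export
normalize_to_baseline <- function(data, value, baseline, out = "value_norm") {
  v <- dplyr::pull(data, {{ value }})
  b <- rlang::eval_tidy(rlang::enquo(baseline), data)
  .assert(any(b %in% TRUE), "no baseline days flagged")
  bmean <- mean(v[b], na.rm = TRUE)
  .assert(is.finite(bmean) && bmean > 0,
          "baseline mean must be positive and finite")
  data[[out]] <- v / bmean
  data
}

#' Day-by-cycle longitudinal matrix of a cohort metric
#'
#' Averages a per-(mouse, cycle, day) metric across mice into a days x
#' cycles matrix, plus the day profile (mean over cycles) and cycle profile
#' (mean over days). Missing cells are `NA` and are excluded from means,
#' never zero-filled.
#'
#' @param metrics A data frame with columns `mouse`, `cycle`, `day` and the
#'   metric column.
#' @param design The [block_design()] the metrics come from (fixes the
#'   matrix dimensions).
#' @param value Metric column (tidy-eval).
#' @return An object of class `longitudinal_matrix`: list with `cells`
#'   (tibble `day`, `cycle`, `value` for every design cell), `day_profile`,
#'   `cycle_profile`, `n_days`, `n_cycles`. See [tidy.longitudinal_matrix()]
#'   and [autoplot.longitudinal_matrix()].
#' @export
build_matrix <- function(metrics, design, value) {
  .assert(all(c("mouse", "cycle", "day") %in% names(metrics)),
          "`metrics` must be keyed by (mouse, cycle, day)")
  n_cycles <- max(design$cycle, na.rm = TRUE)
  n_days <- max(design$day, na.rm = TRUE)
  m <- dplyr::filter(metrics, !is.na(.data$cycle), !is.na(.data$day))
  .assert(all(m$cycle >= 1 & m$cycle <= n_cycles &
                m$day >= 1 & m$day <= n_days),
          "metric keys fall outside the design's day/cycle grid")
  dup <- dplyr::count(m, .data$mouse, .data$cycle, .data$day)
  .assert(all(dup$n == 1), "duplicate (mouse, cycle, day) keys")
  cells <- dplyr::summarise(dplyr::group_by(m, .data$day, .data$cycle),
                            value = mean({{ value }}, na.rm = TRUE),
                            .groups = "drop")
  grid <- tidyr::expand_grid(day = seq_len(n_days), cycle = seq_len(n_cycles))
  cells <- dplyr::left_join(grid, cells, by = c("day", "cycle"))
  cells$value[is.nan(cells$value)] <- NA_real_
  day_profile <- dplyr::summarise(
    dplyr::group_by(cells, .data$day),
    value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  cycle_profile <- dplyr::summarise(
    dplyr::group_by(cells, .data$cycle),
    value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  structure(list(cells = cells, day_profile = day_profile,
                 cycle_profile = cycle_profile,
                 n_days = n_days, n_cycles = n_cycles),
            class = "longitudinal_matrix")
}

#' @describeIn build_matrix The full day x cycle cell table.
#' @param x A `longitudinal_matrix`.
#' @param ... Unused.
#' @method tidy longitudinal_matrix
#' @export
tidy.longitudinal_matrix <- function(x, ...) x$cells

#' @describeIn build_matrix One-row summary (dimensions, grand mean).
#' @method glance longitudinal_matrix
#' @export
glance.longitudinal_matrix <- function(x, ...) {
  tibble(n_days = x$n_days, n_cycles = x$n_cycles,
         grand_mean = mean(x$cells$value, na.rm = TRUE),
         n_missing = sum(is.na(x$cells$value)))
}

#' Epoch-wise concordance of motion-inferred and hypnogram sleep/wake
#'
#' The inferred series is resampled to the hypnogram's epoch grid by strict
#' majority (an epoch is sleep when more than half of its samples are
#' sleep), then compared with the hypnogram's sleep/wake (NREM or REM =
#' sleep).
#'
#' @param inferred A [sleep_wake_series()] covering the hypnogram.
#' @param hyp The ground-truth [hypnogram()].
#' @return Fraction of agreeing epochs in `[0, 1]`.
#' @export
concordance <- function(inferred, hyp) {
  sr <- attr(inferred, "sample_rate")
  el <- epoch_len_of(hyp)
  spe <- as.integer(el * sr)
  n_epochs <- nrow(hyp)
  .assert(nrow(inferred) >= n_epochs * spe,
          "inferred series shorter than the hypnogram")
  frac <- colMeans(matrix(inferred$asleep[seq_len(n_epochs * spe)],
                          nrow = spe))
  epoch_sleep <- frac > 0.5
  truth <- hyp$state != "W"
  mean(epoch_sleep == truth)
}
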