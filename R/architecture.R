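period_mask <- function(hyp, period) {
  period <- as.character(period)
  .assert(length(period) == 1 && period %in% c("24h", "light", "dark"),
          "`period` must be one of \"24h\", \"light\", \"dark\"")
  if (period == "24h") rep(TRUE, nrow(hyp)) else hyp$phase == period
}

#' Minutes spent in each vigilance state
#'
#' @param hyp A [hypnogram()] with phase annotation.
#' @param period `"24h"`, `"light"` or `"dark"`.
#' @return A tibble with columns `state` and `minutes` (one row per state,
#'   zeros included); the rows sum to the period duration.
#' @examples
#' state_amounts(hypnogram(rep(c("W", "NR"), 50)), "24h")
#' @export
state_amounts <- function(hyp, period = "24h") {
  el <- epoch_len_of(hyp)
  keep <- period_mask(hyp, period)
  counts <- table(factor(hyp$state[keep], levels = .states))
  tibble(state = factor(.states, levels = .states),
         minutes = as.numeric(counts) * el / 60)
}

#' Time course of a state in fixed bins across 24 h
#'
#' @param hyp A 24-h [hypnogram()].
#' @param state State to tally (`"W"`, `"NR"` or `"R"`).
#' @param bin_h Bin width in hours; must divide 24.
#' @return A tibble with `bin` (1-based), `zt_lo_h`, `zt_hi_h` and `minutes`;
#'   the bins sum to the 24-h state amount.
#' @export
time_course <- function(hyp, state = "NR", bin_h = 2) {
  .assert(state %in% .states, "unknown state")
  .assert(24 %% bin_h == 0, "`bin_h` must divide 24")
  el <- epoch_len_of(hyp)
  n_bins <- as.integer(24 / bin_h)
  bin <- pmin(floor((hyp$zt_s %% 86400) / (bin_h * 3600)) + 1, n_bins)
  hit <- hyp$state == state
  mins <- vapply(seq_len(n_bins),
                 function(b) sum(hit & bin == b) * el / 60, numeric(1))
  tibble(bin = seq_len(n_bins),
         zt_lo_h = (seq_len(n_bins) - 1) * bin_h,
         zt_hi_h = seq_len(n_bins) * bin_h,
         minutes = mins)
}

#' Segment maximal same-state episodes
#'
#' An episode is a maximal run of consecutive epochs in the given state.
#' With the default strict 8-s filter on 4-s epochs, 2-epoch runs (exactly
#' 8 s) fail the filter and 3-epoch runs (12 s) pass: episodes must be
#' *longer than* `min_dur_s`.
#'
#' @param hyp A [hypnogram()].
#' @param state State whose episodes to extract (default NREM).
#' @param min_dur_s Minimum-duration filter, seconds.
#' @param strict Use strict inequality (`duration > min_dur_s`)? When
#'   `FALSE`, `>=` is used.
#' @return An episode table: tibble with `state`, `start_epoch`, `n_epochs`,
#'   `duration_s` and `passes_min_dur`, ordered and non-overlapping.
#' @export
detect_episodes <- function(hyp, state = "NR", min_dur_s = 8, strict = TRUE) {
  .assert(state %in% .states, "unknown state")
  el <- epoch_len_of(hyp)
  r <- rle(as.character(hyp$state))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == state
  dur <- r$lengths[keep] * el
  tibble(
    state = rep(state, sum(keep)),
    start_epoch = starts[keep],
    n_epochs = r$lengths[keep],
    duration_s = dur,
    passes_min_dur = if (strict) dur > min_dur_s else dur >= min_dur_s
  )
}

#' Histogram of episode durations in fixed clusters
#'
#' Durations are clustered into half-open bins `[0, bin_s)`,
#' `[bin_s, 2 bin_s)`, ... up to `max_s`, plus an overflow cluster
#' `[max_s, Inf)`. Only episodes passing the minimum-duration filter are
#' counted, and counts sum to the number of such episodes.
#'
#' @param episodes An episode table from [detect_episodes()].
#' @param bin_s Cluster width, seconds.
#' @param max_s Lower edge of the overflow cluster, seconds.
#' @return A tibble with `bin_lo_s`, `bin_hi_s` (Inf for overflow) and `n`.
#' @export
episode_histogram <- function(episodes, bin_s = 20, max_s = 240) {
  .assert(max_s %% bin_s == 0, "`max_s` must be a multiple of `bin_s`")
  dur <- episodes$duration_s[episodes$passes_min_dur]
  lo <- seq(0, max_s, by = bin_s)
  hi <- c(lo[-1], Inf)
  idx <- pmin(dur %/% bin_s + 1, length(lo))
  tibble(bin_lo_s = lo, bin_hi_s = hi,
         n = as.integer(tabulate(idx, nbins = length(lo))))
}

#' Detect brief arousals in consolidated NREM sleep
#'
#' A brief arousal is a wake run strictly shorter than `max_wake_s`
#' (at 4-s epochs: at most 3 epochs) whose immediately flanking runs are
#' both single maximal NREM runs lasting at least `min_flank_s`. REM-flanked
#' wake never counts. An event is assigned to the period containing its
#' first wake epoch.
#'
#' @param hyp A [hypnogram()] with phase annotation.
#' @param period `"24h"`, `"light"` or `"dark"`.
#' @param max_wake_s Strict upper bound on the wake run duration, seconds.
#' @param min_flank_s Inclusive lower bound on each flanking NREM run,
#'   seconds.
#' @return A tibble of class `brief_arousals` with `start_epoch`, `n_epochs`,
#'   `left_flank_dur_s`, `right_flank_dur_s`; attributes `density`
#'   (events/hour of the period) and `period_h`. See [glance.brief_arousals()].
#' @export
detect_brief_arousals <- function(hyp, period = "light", max_wake_s = 16,
                                  min_flank_s = 20) {
  el <- epoch_len_of(hyp)
  r <- rle(as.character(hyp$state))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n_runs <- length(r$values)
  keep <- period_mask(hyp, period)
  period_h <- sum(keep) * el / 3600
  .assert(period_h > 0, "hypnogram contains no epochs in the requested period")

  is_event <- logical(n_runs)
  if (n_runs >= 3) {
    i <- 2:(n_runs - 1)
    is_event[i] <- r$values[i] == "W" &
      r$lengths[i] * el < max_wake_s &
      r$values[i - 1] == "NR" & r$lengths[i - 1] * el >= min_flank_s &
      r$values[i + 1] == "NR" & r$lengths[i + 1] * el >= min_flank_s
  }
  ev <- which(is_event & keep[starts])
  out <- tibble(
    start_epoch = starts[ev],
    n_epochs = r$lengths[ev],
    left_flank_dur_s = r$lengths[ev - 1] * el,
    right_flank_dur_s = r$lengths[ev + 1] * el
  )
  structure(out, density = nrow(out) / period_h, period_h = period_h,
            period = period,
            class = c("brief_arousals", class(tibble())))
}

#' @describeIn detect_brief_arousals One-row summary: event count, period
#'   hours and density (events/hour).
#' @param x A `brief_arousals` table.
#' @param ... Unused.
#' @method glance brief_arousals
#' @export
glance.brief_arousals <- function(x, ...) {
  tibble(n_events = nrow(x),
         period_h = attr(x, "period_h"),
         density_per_h = attr(x, "density"))
}

#' Arousal density accessor
#'
#' @param x A `brief_arousals` table from [detect_brief_arousals()].
#' @return Events per hour of the analyzed period.
#' @export
arousal_density <- function(x) {
  .assert(inherits(x, "brief_arousals"),
          "`x` must come from detect_brief_arousals()")
  attr(x, "density")
}
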