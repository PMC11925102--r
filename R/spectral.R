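#' Per-epoch power spectral density on the 0.25-Hz bin grid
#'
#' One periodogram per scoring epoch, computed over the full epoch window
#' (a 4-s epoch gives 0.25-Hz native resolution, matching the reporting
#' grid; no within-epoch averaging). Powers satisfy Parseval's relation:
#' the sum over all retained bins approximates the band-limited signal
#' variance.
#'
#' @param eeg An [eeg_record()] sample-aligned to `hyp` (`sample_rate >= 64`).
#' @param hyp The matching [hypnogram()].
#' @param f_max Upper edge of the retained grid, Hz; bins are half-open
#'   `[f, f + 0.25)` with starts from 0.25 to `f_max - 0.25`.
#' @return A tibble of class `spectral_frame` in long format: `epoch`,
#'   `bin_start` (Hz) and `power` (arbitrary units^2), one row per epoch x
#'   bin. The bin width (0.25 Hz) is carried as an attribute.
#' @export
epoch_psd <- function(eeg, hyp, f_max = 30) {
  sr <- attr(eeg, "sample_rate")
  .assert(sr >= 64, "`sample_rate` must be >= 64 Hz")
  el <- epoch_len_of(hyp)
  .assert(el >= 4, "epochs shorter than 4 s cannot resolve 0.25-Hz bins")
  al <- align_to_epochs(eeg, hyp)
  nps <- al$end[1] - al$start[1]
  n_use <- nrow(al)
  x <- matrix(eeg$value[seq_len(n_use * nps)], nrow = nps)
  X <- stats::mvfft(x)
  df <- sr / nps # = 1 / epoch_len
  k <- seq_len(floor(nps / 2) - 1)
  freqs <- k * df
  keep <- freqs >= 0.25 & freqs < f_max
  # one-sided periodogram: power in bin k is 2 |X_k|^2 / N^2 so that the
  # sum over bins equals the (band-limited) variance
  pw <- 2 * Mod(X[k[keep] + 1, , drop = FALSE])^2 / nps^2
  out <- tibble(
    epoch = rep(seq_len(n_use), each = sum(keep)),
    bin_start = rep(freqs[keep], times = n_use),
    power = as.vector(pw)
  )
  structure(out, bin_width = df, n_epochs = n_use,
            class = c("spectral_frame", class(tibble())))
}

join_states <- function(sf, hyp) {
  dplyr::left_join(
    sf,
    tibble(epoch = hyp$epoch, state = as.character(hyp$state),
           phase = hyp$phase),
    by = "epoch"
  )
}

#' Mean spectrum of one state within a period
#'
#' @param sf A `spectral_frame` from [epoch_psd()].
#' @param hyp The matching [hypnogram()].
#' @param state `"W"`, `"NR"` or `"R"`.
#' @param period `"24h"`, `"light"` or `"dark"`.
#' @return A tibble `bin_start`, `power` (the mean over contributing
#'   epochs), with attributes `n_epochs` and `empty`. When no epoch matches,
#'   `power` is all `NA` and `empty` is `TRUE` (never silently zero-filled).
#' @export
state_spectrum <- function(sf, hyp, state = "NR", period = "24h") {
  .assert(state %in% .states, "unknown state")
  keep <- period_mask(hyp, period) & hyp$state == state
  sel <- hyp$epoch[keep]
  sub <- sf[sf$epoch %in% sel, ]
  n <- length(intersect(sel, unique(sf$epoch)))
  if (n == 0) {
    bins <- sort(unique(sf$bin_start))
    out <- tibble(bin_start = bins, power = NA_real_)
    return(structure(out, n_epochs = 0L, empty = TRUE, state = state,
                     period = period))
  }
  out <- dplyr::summarise(dplyr::group_by(sub, .data$bin_start),
                          power = mean(.data$power), .groups = "drop")
  structure(out, n_epochs = n, empty = FALSE, state = state, period = period)
}

band_mean_by_epoch <- function(sf, lo, hi) {
  sub <- sf[sf$bin_start >= lo & sf$bin_start < hi, ]
  dplyr::summarise(dplyr::group_by(sub, .data$epoch),
                   power = mean(.data$power), .groups = "drop")
}

#' Band metrics: SWA, SWE and beta power
#'
#' Slow-wave activity (SWA) is the mean NREM power over `[0.5, 4)` Hz per
#' epoch; beta is the mean NREM power over `[15, 30)` Hz. Slow-wave energy
#' (SWE) is the running cumulative sum of per-epoch NREM SWA over the
#' light-period epochs: non-NREM epochs contribute zero and do not advance
#' the sum, so the final value equals the sum of light-period NREM SWA
#' values exactly.
#'
#' @param sf A `spectral_frame` from [epoch_psd()].
#' @param hyp The matching, phase-annotated [hypnogram()].
#' @param swa_band,beta_band Half-open frequency bands, Hz.
#' @return An object of class `band_summary`: list with `per_epoch`
#'   (tibble `epoch`, `state`, `phase`, `swa`, `beta` for NREM epochs),
#'   `swe` (tibble `epoch`, `zt_s`, `swe` over light-period epochs),
#'   `swa_mean`, `beta_mean`, `swe_final`, `n_nrem_epochs`. With no NREM
#'   epochs the means are `NA` and `n_nrem_epochs` is 0. See
#'   [tidy.band_summary()] and [glance.band_summary()].
#' @export
band_metrics <- function(sf, hyp, swa_band = c(0.5, 4), beta_band = c(15, 30)) {
  swa <- band_mean_by_epoch(sf, swa_band[1], swa_band[2])
  beta <- band_mean_by_epoch(sf, beta_band[1], beta_band[2])
  per <- dplyr::left_join(
    tibble(epoch = hyp$epoch, state = as.character(hyp$state),
           phase = hyp$phase, zt_s = hyp$zt_s),
    dplyr::rename(swa, swa = "power"), by = "epoch")
  per <- dplyr::left_join(per, dplyr::rename(beta, beta = "power"),
                          by = "epoch")
  per <- per[per$epoch %in% unique(sf$epoch), ]
  nrem <- per[per$state == "NR", ]
  light <- per[per$phase == "light", ]
  incr <- ifelse(light$state == "NR" & !is.na(light$swa), light$swa, 0)
  swe <- tibble(epoch = light$epoch, zt_s = light$zt_s, swe = cumsum(incr))
  structure(
    list(
      per_epoch = nrem[, c("epoch", "state", "phase", "swa", "beta")],
      swe = swe,
      swa_mean = if (nrow(nrem) > 0) mean(nrem$swa) else NA_real_,
      beta_mean = if (nrow(nrem) > 0) mean(nrem$beta) else NA_real_,
      swe_final = if (nrow(swe) > 0) swe$swe[nrow(swe)] else 0,
      n_nrem_epochs = nrow(nrem)
    ),
    class = "band_summary"
  )
}

#' @describeIn band_metrics Per-NREM-epoch SWA/beta values as a tibble.
#' @param x A `band_summary`.
#' @param ... Unused.
#' @method tidy band_summary
#' @export
tidy.band_summary <- function(x, ...) x$per_epoch

#' @describeIn band_metrics One-row summary (SWA mean, beta mean, final SWE,
#'   NREM epoch count).
#' @method glance band_summary
#' @export
glance.band_summary <- function(x, ...) {
  tibble(swa_mean = x$swa_mean, beta_mean = x$beta_mean,
         swe_final = x$swe_final, n_nrem_epochs = x$n_nrem_epochs)
}

#' Peak frequency of a spectrum within a band
#'
#' Returns the bin start (Hz) of the maximal-power bin whose start lies in
#' the half-open `range`. Ties break toward the lower frequency.
#'
#' @param spectrum A tibble with `bin_start` and `power` (e.g. from
#'   [state_spectrum()]).
#' @param range Half-open frequency range `[lo, hi)`, Hz.
#' @return The peak bin start in Hz.
#' @export
spectral_peak <- function(spectrum, range = c(0.5, 4)) {
  sub <- spectrum[spectrum$bin_start >= range[1] &
                    spectrum$bin_start < range[2], ]
  .assert(nrow(sub) > 0, "no spectral bins in the requested range")
  .assert(!anyNA(sub$power), "spectrum is empty (NA power) in the range")
  sub <- sub[order(sub$bin_start), ]
  sub$bin_start[which.max(sub$power)]
}

#' Normalize a band value to a baseline
#'
#' Plain ratio `value / baseline_value`. The baseline choice is the
#' caller's: this package does not presume which reference a study used.
#'
#' @param value Numeric value(s).
#' @param baseline_value Positive baseline.
#' @return `value / baseline_value`.
#' @export
normalize_band <- function(value, baseline_value) {
  .assert(all(baseline_value > 0), "`baseline_value` must be > 0")
  value / baseline_value
}
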