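#' Construct an epoch-wise hypnogram
#'
#' A hypnogram is a tibble with one row per scoring epoch and columns
#' `epoch` (1-based index), `state` (factor with levels `W`, `NR`, `R`),
#' `zt_s` (epoch onset in seconds of zeitgeber time, ZT0 = lights-on),
#' `phase` (`"light"`/`"dark"`) and `rocking_on` (logical). The epoch length
#' is carried as an attribute.
#'
#' Phase labelling follows the half-open convention: the light period is
#' `[ZT0, ZT12)`, so an epoch starting exactly at ZT12 is dark.
#'
#' @param states Character vector (or factor) over `"W"`, `"NR"`, `"R"`.
#' @param epoch_len Epoch length, seconds.
#' @param start_zt Zeitgeber time of the first epoch onset, seconds.
#' @param rocking_on Logical, recycled to epoch length: was the platform
#'   rocking during each epoch?
#' @return A tibble of class `hypnogram`.
#' @examples
#' hypnogram(c("W", "W", "NR", "NR", "R"))
#' @export
hypnogram <- function(states, epoch_len = 4, start_zt = 0,
                      rocking_on = FALSE) {
  states <- as.character(states)
  bad <- setdiff(unique(states), .states)
  .assert(length(bad) == 0,
          paste0("unknown state token(s): ", paste(bad, collapse = ", ")))
  .assert(epoch_len > 0, "`epoch_len` must be > 0")
  n <- length(states)
  zt_s <- start_zt + (seq_len(n) - 1) * epoch_len
  out <- tibble(
    epoch = seq_len(n),
    state = factor(states, levels = .states),
    zt_s = zt_s,
    phase = ifelse(zt_s %% 86400 < 43200, "light", "dark"),
    rocking_on = rep_len(as.logical(rocking_on), n)
  )
  structure(out, epoch_len = epoch_len, start_zt = start_zt,
            class = c("hypnogram", class(tibble())))
}

epoch_len_of <- function(hyp) attr(hyp, "epoch_len") %||% 4

#' Re-annotate light/dark phase labels of a hypnogram
#'
#' Recomputes `zt_s` and `phase` from a (possibly new) zeitgeber anchoring of
#' the first epoch. Light is `[ZT0, ZT12)` on a 12h:12h cycle; the boundary
#' epoch at ZT12 is dark (half-open convention).
#'
#' @param hyp A [hypnogram()].
#' @param start_zt Zeitgeber time (seconds since lights-on) of the first
#'   epoch onset.
#' @return The hypnogram with refreshed `zt_s` and `phase` columns.
#' @export
annotate_phases <- function(hyp, start_zt = attr(hyp, "start_zt") %||% 0) {
  el <- epoch_len_of(hyp)
  hyp$zt_s <- start_zt + (hyp$epoch - 1) * el
  hyp$phase <- ifelse(hyp$zt_s %% 86400 < 43200, "light", "dark")
  attr(hyp, "start_zt") <- start_zt
  hyp
}

#' Read / write hypnogram CSV files
#'
#' The CSV dialect has columns `epoch_index`, `zt_seconds`, `state` and
#' optionally `rocking_on`. States must be `W`, `NR` or `R`; any other token
#' is rejected with the offending row reported. The epoch grid must be
#' uniform.
#'
#' @param path File path.
#' @param hyp A [hypnogram()] (for writing).
#' @return `read_hypnogram()` returns a [hypnogram()];
#'   `write_hypnogram()` returns `path` invisibly.
#' @export
read_hypnogram <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("epoch_index", "zt_seconds", "state")
  missing <- setdiff(need, names(df))
  .assert(length(missing) == 0,
          paste0("hypnogram CSV missing column(s): ",
                 paste(missing, collapse = ", ")))
  bad <- which(!df$state %in% .states)
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown state token \"%s\" at row %d",
                         df$state[bad[1]], bad[1]))
  }
  if (nrow(df) > 1) {
    steps <- diff(df$zt_seconds)
    .assert(length(unique(steps)) == 1,
            sprintf("non-uniform epoch grid near row %d",
                    which(steps != steps[1])[1] + 1))
    el <- steps[1]
  } else {
    el <- 4
  }
  hypnogram(df$state, epoch_len = el, start_zt = df$zt_seconds[1],
            rocking_on = if ("rocking_on" %in% names(df)) df$rocking_on
                         else FALSE)
}

#' @rdname read_hypnogram
#' @export
write_hypnogram <- function(hyp, path) {
  out <- tibble(epoch_index = hyp$epoch, zt_seconds = hyp$zt_s,
                state = as.character(hyp$state), rocking_on = hyp$rocking_on)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Construct an EEG record
#'
#' @param values Numeric sample vector (arbitrary voltage units).
#' @param sample_rate Sampling rate, Hz; must exceed twice the upper filter
#'   edge.
#' @param channel Channel label.
#' @param filter_band Length-2 numeric, the acquisition band-pass in Hz.
#' @param start_zt Zeitgeber time of the first sample, seconds.
#' @return A tibble of class `eeg_record` with columns `t_s` (seconds from
#'   record start) and `value`.
#' @export
eeg_record <- function(values, sample_rate, channel = "EEG",
                       filter_band = c(0.1, 40), start_zt = 0) {
  .assert(sample_rate > 2 * filter_band[2],
          "`sample_rate` must exceed twice the upper filter edge")
  out <- tibble(t_s = (seq_along(values) - 1) / sample_rate,
                value = as.numeric(values))
  structure(out, sample_rate = sample_rate, channel = channel,
            filter_band = filter_band, start_zt = start_zt,
            class = c("eeg_record", class(tibble())))
}

#' Construct a motion trace
#'
#' @param magnitudes Non-negative motion magnitudes (arbitrary units).
#' @param sample_rate Sampling rate, Hz (>= 1).
#' @param threshold Magnitude above which a sample counts as movement.
#' @param start_zt Zeitgeber time of the first sample, seconds.
#' @return A tibble of class `motion_trace` with columns `t_s` and
#'   `magnitude`.
#' @export
motion_trace <- function(magnitudes, sample_rate = 1, threshold = 0.5,
                         start_zt = 0) {
  .assert(sample_rate >= 1, "`sample_rate` must be >= 1 Hz")
  .assert(threshold >= 0, "`threshold` must be >= 0")
  .assert(all(magnitudes >= 0), "`magnitudes` must be >= 0")
  out <- tibble(t_s = (seq_along(magnitudes) - 1) / sample_rate,
                magnitude = as.numeric(magnitudes))
  structure(out, sample_rate = sample_rate, threshold = threshold,
            start_zt = start_zt,
            class = c("motion_trace", class(tibble())))
}

#' Read / write motion-trace CSV files (columns `t_seconds`, `magnitude`)
#'
#' @param path File path.
#' @param trace A [motion_trace()] (for writing).
#' @param threshold Movement threshold attached on read.
#' @return `read_motion()` returns a [motion_trace()].
#' @export
read_motion <- function(path, threshold = 0.5) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("t_seconds", "magnitude")
  .assert(all(need %in% names(df)),
          paste0("motion CSV missing column(s): ",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  .assert(nrow(df) >= 2, "motion CSV needs at least 2 samples")
  dt <- diff(df$t_seconds)
  .assert(max(abs(dt - dt[1])) < 1e-9, "non-uniform motion sampling grid")
  motion_trace(df$magnitude, sample_rate = 1 / dt[1], threshold = threshold,
               start_zt = df$t_seconds[1])
}

#' @rdname read_motion
#' @export
write_motion <- function(trace, path) {
  sr <- attr(trace, "sample_rate")
  start <- attr(trace, "start_zt") %||% 0
  out <- tibble(t_seconds = start + trace$t_s, magnitude = trace$magnitude)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Map a sampled signal onto the hypnogram's epoch grid
#'
#' Returns contiguous, non-overlapping half-open sample-index ranges, one per
#' epoch, each spanning exactly `epoch_len * sample_rate` samples. A trailing
#' partial epoch is truncated (with a warning when a whole epoch is lost);
#' a duration mismatch of more than one epoch is an error.
#'
#' @param signal An [eeg_record()] or [motion_trace()].
#' @param hyp A [hypnogram()].
#' @return A tibble with columns `epoch`, `start` and `end`: sample indices
#'   such that epoch `i` covers `signal$value[start:(end - 1)]`
#'   (1-based, half-open `[start, end)`).
#' @export
align_to_epochs <- function(signal, hyp) {
  sr <- attr(signal, "sample_rate")
  .assert(!is.null(sr), "`signal` must carry a sample_rate attribute")
  el <- epoch_len_of(hyp)
  spe <- el * sr
  .assert(abs(spe - round(spe)) < 1e-9,
          "epoch length must hold an integer number of samples")
  spe <- as.integer(round(spe))
  n_samples <- nrow(signal)
  n_full <- n_samples %/% spe
  n_epochs <- nrow(hyp)
  .assert(abs(n_samples - n_epochs * spe) <= spe,
          "signal and hypnogram durations differ by more than one epoch")
  n_use <- min(n_full, n_epochs)
  if (n_use < n_epochs) {
    rlang::warn(sprintf("signal %d sample(s) short; dropping final epoch",
                        n_epochs * spe - n_samples))
  }
  tibble(epoch = seq_len(n_use),
         start = (seq_len(n_use) - 1L) * spe + 1L,
         end = seq_len(n_use) * spe + 1L)
}

# ---- EDF (European Data Format) ----------------------------------------
# Minimal continuous-recording EDF support: 16-bit samples, any number of
# channels, fixed-duration data records. Written by hand because no EDF
# reader ships with the R stack this package targets.

edf_pad <- function(x, width) {
  x <- as.character(x)
  .assert(all(nchar(x) <= width), "EDF header field overflow")
  formatC(x, width = width, flag = "-")
}

#' Write a single-channel EEG record to an EDF file
#'
#' Samples are scaled to the full 16-bit digital range of the record, so the
#' round trip is exact up to quantization (about 1/65536 of the amplitude
#' range). Records of 1 s duration are used; a trailing partial second is
#' dropped.
#'
#' @param eeg An [eeg_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(eeg, path) {
  sr <- attr(eeg, "sample_rate")
  .assert(abs(sr - round(sr)) < 1e-9, "EDF writer needs an integer sample rate")
  sr <- as.integer(round(sr))
  x <- eeg$value
  n_rec <- length(x) %/% sr
  .assert(n_rec >= 1, "signal shorter than one 1-s EDF record")
  x <- x[seq_len(n_rec * sr)]
  # physical range fields must fit 8 ASCII chars; scale with the values as
  # written so the round trip is consistent
  fit8 <- function(v) {
    for (d in 7:1) {
      s <- sprintf("%.*g", d, v)
      if (nchar(s) <= 8) return(s)
    }
    stop("cannot encode physical range in 8 chars")
  }
  phys_lo_s <- fit8(min(x)); phys_hi_s <- fit8(max(x))
  phys_lo <- as.numeric(phys_lo_s); phys_hi <- as.numeric(phys_hi_s)
  if (phys_hi <= phys_lo) phys_hi <- phys_lo + 1
  x <- pmin(pmax(x, phys_lo), phys_hi)
  dmin <- -32768L; dmax <- 32767L
  dig <- as.integer(round((x - phys_lo) / (phys_hi - phys_lo) *
                            (dmax - dmin) + dmin))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("X X X", 80),
    edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + 256, 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad("1", 4)
  )
  sig <- paste0(
    edf_pad(attr(eeg, "channel") %||% "EEG", 16), edf_pad("", 80),
    edf_pad("uV", 8),
    edf_pad(phys_lo_s, 8), edf_pad(phys_hi_s, 8),
    edf_pad(dmin, 8), edf_pad(dmax, 8),
    edf_pad(paste0("HP:", attr(eeg, "filter_band")[1], "Hz"), 80),
    edf_pad(sr, 8), edf_pad("", 32)
  )
  writeChar(paste0(hdr, sig), con, eos = NULL)
  writeBin(dig, con, size = 2, endian = "little")
  invisible(path)
}

#' Read the first channel of an EDF file as an EEG record
#'
#' Supports continuous EDF with 16-bit samples. Only the first signal is
#' returned.
#'
#' @param path Path to an EDF file.
#' @param filter_band Acquisition band attached to the returned record.
#' @return An [eeg_record()].
#' @export
read_edf <- function(path, filter_band = c(0.1, 40)) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  .assert(ns >= 1, "EDF file declares no signals")
  field <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- field(16); field(80); field(8)
  pmin <- as.numeric(field(8)); pmax <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
  field(80)
  nsamp <- as.integer(field(8)); field(32)
  per_rec <- sum(nsamp)
  raw <- readBin(con, "integer", n = n_rec * per_rec, size = 2,
                 endian = "little", signed = TRUE)
  idx <- rep(rep(seq_len(ns), times = nsamp), times = n_rec)
  dig <- raw[idx == 1]
  x <- (dig - dmin[1]) / (dmax[1] - dmin[1]) * (pmax[1] - pmin[1]) + pmin[1]
  eeg_record(x, sample_rate = nsamp[1] / rec_dur, channel = labels[1],
             filter_band = filter_band)
}
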