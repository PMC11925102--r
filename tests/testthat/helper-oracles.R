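# Brute-force oracles, written independently of the package internals:
# plain element-wise scans with no run-length encoding.

# maximal same-state runs of `state`: data frame start, len
oracle_runs <- function(states, state) {
  starts <- integer(0); lens <- integer(0)
  i <- 1L; n <- length(states)
  while (i <= n) {
    if (states[i] == state) {
      j <- i
      while (j < n && states[j + 1L] == state) j <- j + 1L
      starts <- c(starts, i); lens <- c(lens, j - i + 1L)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(start = starts, len = lens)
}

# brief arousals: wake runs < max_wake_s flanked by NR runs >= min_flank_s
oracle_arousals <- function(states, epoch_len = 4, max_wake_s = 16,
                            min_flank_s = 20) {
  n <- length(states)
  hits <- integer(0)
  i <- 1L
  while (i <= n) {
    if (states[i] == "W") {
      j <- i
      while (j < n && states[j + 1L] == "W") j <- j + 1L
      if ((j - i + 1L) * epoch_len < max_wake_s && i > 1L && j < n) {
        # left flank: maximal NR run ending at i-1
        l <- i - 1L
        while (l > 1L && states[l - 1L] == "NR") l <- l - 1L
        left_ok <- states[i - 1L] == "NR" &&
          (i - l) * epoch_len >= min_flank_s
        r <- j + 1L
        while (r < n && states[r + 1L] == "NR") r <- r + 1L
        right_ok <- states[j + 1L] == "NR" &&
          (r - j) * epoch_len >= min_flank_s
        if (left_ok && right_ok) hits <- c(hits, i)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  hits
}

# immobility rule: label each sample sleep iff it lies in a quiet run
# (magnitude <= thr) lasting >= min_s seconds
oracle_immobility <- function(magnitude, thr, sr = 1, min_s = 40) {
  n <- length(magnitude)
  asleep <- logical(n)
  i <- 1L
  while (i <= n) {
    if (magnitude[i] <= thr) {
      j <- i
      while (j < n && magnitude[j + 1L] <= thr) j <- j + 1L
      if ((j - i + 1L) / sr >= min_s) asleep[i:j] <- TRUE
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  asleep
}

# sleep-to-wake transitions assigned to the wake-onset sample
oracle_frag_count <- function(asleep, keep) {
  count <- 0L
  for (i in seq_len(length(asleep) - 1L)) {
    if (asleep[i] && !asleep[i + 1L] && keep[i + 1L]) count <- count + 1L
  }
  count
}

# direct-sum periodogram power at frequency f (independent of mvfft)
oracle_periodogram_power <- function(x, f, sr) {
  n <- length(x)
  tt <- (seq_len(n) - 1) / sr
  2 * (sum(x * cos(2 * pi * f * tt))^2 + sum(x * sin(2 * pi * f * tt))^2) / n^2
}

random_states <- function(n, seed = NULL,
                          prob = c(W = 0.4, NR = 0.45, R = 0.15)) {
  if (!is.null(seed)) set.seed(seed)
  sample(c("W", "NR", "R"), n, replace = TRUE, prob = prob)
}

# synthetic spectral frame with a given epochs x bins power matrix
make_frame <- function(power_matrix, bins) {
  out <- tibble::tibble(
    epoch = rep(seq_len(nrow(power_matrix)), each = length(bins)),
    bin_start = rep(bins, times = nrow(power_matrix)),
    power = as.vector(t(power_matrix))
  )
  structure(out, bin_width = diff(bins[1:2]), n_epochs = nrow(power_matrix),
            class = c("spectral_frame", class(tibble::tibble())))
}
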