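cfg <- generator_config()

test_that("with zero rocking gain, rocking-on and rocking-off days are identical", {
  cfg0 <- generator_config(rocking_gain = 0)
  h_on <- simulate_hypnogram(cfg0, design_day(rocking = TRUE), seed = 42)
  h_off <- simulate_hypnogram(cfg0, design_day(rocking = FALSE), seed = 42)
  expect_equal(as.character(h_on$state), as.character(h_off$state))
})

test_that("dark-period dynamics are unchanged by rocking (same seed, exact)", {
  h_on <- simulate_hypnogram(cfg, design_day(rocking = TRUE), seed = 9)
  h_off <- simulate_hypnogram(cfg, design_day(rocking = FALSE), seed = 9)
  expect_false(identical(as.character(h_on$state[h_on$phase == "light"]),
                         as.character(h_off$state[h_off$phase == "light"])))
  # the dark half consumes the same RNG substream only if the light half
  # used the same number of draws, so compare distributions instead
  dark_on <- sapply(1:40, function(i)
    state_amounts(simulate_hypnogram(cfg, design_day(TRUE), seed = i),
                  "dark")$minutes[2])
  dark_off <- sapply(41:80, function(i)
    state_amounts(simulate_hypnogram(cfg, design_day(FALSE), seed = i),
                  "dark")$minutes[2])
  expect_gt(stats::t.test(dark_on, dark_off)$p.value, 0.05)
})

test_that("rocking without habituation increases light-period NREM sleep", {
  cfg_inf <- generator_config(tau_within = 1e9, tau_across = 1e9)
  n <- 40
  nr_on <- sapply(seq_len(n), function(i)
    state_amounts(simulate_hypnogram(cfg_inf, design_day(TRUE), seed = 100 + i),
                  "light")$minutes[2])
  nr_off <- sapply(seq_len(n), function(i)
    state_amounts(simulate_hypnogram(cfg_inf, design_day(FALSE), seed = 500 + i),
                  "light")$minutes[2])
  expect_gt(mean(nr_on), mean(nr_off) + 30) # strong, not marginal
})

test_that("within-day habituation concentrates the NREM gain early in the light period", {
  n <- 60
  gain_bins <- function(rocking, seed0) {
    t(sapply(seq_len(n), function(i) {
      h <- simulate_hypnogram(cfg, design_day(rocking), seed = seed0 + i)
      time_course(h, "NR", bin_h = 2)$minutes[c(1, 6)]
    }))
  }
  on <- gain_bins(TRUE, 0); off <- gain_bins(FALSE, 2000)
  gain_early <- mean(on[, 1]) - mean(off[, 1]) # ZT0-2
  gain_late <- mean(on[, 2]) - mean(off[, 2])  # ZT10-12
  expect_gt(gain_early, gain_late)
  expect_gt(gain_early, 0)
})

test_that("without rocking, light-period NREM is distribution-stable across cycles", {
  n <- 100
  nr_c1 <- sapply(seq_len(n), function(i)
    state_amounts(simulate_hypnogram(cfg, design_day(FALSE, cycle = 1),
                                     seed = i), "light")$minutes[2])
  nr_c9 <- sapply(seq_len(n), function(i)
    state_amounts(simulate_hypnogram(cfg, design_day(FALSE, cycle = 9),
                                     seed = 10000 + i), "light")$minutes[2])
  expect_gt(suppressWarnings(stats::ks.test(nr_c1, nr_c9)$p.value), 0.01)
})

test_that("REM is entered only from NREM", {
  for (s in 1:5) {
    h <- simulate_hypnogram(cfg, design_day(TRUE), seed = s)
    st <- as.character(h$state)
    before_rem <- st[which(st[-1] == "R" & st[-length(st)] != "R")]
    expect_true(all(before_rem == "NR"))
  }
})

test_that("cohort with zero between-mouse variability uses the shared dwell parameters", {
  des <- block_design(n_cycles = 1, days_per_block = 2, baseline_days = 3)
  spec <- cohort_spec(2, des, group = "SE", between_mouse_sd = 0, seed = 5)
  coh <- simulate_cohort(spec, cfg, motion = FALSE, include_rest_weeks = FALSE)
  row <- coh[coh$mouse == 2 & !coh$is_baseline & coh$day == 1, ]
  ref <- simulate_hypnogram(cfg, design_day(TRUE, cycle = 1, day = 1),
                            seed = 5 + 2 * 100000L + row$sched_day * 100L)
  expect_equal(as.character(row$hypnogram[[1]]$state), as.character(ref$state))
})

test_that("cohort simulation is reproducible and respects the schedule", {
  des <- block_design(n_cycles = 2, days_per_block = 7, baseline_days = 3)
  spec <- cohort_spec(1, des, group = "SE", between_mouse_sd = 0.1, seed = 3)
  a <- simulate_cohort(spec, cfg, motion = FALSE, include_rest_weeks = FALSE)
  b <- simulate_cohort(spec, cfg, motion = FALSE, include_rest_weeks = FALSE)
  expect_identical(
    lapply(a$hypnogram, function(h) as.character(h$state)),
    lapply(b$hypnogram, function(h) as.character(h$state))
  )
  expect_equal(nrow(a), 3 + 14) # 3 baseline + 2 stimulation weeks
  expect_true(all(!a$hypnogram[[1]]$rocking_on)) # baseline day: no rocking
  stim <- a[!a$is_baseline, ]
  expect_true(all(sapply(stim$hypnogram, function(h)
    any(h$rocking_on) && !any(h$rocking_on[h$phase == "dark"]))))
  # control group: platform never moves
  spec_s <- cohort_spec(1, des, group = "S", between_mouse_sd = 0, seed = 3)
  cs <- simulate_cohort(spec_s, cfg, motion = FALSE, include_rest_weeks = FALSE)
  expect_true(all(!sapply(cs$hypnogram, function(h) any(h$rocking_on))))
})

test_that("simulated EEG carries the configured state oscillations", {
  hyp_mix <- hypnogram(c(rep("W", 20), rep("NR", 20), rep("R", 20)))
  eeg <- simulate_eeg(hyp_mix, cfg, seed = 8)
  sf <- epoch_psd(eeg, hyp_mix)
  # rocking-off NREM: argmax at the baseline delta peak
  expect_equal(spectral_peak(state_spectrum(sf, hyp_mix, "NR"), c(0.5, 30)),
               cfg$delta_peak_base)
  # REM: theta peak
  expect_equal(spectral_peak(state_spectrum(sf, hyp_mix, "R"), c(4, 30)),
               cfg$theta_freq)
  # rocking-on NREM: entrained at entrain_factor x rocking_freq
  hyp_on <- hypnogram(rep("NR", 30), rocking_on = TRUE)
  sf_on <- epoch_psd(simulate_eeg(hyp_on, cfg, seed = 8), hyp_on)
  expect_equal(spectral_peak(state_spectrum(sf_on, hyp_on, "NR")),
               cfg$entrain_factor * cfg$rocking_freq)
  # all-wake day: NREM selection is empty-flagged, not zero-filled
  hyp_w <- hypnogram(rep("W", 30))
  sf_w <- epoch_psd(simulate_eeg(hyp_w, cfg, seed = 1), hyp_w)
  sp <- state_spectrum(sf_w, hyp_w, "NR")
  expect_true(attr(sp, "empty"))
  expect_equal(attr(sp, "n_epochs"), 0L)
  expect_true(all(is.na(sp$power)))
})

test_that("motion traces obey the wake gap cap and sleep quietness", {
  # all-sleep hypnogram with no twitches: zero supra-threshold samples
  cfg_q <- generator_config(twitch_rate_sleep = 0)
  hyp_s <- hypnogram(rep("NR", 900)) # 1 h
  mt <- simulate_motion(hyp_s, cfg_q, seed = 3)
  expect_equal(sum(mt$magnitude > attr(mt, "threshold")), 0)
  # wake runs: no quiet gap (boundaries included) exceeds the cap
  hyp_w <- hypnogram(rep("W", 900))
  mtw <- simulate_motion(hyp_w, cfg_q, seed = 4)
  mov <- which(mtw$magnitude > attr(mtw, "threshold"))
  gaps <- diff(c(0, mov, nrow(mtw) + 1)) - 1
  expect_lte(max(gaps), cfg_q$motion_gap_cap_wake)
})

test_that("with no twitches the immobility rule recovers sleep except at bout edges", {
  cfg_q <- generator_config(twitch_rate_sleep = 0, motion_gap_cap_wake = 20)
  # long consolidated bouts (every sleep run >= 40 s)
  states <- rep(rep(c("W", "NR"), 10), each = 45)
  hyp <- hypnogram(states)
  mt <- simulate_motion(hyp, cfg_q, seed = 6)
  sw <- infer_sleep(mt, min_immobility_s = 40)
  truth <- rep(states != "W", each = 4)
  mismatch <- which(sw$asleep != truth)
  # every mismatched second lies within one gap-cap of a state transition
  trans_s <- (which(diff(states != "W") != 0)) * 4
  if (length(mismatch) > 0) {
    d <- sapply(mismatch, function(s) min(abs(s - trans_s)))
    expect_lte(max(d), cfg_q$motion_gap_cap_wake)
  }
  expect_gt(mean(sw$asleep == truth), 0.9)
})
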