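quiet_trace <- function(pattern, sr = 1) {
  # pattern: numeric vector, 0 = quiet, 1 = moving
  motion_trace(ifelse(pattern > 0, 1, 0.1), sample_rate = sr, threshold = 0.5)
}

test_that("the immobility rule splits exactly at 40 s", {
  # 40-s quiet run: sleep in full (including its first seconds)
  tr40 <- quiet_trace(c(1, rep(0, 40), 1))
  expect_equal(sum(infer_sleep(tr40)$asleep), 40)
  # 39-s quiet run: wake
  tr39 <- quiet_trace(c(1, rep(0, 39), 1))
  expect_equal(sum(infer_sleep(tr39)$asleep), 0)
})

test_that("immobility labeling matches the brute-force scan on random traces", {
  for (s in 1:300) {
    set.seed(s)
    mag <- ifelse(runif(300) < 0.03, 1, 0.1)
    tr <- motion_trace(mag, sample_rate = 1, threshold = 0.5)
    expect_equal(infer_sleep(tr)$asleep,
                 oracle_immobility(mag, 0.5, 1, 40))
  }
})

test_that("infer_sleep is idempotent and monotone in the immobility threshold", {
  set.seed(2)
  mag <- ifelse(runif(2000) < 0.02, 1, 0.1)
  tr <- motion_trace(mag, sample_rate = 1, threshold = 0.5)
  a <- infer_sleep(tr, 40)
  b <- infer_sleep(tr, 40)
  expect_identical(a$asleep, b$asleep)
  shorter <- infer_sleep(tr, 20)
  expect_true(all(shorter$asleep >= a$asleep)) # lowering never loses sleep
})

test_that("sleep amount sums correctly and conserves period length", {
  all_sleep <- sleep_wake_series(rep(TRUE, 43200), sample_rate = 1)
  expect_equal(sleep_amount(all_sleep, "light"), 720)
  all_wake <- sleep_wake_series(rep(FALSE, 86400), sample_rate = 1)
  expect_equal(sleep_amount(all_wake, "24h"), 0)
  set.seed(4)
  sw <- sleep_wake_series(runif(86400) < 0.6, sample_rate = 1)
  wake_min <- sum(!sw$asleep & sw$t_s %% 86400 < 43200) / 60
  expect_equal(sleep_amount(sw, "light") + wake_min, 720)
})

test_that("fragmentation index counts sleep-to-wake transitions per hour", {
  # S,W,S,W in 2 h -> 2 transitions -> 1.0/h
  sw <- sleep_wake_series(rep(c(TRUE, FALSE), each = 1800, times = 2),
                          sample_rate = 1)
  expect_equal(fragmentation_index(sw, "24h"), 1.0)
  # monophasic sleep: 0
  mono <- sleep_wake_series(rep(TRUE, 7200), sample_rate = 1)
  expect_equal(fragmentation_index(mono, "24h"), 0)
  # exact-count invariant: index x hours is an integer
  set.seed(8)
  r <- sleep_wake_series(runif(7200) < 0.5, sample_rate = 1)
  expect_equal(fragmentation_index(r, "24h") * 2 %% 1, 0)
})

test_that("reversing a series swaps the counted transition type", {
  for (s in 1:50) {
    set.seed(s)
    x <- runif(500) < 0.5
    fwd <- sleep_wake_series(x, sample_rate = 1)
    rev_sw <- sleep_wake_series(rev(x), sample_rate = 1)
    sw_trans <- sum(x[-length(x)] & !x[-1])       # sleep -> wake
    ws_trans <- sum(!x[-length(x)] & x[-1])       # wake -> sleep
    keep <- rep(TRUE, 500)
    expect_equal(fragmentation_index(fwd, "24h") * (500 / 3600), sw_trans)
    expect_equal(fragmentation_index(rev_sw, "24h") * (500 / 3600), ws_trans)
    expect_lte(abs(sw_trans - ws_trans), 1)
    expect_equal(sw_trans, oracle_frag_count(x, keep))
  }
})

test_that("baseline normalization maps the baseline mean to exactly 1", {
  df <- tibble::tibble(day = 1:5, v = c(10, 10, 10, 12, 10),
                       bsl = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  out <- normalize_to_baseline(df, v, bsl)
  expect_equal(out$value_norm, c(1, 1, 1, 1.2, 1))
  # baseline days average to exactly 1.0
  df2 <- tibble::tibble(v = c(8, 12, 10, 15), bsl = c(TRUE, TRUE, TRUE, FALSE))
  out2 <- normalize_to_baseline(df2, v, bsl)
  expect_equal(mean(out2$value_norm[df2$bsl]), 1.0)
  # scale invariance
  out3 <- normalize_to_baseline(dplyr::mutate(df2, v = v * 7.3), v, bsl)
  expect_equal(out3$value_norm, out2$value_norm)
  expect_error(normalize_to_baseline(
    tibble::tibble(v = 1, bsl = FALSE), v, bsl), "baseline")
})

test_that("longitudinal matrices average across mice with NA-safe profiles", {
  des <- block_design(n_cycles = 2, days_per_block = 7, baseline_days = 3)
  # constant metric -> all ones
  grid <- tidyr::expand_grid(mouse = 1:3, cycle = 1:2, day = 1:7)
  lm1 <- build_matrix(dplyr::mutate(grid, v = 1), des, v)
  expect_true(all(tidy(lm1)$value == 1))
  expect_true(all(lm1$day_profile$value == 1))
  # single mouse, single cycle: matrix equals the input row
  one <- tibble::tibble(mouse = 1, cycle = 1, day = 1:7, v = c(5, 4, 3, 2, 1, 2, 3))
  des1 <- block_design(n_cycles = 1)
  lm2 <- build_matrix(one, des1, v)
  expect_equal(tidy(lm2)$value, one$v)
  # profiles equal brute-force group-by means; missing cells excluded
  set.seed(3)
  m <- dplyr::mutate(grid, v = rnorm(dplyr::n(), 10))
  m <- m[-5, ] # drop one (mouse, cycle, day) observation
  lm3 <- build_matrix(m, des, v)
  for (d in 1:7) {
    cell_vals <- sapply(1:2, function(cy)
      mean(m$v[m$day == d & m$cycle == cy]))
    expect_equal(lm3$day_profile$value[lm3$day_profile$day == d],
                 mean(cell_vals))
  }
  for (cy in 1:2) {
    cell_vals <- sapply(1:7, function(d)
      mean(m$v[m$day == d & m$cycle == cy]))
    expect_equal(lm3$cycle_profile$value[lm3$cycle_profile$cycle == cy],
                 mean(cell_vals))
  }
  g <- glance(lm3)
  expect_equal(c(g$n_days, g$n_cycles), c(7, 2))
  expect_error(build_matrix(dplyr::mutate(grid, cycle = cycle + 5), des, v),
               "outside")
})

test_that("a small two-cycle cohort yields a 7 x 2 day-by-cycle matrix", {
  cfg <- generator_config()
  des <- block_design(n_cycles = 2, days_per_block = 7, baseline_days = 3)
  spec <- cohort_spec(2, des, group = "SE", between_mouse_sd = 0.05, seed = 21)
  coh <- simulate_cohort(spec, cfg, motion = FALSE, include_rest_weeks = FALSE)
  met <- cohort_sleep_metrics(coh, source = "hypnogram")
  norm <- met |>
    dplyr::group_by(mouse) |>
    dplyr::group_modify(~ normalize_to_baseline(.x, sleep_min, is_baseline)) |>
    dplyr::ungroup()
  lm <- build_matrix(norm[!norm$is_baseline, ], des, value_norm)
  expect_equal(lm$n_days, 7)
  expect_equal(lm$n_cycles, 2)
  expect_equal(nrow(tidy(lm)), 14)
  expect_true(all(is.finite(tidy(lm)$value)))
})

test_that("concordance is exact for identical and complementary series", {
  h <- hypnogram(random_states(1000, seed = 2))
  truth <- sleep_series(h)
  expect_equal(concordance(truth, h), 1.0)
  flipped <- sleep_wake_series(!truth$asleep, sample_rate = 1)
  expect_equal(concordance(flipped, h), 0.0)
})

test_that("concordance uses strict epoch majority", {
  h <- hypnogram(c("NR", "W"))
  # epoch 1: 2/4 samples asleep -> not a majority -> wake -> mismatch
  sw <- sleep_wake_series(c(TRUE, TRUE, FALSE, FALSE, rep(FALSE, 4)),
                          sample_rate = 1)
  expect_equal(concordance(sw, h), 0.5)
  # 3/4 asleep -> sleep
  sw2 <- sleep_wake_series(c(TRUE, TRUE, TRUE, FALSE, rep(FALSE, 4)),
                           sample_rate = 1)
  expect_equal(concordance(sw2, h), 1.0)
})
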