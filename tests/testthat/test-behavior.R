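# brute-force circular zero-run scan used as the oracle for sleep extraction
brute_zero_runs <- function(binary) {
  n <- length(binary)
  starts <- which(binary == 0L & binary[((seq_len(n) - 2L) %% n) + 1L] == 1L)
  runs <- lapply(starts, function(s) {
    len <- 0L
    while (binary[((s - 1L + len) %% n) + 1L] == 0L) len <- len + 1L
    list(start = s - 1L, length = len)
  })
  runs
}

brute_longest_run <- function(binary, anchor) {
  runs <- brute_zero_runs(binary)
  lens <- vapply(runs, `[[`, integer(1), "length")
  best <- runs[lens == max(lens)]
  covers <- vapply(best, function(r) {
    ((anchor - r$start) %% length(binary)) < r$length
  }, logical(1))
  if (any(covers)) return(best[[which(covers)[1L]]])
  best[[which.min(vapply(best, `[[`, integer(1), "start"))]]
}

test_that("sleep extraction recovers the household-A narrative", {
  # motion in slots 11-44: sleep 10:30 pm (slot 45), wake 5:30 am (slot 11)
  sw <- extract_sleep_wake(pattern_hh_a())
  expect_equal(sw$sleep_slot, 45L)
  expect_equal(sw$wake_slot, 11L)
  expect_equal(sw$sleep_duration_minutes, 420)
})

test_that("degenerate patterns yield undefined sleep parameters", {
  sw0 <- extract_sleep_wake(rep(0L, 48L))
  expect_true(is.na(sw0$wake_slot) && is.na(sw0$sleep_slot))
  sw1 <- extract_sleep_wake(rep(1L, 48L))
  expect_true(is.na(sw1$wake_slot) && is.na(sw1$sleep_slot))
  expect_error(extract_sleep_wake(rep(0L, 12L)), "48")
})

test_that("longest circular zero run matches exhaustive enumeration on 12 slots", {
  # every 12-slot binary pattern except the two degenerate ones
  for (code in 1:(2^12 - 2L)) {
    binary <- as.integer(intToBits(code)[1:12])
    got <- pirvae:::longest_zero_run(binary, anchor = 2L)
    ref <- brute_longest_run(binary, anchor = 2L)
    expect_identical(got$start, ref$start)
    expect_identical(got$length, ref$length)
  }
})

test_that("ties are broken toward the run containing 3:00 am", {
  # two 11-slot zero runs: one over midnight (44..47,0..6) containing 3:00 am,
  # one midday (20..30)
  b <- rep(1L, 48L)
  b[c(45:48, 1:7)] <- 0L
  b[21:31] <- 0L
  sw <- extract_sleep_wake(b)
  expect_equal(sw$sleep_slot, 44L)
  expect_equal(sw$wake_slot, 7L)
  expect_equal(sw$sleep_duration_minutes, 330)
})

test_that("minutes at home counts motion and optionally the sleep run", {
  expect_equal(minutes_at_home(rep(0L, 48L)), 0)
  expect_equal(minutes_at_home(pattern_hh_a(), mode = "motion"), 34 * 30)
  # 34 motion slots + 14-slot sleep run = a full day at home
  expect_equal(minutes_at_home(pattern_hh_a(), mode = "motion_sleep"), 1440)
  one_more <- pattern_hh_a()
  one_more[47L] <- 1L
  expect_equal(minutes_at_home(one_more, mode = "motion") -
                 minutes_at_home(pattern_hh_a(), mode = "motion"), 30)
  # monotone in the number of positive slots
  set.seed(2)
  d <- rep(0L, 48L)
  prev <- 0
  for (slot in sample(48L)) {
    d[slot] <- 1L
    cur <- minutes_at_home(d, mode = "motion")
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("regular pattern recovers a clean schedule from a trained model", {
  fx <- overfit_fixture()
  rp <- regular_pattern(fx$model, fx$dm)
  expect_length(rp$probs, 48L)
  expect_true(all(rp$probs >= 0 & rp$probs <= 1))
  expect_equal(rp$binary, fx$pattern)
  expect_equal(rp$binary, as.integer(rp$probs >= 0.5))
  expect_error(regular_pattern(fit_lstm_vae(fx$dm, toy_cfg(epochs = 0L)),
                               fx$dm), "untrained")
})

test_that("weekday subsets partition the year", {
  dm <- build_day_matrix(generate_household(noiseless_spec(n_days = 365L)))
  sizes <- table(dm$day_of_week)
  expect_equal(sum(sizes), 365L)
  expect_true(all(sizes %in% c(52L, 53L)))
})

test_that("per-weekday models expose a weekend schedule difference", {
  spec <- household_spec(p_fire_active = 1, p_fire_idle = 0,
                         wake_slot = 14L, depart_slot = 19L, return_slot = 33L,
                         sleep_slot = 45L,
                         weekend_profile = list(depart_slot = NA,
                                                return_slot = NA),
                         n_days = 140L, seed = 31L)
  dm <- build_day_matrix(generate_household(spec))
  pats <- weekday_models(dm, toy_cfg(epochs = 25L), min_days = 10L)
  expect_named(pats, c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"))
  midday <- 20:33  # inside the weekday away window
  expect_true(any(pats$Mon$binary[midday] == 0L))
  expect_true(all(pats$Sat$binary[midday] == 1L))
  expect_true(all(pats$Sun$binary[midday] == 1L))
  # undersized subsets are skipped with a warning
  small <- dm_subset(dm, which(dm$day_of_week == 0L)[1:5])
  w <- capture_warnings(p2 <- weekday_models(small, toy_cfg(epochs = 1L),
                                             min_days = 10L))
  expect_length(w, 7L)
  expect_match(w, "undefined", all = TRUE)
  expect_true(all(vapply(p2, is.null, logical(1))))
})

test_that("weekend-vs-weekday test matches the enumeration oracle", {
  # all days identical: no evidence of a difference
  tied <- weekend_weekday_test(rep(600, 14), rep(0:6, 2))
  expect_equal(tied$p_value, 1)
  # 3 vs 3 values without ties: U equals the concordant-pair count
  minutes <- c(700, 680, 720, 500, 510, 490)
  dow <- c(5L, 5L, 6L, 0L, 1L, 2L)
  got <- weekend_weekday_test(minutes, dow)
  u_oracle <- sum(outer(minutes[1:3], minutes[4:6], `>`))
  expect_equal(got$statistic, u_oracle)
  expect_error(weekend_weekday_test(rep(1, 5), rep(0L, 5)), "non-empty")
})

test_that("a generator weekend effect is detected as significant", {
  # weekend away window 6 slots shorter: +180 min at home per weekend day
  spec <- household_spec(wake_slot = 14L, depart_slot = 19L, return_slot = 33L,
                         sleep_slot = 45L,
                         weekend_profile = list(depart_slot = 22L,
                                                return_slot = 30L),
                         n_days = 365L, seed = 47L)
  dm <- build_day_matrix(generate_household(spec))
  mins <- apply(dm$X, 1L, minutes_at_home)
  res <- weekend_weekday_test(mins, dm$day_of_week)
  expect_lt(res$p_value, 0.05)
  expect_gt(mean(mins[dm$day_of_week >= 5L]) - mean(mins[dm$day_of_week < 5L]),
            120)
})

test_that("behaviour summary assembles sleep, minutes and contrast", {
  fx <- overfit_fixture()
  spec <- household_spec(p_fire_active = 1, p_fire_idle = 0,
                         wake_slot = 11L, depart_slot = 19L, return_slot = 33L,
                         sleep_slot = 45L,
                         weekend_profile = list(depart_slot = NA,
                                                return_slot = NA),
                         n_days = 60L, seed = 53L)
  dm <- build_day_matrix(generate_household(spec))
  rp <- structure(list(probs = as.numeric(pattern_hh_a()),
                       binary = pattern_hh_a(), source = "annual"),
                  class = "regular_pattern")
  bs <- summarize_behavior(rp, dm)
  expect_equal(bs$wake_slot, 11L)
  expect_equal(bs$sleep_slot, 45L)
  expect_equal(bs$sleep_duration_minutes, 420)
  expect_true(all(bs$minutes_at_home_by_dow >= 0 &
                    bs$minutes_at_home_by_dow <= 1440))
  expect_gt(mean(bs$minutes_at_home_by_dow[c("Sat", "Sun")]),
            mean(bs$minutes_at_home_by_dow[c("Mon", "Tue", "Wed", "Thu", "Fri")]))
  tab <- behavior_summary_table(bs)
  expect_equal(tab$wake_time, "05:30")
  expect_equal(tab$sleep_time, "22:30")
  expect_equal(tab$sleep_duration_minutes, 420)
})
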