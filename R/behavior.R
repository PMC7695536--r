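#' Regular activity pattern of a household
#'
#' The household's habitual 48-slot motion template: for each day the model
#' reconstructs the sequence from the posterior mean (z = mu, no sampling
#' noise), and the per-slot probabilities are averaged over all days. The
#' binary pattern thresholds the averaged probabilities at 0.5.
#'
#' @param model a trained `lstm_vae`.
#' @param dm a non-empty `day_matrix`.
#' @param source label stored on the pattern (`"annual"` or `"per_weekday"`).
#' @return object of class `regular_pattern` with `probs` (48 values in
#'   [0, 1]), `binary` (0/1, `probs >= 0.5`), and `source`.
#' @export
regular_pattern <- function(model, dm, source = "annual") {
  if (!isTRUE(model$trained)) stop("model is untrained")
  if (!inherits(dm, "day_matrix") || nrow(dm$X) == 0L) {
    stop("dm must be a non-empty day_matrix")
  }
  Y <- vae_reconstruct(model, dm$X, posterior = "mean")
  probs <- colMeans(Y)
  structure(list(probs = probs, binary = as.integer(probs >= 0.5),
                 source = source),
            class = "regular_pattern")
}

#' @export
print.regular_pattern <- function(x, ...) {
  cat("<regular_pattern> (", x$source, ") ",
      paste(x$binary, collapse = ""), "\n", sep = "")
  invisible(x)
}

# Longest circular run of zeros in a binary vector. Returns start (0-based),
# length; ties broken by the run containing `anchor` (slot 6 = 3:00 am for a
# 48-slot day), else the earliest-starting run.
longest_zero_run <- function(binary, anchor = 6L) {
  n <- length(binary)
  if (all(binary == 1L)) return(list(start = NA_integer_, length = 0L))
  if (all(binary == 0L)) return(list(start = NA_integer_, length = n))
  # unwrap: double the vector to expose circular runs
  r <- rle(c(binary, binary))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  zi <- which(r$values == 0L & starts <= n)
  lens <- pmin(r$lengths[zi], n)  # a circular run can't exceed n
  best_len <- max(lens)
  cand <- zi[lens == best_len]
  cand_starts <- (starts[cand] - 1L) %% n  # 0-based
  cand_lens <- pmin(r$lengths[cand], n)
  # tie-break: run covering the anchor slot
  covers <- vapply(seq_along(cand), function(j) {
    offs <- (anchor - cand_starts[j]) %% n
    offs < cand_lens[j]
  }, logical(1))
  pick <- if (any(covers)) which(covers)[1L] else which.min(cand_starts)
  list(start = as.integer(cand_starts[pick]), length = as.integer(best_len))
}

#' Wake time, sleep time and sleep duration from a regular pattern
#'
#' The nightly sleep period is the longest circular run of motionless slots
#' in the binary pattern (sleep typically spans midnight, hence circular).
#' Ties are resolved toward the run containing 3:00 am (slot 6), else the
#' earliest-starting run. `sleep_slot` is the first slot of that run,
#' `wake_slot` the slot immediately after it, and the duration is 30 minutes
#' per slot. All-one or all-zero patterns yield undefined (`NA`) outputs.
#'
#' @param rp a `regular_pattern` (or any binary vector of length 48).
#' @return list with `wake_slot`, `sleep_slot` (0-based slot indices or `NA`)
#'   and `sleep_duration_minutes`.
#' @export
extract_sleep_wake <- function(rp) {
  binary <- if (inherits(rp, "regular_pattern")) rp$binary else as.integer(rp)
  if (length(binary) != 48L) stop("pattern must have 48 slots")
  if (all(binary == 1L) || all(binary == 0L)) {
    return(list(wake_slot = NA_integer_, sleep_slot = NA_integer_,
                sleep_duration_minutes = NA_real_))
  }
  run <- longest_zero_run(binary, anchor = 6L)
  list(wake_slot = as.integer((run$start + run$length) %% 48L),
       sleep_slot = run$start,
       sleep_duration_minutes = 30 * run$length)
}

#' Minutes at home in a day or pattern
#'
#' In `"motion"` mode (raw single days), time at home is 30 minutes per
#' motion-positive slot. In `"motion_sleep"` mode (regular patterns, where
#' the nightly motionless run can be attributed to sleep rather than
#' absence), the sleep run also counts as at home.
#'
#' @param x binary vector of 48 slots, or a `regular_pattern`.
#' @param mode `"motion"` or `"motion_sleep"`.
#' @return minutes in [0, 1440].
#' @export
minutes_at_home <- function(x, mode = c("motion", "motion_sleep")) {
  mode <- match.arg(mode)
  binary <- if (inherits(x, "regular_pattern")) x$binary else as.integer(x)
  if (length(binary) != 48L) stop("day must have 48 slots")
  mins <- 30 * sum(binary)
  if (mode == "motion_sleep") {
    sw <- extract_sleep_wake(binary)
    if (!is.na(sw$sleep_duration_minutes)) mins <- mins + sw$sleep_duration_minutes
  }
  min(mins, 1440)
}

#' Day-of-week specific regular patterns
#'
#' Splits the year into its seven day-of-week subsets and trains a separate
#' model per weekday, returning each subset's regular pattern. Subsets
#' smaller than `min_days` are skipped with a warning (undefined pattern).
#'
#' @param dm a `day_matrix` covering the year.
#' @param config a [vae_config()]; the seed is offset by the weekday index so
#'   the seven fits are independent yet reproducible.
#' @param min_days minimum subset size (default 20).
#' @return named list of 7 `regular_pattern` objects (Mon..Sun) or `NULL`
#'   where a subset was undersized.
#' @export
weekday_models <- function(dm, config = vae_config(), min_days = 20L) {
  out <- stats::setNames(vector("list", 7L),
                         c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"))
  for (d in 0:6) {
    idx <- which(dm$day_of_week == d)
    if (length(idx) < min_days) {
      warning("weekday ", names(out)[d + 1L], " has only ", length(idx),
              " days (< ", min_days, "): pattern undefined")
      next
    }
    sub <- dm_subset(dm, idx)
    cfg <- config
    cfg$seed <- config$seed + d
    model <- fit_lstm_vae(sub, cfg)
    out[[d + 1L]] <- regular_pattern(model, sub, source = "per_weekday")
  }
  out
}

#' Weekend versus weekday time-at-home contrast
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test comparing per-day minutes
#' at home on weekend days (Saturday, Sunday) against weekdays. Robust to the
#' non-normal, tie-heavy minute distributions; completely tied inputs return
#' p = 1 (no evidence of a difference).
#'
#' @param minutes_per_day numeric vector of per-day minutes at home.
#' @param day_of_week integer 0-6 per day (0 = Monday).
#' @return list with `statistic` (Mann-Whitney U for the weekend group) and
#'   `p_value`.
#' @export
weekend_weekday_test <- function(minutes_per_day, day_of_week) {
  if (length(minutes_per_day) != length(day_of_week)) {
    stop("minutes_per_day and day_of_week must be aligned")
  }
  we <- minutes_per_day[day_of_week >= 5L]
  wd <- minutes_per_day[day_of_week < 5L]
  if (length(we) == 0L || length(wd) == 0L) {
    stop("both weekend and weekday groups must be non-empty")
  }
  wt <- suppressWarnings(stats::wilcox.test(we, wd, exact = FALSE))
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # all observations tied: zero-variance rank statistic
  list(statistic = unname(wt$statistic), p_value = p)
}

#' Behavioural indicator summary for one household
#'
#' Combines the regular-pattern sleep parameters with per-day minutes at
#' home (motion mode on raw days) and the weekend-vs-weekday contrast.
#'
#' @param rp the household's annual `regular_pattern`.
#' @param dm the household's `day_matrix`.
#' @param minutes_mode at-home definition for the day-of-week means; see
#'   [minutes_at_home()].
#' @return object of class `behavior_summary` with `wake_slot`, `sleep_slot`,
#'   `sleep_duration_minutes`, `minutes_at_home_by_dow` (named, Mon..Sun),
#'   `weekend_vs_weekday_stat`, `weekend_vs_weekday_p`, `minutes_mode`.
#' @export
summarize_behavior <- function(rp, dm, minutes_mode = "motion") {
  sw <- extract_sleep_wake(rp)
  mins <- apply(dm$X, 1L, minutes_at_home, mode = minutes_mode)
  by_dow <- vapply(0:6, function(d) {
    v <- mins[dm$day_of_week == d]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  names(by_dow) <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  tst <- weekend_weekday_test(mins, dm$day_of_week)
  structure(list(
    household_id = dm$household_id,
    wake_slot = sw$wake_slot,
    sleep_slot = sw$sleep_slot,
    sleep_duration_minutes = sw$sleep_duration_minutes,
    minutes_at_home_by_dow = by_dow,
    weekend_vs_weekday_stat = tst$statistic,
    weekend_vs_weekday_p = tst$p_value,
    minutes_mode = minutes_mode
  ), class = "behavior_summary")
}

slot_to_hhmm <- function(slot) {
  if (is.na(slot)) return(NA_character_)
  sprintf("%02d:%02d", (slot * 30L) %/% 60L, (slot * 30L) %% 60L)
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat("<behavior_summary> ", x$household_id,
      ": wake ", slot_to_hhmm(x$wake_slot),
      ", sleep ", slot_to_hhmm(x$sleep_slot),
      ", sleep duration ", x$sleep_duration_minutes, " min",
      ", weekend-vs-weekday p = ", signif(x$weekend_vs_weekday_p, 3),
      "\n", sep = "")
  invisible(x)
}

#' Behaviour summary as a one-row data.frame
#'
#' @param bs a `behavior_summary`.
#' @return data.frame with wake/sleep times as HH:MM, duration, seven
#'   day-of-week minute means, test statistic and p-value.
#' @export
behavior_summary_table <- function(bs) {
  row <- data.frame(household_id = bs$household_id,
                    wake_time = slot_to_hhmm(bs$wake_slot),
                    sleep_time = slot_to_hhmm(bs$sleep_slot),
                    sleep_duration_minutes = bs$sleep_duration_minutes,
                    stringsAsFactors = FALSE)
  dow <- as.data.frame(as.list(bs$minutes_at_home_by_dow))
  names(dow) <- paste0("minutes_", names(bs$minutes_at_home_by_dow))
  cbind(row, dow,
        data.frame(weekend_vs_weekday_stat = bs$weekend_vs_weekday_stat,
                   weekend_vs_weekday_p = bs$weekend_vs_weekday_p,
                   minutes_mode = bs$minutes_mode))
}
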