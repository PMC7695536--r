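#' Specify a synthetic household
#'
#' A household specification defines the daily schedule and sensor behaviour
#' used by [generate_household()]. The day is divided into 48 half-hour slots
#' (slot 0 = 00:00-00:30 local time). Occupants are modelled as a single
#' household-level occupancy state: active between `wake_slot` and
#' `depart_slot`, away until `return_slot`, active again until `sleep_slot`,
#' and asleep otherwise. While active, each PIR sensor fires independently in
#' every 5-minute step with probability `p_fire_active`; while asleep or away
#' it fires spuriously with probability `p_fire_idle`.
#'
#' @param n_sensors number of PIR sensors (the study corpus required >= 8).
#' @param wake_slot,sleep_slot half-hour slot indices in 0-47 bounding the
#'   active day; `wake_slot < sleep_slot`.
#' @param depart_slot,return_slot optional slot indices of an away window
#'   (`wake_slot < depart_slot < return_slot < sleep_slot`); `NA` for a
#'   household with no regular absence.
#' @param weekend_profile optional list with elements `wake_slot`,
#'   `depart_slot`, `return_slot`, `sleep_slot` overriding the schedule on
#'   Saturdays and Sundays. Elements omitted from the list inherit the weekday
#'   value; set `depart_slot`/`return_slot` to `NA` to remove the away window
#'   at weekends.
#' @param p_fire_active probability a sensor fires in a 5-minute step while
#'   occupants are active. Default 0.25: with 8 sensors this gives an expected
#'   12 activations per active half-hour, comfortably above the motion-state
#'   threshold, while leaving realistic per-sensor sparsity.
#' @param p_fire_idle spurious firing probability while asleep/away. Default
#'   0.005 (about one false activation per sensor per 24 idle hours).
#' @param n_days number of calendar days to simulate.
#' @param missing_day_rate probability a (non-anomalous) day is dropped whole,
#'   emulating connectivity outages.
#' @param anomaly_days integer vector of 0-based day indices to corrupt.
#' @param anomaly_mode one of `"absence"` (all daytime activity suppressed),
#'   `"insomnia"` (activity continues through the night), `"shifted"`
#'   (schedule rotated by `anomaly_shift` slots).
#' @param anomaly_shift slot offset used by `anomaly_mode = "shifted"`.
#' @param seed integer seed making the generated panel reproducible.
#' @param epoch first calendar date of the simulation; the default Monday
#'   2018-01-01 anchors day-of-week arithmetic.
#'
#' @return an object of class `household_spec`.
#' @seealso [generate_household()], [generate_cohort()]
#' @export
household_spec <- function(n_sensors = 8L,
                           wake_slot = 14L,
                           depart_slot = NA_integer_,
                           return_slot = NA_integer_,
                           sleep_slot = 45L,
                           weekend_profile = NULL,
                           p_fire_active = 0.25,
                           p_fire_idle = 0.005,
                           n_days = 365L,
                           missing_day_rate = 0,
                           anomaly_days = integer(0),
                           anomaly_mode = c("absence", "insomnia", "shifted"),
                           anomaly_shift = 6L,
                           seed = 1L,
                           epoch = as.Date("2018-01-01")) {
  spec <- structure(list(
    n_sensors = as.integer(n_sensors),
    wake_slot = as.integer(wake_slot),
    depart_slot = as.integer(depart_slot),
    return_slot = as.integer(return_slot),
    sleep_slot = as.integer(sleep_slot),
    weekend_profile = weekend_profile,
    p_fire_active = p_fire_active,
    p_fire_idle = p_fire_idle,
    n_days = as.integer(n_days),
    missing_day_rate = missing_day_rate,
    anomaly_days = as.integer(sort(unique(anomaly_days))),
    anomaly_mode = match.arg(anomaly_mode),
    anomaly_shift = as.integer(anomaly_shift),
    seed = as.integer(seed),
    epoch = as.Date(epoch)
  ), class = "household_spec")
  validate_household_spec(spec)
  spec
}

validate_household_spec <- function(spec) {
  if (!inherits(spec, "household_spec")) stop("not a household_spec")
  with(spec, {
    if (n_sensors < 1L) stop("invalid spec: n_sensors must be a positive integer")
    if (n_days < 1L) stop("invalid spec: n_days must be a positive integer")
    check_schedule(wake_slot, depart_slot, return_slot, sleep_slot, "weekday")
    if (!is.null(weekend_profile)) {
      we <- resolve_weekend_profile(spec)
      check_schedule(we$wake_slot, we$depart_slot, we$return_slot, we$sleep_slot,
                     "weekend")
    }
    for (p in c(p_fire_active, p_fire_idle, missing_day_rate)) {
      if (!is.numeric(p) || p < 0 || p > 1) {
        stop("invalid spec: probabilities must lie in [0, 1]")
      }
    }
    if (p_fire_active <= p_fire_idle) {
      stop("invalid spec: p_fire_active must exceed p_fire_idle ",
           "(no schedule signal otherwise)")
    }
    if (length(anomaly_days) &&
        (min(anomaly_days) < 0L || max(anomaly_days) >= n_days)) {
      stop("invalid spec: anomaly_days must lie in {0, ..., n_days - 1}")
    }
  })
  invisible(spec)
}

check_schedule <- function(wake, depart, ret, sleep, label) {
  slot_ok <- function(s) !is.na(s) && s >= 0L && s <= 47L
  if (!slot_ok(wake) || !slot_ok(sleep)) {
    stop("invalid spec: ", label, " wake/sleep slots must lie in 0-47")
  }
  if (wake >= sleep) stop("invalid spec: ", label, " wake_slot must precede sleep_slot")
  if (is.na(depart) != is.na(ret)) {
    stop("invalid spec: ", label, " depart_slot and return_slot must be given together")
  }
  if (!is.na(depart)) {
    if (!(depart > wake && depart < ret)) {
      stop("invalid spec: ", label, " depart_slot must lie in (wake_slot, return_slot)")
    }
    if (ret >= sleep) stop("invalid spec: ", label, " return_slot must precede sleep_slot")
  }
  invisible(NULL)
}

resolve_weekend_profile <- function(spec) {
  base <- spec[c("wake_slot", "depart_slot", "return_slot", "sleep_slot")]
  wp <- spec$weekend_profile
  if (is.null(wp)) return(base)
  for (nm in intersect(names(wp), names(base))) {
    base[[nm]] <- if (is.null(wp[[nm]]) || is.na(wp[[nm]])) NA_integer_ else as.integer(wp[[nm]])
  }
  base
}

# 0 = Monday ... 6 = Sunday; weekend is dow >= 5
day_of_week <- function(dates) {
  (as.integer(as.POSIXlt(dates)$wday + 6L)) %% 7L
}

# logical vector over the 48 slots during which occupants are active
schedule_active_slots <- function(wake, depart, ret, sleep) {
  active <- rep(FALSE, 48L)
  if (is.na(depart)) {
    active[(wake:(sleep - 1L)) + 1L] <- TRUE
  } else {
    active[(wake:(depart - 1L)) + 1L] <- TRUE
    active[(ret:(sleep - 1L)) + 1L] <- TRUE
  }
  active
}

apply_anomaly <- function(active, mode, shift, wake, sleep) {
  switch(mode,
    absence  = rep(FALSE, 48L),
    insomnia = {
      night <- rep(TRUE, 48L)
      night[(wake:(sleep - 1L)) + 1L] <- FALSE  # the usual sleep period
      active | night
    },
    shifted  = active[((seq_len(48L) - 1L - shift) %% 48L) + 1L]
  )
}

#' Simulate one household-year of PIR sensor activations
#'
#' Draws a binary activation stream on the 5-minute grid for every sensor,
#' following the schedule in `spec`. On non-anomalous days each sensor fires
#' independently with `p_fire_active` during active slots and `p_fire_idle`
#' otherwise; days listed in `spec$anomaly_days` are corrupted according to
#' `spec$anomaly_mode` and carry a ground-truth label. Whole days may be
#' dropped at `missing_day_rate` (anomalous days are never dropped, so labels
#' stay consistent). Identical spec and seed give an identical panel.
#'
#' @param spec a [household_spec()].
#' @param household_id identifier stored in the panel.
#' @return an object of class `sensor_panel` with elements `household_id`,
#'   `timestamps` (POSIXct, UTC, 5-minute grid with gaps only for missing
#'   days), `activations` (0/1 matrix, steps x sensors), `dates` (distinct
#'   days present), `anomaly_labels` (0/1 per present day), `day_of_week`
#'   (0 = Monday), `days_online`.
#' @export
generate_household <- function(spec, household_id = "HH0") {
  validate_household_spec(spec)
  wd <- spec[c("wake_slot", "depart_slot", "return_slot", "sleep_slot")]
  we <- resolve_weekend_profile(spec)
  all_dates <- spec$epoch + seq_len(spec$n_days) - 1L
  dow <- day_of_week(all_dates)
  is_anom <- seq_len(spec$n_days) - 1L
  is_anom <- as.integer(is_anom %in% spec$anomaly_days)

  withr::with_seed(spec$seed, {
    present <- rep(TRUE, spec$n_days)
    if (spec$missing_day_rate > 0) {
      droppable <- which(is_anom == 0L)
      present[droppable] <- stats::runif(length(droppable)) >= spec$missing_day_rate
    }
    day_mats <- vector("list", spec$n_days)
    for (d in seq_len(spec$n_days)) {
      if (!present[d]) next
      prof <- if (dow[d] >= 5L) we else wd
      active <- schedule_active_slots(prof$wake_slot, prof$depart_slot,
                                      prof$return_slot, prof$sleep_slot)
      if (is_anom[d] == 1L) {
        active <- apply_anomaly(active, spec$anomaly_mode, spec$anomaly_shift,
                                prof$wake_slot, prof$sleep_slot)
      }
      p_step <- ifelse(rep(active, each = 6L), spec$p_fire_active, spec$p_fire_idle)
      fires <- matrix(stats::runif(288L * spec$n_sensors), 288L, spec$n_sensors) <
        p_step  # p_step recycles down rows: constant within a 5-min step
      day_mats[[d]] <- fires + 0L
    }
  })

  keep <- which(present)
  activations <- do.call(rbind, day_mats[keep])
  step_offsets <- rep((seq_len(288L) - 1L) * 300, length(keep))
  day_starts <- rep(as.POSIXct(all_dates[keep], tz = "UTC"), each = 288L)
  timestamps <- day_starts + step_offsets

  structure(list(
    household_id = household_id,
    timestamps = timestamps,
    activations = activations,
    dates = all_dates[keep],
    anomaly_labels = is_anom[keep],
    day_of_week = dow[keep],
    days_online = length(keep),
    spec = spec  # generating spec kept as ground truth for synthetic panels
  ), class = "sensor_panel")
}

#' Simulate a cohort of households with jittered schedules
#'
#' Produces `n_households` panels from a common base schedule. Each household
#' receives independent integer offsets, uniform on `-jitter_slots` to
#' `jitter_slots`, applied to wake, departure, return and sleep slots
#' (clamped so the schedule invariants hold), plus its own derived seed, so
#' the cohort is heterogeneous yet fully reproducible.
#'
#' @param n_households number of households (>= 1).
#' @param base_spec a [household_spec()] shared by the cohort.
#' @param seed cohort-level seed.
#' @param jitter_slots maximum schedule offset in half-hour slots.
#' @return list of `sensor_panel` objects with ids `"HH0"`, `"HH1"`, ...
#' @export
generate_cohort <- function(n_households, base_spec, seed = 1L, jitter_slots = 2L) {
  if (n_households < 1L) stop("n_households must be >= 1")
  validate_household_spec(base_spec)
  withr::with_seed(seed, {
    offs <- matrix(sample(-jitter_slots:jitter_slots,
                          4L * n_households, replace = TRUE),
                   nrow = n_households)
    hh_seeds <- sample.int(.Machine$integer.max - 1L, n_households)
  })
  lapply(seq_len(n_households), function(i) {
    sp <- base_spec
    sp$wake_slot <- clamp_slot(sp$wake_slot + offs[i, 1L], 0L, 46L)
    sp$sleep_slot <- clamp_slot(sp$sleep_slot + offs[i, 2L], sp$wake_slot + 1L, 47L)
    if (!is.na(sp$depart_slot)) {
      sp$depart_slot <- clamp_slot(sp$depart_slot + offs[i, 3L],
                                   sp$wake_slot + 1L, sp$sleep_slot - 2L)
      sp$return_slot <- clamp_slot(sp$return_slot + offs[i, 4L],
                                   sp$depart_slot + 1L, sp$sleep_slot - 1L)
    }
    sp$seed <- hh_seeds[i]
    generate_household(sp, household_id = paste0("HH", i - 1L))
  })
}

clamp_slot <- function(x, lo, hi) as.integer(pmin(pmax(x, lo), hi))

#' @export
print.sensor_panel <- function(x, ...) {
  cat("<sensor_panel> ", x$household_id, ": ",
      ncol(x$activations), " sensors, ", x$days_online, " days online, ",
      sum(x$anomaly_labels), " labelled anomalous day(s)\n", sep = "")
  invisible(x)
}

#' Write / read a sensor panel as CSV
#'
#' The activation file has an ISO-8601 `timestamp` column followed by one 0/1
#' column per sensor (`sensor_0`, ...); the sidecar label file has `date` and
#' `is_anomaly` columns. [read_sensor_panel()] inverts [write_sensor_panel()]
#' and accepts any real export in the same dialect.
#'
#' @param panel a `sensor_panel`.
#' @param activations_file,labels_file CSV paths; `labels_file` may be `NULL`
#'   when no ground truth exists (real data).
#' @param household_id id to attach on read.
#' @return `write_sensor_panel` returns the panel invisibly;
#'   `read_sensor_panel` returns a `sensor_panel`.
#' @export
write_sensor_panel <- function(panel, activations_file, labels_file = NULL) {
  df <- data.frame(timestamp = format(panel$timestamps, "%Y-%m-%dT%H:%M:%SZ",
                                      tz = "UTC"))
  act <- as.data.frame(panel$activations)
  names(act) <- paste0("sensor_", seq_len(ncol(act)) - 1L)
  utils::write.csv(cbind(df, act), activations_file, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(labels_file)) {
    utils::write.csv(data.frame(date = format(panel$dates),
                                is_anomaly = panel$anomaly_labels),
                     labels_file, row.names = FALSE, quote = FALSE)
  }
  invisible(panel)
}

#' @rdname write_sensor_panel
#' @export
read_sensor_panel <- function(activations_file, labels_file = NULL,
                              household_id = "HH0") {
  df <- utils::read.csv(activations_file, check.names = FALSE)
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (anyNA(ts)) stop("unparseable timestamps in ", activations_file)
  act <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(act) <- "integer"
  dates <- sort(unique(as.Date(ts, tz = "UTC")))
  labels <- rep(0L, length(dates))
  if (!is.null(labels_file)) {
    lab <- utils::read.csv(labels_file)
    labels <- as.integer(lab$is_anomaly[match(format(dates), lab$date)])
    labels[is.na(labels)] <- 0L
  }
  structure(list(
    household_id = household_id,
    timestamps = ts,
    activations = act,
    dates = dates,
    anomaly_labels = labels,
    day_of_week = day_of_week(dates),
    days_online = length(dates)
  ), class = "sensor_panel")
}

#' Cohort manifest
#'
#' One row per household with the metadata used by the inclusion criteria.
#'
#' @param panels list of `sensor_panel` objects.
#' @param n_occupants optional integer vector of occupant counts.
#' @return data.frame with columns `household_id`, `n_sensors`, `days_online`
#'   (and `n_occupants` when supplied).
#' @export
cohort_manifest <- function(panels, n_occupants = NULL) {
  out <- data.frame(
    household_id = vapply(panels, function(p) p$household_id, character(1)),
    n_sensors = vapply(panels, function(p) ncol(p$activations), integer(1)),
    days_online = vapply(panels, function(p) p$days_online, integer(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(n_occupants)) out$n_occupants <- as.integer(n_occupants)
  out
}
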