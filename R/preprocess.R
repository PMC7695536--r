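#' Half-hour motion state from a 6-step sensor window
#'
#' Collapses one 30-minute window of 5-minute sensor reports into a single
#' binary motion state: positive iff the total number of activations across
#' all sensors and steps is at least 4. This one rule covers both "a single
#' sensor active for 20 minutes" (4 of 6 steps) and "4 sensors each active in
#' one step".
#'
#' @param window binary matrix with exactly 6 rows (5-minute steps) and one
#'   column per sensor.
#' @return integer 0 or 1.
#' @export
motion_state <- function(window) {
  w <- as.matrix(window)
  if (nrow(w) != 6L) stop("window must have exactly 6 five-minute steps")
  if (!all(w == 0L | w == 1L)) stop("window entries must be binary")
  as.integer(sum(w) >= 4L)
}

#' Build the daily 48-slot day matrix from a sensor panel
#'
#' Aggregates the 5-minute stream into one binary row per complete calendar
#' day: slot s (s = 0..47, aligned to clock half-hours) is the
#' [motion_state()] of its 6-step window. Days with fewer than 288 timestamp
#' rows are dropped and reported; `NA` activations within present rows are
#' treated as "no motion reported" and zero-filled.
#'
#' @param panel a `sensor_panel` (simulated or read from CSV).
#' @return object of class `day_matrix`: `household_id`, `dates`, `X`
#'   (n_days x 48 binary matrix), `day_of_week` (0 = Monday), and
#'   `anomaly_labels` when the panel carries ground truth.
#' @export
build_day_matrix <- function(panel) {
  if (!inherits(panel, "sensor_panel")) stop("panel must be a sensor_panel")
  if (length(panel$timestamps) == 0L) {
    warning("empty panel: returning empty day matrix")
    return(new_day_matrix(panel$household_id, as.Date(character(0)),
                          matrix(integer(0), 0L, 48L), integer(0)))
  }
  secs <- as.numeric(panel$timestamps)
  if (any(secs %% 300 != 0)) {
    stop("timestamps are not aligned to the 5-minute grid")
  }
  act <- panel$activations
  if (anyNA(act)) {
    message(panel$household_id, ": zero-filling ", sum(is.na(act)),
            " missing activation value(s)")
    act[is.na(act)] <- 0L
  }
  dates <- as.Date(panel$timestamps, tz = "UTC")
  cnt <- table(dates)
  complete <- names(cnt)[cnt == 288L]
  if (length(complete) < length(cnt)) {
    message(panel$household_id, ": dropping ", length(cnt) - length(complete),
            " incomplete day(s)")
  }
  keep_dates <- as.Date(complete)
  n <- length(keep_dates)
  X <- matrix(0L, n, 48L)
  step_total <- rowSums(act)
  for (i in seq_len(n)) {
    day_tot <- step_total[dates == keep_dates[i]]
    ord <- order(secs[dates == keep_dates[i]])
    slot_sums <- colSums(matrix(day_tot[ord], 6L, 48L))
    X[i, ] <- as.integer(slot_sums >= 4L)
  }
  labels <- NULL
  if (!is.null(panel$anomaly_labels)) {
    labels <- panel$anomaly_labels[match(keep_dates, panel$dates)]
  }
  new_day_matrix(panel$household_id, keep_dates, X, day_of_week(keep_dates),
                 labels)
}

#' Construct a day matrix from a binary day-by-slot matrix
#'
#' Mostly useful for assembling hand-built day sets; [build_day_matrix()] is
#' the usual route from raw sensor data. Day-of-week is derived from `dates`
#' (0 = Monday).
#'
#' @param household_id id string.
#' @param dates vector of calendar dates, one per row of `X`.
#' @param X binary matrix with 48 columns.
#' @param anomaly_labels optional 0/1 ground-truth vector per day.
#' @return object of class `day_matrix`.
#' @export
day_matrix <- function(household_id, dates, X, anomaly_labels = NULL) {
  dates <- as.Date(dates)
  X <- as.matrix(X)
  storage.mode(X) <- "integer"
  if (!all(X == 0L | X == 1L)) stop("X entries must be binary")
  new_day_matrix(household_id, dates, X, day_of_week(dates), anomaly_labels)
}

new_day_matrix <- function(household_id, dates, X, dow, anomaly_labels = NULL) {
  stopifnot(ncol(X) == 48L, nrow(X) == length(dates), length(dow) == length(dates))
  structure(list(household_id = household_id, dates = dates, X = X,
                 day_of_week = dow, anomaly_labels = anomaly_labels),
            class = "day_matrix")
}

#' @export
print.day_matrix <- function(x, ...) {
  cat("<day_matrix> ", x$household_id, ": ", nrow(x$X),
      " days x 48 slots\n", sep = "")
  invisible(x)
}

#' Subset a day matrix by day index
#'
#' @param dm a `day_matrix`.
#' @param idx integer day indices to keep.
#' @return a `day_matrix` with the selected days (order preserved as given).
#' @export
dm_subset <- function(dm, idx) {
  new_day_matrix(dm$household_id, dm$dates[idx], dm$X[idx, , drop = FALSE],
                 dm$day_of_week[idx],
                 if (!is.null(dm$anomaly_labels)) dm$anomaly_labels[idx])
}

#' Cohort inclusion criteria
#'
#' Defaults mirror the study design: at least 8 PIR sensors, online for at
#' least 355 days of the year, and up to 4 occupants (checked only when the
#' manifest records occupant counts).
#'
#' @param min_sensors,min_days_online,max_occupants positive integers.
#' @return object of class `inclusion_criteria`.
#' @export
inclusion_criteria <- function(min_sensors = 8L, min_days_online = 355L,
                               max_occupants = 4L) {
  if (min_sensors < 1L || min_days_online < 1L || max_occupants < 1L) {
    stop("inclusion criteria must be positive")
  }
  structure(list(min_sensors = as.integer(min_sensors),
                 min_days_online = as.integer(min_days_online),
                 max_occupants = as.integer(max_occupants)),
            class = "inclusion_criteria")
}

#' Filter a cohort manifest by inclusion criteria
#'
#' @param manifest data.frame with `household_id`, `n_sensors`, `days_online`
#'   and optionally `n_occupants` columns.
#' @param criteria an [inclusion_criteria()].
#' @return the manifest rows meeting all criteria, original order preserved.
#' @export
apply_inclusion <- function(manifest, criteria = inclusion_criteria()) {
  for (col in c("household_id", "n_sensors", "days_online")) {
    if (!col %in% names(manifest)) stop("manifest is missing column ", col)
    bad <- which(is.na(manifest[[col]]))
    if (length(bad)) {
      stop("missing ", col, " for household ",
           paste(manifest$household_id[bad[1]], collapse = ", "))
    }
  }
  keep <- manifest$n_sensors >= criteria$min_sensors &
    manifest$days_online >= criteria$min_days_online
  if ("n_occupants" %in% names(manifest)) {
    occ <- manifest$n_occupants
    keep <- keep & (is.na(occ) | occ <= criteria$max_occupants)
  }
  manifest[keep, , drop = FALSE]
}

#' Random day-level train/test split
#'
#' Partitions the days of a day matrix into disjoint train and test sets with
#' `round(ratio * n_days)` training days, reproducibly under `seed`.
#'
#' @param dm a `day_matrix` with at least 2 days.
#' @param ratio training fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return list with `day_matrix` elements `train` and `test`.
#' @export
split_train_test <- function(dm, ratio = 0.8, seed = 1L) {
  if (!(ratio > 0 && ratio < 1)) stop("ratio must lie strictly in (0, 1)")
  n <- nrow(dm$X)
  if (n < 2L) stop("need at least 2 days to split")
  n_train <- as.integer(round(ratio * n))
  n_train <- max(1L, min(n - 1L, n_train))
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  idx <- sort(idx)
  list(train = dm_subset(dm, idx), test = dm_subset(dm, setdiff(seq_len(n), idx)))
}

#' Write / read a day matrix as CSV
#'
#' Columns: `date`, `dow` (0 = Monday), `slot_00` ... `slot_47`, plus
#' `is_anomaly` when ground-truth labels are present.
#'
#' @param dm a `day_matrix`.
#' @param file CSV path.
#' @param household_id id to attach on read.
#' @return `write_day_matrix` returns `dm` invisibly; `read_day_matrix`
#'   returns a `day_matrix`.
#' @export
write_day_matrix <- function(dm, file) {
  df <- data.frame(date = format(dm$dates), dow = dm$day_of_week)
  slots <- as.data.frame(dm$X)
  names(slots) <- sprintf("slot_%02d", 0:47)
  df <- cbind(df, slots)
  if (!is.null(dm$anomaly_labels)) df$is_anomaly <- dm$anomaly_labels
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(dm)
}

#' @rdname write_day_matrix
#' @export
read_day_matrix <- function(file, household_id = "HH0") {
  df <- utils::read.csv(file)
  slot_cols <- grep("^slot_", names(df))
  X <- as.matrix(df[, slot_cols, drop = FALSE])
  storage.mode(X) <- "integer"
  dimnames(X) <- NULL
  new_day_matrix(household_id, as.Date(df$date), X, as.integer(df$dow),
                 if ("is_anomaly" %in% names(df)) as.integer(df$is_anomaly))
}
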