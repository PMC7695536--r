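#' Per-day reconstruction-loss scores
#'
#' The anomaly score of a day is its binary cross-entropy against the model's
#' stochastic reconstruction, averaged over `n_mc` posterior draws. One draw
#' (the default from [vae_config()]) is the cheapest faithful reading of the
#' stochastic reconstruction; raise `n_mc` to reduce score variance.
#'
#' @param model a trained `lstm_vae`.
#' @param dm a `day_matrix` to score.
#' @param seed seed for the posterior draws.
#' @param n_mc posterior samples per day (defaults to the model config).
#' @return non-negative numeric vector, one score per day.
#' @export
score_days <- function(model, dm, seed = 1L, n_mc = model$config$n_mc) {
  if (!isTRUE(model$trained)) stop("model is untrained: fit it before scoring")
  if (!inherits(dm, "day_matrix")) stop("dm must be a day_matrix")
  X <- dm$X
  withr::with_seed(seed, {
    scores <- numeric(nrow(X))
    for (m in seq_len(n_mc)) {
      Y <- vae_reconstruct(model, X, posterior = "sample")
      scores <- scores + bce_per_row(X, Y)
    }
    scores / n_mc
  })
}

#' Median + IQR anomaly threshold
#'
#' threshold = median(scores) + (P75 - P25), with linear-interpolation
#' quantiles. A day scoring at or above this value is declared anomalous.
#'
#' @param scores numeric vector of at least 4 per-day scores.
#' @return scalar threshold.
#' @export
anomaly_threshold <- function(scores) {
  if (length(scores) < 4L) {
    stop("need at least 4 scores for a meaningful median + IQR threshold")
  }
  if (!all(is.finite(scores))) stop("scores must be finite")
  q <- stats::quantile(scores, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  q[2L] + (q[3L] - q[1L])
}

#' Flag days at or above the threshold
#'
#' @param scores per-day scores.
#' @param threshold scalar from [anomaly_threshold()].
#' @return integer 0/1 vector; 1 where `scores >= threshold` (inclusive).
#' @export
flag_anomalies <- function(scores, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  as.integer(scores >= threshold)
}

# Rank-based ROC AUC (Mann-Whitney formulation, midranks for ties).
auc_rank <- function(labels, scores) {
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Slot-level validation AUC
#'
#' Measures how well the model's per-slot reconstruction probabilities
#' recognize the observed activations and deactivations of a validation
#' year: ROC AUC pooled over all (day, slot) pairs, with the observed binary
#' slot value as label and the reconstruction probability as score.
#'
#' @param model a trained `lstm_vae`.
#' @param validation_dm a non-empty `day_matrix`.
#' @param seed seed for the posterior draw behind the reconstruction.
#' @return AUC in [0, 1], or `NA` when the validation slots are single-class.
#' @export
validation_auc <- function(model, validation_dm, seed = 1L) {
  if (!isTRUE(model$trained)) stop("model is untrained")
  X <- validation_dm$X
  if (nrow(X) == 0L) stop("validation day matrix is empty")
  Y <- withr::with_seed(seed, vae_reconstruct(model, X, posterior = "sample"))
  auc_rank(as.integer(as.vector(X)), as.vector(Y))
}

#' Assemble the per-household anomaly report
#'
#' Mirrors the per-household validation table: abnormal-day count, total
#' observed days, mean reconstruction loss, slot-level AUC, and the number of
#' abnormal days falling on weekends.
#'
#' @param household_id id string.
#' @param dates per-day calendar dates.
#' @param day_of_week integer 0-6 per day (0 = Monday; weekend is 5, 6).
#' @param scores per-day reconstruction scores.
#' @param threshold scalar; defaults to [anomaly_threshold()] of `scores`.
#' @param auc slot-level validation AUC, or `NA` when no validation year exists.
#' @return object of class `anomaly_report`.
#' @export
summarize_household <- function(household_id, dates, day_of_week, scores,
                                threshold = anomaly_threshold(scores),
                                auc = NA_real_) {
  n <- length(dates)
  if (length(scores) != n || length(day_of_week) != n) {
    stop("dates, day_of_week and scores must be aligned")
  }
  flags <- flag_anomalies(scores, threshold)
  structure(list(
    household_id = household_id,
    dates = dates,
    scores = scores,
    threshold = threshold,
    flags = flags,
    mean_loss = mean(scores),
    auc = auc,
    n_abnormal = sum(flags),
    n_abnormal_weekend = sum(flags[day_of_week >= 5L]),
    n_observed = n
  ), class = "anomaly_report")
}

#' @export
print.anomaly_report <- function(x, ...) {
  cat("<anomaly_report> ", x$household_id, ": ", x$n_abnormal, "/",
      x$n_observed, " abnormal days (", x$n_abnormal_weekend,
      " on weekends), mean loss ", signif(x$mean_loss, 3),
      ", threshold ", signif(x$threshold, 3), "\n", sep = "")
  invisible(x)
}

#' One summary row per report, validation-table style
#'
#' @param reports list of `anomaly_report` objects.
#' @return data.frame with columns `household_id`, `abnormal_days`,
#'   `total_observed_days`, `loss`, `auc`, `abnormal_weekend`.
#' @export
anomaly_report_table <- function(reports) {
  if (inherits(reports, "anomaly_report")) reports <- list(reports)
  do.call(rbind, lapply(reports, function(r) {
    data.frame(household_id = r$household_id,
               abnormal_days = r$n_abnormal,
               total_observed_days = r$n_observed,
               loss = r$mean_loss,
               auc = r$auc,
               abnormal_weekend = r$n_abnormal_weekend,
               stringsAsFactors = FALSE)
  }))
}

#' Per-day anomaly detail table
#'
#' @param report an `anomaly_report`.
#' @return data.frame with `date`, `score`, `flag`.
#' @export
anomaly_day_table <- function(report) {
  data.frame(date = format(report$dates), score = report$scores,
             flag = report$flags, stringsAsFactors = FALSE)
}
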