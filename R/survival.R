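#' Kaplan-Meier curve for time to disengagement
#'
#' Product-limit estimate for one arm, with Greenwood variance and a
#' log-transformed 95% confidence band clipped to \[0,1\] (the log transform
#' keeps the band inside the unit interval, which a plain Greenwood band
#' does not guarantee). Events at the same day are handled simultaneously
#' and users censored at a day remain at risk through that day. The median
#' is the first time at which the survival fraction is at or below 0.5
#' (`NA` if never reached).
#'
#' @param data Tibble with columns `time` (integer day) and `event`
#'   (1 = disengaged, 0 = censored), one row per user of a single arm.
#' @param level Confidence level (default 0.95).
#' @return An object of class `km_curve`: a tibble `time, n_risk, n_event,
#'   survival, std_err, ci_low, ci_high` with the median survival time as
#'   attribute `"median"`.
#' @export
km_estimate <- function(data, level = 0.95) {
  if (nrow(data) == 0) stop("no users in arm", call. = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = data,
                          conf.type = "log", conf.int = level)
  curve <- tibble::tibble(time = sf$time,
                          n_risk = sf$n.risk,
                          n_event = sf$n.event,
                          survival = sf$surv,
                          std_err = sf$surv * sf$std.err,  # Greenwood SE of S
                          ci_low = pmax(ifelse(is.na(sf$lower), 0, sf$lower), 0),
                          ci_high = pmin(ifelse(is.na(sf$upper), 1, sf$upper), 1))
  med <- curve$time[curve$survival <= 0.5]
  attr(curve, "median") <- if (length(med) > 0) min(med) else NA_real_
  class(curve) <- c("km_curve", class(curve))
  curve
}

#' Log-rank test across arms
#'
#' Compares time to disengagement across `k` arms: at each distinct event
#' time the observed event counts per arm are contrasted with their
#' hypergeometric expectations, and the accumulated
#' \eqn{(O-E)^\top V^{-1} (O-E)} over `k - 1` arms is referred to a
#' chi-squared distribution with `k - 1` degrees of freedom.
#'
#' @param data Tibble with columns `time`, `event` and `arm`.
#' @return A list with `chi2`, `df` and `p`. With no events at all the
#'   statistic is 0 and `p = 1`, with a warning.
#' @export
logrank <- function(data) {
  arms <- unique(data$arm)
  if (length(arms) < 2) stop("log-rank test needs at least 2 arms", call. = FALSE)
  df <- length(arms) - 1L
  if (sum(data$event) == 0) {
    warning("no events in any arm; log-rank statistic is 0", call. = FALSE)
    return(list(chi2 = 0, df = df, p = 1))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ arm, data = data)
  list(chi2 = unname(sd$chisq), df = df,
       p = unname(pchisq(sd$chisq, df, lower.tail = FALSE)))
}

#' Write per-arm survival curves and the log-rank summary
#'
#' @param data Disengagement tibble (`user_id, arm, time, event`).
#' @param dir Output directory.
#' @return Invisibly, a list with the curves (one `km_curve` per arm) and
#'   the log-rank result.
#' @export
write_survival_outputs <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  curves <- lapply(split(data, data$arm), km_estimate)
  for (arm in names(curves)) {
    readr::write_csv(
      dplyr::select(curves[[arm]], "time", "survival", "ci_low", "ci_high",
                    "n_risk", "n_event"),
      file.path(dir, paste0("km_", arm, ".csv")))
  }
  lr <- logrank(data)
  readr::write_csv(tibble::tibble(chi2 = lr$chi2, df = lr$df, p = lr$p),
                   file.path(dir, "logrank.csv"))
  invisible(list(curves = curves, logrank = lr))
}
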