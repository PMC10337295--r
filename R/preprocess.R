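#' Read a screen-view event log
#'
#' Reads a CSV with columns `user_id` and `timestamp` (ISO-8601). Rows whose
#' timestamp cannot be parsed raise an error naming the offending line
#' numbers.
#'
#' @param path CSV file path.
#' @return A tibble `user_id, timestamp` with POSIXct timestamps on the study
#'   clock.
#' @export
read_events <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    user_id = readr::col_character(), timestamp = readr::col_character()))
  ts <- as.POSIXct(raw$timestamp, tz = .study_tz,
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"),
                   optional = TRUE)
  bad <- which(is.na(ts) & !is.na(raw$timestamp))
  if (length(bad) > 0)
    stop("unparseable timestamp on line(s) ",
         paste(utils::head(bad + 1L, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "", call. = FALSE)
  tibble::tibble(user_id = raw$user_id, timestamp = ts)
}

#' Shift event timestamps to local study time
#'
#' Applies a fixed minute offset to every timestamp, e.g. +60 to move a UTC
#' export onto British Summer Time. With offset 0 this is the identity.
#'
#' @param events Event tibble (`user_id`, `timestamp`).
#' @param offset_minutes Minutes to add to every timestamp.
#' @return The events with shifted timestamps.
#' @export
to_local <- function(events, offset_minutes) {
  events$timestamp <- events$timestamp + 60 * offset_minutes
  events
}

#' Group screen views into sessions
#'
#' Consecutive views by the same user separated by at most `gap_s` seconds
#' belong to one session; a gap strictly greater than `gap_s` starts a new
#' session (the 30-minute inactivity rule). Session length is the difference
#' between first and last view, so a single-view session has length 0 and
#' all lengths underestimate true usage time.
#'
#' @param events Event tibble; sorted per user internally.
#' @param gap_s Inactivity threshold in seconds (default 1800).
#' @return A tibble `user_id, start, end, duration_s, n_views`, one row per
#'   session.
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   user_id = "u1",
#'   timestamp = as.POSIXct("2020-01-02 20:00:00", tz = "UTC") + c(0, 1740))
#' sessionize(ev)
sessionize <- function(events, gap_s = 1800) {
  if (gap_s <= 0) stop("`gap_s` must be positive", call. = FALSE)
  if (nrow(events) == 0) {
    return(tibble::tibble(user_id = character(),
                          start = as.POSIXct(character(), tz = .study_tz),
                          end = as.POSIXct(character(), tz = .study_tz),
                          duration_s = numeric(), n_views = integer()))
  }
  ev <- dplyr::arrange(events, .data$user_id, .data$timestamp)
  secs <- as.numeric(ev$timestamp)
  new_user <- ev$user_id != c("", ev$user_id[-nrow(ev)])
  gap <- secs - c(secs[1], secs[-length(secs)])
  new_session <- new_user | gap > gap_s
  sid <- cumsum(new_session)
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(user_id = ev$user_id, t = ev$timestamp, sid = sid),
                    .data$user_id, .data$sid),
    start = min(.data$t), end = max(.data$t), n_views = dplyr::n(),
    .groups = "drop")
  dplyr::select(
    dplyr::mutate(dplyr::arrange(out, .data$user_id, .data$start),
                  duration_s = as.numeric(.data$end) - as.numeric(.data$start)),
    "user_id", "start", "end", "duration_s", "n_views")
}

## seconds after the user's study-day-1 midnight, and study day, per event
event_day_tod <- function(events, origin) {
  secs <- time_to_secs(events$timestamp, origin)
  list(day = as.integer(floor(secs / .day_s)) + 1L, tod = secs %% .day_s)
}

#' Derive decision-point records with outcomes and covariates
#'
#' Joins the randomization table with window-membership indicators computed
#' from the event log. All windows are half-open `[start, end)`: the proximal
#' outcome `Y_hour` indicates any view in the decision-point hour, `Y_24h`
#' any view from the decision point to the next day's decision point,
#' `opened_before_8pm` any view earlier the same day, `opened_after_9pm_prev`
#' any view after the outcome window the previous day, and
#' `already_engaged_prev` the previous day's `Y_hour`. `habituation`
#' indicates any notification delivered the previous day (from the
#' randomization table). "Opening the app" means any screen view in the
#' window, not only session starts, because a notification tap lands
#' directly on the app's landing page.
#'
#' @param events Event tibble in local study time.
#' @param randomization Randomization tibble (`user_id, day, option,
#'   p_standard, p_new, p_none`).
#' @param baseline Baseline covariate tibble.
#' @param config A [trial_config()] supplying the decision time and start
#'   date.
#' @return A tibble with one row per user-day in the randomization table.
#'   Users present in the table but absent from the log get all-zero
#'   outcomes; users in the log but not in the table are dropped with a
#'   warning.
#' @export
derive_decision_points <- function(events, randomization, baseline, config) {
  origin <- study_origin(config$start_date)
  ds <- config$decision_s
  grid <- randomization
  extra <- setdiff(unique(events$user_id), unique(grid$user_id))
  if (length(extra) > 0) {
    warning(length(extra), " user(s) present in events but not in the ",
            "randomization table were dropped", call. = FALSE)
    events <- events[!events$user_id %in% extra, , drop = FALSE]
  }
  dt <- event_day_tod(events, origin)
  ev <- tibble::tibble(user_id = events$user_id, day = dt$day, tod = dt$tod)

  flag <- function(df) {
    df <- dplyr::distinct(df)
    df$val <- 1L
    df
  }
  in_hour  <- flag(ev[ev$tod >= ds & ev$tod < ds + 3600, c("user_id", "day")])
  before   <- flag(ev[ev$tod < ds, c("user_id", "day")])
  after9   <- flag(ev[ev$tod >= ds + 3600, c("user_id", "day")])
  ## event at (day e, tod) belongs to the 24 h window opening on day e if
  ## tod >= decision time, else to the window opened the previous day
  w24 <- ev
  w24$day <- ifelse(w24$tod >= ds, w24$day, w24$day - 1L)
  w24 <- flag(w24[w24$day >= 1L, c("user_id", "day")])

  j <- function(g, f, col) {
    g[[col]] <- dplyr::coalesce(
      dplyr::left_join(g, f, by = c("user_id", "day"))$val, 0L)
    g
  }
  grid <- j(grid, in_hour, "Y_hour")
  grid <- j(grid, w24, "Y_24h")
  grid <- j(grid, before, "opened_before_8pm")

  prev <- function(f) { f$day <- f$day + 1L; f }
  grid <- j(grid, prev(after9), "opened_after_9pm_prev")
  grid <- j(grid, prev(in_hour), "already_engaged_prev")
  delivered <- flag(grid[grid$option != "none", c("user_id", "day")])
  grid <- j(grid, prev(delivered), "habituation")
  grid$opened_after_9pm_prev[grid$day == 1L] <- 0L
  grid$already_engaged_prev[grid$day == 1L] <- 0L
  grid$habituation[grid$day == 1L] <- 0L

  dplyr::arrange(dplyr::left_join(grid, baseline, by = "user_id"),
                 .data$user_id, .data$day)
}

#' Time to disengagement
#'
#' A user disengages on the first day `d` such that days `d` to
#' `d + run_days - 1` all have zero screen views; the event is only defined
#' over the first `horizon_days` days of follow-up, and users with no
#' qualifying day are censored at the horizon.
#'
#' @param events Event tibble in local study time.
#' @param users Tibble of users to score, with columns `user_id` and
#'   (optionally) `arm`; users without any event count as never having used
#'   the app after day 0. Defaults to the users appearing in `events`.
#' @param horizon_days Last day at which the event is defined (default 23).
#' @param run_days Length of the no-use run defining disengagement
#'   (default 7).
#' @param followup_days Total follow-up (default 30); must cover
#'   `horizon_days + run_days - 1`.
#' @param origin POSIXct midnight of study day 1; defaults to midnight of
#'   the earliest event date.
#' @return A tibble `user_id, arm, time, event` with integer `time` in
#'   `[1, horizon_days]`.
#' @export
derive_disengagement <- function(events, users = NULL, horizon_days = 23,
                                 run_days = 7, followup_days = 30,
                                 origin = NULL) {
  if (horizon_days + run_days - 1 > followup_days)
    stop("horizon_days + run_days - 1 exceeds followup_days", call. = FALSE)
  if (is.null(users)) {
    users <- tibble::tibble(user_id = unique(events$user_id),
                            arm = NA_character_)
  }
  if (!"arm" %in% names(users)) users$arm <- NA_character_
  if (is.null(origin)) {
    origin <- if (nrow(events) > 0) {
      trunc(min(events$timestamp), "days")
    } else {
      study_origin(Sys.Date())
    }
  }
  dt <- event_day_tod(events, origin)
  act <- unique(data.frame(user_id = events$user_id, day = dt$day))
  act <- act[act$day >= 1 & act$day <= followup_days, , drop = FALSE]
  act_by_user <- split(act$day, act$user_id)

  score <- function(uid) {
    used <- logical(followup_days)
    used[act_by_user[[uid]]] <- TRUE
    for (d in seq_len(horizon_days)) {
      if (!any(used[d:(d + run_days - 1)])) return(c(d, 1L))
    }
    c(horizon_days, 0L)
  }
  res <- vapply(users$user_id, score, numeric(2))
  tibble::tibble(user_id = users$user_id, arm = users$arm,
                 time = as.integer(res[1, ]), event = as.integer(res[2, ]))
}

#' Modal imputation of missing baseline categories
#'
#' Replaces missing `sex` and `employment` values by the most frequent (or,
#' for a sensitivity analysis, the second most frequent) observed category,
#' computed over the pooled analysis set. The number of imputed values per
#' arm is attached as attribute `"imputation_counts"`.
#'
#' @param baseline Baseline tibble with possible `NA` in `sex`/`employment`.
#' @param strategy `"modal"` or `"second_modal"`.
#' @return The baseline tibble with missing values filled in.
#' @export
impute_modal <- function(baseline, strategy = c("modal", "second_modal")) {
  strategy <- match.arg(strategy)
  rank_wanted <- if (strategy == "modal") 1L else 2L
  counts <- NULL
  for (col in c("sex", "employment")) {
    miss <- is.na(baseline[[col]])
    if (!any(miss)) next
    tab <- sort(table(baseline[[col]][!miss]), decreasing = TRUE)
    if (length(tab) == 0)
      stop("all values of `", col, "` are missing; cannot impute", call. = FALSE)
    if (length(tab) < rank_wanted)
      stop("fewer than ", rank_wanted, " observed categories in `", col, "`",
           call. = FALSE)
    fill <- names(tab)[rank_wanted]
    cnt <- table(factor(baseline$arm[miss], levels = unique(baseline$arm)))
    counts <- rbind(counts, data.frame(variable = col, imputed_to = fill,
                                       arm = names(cnt), n = as.integer(cnt)))
    baseline[[col]][miss] <- fill
  }
  attr(baseline, "imputation_counts") <- counts
  baseline
}

#' Per-arm usage summaries
#'
#' Median and interquartile range of the number of sessions per user over the
#' first `followup_days` days (users with no sessions count 0), and of the
#' session lengths in seconds pooled over sessions, by arm. Quantiles use the
#' averaged inverse-ECDF convention (`type = 2`), which returns order
#' statistics for odd counts and half-integer medians for even counts.
#'
#' @param sessions Session tibble from [sessionize()].
#' @param baseline Baseline tibble supplying the user-to-arm mapping.
#' @param followup_days Number of days of sessions to include (default 30).
#' @param origin POSIXct midnight of study day 1; defaults to midnight of the
#'   earliest session start.
#' @return A tibble with one row per arm: user count, session-count median
#'   and quartiles, and session-length median and quartiles.
#' @export
usage_summary <- function(sessions, baseline, followup_days = 30,
                          origin = NULL) {
  if (is.null(origin)) {
    origin <- if (nrow(sessions) > 0) trunc(min(sessions$start), "days")
              else study_origin(Sys.Date())
  }
  day <- floor(time_to_secs(sessions$start, origin) / .day_s) + 1
  ses <- sessions[day >= 1 & day <= followup_days, , drop = FALSE]
  ses <- dplyr::left_join(ses, baseline[, c("user_id", "arm")], by = "user_id")

  per_user <- dplyr::count(ses, .data$user_id, name = "n_sessions")
  per_user <- dplyr::left_join(baseline[, c("user_id", "arm")], per_user,
                               by = "user_id")
  per_user$n_sessions[is.na(per_user$n_sessions)] <- 0L

  arms <- unique(baseline$arm)
  empty <- setdiff(arms, unique(ses$arm))
  if (length(empty) > 0)
    warning("arm(s) without any session omitted from length summaries: ",
            paste(empty, collapse = ", "), call. = FALSE)
  q2 <- function(x, p) unname(quantile(x, p, type = 2))
  cnt <- dplyr::summarise(
    dplyr::group_by(per_user, .data$arm),
    n_users = dplyr::n(),
    sessions_median = q2(.data$n_sessions, 0.5),
    sessions_q1 = q2(.data$n_sessions, 0.25),
    sessions_q3 = q2(.data$n_sessions, 0.75),
    .groups = "drop")
  dur <- dplyr::summarise(
    dplyr::group_by(ses, .data$arm),
    duration_median = q2(.data$duration_s, 0.5),
    duration_q1 = q2(.data$duration_s, 0.25),
    duration_q3 = q2(.data$duration_s, 0.75),
    .groups = "drop")
  dplyr::left_join(cnt, dur, by = "arm")
}
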