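#' Trial configuration
#'
#' Defines the structural parameters of a three-arm notification trial with a
#' micro-randomized (MRT) arm: how many users and days, the daily multinomial
#' assignment probabilities at the decision point, and the split of users
#' across the MRT, standard-policy and no-notification-policy arms.
#'
#' @param n_users Number of users to enrol (non-negative integer).
#' @param n_days Follow-up length in days; at least 8 so that a 7-day
#'   no-use run (disengagement) is definable.
#' @param assign_probs Length-3 probability vector `(standard, new, none)` for
#'   the daily decision-point randomization in the MRT arm. Default
#'   `c(0.3, 0.3, 0.4)`.
#' @param arm_split Length-3 probability vector `(mrt, standard, none)` for the
#'   between-user arm allocation. Default `c(0.6, 0.2, 0.2)`.
#' @param decision_time Local clock time `"HH:MM"` of the daily decision point
#'   (default `"20:00"`); the proximal outcome window is the following hour.
#' @param standard_arm_time Clock time at which the standard-policy arm
#'   receives its fixed daily message (default `"11:00"`).
#' @param start_date Calendar date of study day 1 (`"YYYY-MM-DD"`).
#' @param emit_utc If `TRUE`, emitted screen-view timestamps are shifted back
#'   by `utc_offset_min` minutes (i.e. written on a UTC clock that the
#'   preprocessor must shift to local time with [to_local()]).
#' @param utc_offset_min Local-time offset in minutes used when
#'   `emit_utc = TRUE` (default 60, the UTC -> British Summer Time shift).
#' @param seed Integer seed controlling all randomness of the generator.
#'
#' @return An object of class `trial_config` (a validated list).
#' @seealso [generative_params()], [generate_baseline()], [simulate_trial()]
#' @export
#' @examples
#' cfg <- trial_config(n_users = 50, seed = 1)
trial_config <- function(n_users,
                         n_days = 30,
                         assign_probs = c(0.3, 0.3, 0.4),
                         arm_split = c(0.6, 0.2, 0.2),
                         decision_time = "20:00",
                         standard_arm_time = "11:00",
                         start_date = "2020-01-02",
                         emit_utc = FALSE,
                         utc_offset_min = 60,
                         seed = 1L) {
  if (length(n_users) != 1 || is.na(n_users) || n_users < 0 || n_users != floor(n_users))
    stop("`n_users` must be a non-negative integer", call. = FALSE)
  if (length(n_days) != 1 || is.na(n_days) || n_days < 8)
    stop("`n_days` must be >= 8 so disengagement is definable", call. = FALSE)
  check_probs(assign_probs, "assign_probs", open = TRUE)
  check_probs(arm_split, "arm_split")
  cfg <- list(
    n_users = as.integer(n_users),
    n_days = as.integer(n_days),
    assign_probs = setNames(as.numeric(assign_probs), c("standard", "new", "none")),
    arm_split = setNames(as.numeric(arm_split), c("mrt", "standard", "none")),
    decision_time = decision_time,
    decision_s = parse_clock(decision_time),
    standard_arm_time = standard_arm_time,
    standard_arm_s = parse_clock(standard_arm_time),
    start_date = start_date,
    emit_utc = isTRUE(emit_utc),
    utc_offset_min = as.numeric(utc_offset_min),
    seed = as.integer(seed)
  )
  class(cfg) <- "trial_config"
  cfg
}

check_probs <- function(p, name, open = FALSE) {
  if (length(p) != 3 || anyNA(p) || any(p < 0) || any(p > 1))
    stop("`", name, "` must be 3 probabilities in [0,1]", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8)
    stop("`", name, "` must sum to 1", call. = FALSE)
  invisible(p)
}

#' Generative parameters of the synthetic trial
#'
#' All effect sizes, baseline rates and dynamics governing the synthetic data
#' generator. The engagement model is log-linear on the risk scale: the
#' probability that user \eqn{i} opens the app in the decision-point hour of
#' day \eqn{d} is
#' \deqn{\min\{0.99,\; \exp(u_i + \log p_0 + A (\beta_1 + (d-1)\beta_d +
#'   \eta_H H + \eta_E E))\}}
#' where \eqn{u_i \sim N(0, \sigma_u^2)} is a user random intercept,
#' \eqn{p_0} = `base_window_prob`, \eqn{A} indicates a notification delivered
#' at the decision point, \eqn{H} indicates a notification received the day
#' before (habituation) and \eqn{E} indicates the user opened the app in the
#' decision window the day before (already engaged). A log link keeps the
#' treatment contrast a relative risk, matching the analysis model.
#'
#' @param base_window_prob Baseline probability of opening the app in the
#'   decision-point hour with no notification (default 0.036).
#' @param log_rr_day1 Log relative risk of a notification on day 1
#'   (default `log(3.5)`).
#' @param log_rr_decay_per_day Additive change in the log relative risk per
#'   day since download (default `log(0.993)`).
#' @param habituation_log_ratio,engaged_log_ratio Effect-moderation log
#'   ratios for the habituation and already-engaged states (default 0).
#' @param user_sd Standard deviation of the between-user random intercept on
#'   the log scale (default 0.7).
#' @param daytime_open_prob Per-day probability of an app open before the
#'   decision point (drives the "opened before 8 PM" covariate; default 0.5).
#' @param late_open_prob Per-day probability of an open after the outcome
#'   window, i.e. after 9 PM (default 0.15).
#' @param diseng_hazard Per-day probability of entering the absorbing
#'   disengaged state, from day 2 onward (default 0.07, which puts the median
#'   first no-use day near the 11 days the field reports for this kind of
#'   app).
#' @param views_per_session_mean Mean number of screen views per session;
#'   views are `1 + Poisson(mean - 1)` (default 4).
#' @param interview_gap_mean_s Mean inter-view gap in seconds within a
#'   session, exponential truncated below 1800 s so generated sessions can
#'   never be split by the 30-minute sessionization rule (default 20).
#' @param missing_rate Probability that sex and employment are each missing
#'   at baseline (default 60/566, the rate observed in the motivating trial).
#'
#' @return An object of class `generative_params` (a validated list).
#' @export
generative_params <- function(base_window_prob = 0.036,
                              log_rr_day1 = log(3.5),
                              log_rr_decay_per_day = log(0.993),
                              habituation_log_ratio = 0,
                              engaged_log_ratio = 0,
                              user_sd = 0.7,
                              daytime_open_prob = 0.5,
                              late_open_prob = 0.15,
                              diseng_hazard = 0.07,
                              views_per_session_mean = 4,
                              interview_gap_mean_s = 20,
                              missing_rate = 60 / 566) {
  for (nm in c("base_window_prob", "daytime_open_prob", "late_open_prob",
               "diseng_hazard", "missing_rate")) {
    v <- get(nm)
    if (length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop("`", nm, "` must be a probability in [0,1]", call. = FALSE)
  }
  if (user_sd < 0) stop("`user_sd` must be non-negative", call. = FALSE)
  if (views_per_session_mean < 1) stop("`views_per_session_mean` must be >= 1", call. = FALSE)
  if (interview_gap_mean_s <= 0) stop("`interview_gap_mean_s` must be positive", call. = FALSE)
  p <- list(
    base_window_prob = base_window_prob,
    log_rr_day1 = log_rr_day1,
    log_rr_decay_per_day = log_rr_decay_per_day,
    habituation_log_ratio = habituation_log_ratio,
    engaged_log_ratio = engaged_log_ratio,
    user_sd = user_sd,
    daytime_open_prob = daytime_open_prob,
    late_open_prob = late_open_prob,
    diseng_hazard = diseng_hazard,
    views_per_session_mean = views_per_session_mean,
    interview_gap_mean_s = interview_gap_mean_s,
    missing_rate = missing_rate
  )
  class(p) <- "generative_params"
  p
}
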