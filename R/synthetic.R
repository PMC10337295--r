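#' Generate a synthetic baseline table
#'
#' Draws one baseline record per user: arm allocation by independent draws
#' with the configured split, age from a normal distribution with mean 44 and
#' SD 12 truncated to 18--90 years, sex 50/50, AUDIT risk-zone membership
#' with probabilities (0.49, 0.20, 0.31) for hazardous (8--15), harmful
#' (16--19) and at-risk-of-dependence (20--40) and a uniform integer score
#' within the zone, and employment type with probabilities (0.70, 0.14, 0.16)
#' for nonmanual/manual/other. Sex and employment are then each set missing
#' (`NA`) with probability `params$missing_rate`, mimicking the
#' technical-glitch missingness pattern of app-collected baselines.
#'
#' @param config A [trial_config()].
#' @param params A [generative_params()].
#' @return A tibble with columns `user_id`, `age`, `sex`, `employment`,
#'   `audit`, `arm`.
#' @export
#' @examples
#' b <- generate_baseline(trial_config(n_users = 20, seed = 7))
generate_baseline <- function(config, params = generative_params()) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(config$seed)
  n <- config$n_users
  if (n == 0) {
    return(tibble::tibble(user_id = character(), age = integer(),
                          sex = character(), employment = character(),
                          audit = integer(), arm = character()))
  }
  arm <- sample(names(config$arm_split), n, replace = TRUE, prob = config$arm_split)
  ## truncated normal via inverse-CDF so no rejection loop is needed
  lo <- pnorm(18, 44, 12); hi <- pnorm(90, 44, 12)
  age <- as.integer(round(qnorm(runif(n, lo, hi), 44, 12)))
  sex <- sample(c("male", "female"), n, replace = TRUE)
  zone <- sample(1:3, n, replace = TRUE, prob = c(0.49, 0.20, 0.31))
  zlo <- c(8L, 16L, 20L)[zone]
  zhi <- c(15L, 19L, 40L)[zone]
  audit <- zlo + as.integer(floor(runif(n) * (zhi - zlo + 1L)))
  employment <- sample(c("nonmanual", "manual", "other"), n, replace = TRUE,
                       prob = c(0.70, 0.14, 0.16))
  out <- tibble::tibble(user_id = sprintf("u%05d", seq_len(n)),
                        age = age, sex = sex, employment = employment,
                        audit = audit, arm = arm)
  inject_missingness(out, params$missing_rate)
}

#' Set baseline sex and employment missing at random
#'
#' Each record's `sex` and `employment` are independently replaced by `NA`
#' with the given probability; all other fields are untouched. Uses the
#' current RNG stream.
#'
#' @param baseline A baseline tibble as from [generate_baseline()].
#' @param rate Missingness probability in \[0,1\].
#' @return The baseline tibble with missing values injected.
#' @export
inject_missingness <- function(baseline, rate) {
  if (length(rate) != 1 || is.na(rate) || rate < 0 || rate > 1)
    stop("`rate` must be a probability in [0,1]", call. = FALSE)
  n <- nrow(baseline)
  if (n == 0 || rate == 0) return(baseline)
  baseline$sex[runif(n) < rate] <- NA_character_
  baseline$employment[runif(n) < rate] <- NA_character_
  baseline
}

#' Simulate the latent user-day process of a notification trial
#'
#' The generative core: for every user and every follow-up day it draws the
#' randomized notification option, the absorbing disengagement state, and the
#' binary open indicators (decision-point hour, daytime, late evening) from
#' the log-linear risk model described in [generative_params()]. MRT-arm
#' users are randomized daily at the decision point with `assign_probs`;
#' standard-arm users receive the fixed daily message with probability 1 (not
#' at the decision point, so it never counts as decision-point treatment);
#' no-notification users never receive one. Day 1 always contains a daytime
#' onboarding open (registration happens in the app), and disengagement can
#' start from day 2 onward.
#'
#' @inheritParams generate_baseline
#' @param baseline Baseline table from [generate_baseline()].
#' @return A tibble with one row per user-day: identifiers, assignment
#'   (`option`, `p_standard`, `p_new`, `p_none`, `A`), latent states
#'   (`habituation`, `already_engaged_prev`, `disengaged`), open indicators
#'   (`Y_hour`, `Y_24h`, `opened_before_8pm`, `opened_after_9pm_prev`,
#'   `daytime_open`, `late_open`) and the joined baseline covariates. In this
#'   latent table `opened_after_9pm_prev` reflects late-evening opens; the
#'   event-derived records from [derive_decision_points()] additionally pick
#'   up outcome-window sessions that run past the window end.
#' @export
simulate_decision_table <- function(config, params = generative_params(),
                                    baseline = generate_baseline(config, params)) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(config$seed + 1L)
  n <- nrow(baseline)
  nd <- config$n_days
  empty <- tibble::tibble(
    user_id = character(), day = integer(), option = character(),
    p_standard = numeric(), p_new = numeric(), p_none = numeric(),
    A = integer(), habituation = integer(), already_engaged_prev = integer(),
    disengaged = integer(), Y_hour = integer(), Y_24h = integer(),
    opened_before_8pm = integer(), opened_after_9pm_prev = integer(),
    daytime_open = integer(), late_open = integer())
  if (n == 0) return(dplyr::left_join(empty, baseline, by = "user_id"))

  u <- rnorm(n, 0, params$user_sd)
  dis_day <- if (params$diseng_hazard > 0) 2L + rgeom(n, params$diseng_hazard) else rep(Inf, n)

  is_mrt <- baseline$arm == "mrt"
  opts <- c("standard", "new", "none")
  option <- matrix("none", n, nd)
  option[baseline$arm == "standard", ] <- "standard"
  if (any(is_mrt)) {
    option[is_mrt, ] <- sample(opts, sum(is_mrt) * nd, replace = TRUE,
                               prob = config$assign_probs)
  }
  delivered <- option != "none"
  A <- delivered & matrix(is_mrt, n, nd)   # decision-point notification

  Y <- H <- E <- DT <- LT <- alive_m <- matrix(0L, n, nd)
  n_clipped <- 0L
  y_prev <- integer(n)
  for (d in seq_len(nd)) {
    alive <- d < dis_day
    H_d <- if (d == 1) integer(n) else as.integer(delivered[, d - 1])
    E_d <- if (d == 1) integer(n) else y_prev
    lin <- u + log(params$base_window_prob) +
      as.integer(A[, d]) * (params$log_rr_day1 +
                              (d - 1) * params$log_rr_decay_per_day +
                              params$habituation_log_ratio * H_d +
                              params$engaged_log_ratio * E_d)
    p <- exp(lin)
    n_clipped <- n_clipped + sum(p > 1)
    p <- pmin(p, 0.99)
    p[!alive] <- 0
    y <- rbinom(n, 1L, p)
    dt <- if (d == 1) rep(1L, n) else as.integer(rbinom(n, 1L, params$daytime_open_prob) & alive)
    lt <- as.integer(rbinom(n, 1L, params$late_open_prob) & alive)
    Y[, d] <- y; H[, d] <- H_d; E[, d] <- E_d
    DT[, d] <- dt; LT[, d] <- lt; alive_m[, d] <- as.integer(alive)
    y_prev <- y
  }
  if (n_clipped > 0)
    warning(n_clipped, " user-day open probabilities exceeded 1 before clipping",
            call. = FALSE)

  Y24 <- Y | LT
  if (nd > 1) Y24[, seq_len(nd - 1)] <- Y24[, seq_len(nd - 1)] | DT[, 2:nd]
  after9_prev <- cbind(0L, LT[, seq_len(nd - 1), drop = FALSE])

  p_mat <- rbind(mrt = config$assign_probs,
                 standard = c(1, 0, 0), none = c(0, 0, 1))
  arm_row <- match(baseline$arm, rownames(p_mat))

  out <- tibble::tibble(
    user_id = rep(baseline$user_id, nd),
    day = rep(seq_len(nd), each = n),
    option = as.vector(option),
    p_standard = p_mat[arm_row, 1][rep(seq_len(n), nd)],
    p_new = p_mat[arm_row, 2][rep(seq_len(n), nd)],
    p_none = p_mat[arm_row, 3][rep(seq_len(n), nd)],
    A = as.integer(as.vector(A)),
    habituation = as.integer(as.vector(H)),
    already_engaged_prev = as.integer(as.vector(E)),
    disengaged = 1L - as.vector(alive_m),
    Y_hour = as.vector(Y),
    Y_24h = as.integer(as.vector(Y24)),
    opened_before_8pm = as.vector(DT),
    opened_after_9pm_prev = as.vector(after9_prev),
    daytime_open = as.vector(DT),
    late_open = as.vector(LT))
  out <- dplyr::arrange(dplyr::left_join(out, baseline, by = "user_id"),
                        .data$user_id, .data$day)
  out
}

#' Simulate a complete trial: randomization table and screen-view log
#'
#' Runs [simulate_decision_table()] and then emits a raw screen-view stream
#' consistent with it: every open becomes a session whose start is uniform in
#' its window (daytime 09:00--19:30, decision hour, late evening
#' 21:00--23:00), with `1 + Poisson(mean - 1)` views separated by exponential
#' gaps truncated below 1800 s. Daytime sessions are truncated at the
#' decision time and evening/late sessions at midnight so the outcome windows
#' remain identifiable from the log. When `config$emit_utc` is `TRUE` the
#' emitted timestamps are shifted back by `config$utc_offset_min` minutes.
#'
#' @inheritParams simulate_decision_table
#' @return A list with elements `randomization` (tibble `user_id, day,
#'   option, p_standard, p_new, p_none`), `events` (tibble `user_id,
#'   timestamp`), `latent` (the full decision table) and `baseline`.
#' @export
#' @examples
#' cfg <- trial_config(n_users = 12, seed = 3)
#' sim <- simulate_trial(cfg)
simulate_trial <- function(config, params = generative_params(),
                           baseline = generate_baseline(config, params)) {
  latent <- simulate_decision_table(config, params, baseline)
  origin <- study_origin(config$start_date)
  ds <- config$decision_s

  opens <- dplyr::bind_rows(
    dplyr::transmute(dplyr::filter(latent, .data$daytime_open == 1),
                     user_id = .data$user_id,
                     lo = (.data$day - 1) * .day_s + 9 * 3600,
                     hi = (.data$day - 1) * .day_s + 19.5 * 3600,
                     bound = (.data$day - 1) * .day_s + ds),
    dplyr::transmute(dplyr::filter(latent, .data$Y_hour == 1),
                     user_id = .data$user_id,
                     lo = (.data$day - 1) * .day_s + ds,
                     hi = (.data$day - 1) * .day_s + ds + 3600,
                     bound = .data$day * .day_s),
    dplyr::transmute(dplyr::filter(latent, .data$late_open == 1),
                     user_id = .data$user_id,
                     lo = (.data$day - 1) * .day_s + ds + 3600,
                     hi = (.data$day - 1) * .day_s + ds + 3 * 3600,
                     bound = .data$day * .day_s))
  opens <- dplyr::arrange(opens, .data$user_id, .data$lo)

  K <- nrow(opens)
  if (K > 0) {
    start <- opens$lo + runif(K) * (opens$hi - opens$lo)
    nv <- 1L + rpois(K, params$views_per_session_mean - 1)
    idx <- rep(seq_len(K), nv)
    g <- rtexp(length(idx), params$interview_gap_mean_s, 1800)
    first <- idx != c(0L, idx[-length(idx)])
    g[first] <- 0
    cg <- cumsum(g)
    rel <- cg - rep(cg[first], nv)
    ts <- rep(start, nv) + rel
    keep <- ts < rep(opens$bound, nv)
    events <- tibble::tibble(user_id = opens$user_id[idx][keep], secs = ts[keep])
  } else {
    events <- tibble::tibble(user_id = character(), secs = numeric())
  }
  if (config$emit_utc) events$secs <- events$secs - 60 * config$utc_offset_min
  events <- dplyr::arrange(
    tibble::tibble(user_id = events$user_id,
                   timestamp = secs_to_time(events$secs, origin)),
    .data$user_id, .data$timestamp)

  list(randomization = dplyr::select(latent, "user_id", "day", "option",
                                     "p_standard", "p_new", "p_none"),
       events = events,
       latent = latent,
       baseline = baseline)
}

## exponential with mean mu truncated to [0, cap)
rtexp <- function(n, mu, cap) {
  -mu * log(1 - runif(n) * (1 - exp(-cap / mu)))
}

#' Write a simulated trial to CSV files
#'
#' Writes `events.csv` (`user_id,timestamp` in ISO-8601 with millisecond
#' precision), `baseline.csv`, `randomization.csv` and a `manifest.json`
#' echoing the seed and the full configuration and generative parameter set,
#' so a run can be reproduced exactly.
#'
#' @param sim Result of [simulate_trial()].
#' @param dir Output directory (created if needed).
#' @param config,params The objects used to generate `sim`.
#' @return Invisibly, the paths written.
#' @export
write_trial_csvs <- function(sim, dir, config, params = generative_params()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("events.csv", "baseline.csv", "randomization.csv",
                            "simulation_manifest.json"))
  ev <- sim$events
  ev$timestamp <- format(ev$timestamp, "%Y-%m-%dT%H:%M:%OS3")
  readr::write_csv(ev, paths[1])
  readr::write_csv(sim$baseline, paths[2])
  readr::write_csv(sim$randomization, paths[3])
  jsonlite::write_json(list(config = unclass(config), params = unclass(params)),
                       paths[4], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
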