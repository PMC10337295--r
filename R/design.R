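#' Two-proportion sample size
#'
#' Per-group sample size for detecting a difference between two proportions
#' with the normal approximation:
#' \deqn{n = \mathrm{round}\left[(z_\alpha + z_\mathrm{power})^2
#'   \frac{p_1(1-p_1) + p_2(1-p_2)}{(p_1 - p_2)^2}\right].}
#' The critical values default to the two-decimal table values 1.96 (two-
#' sided 5% level) and 0.84 (80% power) with rounding to the nearest
#' integer; with `p = (0.55, 0.65)` this gives 372 per group. (Using the
#' exact quantile 0.8416 instead gives 373; the tabled values are the
#' convention adopted here.)
#'
#' @param p1,p2 The two proportions, in (0,1) and distinct.
#' @param z_alpha Critical value for the two-sided type-I error
#'   (default 1.96).
#' @param z_power Critical value for the power (default 0.84).
#' @param rounding `"nearest"` or `"ceil"`.
#' @return Integer per-group sample size.
#' @export
#' @examples
#' two_prop_n(0.55, 0.65)   # 372
two_prop_n <- function(p1, p2, z_alpha = 1.96, z_power = 0.84,
                       rounding = c("nearest", "ceil")) {
  rounding <- match.arg(rounding)
  if (any(c(p1, p2) <= 0 | c(p1, p2) >= 1))
    stop("proportions must lie strictly in (0,1)", call. = FALSE)
  if (p1 == p2) stop("p1 and p2 must differ; the design is undefined", call. = FALSE)
  n <- (z_alpha + z_power)^2 * (p1 * (1 - p1) + p2 * (1 - p2)) / (p1 - p2)^2
  as.integer(if (rounding == "nearest") round(n) else ceiling(n))
}

#' Power scenario for the MRT excursion-effect tests
#'
#' @param effect_day1 Generative day-1 relative risk (default 2.16, the
#'   trial's planning scenario).
#' @param decay_per_day Multiplicative change in the relative risk per day
#'   (default 0.911).
#' @param n_users MRT-arm size.
#' @param n_days Follow-up days (default 30).
#' @param alpha Two-sided test level (default 0.05).
#' @param reps Number of simulation replicates.
#' @param test `"marginal"` (Wald test of the marginal log relative risk) or
#'   `"time_moderation"` (Wald test of the per-day change coefficient).
#' @param params [generative_params()] overrides for the generator (effect
#'   and decay are set from `effect_day1`/`decay_per_day`).
#' @return An object of class `power_scenario`.
#' @export
power_scenario <- function(effect_day1 = 2.16, decay_per_day = 0.911,
                           n_users = 349, n_days = 30, alpha = 0.05,
                           reps = 500,
                           test = c("marginal", "time_moderation"),
                           params = generative_params(missing_rate = 0)) {
  if (reps < 1) stop("`reps` must be at least 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0,1)", call. = FALSE)
  sc <- list(effect_day1 = effect_day1, decay_per_day = decay_per_day,
             n_users = n_users, n_days = n_days, alpha = alpha,
             reps = as.integer(reps), test = match.arg(test), params = params)
  class(sc) <- "power_scenario"
  sc
}

#' Simulation-based rejection rate of an excursion-effect Wald test
#'
#' For each replicate, simulates an MRT arm of `n_users` users over `n_days`
#' days from the generative model with day-1 log relative risk
#' `log(effect_day1)` and per-day decay `log(decay_per_day)`, fits the
#' scenario's excursion-effect model on the simulated decision points
#' (marginal: moderator `"none"`, testing the intercept; time moderation:
#' moderator `"day"`, testing the per-day coefficient) and records whether
#' the two-sided Wald test rejects at level `alpha`. Replicate seeds are
#' derived deterministically from `seed`. Under a null scenario
#' (`effect_day1 = 1`, `decay_per_day = 1`) the rate estimates the type-I
#' error; under an alternative it estimates power.
#'
#' @param scenario A [power_scenario()].
#' @param seed Master seed for the replicate stream.
#' @return A list with `rate`, `se` (binomial Monte-Carlo standard error),
#'   `reps_used` and `divergent` (replicates whose fit failed or did not
#'   converge; more than 5% of them is an error).
#' @export
simulate_rejection_rate <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "power_scenario"))
  set.seed(seed)
  rep_seeds <- sample.int(2^31 - 2, scenario$reps)
  params <- scenario$params
  params$log_rr_day1 <- log(scenario$effect_day1)
  params$log_rr_decay_per_day <- log(scenario$decay_per_day)
  spec <- emee_spec(
    contrast = "pooled",
    moderator = if (scenario$test == "marginal") "none" else "day")
  test_coef <- if (scenario$test == "marginal") 1L else 2L

  reject <- logical(scenario$reps)
  ok <- logical(scenario$reps)
  for (r in seq_len(scenario$reps)) {
    cfg <- trial_config(n_users = scenario$n_users, n_days = scenario$n_days,
                        arm_split = c(1, 0, 0), seed = rep_seeds[r])
    fit <- tryCatch(suppressWarnings({
      records <- simulate_decision_table(cfg, params)
      f <- fit_emee(build_contrast(records, spec))
      if (!f$converged) NULL else f
    }), error = function(e) NULL)
    if (is.null(fit)) next
    ok[r] <- TRUE
    reject[r] <- wald_test(fit, test_coef)$p < scenario$alpha
  }
  n_ok <- sum(ok)
  divergent <- scenario$reps - n_ok
  if (divergent > 0.05 * scenario$reps)
    stop(divergent, " of ", scenario$reps,
         " replicates failed to converge; simulation unreliable", call. = FALSE)
  rate <- mean(reject[ok])
  list(rate = rate, se = sqrt(rate * (1 - rate) / n_ok),
       reps_used = n_ok, divergent = divergent)
}
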