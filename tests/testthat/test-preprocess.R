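test_that("sessionization applies the 30-minute gap rule with strict boundary", {
  one <- sessionize(make_events("u1", "2020-01-02 20:05:00"))
  expect_equal(nrow(one), 1)
  expect_equal(one$duration_s, 0)
  expect_equal(one$n_views, 1L)

  near <- sessionize(make_events("u1", c("2020-01-02 20:00:00",
                                         "2020-01-02 20:29:00")))
  expect_equal(nrow(near), 1)        # 1740 s <= 1800 s: same session
  expect_equal(near$duration_s, 1740)

  split <- sessionize(make_events("u1", c("2020-01-02 20:00:00",
                                          "2020-01-02 20:31:00",
                                          "2020-01-02 20:32:00")))
  expect_equal(nrow(split), 2)       # 1860 s > 1800 s: new session
  expect_equal(split$n_views, c(1L, 2L))
  expect_equal(split$duration_s, c(0, 60))

  exact <- sessionize(make_events("u1", c("2020-01-02 20:00:00",
                                          "2020-01-02 20:30:00")))
  expect_equal(nrow(exact), 1)       # exactly 1800 s does not split
})

test_that("sessionization is invariant to input ordering and user interleaving", {
  ev <- dplyr::bind_rows(
    make_events("u2", c("2020-01-02 10:00:00", "2020-01-02 10:10:00")),
    make_events("u1", c("2020-01-02 10:05:00", "2020-01-03 09:00:00")))
  shuffled <- ev[c(3, 1, 4, 2), ]
  expect_equal(sessionize(ev), sessionize(shuffled))
  expect_equal(nrow(sessionize(ev)), 3)
})

test_that("timezone shift is exact, invertible and flips window membership", {
  ev <- make_events("u1", "2020-01-02 19:30:00")
  expect_equal(to_local(ev, 0), ev)
  expect_equal(to_local(to_local(ev, -60), 60), ev)

  cfg <- trial_config(n_users = 1, n_days = 8)
  rand <- tibble::tibble(user_id = "u1", day = 1:8, option = "none",
                         p_standard = 0, p_new = 0, p_none = 1)
  base <- tibble::tibble(user_id = "u1", age = 40, sex = "female",
                         employment = "nonmanual", audit = 10, arm = "mrt")
  before <- derive_decision_points(ev, rand, base, cfg)
  after <- derive_decision_points(to_local(ev, 60), rand, base, cfg)
  expect_equal(before$Y_hour[1], 0)   # 19:30 is before the window
  expect_equal(after$Y_hour[1], 1)    # 20:30 is inside it
})

test_that("decision-point windows are half-open and lagged covariates align", {
  cfg <- trial_config(n_users = 1, n_days = 8)
  rand <- tibble::tibble(user_id = "u1", day = 1:8, option = "standard",
                         p_standard = 0.3, p_new = 0.3, p_none = 0.4)
  base <- tibble::tibble(user_id = "u1", age = 40, sex = "male",
                         employment = "manual", audit = 12, arm = "mrt")

  rec <- derive_decision_points(
    make_events("u1", "2020-01-04 20:59:59"), rand, base, cfg)
  expect_equal(rec$Y_hour[rec$day == 3], 1)
  expect_equal(rec$already_engaged_prev[rec$day == 4], 1)
  expect_equal(rec$Y_24h[rec$day == 3], 1)

  rec2 <- derive_decision_points(
    make_events("u1", "2020-01-04 21:00:00"), rand, base, cfg)
  expect_equal(rec2$Y_hour[rec2$day == 3], 0)
  expect_equal(rec2$opened_after_9pm_prev[rec2$day == 4], 1)
  expect_equal(rec2$Y_24h[rec2$day == 3], 1)  # 24 h window still catches it

  # no events at all: outcomes all zero, habituation still from randomization
  rec3 <- derive_decision_points(make_events(character(), character()),
                                 rand, base, cfg)
  expect_true(all(rec3$Y_hour == 0) && all(rec3$Y_24h == 0))
  expect_equal(rec3$habituation, c(0L, rep(1L, 7)))

  # unknown user in the event log is dropped with a warning
  expect_warning(
    derive_decision_points(make_events("ghost", "2020-01-02 20:10:00"),
                           rand, base, cfg),
    "dropped")
})

test_that("24-hour outcome dominates the hourly outcome on simulated trials", {
  cfg <- trial_config(n_users = 120, seed = 4)
  sim <- simulate_trial(cfg)
  rec <- derive_decision_points(sim$events, sim$randomization,
                                sim$baseline, cfg)
  expect_true(all(rec$Y_24h >= rec$Y_hour))
})

test_that("disengagement is the earliest 7-day no-use run, censored at 23", {
  day_ev <- function(days) make_events(
    "u1", sprintf("2020-01-%02d 12:00:00", days))
  origin <- as.POSIXct("2020-01-01", tz = "UTC")

  d <- derive_disengagement(day_ev(1:3), origin = origin)
  expect_equal(c(d$time, d$event), c(4L, 1L))

  d <- derive_disengagement(day_ev(1:30), origin = origin)
  expect_equal(c(d$time, d$event), c(23L, 0L))

  d <- derive_disengagement(day_ev(c(1, 9)), origin = origin)
  expect_equal(c(d$time, d$event), c(2L, 1L))  # gap days 2-8 qualifies first

  expect_error(derive_disengagement(day_ev(1), horizon_days = 25,
                                    followup_days = 30, origin = origin),
               "exceeds")
})

test_that("disengagement matches the exhaustive-scan oracle on random logs", {
  set.seed(123)
  origin <- as.POSIXct("2020-01-01", tz = "UTC")
  for (i in 1:50) {
    days <- sort(sample(1:30, sample(0:12, 1)))
    users <- tibble::tibble(user_id = "u1", arm = "mrt")
    ev <- if (length(days) > 0) {
      make_events("u1", format(origin + (days - 1) * 86400 + 43200))
    } else make_events(character(), character())
    got <- derive_disengagement(ev, users = users, origin = origin)
    want <- oracle_disengagement(days)
    expect_equal(c(got$time, got$event), unname(want))
    expect_true(got$time >= 1 && got$time <= 23)
  }
})

test_that("every user is either an event or censored, never both or neither", {
  cfg <- trial_config(n_users = 90, seed = 30)
  sim <- simulate_trial(cfg)
  d <- derive_disengagement(sim$events, users = sim$baseline,
                            origin = mrtengage:::study_origin(cfg$start_date))
  expect_equal(nrow(d), 90)
  expect_true(all(d$event %in% 0:1))
  expect_true(all(d$time >= 1 & d$time <= 23))
  expect_true(all(d$time[d$event == 0] == 23))
})

test_that("modal imputation fills with the most (or second most) common level", {
  base <- tibble::tibble(
    user_id = sprintf("u%03d", 1:566),
    age = 40, audit = 10,
    sex = c(rep("female", 259), rep("male", 247), rep(NA, 60)),
    employment = c(rep("nonmanual", 353), rep("manual", 71),
                   rep("other", 82), rep(NA, 60)),
    arm = rep(c("mrt", "standard", "none"), length.out = 566))

  modal <- impute_modal(base, "modal")
  expect_true(all(modal$sex[is.na(base$sex)] == "female"))
  expect_true(all(modal$employment[is.na(base$employment)] == "nonmanual"))
  expect_false(anyNA(modal$sex))

  second <- impute_modal(base, "second_modal")
  expect_true(all(second$sex[is.na(base$sex)] == "male"))
  expect_true(all(second$employment[is.na(base$employment)] == "other"))

  clean <- base[1:100, ]
  expect_identical(impute_modal(clean, "modal"), clean,
                   ignore_attr = "imputation_counts")

  broken <- base
  broken$sex <- NA_character_
  expect_error(impute_modal(broken), "cannot impute")
})

test_that("usage summaries report order-statistic medians and IQRs by arm", {
  base <- tibble::tibble(user_id = c("a", "b", "c"), arm = "mrt")
  ses <- tibble::tibble(
    user_id = c("a", "b", "c"),
    start = as.POSIXct("2020-01-02 10:00:00", tz = "UTC"),
    end = as.POSIXct("2020-01-02 10:00:10", tz = "UTC"),
    duration_s = 10, n_views = 2L)
  u <- usage_summary(ses, base)
  expect_equal(u$sessions_median, 1)
  expect_equal(u$duration_median, 10)

  ses$duration_s <- c(9, 36, 115)
  u2 <- usage_summary(ses, base)
  expect_equal(c(u2$duration_median, u2$duration_q1, u2$duration_q3),
               c(36, 9, 115))

  # per-user counts against a sort oracle, including an even-sized arm
  set.seed(7)
  counts <- sample(0:25, 20, replace = TRUE)
  base3 <- tibble::tibble(user_id = sprintf("u%02d", 1:20), arm = "mrt")
  ses3 <- tibble::tibble(
    user_id = rep(base3$user_id, counts),
    start = as.POSIXct("2020-01-02 10:00:00", tz = "UTC") +
      unlist(lapply(counts, function(k) seq_len(k) * 7200))[seq_len(sum(counts))],
    end = as.POSIXct("2020-01-02 10:00:00", tz = "UTC"),
    duration_s = 5, n_views = 1L)
  u3 <- usage_summary(ses3, base3, followup_days = 30)
  expect_equal(u3$sessions_median, median(counts))
})
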