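test_that("exactly balanced intercept-only case matches the closed form", {
  # one user, 10 treated (6 successes), 10 untreated (2 successes), p = 0.5:
  # exp(beta) = ((1-p) S1) / (p S0) = 3, exp(alpha) = S0/n0 = 0.2
  rec <- make_intercept_records(10, 6, 10, 2, p = 0.5)
  fit <- fit_emee(build_contrast(rec, intercept_spec()))
  expect_true(fit$converged)
  expect_equal(unname(exp(fit$beta)), 3, tolerance = 1e-8)
  expect_equal(unname(exp(fit$alpha)), 0.2, tolerance = 1e-8)
})

test_that("unbalanced intercept-only fits agree with the bisection oracle", {
  rec <- make_intercept_records(7, 3, 13, 2, p = 0.6)
  fit <- fit_emee(build_contrast(rec, intercept_spec()))
  want <- oracle_emee_root(A = rep(1:0, c(7, 13)),
                           Y = rec$Y_hour, W = rep(1, 20), ptilde = 0.6)
  expect_equal(unname(fit$alpha), unname(want["alpha"]), tolerance = 1e-6)
  expect_equal(unname(fit$beta), unname(want["beta"]), tolerance = 1e-6)
  expect_equal(unname(exp(fit$beta)), 39 / 14, tolerance = 1e-6)
})

test_that("oracle equivalence holds with non-trivial centering weights", {
  set.seed(61)
  for (i in 1:8) {
    n <- sample(10:30, 1)
    repeat {
      A <- rbinom(n, 1, 0.6)
      Y <- rbinom(n, 1, 0.3 + 0.3 * A)
      if (sum(Y[A == 1]) > 0 && sum(Y[A == 0]) > 0 &&
          length(unique(A)) == 2) break
    }
    rec <- tibble::tibble(user_id = "u1", day = seq_len(n),
                          option = ifelse(A == 1, "standard", "none"),
                          p_standard = 0.6, p_new = 0, p_none = 0.4,
                          Y_hour = Y)
    fit <- fit_emee(build_contrast(rec, intercept_spec(centering_prob = 0.35)))
    W <- (0.35 / 0.6)^A * (0.65 / 0.4)^(1 - A)
    want <- oracle_emee_root(A, Y, W, ptilde = 0.35)
    expect_equal(unname(fit$alpha), unname(want["alpha"]), tolerance = 1e-6)
    expect_equal(unname(fit$beta), unname(want["beta"]), tolerance = 1e-6)
  }
})

test_that("default centering makes all weights one, identical to forced weights", {
  rec <- make_intercept_records(8, 4, 12, 3, p = 0.4)
  set <- build_contrast(rec, intercept_spec())
  expect_true(all(set$W == 1))
  forced <- set
  forced$W <- rep(1, length(set$W))
  expect_identical(fit_emee(set)[c("alpha", "beta")],
                   fit_emee(forced)[c("alpha", "beta")])
})

test_that("null treatment-control difference gives a zero log relative risk", {
  rec <- make_intercept_records(10, 4, 10, 4, p = 0.5)
  fit <- fit_emee(build_contrast(rec, intercept_spec()))
  expect_equal(unname(fit$beta), 0, tolerance = 1e-8)
})

test_that("contrast construction: counts, probabilities and weights", {
  cfg <- trial_config(n_users = 349, arm_split = c(1, 0, 0), seed = 14)
  rec <- suppressWarnings(
    simulate_decision_table(cfg, generative_params(missing_rate = 0)))
  pooled <- build_contrast(rec, emee_spec("pooled"))
  expect_equal(length(pooled$Y), 10470)
  expect_true(all(pooled$p == 0.6))
  expect_true(all(pooled$W == 1))

  sn <- build_contrast(rec, emee_spec("standard_vs_none"))
  expect_lt(abs(length(sn$Y) - 0.7 * 10470), 3 * sqrt(10470 * 0.3 * 0.7))
  expect_true(all(abs(sn$p - 3 / 7) < 1e-12))

  nn <- build_contrast(rec, emee_spec("new_vs_none"))
  expect_true(all(abs(nn$p - 3 / 7) < 1e-12))
})

test_that("estimates are invariant to covariate rescaling and user relabeling", {
  cfg <- trial_config(n_users = 120, arm_split = c(1, 0, 0), seed = 25)
  rec <- suppressWarnings(
    simulate_decision_table(cfg, generative_params(missing_rate = 0)))
  spec <- emee_spec("pooled", "day")
  fit <- fit_emee(build_contrast(rec, spec))

  rec2 <- rec
  rec2$age <- (rec2$age - 40) / 10       # affine rescale of a control column
  fit2 <- fit_emee(build_contrast(rec2, spec))
  expect_equal(fit$beta, fit2$beta, tolerance = 1e-8)

  rec3 <- rec
  relabel <- setNames(sprintf("z%04d", seq_along(unique(rec$user_id))),
                      sample(unique(rec$user_id)))
  rec3$user_id <- unname(relabel[rec3$user_id])
  fit3 <- fit_emee(build_contrast(rec3, spec))
  expect_equal(fit$beta, fit3$beta, tolerance = 1e-10)
  expect_equal(fit$vcov, fit3$vcov, tolerance = 1e-10)
})

test_that("degenerate cells and collinear designs are rejected with diagnosis", {
  rec <- make_intercept_records(10, 0, 10, 3, p = 0.5)
  expect_error(fit_emee(build_contrast(rec, intercept_spec())),
               "no successes.*A=1")

  cfg <- trial_config(n_users = 60, arm_split = c(1, 0, 0), seed = 33)
  sim <- suppressWarnings(
    simulate_decision_table(cfg, generative_params(missing_rate = 0)))
  sim$age_copy <- sim$age
  spec <- emee_spec("pooled", control = c("age", "age_copy"))
  expect_error(fit_emee(build_contrast(sim, spec)), "collinear")

  one_level <- make_intercept_records(10, 5, 10, 2, p = 0.5)
  one_level$option <- "none"
  expect_error(build_contrast(one_level, intercept_spec()),
               "fewer than two treatment levels")
})

test_that("effect reporting exponentiates the right linear combinations", {
  fake <- function(beta, vb, moderator) {
    structure(list(alpha = c(`(Intercept)` = -3), beta = beta,
                   vcov = rbind(0, cbind(0, vb)),
                   spec = list(moderator = moderator)),
              class = "emee_fit")
  }
  tm <- report_effects(fake(c(log(3.849), log(0.993)),
                            diag(c(0.0256, 1e-4)), "day"))
  expect_equal(tm$estimate[tm$quantity == "day1_rr"], 3.849)
  expect_equal(tm$estimate[tm$quantity == "per_day_change"], 0.993)
  expect_true(all(tm$ci_low < tm$estimate & tm$estimate < tm$ci_high))

  bm <- report_effects(fake(c(log(3.620), log(0.875)),
                            diag(c(0.01, 0.02)), "already_engaged"))
  expect_equal(bm$estimate[bm$quantity == "rr_yes"], 3.620 * 0.875)
  expect_equal(bm$estimate[bm$quantity == "ratio_yes_no"], 0.875)

  null <- report_effects(fake(c(`(Intercept)` = 0), matrix(0, 1, 1), "none"))
  expect_equal(unlist(null[, c("estimate", "ci_low", "ci_high")]),
               c(estimate = 1, ci_low = 1, ci_high = 1))
})

test_that("Wald tests use the sandwich standard error and normal reference", {
  fake <- structure(list(alpha = c(`(Intercept)` = -3),
                         beta = c(`(Intercept)` = 0, day1 = 1.96),
                         vcov = diag(c(1, 1, 1)),
                         spec = list(moderator = "day")),
                    class = "emee_fit")
  w1 <- wald_test(fake, 1)
  expect_equal(w1$z, 0)
  expect_equal(w1$p, 1)
  w2 <- wald_test(fake, 2)
  expect_equal(w2$p, 0.05, tolerance = 1e-3)
  expect_error(wald_test(fake, 3), "out of range")
})

test_that("moderated fits put the moderator main effect in the control model", {
  cfg <- trial_config(n_users = 150, arm_split = c(1, 0, 0), seed = 55)
  rec <- suppressWarnings(
    simulate_decision_table(cfg, generative_params(missing_rate = 0)))
  set <- build_contrast(rec, emee_spec("pooled", "habituation"))
  expect_true("habituation" %in% colnames(set$G))
  expect_equal(colnames(set$F), c("(Intercept)", "habituation"))
  fit <- fit_emee(set)
  expect_true(fit$converged)
  eff <- report_effects(fit)
  expect_equal(eff$estimate[eff$quantity == "rr_yes"],
               eff$estimate[eff$quantity == "rr_no"] *
                 eff$estimate[eff$quantity == "ratio_yes_no"],
               tolerance = 1e-10)
})
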