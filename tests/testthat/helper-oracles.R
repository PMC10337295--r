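# Independent oracles used to cross-check the package implementations.

# Root of the intercept-only excursion estimating equations by profiling the
# control intercept out analytically and locating the moderator-equation root
# with a dense grid scan plus bisection. Independent of the Newton solver.
oracle_emee_root <- function(A, Y, W, ptilde, lower = -12, upper = 12) {
  prof_a <- function(b) log(sum(W * exp(-A * b) * Y) / sum(W))
  ee2 <- function(b) {
    a <- prof_a(b)
    sum(W * (exp(-A * b) * Y - exp(a)) * (A - ptilde))
  }
  bs <- seq(lower, upper, length.out = 4001)
  v <- vapply(bs, ee2, 0)
  i <- which(v[-1] * v[-length(v)] <= 0)[1]
  stopifnot(!is.na(i))
  lo <- bs[i]; hi <- bs[i + 1]
  flo <- ee2(lo)
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    fm <- ee2(mid)
    if (flo * fm <= 0) hi <- mid else { lo <- mid; flo <- fm }
  }
  b <- (lo + hi) / 2
  c(alpha = prof_a(b), beta = b)
}

# Log-rank statistic by brute-force accumulation of per-event-time k x 2
# tables: observed minus hypergeometric-expected events per arm, with the
# multivariate hypergeometric covariance, over the first k - 1 arms.
oracle_logrank_chi2 <- function(time, event, arm) {
  arms <- sort(unique(arm))
  k <- length(arms)
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(event == 1 & time == t)
    nj <- vapply(arms, function(a) sum(at_risk & arm == a), 0)
    dj <- vapply(arms, function(a) sum(at_risk & arm == a & event == 1 & time == t), 0)
    O <- O + dj
    E <- E + d * nj / n
    if (n > 1) {
      for (i in 1:k) for (j in 1:k) {
        V[i, j] <- V[i, j] +
          d * (n - d) / (n - 1) * nj[i] * ((i == j) * n - nj[j]) / n^2
      }
    }
  }
  om <- (O - E)[-k]
  drop(t(om) %*% solve(V[-k, -k, drop = FALSE]) %*% om)
}

# Exhaustive-scan disengagement rule: earliest day d in 1..horizon such that
# none of days d..d+run-1 appears in the set of active days.
oracle_disengagement <- function(use_days, horizon = 23, run = 7) {
  for (d in seq_len(horizon)) {
    if (!any(d:(d + run - 1) %in% use_days)) return(c(time = d, event = 1))
  }
  c(time = horizon, event = 0)
}

# Event tibble from clock strings on the study clock.
make_events <- function(user, times) {
  tibble::tibble(user_id = user,
                 timestamp = as.POSIXct(times, tz = "UTC"))
}

# Decision-point records for an intercept-only single-user contrast: n1
# treated rows with s1 successes, n0 untreated with s0, constant
# randomization probability p of (pooled) treatment.
make_intercept_records <- function(n1, s1, n0, s0, p, user = "u1") {
  n <- n1 + n0
  tibble::tibble(
    user_id = user, day = seq_len(n),
    option = rep(c("standard", "none"), c(n1, n0)),
    p_standard = p, p_new = 0, p_none = 1 - p,
    Y_hour = c(rep(1:0, c(s1, n1 - s1)), rep(1:0, c(s0, n0 - s0))))
}

intercept_spec <- function(centering_prob = NULL, correction = FALSE) {
  emee_spec("pooled", "none", control = character(0),
            centering_prob = centering_prob,
            small_sample_correction = correction)
}
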