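#' Specify an excursion-effect model
#'
#' Defines the estimand and model for the estimator of the marginal excursion
#' effect (EMEE) of a binary time-varying treatment on a binary proximal
#' outcome, on the relative-risk scale:
#' \deqn{\log E[Y_{t+1} \mid H_t, A_t] = g(H_t)^\top \alpha + A_t f(S_t)^\top \beta}
#' where \eqn{f} are the moderator features (always including an intercept)
#' and \eqn{g} the control features. `exp(beta)` are relative risks; the
#' control part is a working model and its misspecification does not bias
#' `beta`.
#'
#' @param contrast Which treatment contrast to estimate: `"pooled"` (any
#'   notification vs none), `"standard_vs_none"` or `"new_vs_none"`. The
#'   type-specific contrasts subset to decision points assigned that type or
#'   none, with the conditional randomization probability (3/7 under the
#'   default 0.3/0.3/0.4 scheme).
#' @param moderator `"none"` (marginal effect), `"day"` (linear effect
#'   moderation in days since download, centred at day 1 so `exp(beta0)` is
#'   the day-1 relative risk), `"habituation"` or `"already_engaged"`
#'   (binary-state moderation; the moderator's main effect is added to the
#'   control features).
#' @param outcome Outcome column: `"Y_hour"` (decision-point hour) or
#'   `"Y_24h"` (24-hour window).
#' @param control Character vector of control feature columns (intercept is
#'   implicit and always first). The default is the trial's adjustment set:
#'   age, AUDIT score, days since download, sex and employment indicators,
#'   and the two time-varying opening covariates.
#' @param centering_prob Centering probability \eqn{\tilde p}: `NULL` (use
#'   the randomization probability of treatment, making all weights 1), a
#'   scalar in (0,1), or a function of the record tibble returning one value
#'   per row.
#' @param small_sample_correction Apply the hat-matrix inverse inflation of
#'   per-user residuals in the sandwich variance (default `TRUE`).
#' @return An object of class `emee_spec`.
#' @export
emee_spec <- function(contrast = c("pooled", "standard_vs_none", "new_vs_none"),
                      moderator = c("none", "day", "habituation", "already_engaged"),
                      outcome = c("Y_hour", "Y_24h"),
                      control = c("age", "audit", "day1", "sex_male",
                                  "emp_manual", "emp_other",
                                  "opened_before_8pm", "opened_after_9pm_prev"),
                      centering_prob = NULL,
                      small_sample_correction = TRUE) {
  spec <- list(contrast = match.arg(contrast),
               moderator = match.arg(moderator),
               outcome = match.arg(outcome),
               control = control,
               centering_prob = centering_prob,
               small_sample_correction = isTRUE(small_sample_correction))
  class(spec) <- "emee_spec"
  spec
}

## Materialize derived design columns on a decision-point tibble.
design_frame <- function(records) {
  records$day1 <- records$day - 1
  if ("sex" %in% names(records)) {
    records$sex_male <- as.numeric(records$sex == "male")
  }
  if ("employment" %in% names(records)) {
    records$emp_manual <- as.numeric(records$employment == "manual")
    records$emp_other <- as.numeric(records$employment == "other")
  }
  records
}

moderator_column <- function(moderator) {
  switch(moderator,
         none = NULL,
         day = "day1",
         habituation = "habituation",
         already_engaged = "already_engaged_prev")
}

#' Build an estimation set for a treatment contrast
#'
#' Subsets MRT-arm decision points to the requested contrast, defines the
#' binary treatment `A` and its randomization probability `p`, materializes
#' the moderator feature matrix `F` and control feature matrix `G`, and
#' computes the centering weights
#' \eqn{W = (\tilde p / p)^A ((1-\tilde p)/(1-p))^{1-A}}.
#'
#' For the pooled contrast `A` indicates any notification and
#' `p = p_standard + p_new`; for a type-specific contrast, decision points
#' assigned the other type are dropped and `p` is the conditional probability
#' of that type given not-the-other.
#'
#' @param records Decision-point tibble (MRT arm; rows from other arms are
#'   dropped if an `arm` column is present).
#' @param spec An [emee_spec()].
#' @return An object of class `estimation_set`.
#' @export
build_contrast <- function(records, spec) {
  stopifnot(inherits(spec, "emee_spec"))
  records <- design_frame(records)
  if ("arm" %in% names(records)) records <- records[records$arm == "mrt", , drop = FALSE]
  if (nrow(records) == 0) stop("no MRT-arm records", call. = FALSE)

  if (spec$contrast == "pooled") {
    A <- as.numeric(records$option %in% c("standard", "new"))
    p <- records$p_standard + records$p_new
  } else {
    type <- if (spec$contrast == "standard_vs_none") "standard" else "new"
    other <- setdiff(c("standard", "new"), type)
    records <- records[records$option != other, , drop = FALSE]
    A <- as.numeric(records$option == type)
    pt_col <- records[[paste0("p_", type)]]
    p <- pt_col / (pt_col + records$p_none)
  }
  if (length(unique(A)) < 2)
    stop("estimation set has fewer than two treatment levels after subsetting",
         call. = FALSE)
  if (any(p <= 0 | p >= 1))
    stop("treatment probabilities must lie strictly in (0,1)", call. = FALSE)

  ptilde <- spec$centering_prob
  ptilde <- if (is.null(ptilde)) p
            else if (is.function(ptilde)) ptilde(records)
            else rep(as.numeric(ptilde), nrow(records))
  if (any(ptilde <= 0 | ptilde >= 1))
    stop("centering probabilities must lie strictly in (0,1)", call. = FALSE)
  W <- (ptilde / p)^A * ((1 - ptilde) / (1 - p))^(1 - A)

  mod_col <- moderator_column(spec$moderator)
  f_names <- c("(Intercept)", mod_col)
  g_cols <- spec$control
  if (!is.null(mod_col) && spec$moderator != "day" && !mod_col %in% g_cols)
    g_cols <- c(g_cols, mod_col)   # moderator main effect in the control model
  g_names <- c("(Intercept)", g_cols)

  need <- unique(c(spec$outcome, mod_col, g_cols))
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0)
    stop("records lack required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  use <- records[, need, drop = FALSE]
  if (anyNA(use))
    stop("NA in model columns; impute baseline covariates first (impute_modal)",
         call. = FALSE)

  Fm <- cbind(1, as.matrix(use[, mod_col, drop = FALSE]))
  colnames(Fm) <- f_names
  Gm <- cbind(1, as.matrix(use[, g_cols, drop = FALSE]))
  colnames(Gm) <- g_names

  set <- list(user_id = records$user_id, day = records$day,
              A = A, p = p, ptilde = ptilde, W = W,
              Y = as.numeric(use[[spec$outcome]]),
              F = Fm, G = Gm, spec = spec)
  class(set) <- "estimation_set"
  set
}

#' Fit the excursion-effect estimating equations
#'
#' Solves the stacked per-user estimating equations
#' \deqn{\sum_i \sum_t W_t \left(e^{-A_t f_t^\top \beta} Y_t -
#'   e^{g_t^\top \alpha}\right)
#'   \begin{pmatrix} g_t \\ (A_t - \tilde p_t) f_t \end{pmatrix} = 0}
#' by damped Newton-Raphson with the analytic Jacobian. Initialization sets
#' `beta = 0` and the control intercept to the log of the untreated outcome
#' mean; convergence requires the largest absolute update below `tol`.
#' The variance is the sandwich \eqn{B^{-1} M B^{-\top} / n} over per-user
#' contributions; with the small-sample correction each user's residual
#' vector is pre-multiplied by the inverse of `I` minus that user's hat
#' matrix before entering the meat, which counters the downward bias of the
#' plain sandwich when users number only in the hundreds.
#'
#' @param set An [build_contrast()] estimation set.
#' @param tol Convergence tolerance on the Newton update (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 50), with up to 10
#'   step-halvings per iteration.
#' @return An object of class `emee_fit` with elements `alpha`, `beta`,
#'   `vcov` (over `c(alpha, beta)`), `n_users`, `n_points`, `converged`,
#'   `iterations`.
#' @export
fit_emee <- function(set, tol = 1e-8, max_iter = 50) {
  stopifnot(inherits(set, "estimation_set"))
  A <- set$A; Y <- set$Y; W <- set$W; pt <- set$ptilde
  Fm <- set$F; Gm <- set$G
  qf <- ncol(Fm); qg <- ncol(Gm); q <- qf + qg

  check_cells(set)
  X <- cbind(Gm, (A - pt) * Fm)
  qrX <- qr(X)
  if (qrX$rank < q) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):q]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  theta <- c(log(mean(Y[A == 0])), rep(0, q - 1))
  Cmat <- W * cbind(Gm, (A - pt) * Fm)      # rows c_it

  score <- function(theta) {
    mu <- exp(drop(Gm %*% theta[1:qg]))
    eb <- exp(-A * drop(Fm %*% theta[(qg + 1):q]))
    r <- eb * Y - mu
    list(U = drop(crossprod(Cmat, r)), mu = mu, eb = eb, r = r)
  }

  s <- score(theta)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    D <- cbind(s$mu * Gm, (A * s$eb * Y) * Fm)   # rows d_it
    Bn <- crossprod(Cmat, D)
    delta <- solve(Bn, s$U)
    step <- 1
    repeat {
      cand <- theta + step * delta
      s_new <- score(cand)
      if (all(is.finite(s_new$U)) &&
          (sum(s_new$U^2) < sum(s$U^2) || step < 1 / 1024)) break
      step <- step / 2
    }
    theta <- theta + step * delta
    s <- s_new
    if (max(abs(step * delta)) < tol) { converged <- TRUE; break }
  }

  ## sandwich at the solution
  D <- cbind(s$mu * Gm, (A * s$eb * Y) * Fm)
  Bn <- crossprod(Cmat, D)
  Binv <- solve(Bn)
  idx <- split(seq_along(Y), set$user_id)
  n_users <- length(idx)
  Mn <- matrix(0, q, q)
  for (ii in idx) {
    Ci <- Cmat[ii, , drop = FALSE]
    ri <- s$r[ii]
    if (set$spec$small_sample_correction) {
      Hi <- D[ii, , drop = FALSE] %*% Binv %*% t(Ci)
      ri <- solve(diag(length(ii)) - Hi, ri)
    }
    Ui <- drop(crossprod(Ci, ri))
    Mn <- Mn + tcrossprod(Ui)
  }
  V <- Binv %*% Mn %*% t(Binv)
  nms <- c(paste0("alpha:", colnames(Gm)), paste0("beta:", colnames(Fm)))
  dimnames(V) <- list(nms, nms)

  fit <- list(alpha = setNames(theta[1:qg], colnames(Gm)),
              beta = setNames(theta[(qg + 1):q], colnames(Fm)),
              vcov = V, n_users = n_users, n_points = length(Y),
              converged = converged, iterations = iter, spec = set$spec)
  class(fit) <- "emee_fit"
  fit
}

## Refuse to fit when a required treatment-by-stratum cell has no successes:
## the log-scale root would be at -Inf.
check_cells <- function(set) {
  strata <- list(all = rep(TRUE, length(set$Y)))
  binary_f <- colnames(set$F)[-1][apply(set$F[, -1, drop = FALSE], 2,
                                        function(x) all(x %in% c(0, 1)))]
  for (b in binary_f) {
    strata[[paste0(b, "=0")]] <- set$F[, b] == 0
    strata[[paste0(b, "=1")]] <- set$F[, b] == 1
  }
  for (nm in names(strata)) {
    for (a in 0:1) {
      sel <- strata[[nm]] & set$A == a
      if (sum(set$Y[sel]) == 0)
        stop("no successes in cell {", nm, ", A=", a,
             "}; excursion effect diverges", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.emee_fit <- function(x, ...) {
  cat("EMEE fit:", x$spec$contrast, "contrast, moderator =", x$spec$moderator,
      "\n", x$n_points, "decision points from", x$n_users, "users;",
      if (x$converged) "converged" else "DID NOT CONVERGE",
      "in", x$iterations, "iterations\n")
  se <- sqrt(diag(x$vcov))
  qg <- length(x$alpha)
  tab <- data.frame(estimate = c(x$alpha, x$beta),
                    se = se,
                    exp_estimate = exp(c(x$alpha, x$beta)))
  rownames(tab) <- names(se)
  print(tab, digits = 4)
  invisible(x)
}

#' Wald test of one excursion-effect coefficient
#'
#' @param fit An [fit_emee()] result.
#' @param coef Index (or name) of the coefficient within `beta`.
#' @return A list with `z` and the two-sided `p` value from the standard
#'   normal reference.
#' @export
wald_test <- function(fit, coef = 1) {
  stopifnot(inherits(fit, "emee_fit"))
  j <- if (is.character(coef)) match(coef, names(fit$beta)) else as.integer(coef)
  if (is.na(j) || j < 1 || j > length(fit$beta))
    stop("coefficient index out of range", call. = FALSE)
  se <- sqrt(diag(fit$vcov))[length(fit$alpha) + j]
  z <- unname(fit$beta[j] / se)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Report excursion effects as relative risks with confidence intervals
#'
#' Exponentiates the fitted log-relative-risk coefficients and Wald
#' intervals of the relevant linear combinations (delta method on the log
#' scale): for the marginal model a single relative risk; for the
#' time-moderated model the day-1 relative risk and the multiplicative
#' change per day; for a binary moderator the relative risk in the "no" and
#' "yes" states and their ratio.
#'
#' @param fit An [fit_emee()] result.
#' @param level Confidence level (default 0.95).
#' @return A tibble `quantity, estimate, ci_low, ci_high` (all on the
#'   relative-risk scale).
#' @export
report_effects <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "emee_fit"))
  zq <- qnorm(1 - (1 - level) / 2)
  qg <- length(fit$alpha)
  vb <- fit$vcov[qg + seq_along(fit$beta), qg + seq_along(fit$beta), drop = FALSE]
  lincom <- function(l) {
    est <- sum(l * fit$beta)
    se <- sqrt(drop(t(l) %*% vb %*% l))
    c(exp(est), exp(est - zq * se), exp(est + zq * se))
  }
  rows <- switch(fit$spec$moderator,
    none = list(rr = lincom(1)),
    day = list(day1_rr = lincom(c(1, 0)),
               per_day_change = lincom(c(0, 1))),
    list(rr_no = lincom(c(1, 0)),
         rr_yes = lincom(c(1, 1)),
         ratio_yes_no = lincom(c(0, 1))))
  tibble::tibble(quantity = names(rows),
                 estimate = unname(vapply(rows, `[`, 0, 1)),
                 ci_low = unname(vapply(rows, `[`, 0, 2)),
                 ci_high = unname(vapply(rows, `[`, 0, 3)))
}
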