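---
title: "Estimating near-term notification effects in a micro-randomized trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating near-term notification effects in a micro-randomized trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrtengage)
```

## The design and the estimand

A micro-randomized trial (MRT) randomizes every user repeatedly over time.
In the trial design this package implements, each MRT-arm user is
randomized daily at 8 PM among three options — the standard reminder
message (probability 0.3), a message from a new bank (0.3), or no
notification (0.4) — and the proximal outcome $Y_{t+1}$ is whether the user
opens the app in the following hour. Two parallel arms implement a fixed
daily-message policy and a no-notification policy; across the three arms
the outcome of interest is time to disengagement.

The causal quantity for the MRT is the *excursion effect*: the contrast in
the expected proximal outcome between receiving and not receiving a
notification at a decision point, marginal over each user's history. For a
binary outcome we express it on the relative-risk (RR) scale, because risk
ratios are collapsible over independent user-level heterogeneity under a
log link, which a per-protocol odds ratio is not.

## The estimator

The model is
$$\log E[\,Y_{t+1}\mid H_t, A_t\,] = g(H_t)^\top\alpha + A_t\, f(S_t)^\top\beta,$$
with moderator features $f$ (always containing an intercept) and control
features $g$. $\exp(\beta)$ is the relative risk of interest; $g^\top\alpha$
is a working model whose misspecification does not bias $\beta$ — the price
of that robustness is paid by the centering-and-weighting construction
below rather than by correct outcome modelling.

The per-user estimating function is
$$U_i(\alpha,\beta)=\sum_t W_t\,
  \bigl(e^{-A_t f_t^\top\beta} Y_t - e^{g_t^\top\alpha}\bigr)
  \begin{pmatrix} g_t \\ (A_t-\tilde p_t) f_t\end{pmatrix},
\qquad
W_t=\Bigl(\tfrac{\tilde p_t}{p_t}\Bigr)^{A_t}
    \Bigl(\tfrac{1-\tilde p_t}{1-p_t}\Bigr)^{1-A_t},$$
where $p_t$ is the randomization probability of treatment under the chosen
contrast and $\tilde p_t$ the centering probability. We solve
$\sum_i U_i = 0$ by damped Newton–Raphson with the analytic Jacobian:
$\beta$ starts at 0, the $\alpha$-intercept at the log of the untreated
outcome mean and the rest at 0; a step is halved (up to ten times) whenever
it does not reduce the squared score norm; convergence requires the largest
absolute update below $10^{-8}$, within 50 iterations. Before solving we
refuse designs that cannot have a finite root — any required
treatment-by-moderator cell without a single success — and rank-deficient
designs, naming the collinear columns.

The variance is the sandwich $B^{-1} M B^{-\top}/n$ over per-user
contributions. With a few hundred users the plain sandwich is known to be
anti-conservative, so by default each user's residual vector is inflated by
$(I - H_i)^{-1}$, the inverse of identity minus the user's hat matrix —
the standard small-sample leverage correction for user-clustered
estimating equations — before entering the meat matrix; a flag disables
the correction so that small closed-form test cases can check the plain
algebra. In 500 replicated synthetic trials of 349 users (the acceptance
suite), the corrected 95% Wald interval for the day-1 RR covered the
generating value 96.2% of the time and the null time-moderation test
rejected at 4.8%.

### Contrasts, moderators, controls

Three contrasts are supported. *Pooled* treats any notification as
treatment ($p = 0.6$ under the default probabilities). The type-specific
contrasts drop decision points assigned the other type and use the
conditional randomization probability ($0.3/0.7 = 3/7$); this conditioning
is exact under the trial's independent daily randomization. The centering
probability defaults to $p_t$ itself, making every weight 1; the general
weighted path is retained and exercised in tests because the estimator is
defined with it.

Moderator sets: none (marginal effect); days since download entered as
$d-1$, so $\exp(\beta_0)$ is the day-1 RR and $\exp(\beta_1)$ the
multiplicative change per day; or a binary recent state (habituation =
received a notification yesterday; already engaged = opened during
yesterday's outcome window), reported as the RR in each state and their
ratio. The control set defaults to the trial's adjustment set — age, AUDIT
score, days since download, sex and employment indicators (reference
levels female and nonmanual, the modal categories), and the two
time-varying opening covariates — and a binary moderator's main effect is
always added to the controls so the state-specific effects are interpreted
against a state-adjusted baseline.

## Preprocessing rules

Raw engagement is a stream of timestamped screen views. Sessions are built
with the 30-minute inactivity rule; we take a gap of *strictly more* than
1800 s to start a new session, so the boundary case is well defined and
testable. Session length is last view minus first view, hence a
single-view session has length 0 and all lengths are underestimates.

All outcome and covariate windows are half-open $[\mathrm{start},
\mathrm{end})$: the hourly outcome window is $[20{:}00, 21{:}00)$, the
24-hour outcome $[20{:}00_d, 20{:}00_{d+1})$, "opened before 8 PM" is
$[00{:}00, 20{:}00)$ of the same day and "opened after 9 PM the day
before" is $[21{:}00, 24{:}00)$ of day $d-1$. "Opening the app" means any
screen view in the window, not only session starts, since tapping a
notification lands directly on the app's landing page mid-session or not.
Timestamps are held on a fixed-offset study clock; a UTC export is moved
onto it by a constant shift (`to_local()`), deliberately avoiding civil
time-zone arithmetic so that no daylight-saving transition can move a
window boundary.

Disengagement is the first day starting a run of at least 7 consecutive
no-use days, defined only over the first 23 days of a 30-day follow-up;
users without a qualifying day are censored at day 23. We keep the 23-day
horizon convention as given even though a run starting day 24 would still
fit inside the follow-up, because the survival comparison is defined on
that horizon. Missing baseline sex/employment are imputed with the pooled
modal category (second-most-common for the sensitivity path). Usage
summaries report medians and quartiles with the averaged inverse-ECDF
quantile (`type = 2`), which yields order statistics for odd counts and
half-integer medians for even counts, matching how such tables are
conventionally reported.

## The synthetic generator

No real dataset ships with the package; the generator produces trials with
the statistical structure the analysis assumes, so every stage is testable
end to end. Its defaults are the study conditions: 60/20/20 arm split,
0.3/0.3/0.4 daily assignment, 30-day follow-up, baseline window-open
probability 0.036, day-1 notification RR 3.5 decaying by a factor 0.993
per day, and baseline marginals (age 44 ± 12, AUDIT zones 0.49/0.20/0.31,
sex 50/50, employment 0.70/0.14/0.16, missingness 60/566).

The open-probability model is log-linear with a user random intercept
($\sigma_u = 0.7$) and is clipped at 0.99; a log link is chosen because
the analysis model is log-link, so the generating coefficients are the
estimands. Quantities the study conditions do not pin down were fixed once
at values realistic for an evening-peaked behaviour change app and not
revisited: a per-day disengagement hazard of 0.07 (median first no-use day
near 11), daytime and late-evening open probabilities of 0.5 and 0.15, and
sessions of $1+\mathrm{Poisson}(3)$ views with mean 20 s gaps truncated
below 1800 s (so a generated session can never be split by the
sessionizer). Day 1 always contains a daytime onboarding session, because
registration happens inside the app; consequently the absorbing
disengagement day is drawn from day 2 onward. Daytime sessions are
truncated at 8 PM and evening/late sessions at midnight so that the
generated outcome indicators can be recovered exactly from the emitted
log — a property the test suite checks record by record.

What the generator does *not* emulate: notification content, weekly or
calendar seasonality, drinking-diary entries, gradual (non-absorbing)
disengagement, and any dependence of randomization on context. Passing
tests therefore demonstrate correctness of the estimators and pipelines
under the assumed structure, not robustness to every pattern of real
usage.

## Design computations

The two-proportion sample-size formula
$n = (z_\alpha + z_{\mathrm{power}})^2\,[p_1(1-p_1)+p_2(1-p_2)]/(p_1-p_2)^2$
uses the two-decimal table critical values 1.96 and 0.84 and
nearest-integer rounding, which reproduces the published 372 per group for
$p = (0.55, 0.65)$; the exact quantile 0.8416 would give 373 and is
available by passing `z_power` explicitly. The simulation-based power
path generates MRT arms from this package's generator at a specified
day-1 effect and decay, fits the marginal or time-moderated model on each
replicate and reports the Wald rejection fraction with its binomial
standard error; replicate seeds are derived deterministically from one
master seed, and more than 5% divergent replicates abort the estimate.
Simulation sizes in the shipped tests (500 replicates of 349 users for
size and coverage, 60 replicates for power monotonicity) were chosen as
the smallest giving acceptance-grade Monte-Carlo precision.

## Worked example

```{r, eval = FALSE}
cfg <- trial_config(n_users = 566, seed = 1)
out <- run_pipeline(list(trial = list(n_users = 566, seed = 1)),
                    out_dir = tempfile("mrt-run"))
out$effects
```

The pipeline writes the simulated CSVs, the decision-point table, effect
tables (marginal, time-moderated, two state-moderated and 24-hour models
for each contrast), per-arm Kaplan–Meier curves, the log-rank summary and
a manifest that reproduces the run byte for byte.

## Known limitations

* The estimator assumes every user is available for randomization at every
  decision point; availability indicators are not implemented.
* Type-specific contrasts condition on the two-option subset; with
  data-dependent randomization probabilities that conditioning would need
  revisiting.
* The exact small-sample correction variant used in other implementations
  varies; ours inflates residuals through the per-user hat matrix, and its
  empirical coverage is validated by simulation rather than by algebraic
  equivalence to any particular reference.
* The survival comparison is an unadjusted log-rank across arms; no
  covariate-adjusted or competing-risk analysis is provided.
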