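#' Run the full trial analysis pipeline
#'
#' Orchestrates the stages end to end: `simulate` (synthetic trial written as
#' CSVs), `derive` (sessionization, decision-point records, disengagement
#' times, modal imputation, usage summaries), `fit` (marginal, time-moderated,
#' state-moderated and 24-hour excursion-effect models for the pooled and
#' type-specific contrasts), `survival` (per-arm Kaplan-Meier curves and the
#' log-rank test) and, optionally, `power` (simulation-based rejection rate).
#' Every artifact is written under `out_dir` together with a run manifest
#' (full configuration and seed) and a plain-text summary report; re-running
#' the same manifest reproduces the outputs byte for byte.
#'
#' @param config A named list (or path to a YAML file) with optional blocks
#'   `trial` (arguments to [trial_config()]), `params` (arguments to
#'   [generative_params()]), `power` (arguments to [power_scenario()]),
#'   `stages` (subset of `c("simulate", "derive", "fit", "survival",
#'   "power")`), and scalar keys `gap_s` (sessionization threshold, default
#'   1800), `horizon_days` (default 23), `run_days` (default 7) and
#'   `impute` (`"modal"` or `"second_modal"`).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory artifacts of the executed
#'   stages.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  stages <- config$stages %||% c("simulate", "derive", "fit", "survival")
  known <- c("simulate", "derive", "fit", "survival", "power")
  if (length(setdiff(stages, known)) > 0)
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "),
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cfg <- do.call(trial_config, modifyList(list(n_users = 566), config$trial %||% list()))
  params <- do.call(generative_params, config$params %||% list())
  gap_s <- config$gap_s %||% 1800
  horizon <- config$horizon_days %||% 23
  run_days <- config$run_days %||% 7
  impute <- config$impute %||% "modal"

  manifest <- list(stages = stages, trial = unclass(cfg),
                   params = unclass(params), gap_s = gap_s,
                   horizon_days = horizon, run_days = run_days,
                   impute = impute, power = config$power)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res <- list()
  report <- character()

  if ("simulate" %in% stages) {
    sim <- simulate_trial(cfg, params)
    write_trial_csvs(sim, out_dir, cfg, params)
    res$sim <- sim
  }

  if ("derive" %in% stages) {
    if (is.null(res$sim)) {
      need <- file.path(out_dir, c("events.csv", "baseline.csv", "randomization.csv"))
      if (!all(file.exists(need)))
        stop("stage 'derive' needs the simulate stage outputs (events.csv, ",
             "baseline.csv, randomization.csv) in ", out_dir, call. = FALSE)
      res$sim <- list(
        events = read_events(need[1]),
        baseline = readr::read_csv(need[2], show_col_types = FALSE),
        randomization = readr::read_csv(need[3], show_col_types = FALSE))
    }
    events <- res$sim$events
    if (cfg$emit_utc) events <- to_local(events, cfg$utc_offset_min)
    baseline <- impute_modal(res$sim$baseline, impute)
    sessions <- sessionize(events, gap_s = gap_s)
    records <- derive_decision_points(events, res$sim$randomization, baseline, cfg)
    diseng <- derive_disengagement(events, users = baseline,
                                   horizon_days = horizon, run_days = run_days,
                                   followup_days = cfg$n_days,
                                   origin = study_origin(cfg$start_date))
    usage <- usage_summary(sessions, baseline, followup_days = cfg$n_days,
                           origin = study_origin(cfg$start_date))
    readr::write_csv(records, file.path(out_dir, "decision_points.csv"))
    readr::write_csv(diseng, file.path(out_dir, "disengagement.csv"))
    readr::write_csv(usage, file.path(out_dir, "usage_summary.csv"))
    res$records <- records; res$diseng <- diseng; res$usage <- usage
    report <- c(report, "== Usage by arm (sessions per user; length, s) ==",
                format_table(usage))
  }

  if ("fit" %in% stages) {
    if (is.null(res$records)) {
      f <- file.path(out_dir, "decision_points.csv")
      if (!file.exists(f))
        stop("stage 'fit' needs decision_points.csv from the derive stage",
             call. = FALSE)
      res$records <- readr::read_csv(f, show_col_types = FALSE)
    }
    effects <- fit_effect_tables(res$records)
    readr::write_csv(effects, file.path(out_dir, "effects.csv"))
    res$effects <- effects
    report <- c(report, "", "== Excursion effects (relative-risk scale) ==",
                format_table(effects))
  }

  if ("survival" %in% stages) {
    if (is.null(res$diseng)) {
      f <- file.path(out_dir, "disengagement.csv")
      if (!file.exists(f))
        stop("stage 'survival' needs disengagement.csv from the derive stage",
             call. = FALSE)
      res$diseng <- readr::read_csv(f, show_col_types = FALSE)
    }
    surv <- write_survival_outputs(res$diseng, out_dir)
    res$survival <- surv
    med <- vapply(surv$curves, attr, 0, "median")
    report <- c(report, "", "== Time to disengagement ==",
                paste0("median [days]: ",
                       paste(names(med), med, sep = "=", collapse = ", ")),
                sprintf("log-rank chi2 = %.3f, df = %d, p = %.3f",
                        surv$logrank$chi2, surv$logrank$df, surv$logrank$p))
  }

  if ("power" %in% stages) {
    sc <- do.call(power_scenario, config$power %||% list())
    pw <- simulate_rejection_rate(sc, seed = cfg$seed)
    out <- tibble::tibble(test = sc$test, effect_day1 = sc$effect_day1,
                          decay_per_day = sc$decay_per_day,
                          n_users = sc$n_users, reps = sc$reps,
                          rate = pw$rate, se = pw$se, divergent = pw$divergent)
    readr::write_csv(out, file.path(out_dir, "power.csv"))
    res$power <- pw
    report <- c(report, "", "== Simulated rejection rate ==", format_table(out))
  }

  writeLines(report, file.path(out_dir, "summary.txt"))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## All effect tables of the main analysis: marginal, time-moderated,
## state-moderated and 24-hour models for each treatment contrast.
fit_effect_tables <- function(records) {
  specs <- list()
  for (ctr in c("pooled", "standard_vs_none", "new_vs_none")) {
    specs[[paste0("marginal_", ctr)]] <- emee_spec(ctr, "none")
    specs[[paste0("time_", ctr)]] <- emee_spec(ctr, "day")
    specs[[paste0("habituation_", ctr)]] <- emee_spec(ctr, "habituation")
    specs[[paste0("engaged_", ctr)]] <- emee_spec(ctr, "already_engaged")
    specs[[paste0("h24_", ctr)]] <- emee_spec(ctr, "none", outcome = "Y_24h")
  }
  rows <- lapply(names(specs), function(nm) {
    tab <- tryCatch(
      report_effects(fit_emee(build_contrast(records, specs[[nm]]))),
      error = function(e) {
        warning("model '", nm, "' skipped: ", conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(tab)) return(NULL)
    tab$model <- nm
    tab[, c("model", "quantity", "estimate", "ci_low", "ci_high")]
  })
  dplyr::bind_rows(rows)
}

format_table <- function(df) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 4))
  utils::capture.output(print(as.data.frame(df), row.names = FALSE))
}
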