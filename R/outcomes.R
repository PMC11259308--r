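#' Run one microsimulation of a cohort under both strategies
#'
#' The full per-person pipeline: stratify, assign management (one shared
#' uniform per person), simulate paired event trajectories with common
#' random numbers, and accumulate discounted QALYs and costs per arm.
#'
#' @param cohort cohort data.frame.
#' @param config a [run_config()].
#' @param seed root seed; management, event, and cost draws come from
#'   named substreams of it.
#' @return List with `person` (per-person data.frame holding attributes,
#'   classes, management, both arms' trajectories, `score_qalys`,
#'   `score_cost`, `sscore_qalys`, `sscore_cost`) and `n`.
#' @export
run_microsim <- function(cohort, config = run_config(), seed = 1L) {
  stopifnot(inherits(config, "run_config"))
  n <- nrow(cohort)
  strat <- stratify_cohort(cohort, config$thresholds)
  p_score <- unname(config$policy$score[as.character(strat$score_class)])
  p_sscore <- unname(config$policy$sscore[as.character(strat$sscore_class)])
  u <- substream_runif(seed, "management", n)
  u2 <- if (identical(config$experiment$coupling, "independent")) {
    substream_runif(seed, "management2", n)
  } else NULL
  mgmt <- assign_management(p_score, p_sscore, u,
                            coupling = config$experiment$coupling %||%
                              "comonotonic", u2 = u2)
  horizon <- config$experiment$horizon
  params <- config$events
  if (!identical(params$horizon_years, horizon)) {
    params$horizon_years <- horizon
  }
  traj <- simulate_trajectories(strat, mgmt, params, seed = seed)
  mult <- cost_multipliers(n, config$costs$cost_cv, seed)

  arm <- function(prefix) {
    out <- traj[paste0(prefix, "_", c("first_event", "t_event", "fatal",
                                      "t_death", "cvd_death"))]
    names(out) <- c("first_event", "t_event", "fatal", "t_death", "cvd_death")
    out
  }
  person <- cbind(strat, traj)
  person$score_qalys <- qalys_for_trajectory(
    arm("score"), mgmt$treated_score, config$utilities, config$discount,
    horizon)
  person$sscore_qalys <- qalys_for_trajectory(
    arm("sscore"), mgmt$treated_sscore, config$utilities, config$discount,
    horizon)
  person$score_cost <- costs_for_trajectory(
    arm("score"), mgmt$treated_score, "SCORE", config$costs,
    config$discount, horizon, mult)
  person$sscore_cost <- costs_for_trajectory(
    arm("sscore"), mgmt$treated_sscore, "S_SCORE", config$costs,
    config$discount, horizon, mult)
  list(person = person, n = n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate per-person results into strategy-level outcomes
#'
#' @param person per-person data.frame from [run_microsim()].
#' @param strategy `"SCORE"` or `"S_SCORE"`.
#' @param horizon horizon in years.
#' @param retirement_age retirement age for potential years of working
#'   life lost (default 65).
#' @return One-row data.frame: `n`, cumulative incidences (`cum_cvd`,
#'   `cum_chd`, `cum_stroke`, `cum_all_cause_death`, `cum_cvd_death`,
#'   fractions of first events within the horizon), `treated_fraction`,
#'   `efs_per_1000` (event-free survival years per 1,000 screened),
#'   `pywll_per_1000` (working-life years lost to CVD-related premature
#'   death per 1,000), `mean_cost`, `mean_qalys`, `qalys_per_1000`.
#' @export
aggregate_outcomes <- function(person, strategy = c("SCORE", "S_SCORE"),
                               horizon = 10, retirement_age = 65) {
  strategy <- match.arg(strategy)
  if (nrow(person) == 0L) {
    stop("aggregate_outcomes: empty person set", call. = FALSE)
  }
  p <- if (strategy == "SCORE") "score_" else "sscore_"
  col <- function(x) person[[paste0(p, x)]]
  first <- col("first_event")
  t_death <- col("t_death")
  died <- !is.na(t_death) & t_death <= horizon
  cvd_death <- col("cvd_death")
  treated <- if (strategy == "SCORE") person$treated_score else
    person$treated_sscore
  efs <- mean(pmin(col("t_event"), horizon))
  age_death <- person$age_years + t_death
  pywll <- sum(pmax(retirement_age - age_death[cvd_death], 0)) / nrow(person)
  data.frame(
    strategy = strategy, n = nrow(person),
    cum_cvd = mean(first %in% c("chd", "stroke")),
    cum_chd = mean(first == "chd"),
    cum_stroke = mean(first == "stroke"),
    cum_all_cause_death = mean(died),
    cum_cvd_death = mean(cvd_death),
    treated_fraction = mean(treated),
    efs_per_1000 = efs * 1000,
    pywll_per_1000 = pywll * 1000,
    mean_cost = mean(col("cost")),
    mean_qalys = mean(col("qalys")),
    qalys_per_1000 = mean(col("qalys")) * 1000,
    stringsAsFactors = FALSE)
}

#' Compare strategy outcomes
#'
#' Computes the incremental cost-effectiveness measures of the
#' stratified strategy against the standard one: absolute and relative
#' risk reduction in CVD events, number needed to screen (1/ARR), the
#' ICER (incremental cost per QALY gained), and the incremental net
#' monetary benefit `INMB = WTP * dQALY - dCost`.
#'
#' @param score,sscore one-row data.frames from [aggregate_outcomes()].
#' @param wtp willingness-to-pay threshold in Euro per QALY (default
#'   50000).
#' @return One-row data.frame with `delta_cost`, `delta_qalys`,
#'   `delta_qalys_per_1000`, `icer` (NA when dominance applies or
#'   `dQALY = 0`), `dominance` ("none", "dominant" -- more QALYs at
#'   lower cost -- or "dominated"), `inmb`, `arr`, `rrr`, `nns` (NA when
#'   `ARR <= 0`), `delta_efs_per_1000`, `delta_pywll_per_1000`, `wtp`.
#' @export
compare_strategies <- function(score, sscore, wtp = 50000) {
  stopifnot(score$n == sscore$n)
  dc <- sscore$mean_cost - score$mean_cost
  dq <- sscore$mean_qalys - score$mean_qalys
  dominance <- if (dq > 0 && dc < 0) "dominant" else
    if (dq < 0 && dc > 0) "dominated" else "none"
  icer <- if (dominance != "none" || dq == 0) NA_real_ else dc / dq
  arr <- score$cum_cvd - sscore$cum_cvd
  data.frame(
    delta_cost = dc, delta_qalys = dq, delta_qalys_per_1000 = dq * 1000,
    icer = icer, dominance = dominance,
    inmb = wtp * dq - dc,
    arr = arr,
    rrr = if (score$cum_cvd > 0) arr / score$cum_cvd else NA_real_,
    nns = if (arr > 0) 1 / arr else NA_real_,
    delta_efs_per_1000 = sscore$efs_per_1000 - score$efs_per_1000,
    delta_pywll_per_1000 = sscore$pywll_per_1000 - score$pywll_per_1000,
    changed_management = NA_real_,
    wtp = wtp, stringsAsFactors = FALSE)
}

run_once <- function(cohort, config, seed) {
  sim <- run_microsim(cohort, config, seed)
  horizon <- config$experiment$horizon
  out_s <- aggregate_outcomes(sim$person, "SCORE", horizon)
  out_a <- aggregate_outcomes(sim$person, "S_SCORE", horizon)
  cmp <- compare_strategies(out_s, out_a, config$experiment$wtp)
  cmp$changed_management <- mean(sim$person$changed)
  list(score = out_s, sscore = out_a, comparison = cmp, sim = sim)
}

#' Base-case experiment: repeated bootstrapped microsimulation runs
#'
#' Mirrors the base-case sampling design: a source cohort is generated
#' once from the cohort configuration; each of `n_runs` independent runs
#' bootstraps `n_per_run` individuals from it with replacement, simulates
#' both strategies with shared draws, and aggregates. Point estimates are
#' means across runs; uncertainty intervals are the 2.5th and 97.5th
#' percentiles of the run distribution.
#'
#' @param config a [run_config()].
#' @param n_runs number of independent runs (default 100).
#' @param n_per_run individuals per run (default 20000).
#' @param seed root seed; everything is reproducible given it.
#' @param cohort optional pre-built source cohort (generated from
#'   `config$cohort` when `NULL`).
#' @return Object of class `basecase_result`: `runs` (per-run strategy
#'   outcomes and comparison measures), `summary` (mean and percentile
#'   CI per measure), `comparison` (mean comparison row).
#' @export
run_base_case <- function(config = run_config(), n_runs = 100,
                          n_per_run = 20000, seed = 1L, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (n_runs < 1) stop("n_runs must be at least 1", call. = FALSE)
  if (n_runs < 2) {
    warning("n_runs < 2: confidence intervals unavailable", call. = FALSE)
  }
  if (is.null(cohort)) {
    cohort <- generate_cohort(config$cohort,
                              seed = substream_seed(seed, "basecohort"))
  }
  rows <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- substream_seed(seed, paste0("run", r))
    idx <- substream_eval(run_seed, "bootstrap", function() {
      sample.int(nrow(cohort), n_per_run, replace = TRUE)
    })
    res <- run_once(cohort[idx, , drop = FALSE], config, run_seed)
    wide_s <- res$score[-1]
    names(wide_s) <- paste0("score_", names(wide_s))
    wide_a <- res$sscore[-1]
    names(wide_a) <- paste0("sscore_", names(wide_a))
    rows[[r]] <- cbind(run = r, wide_s, wide_a, res$comparison)
  }
  runs <- do.call(rbind, rows)
  num <- vapply(runs, is.numeric, logical(1)) & names(runs) != "run"
  summary <- data.frame(
    measure = names(runs)[num],
    mean = vapply(runs[num], mean, numeric(1)),
    ci_lo = vapply(runs[num], function(x)
      unname(stats::quantile(x, 0.025, na.rm = TRUE)), numeric(1)),
    ci_hi = vapply(runs[num], function(x)
      unname(stats::quantile(x, 0.975, na.rm = TRUE)), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  comparison <- runs[, names(res$comparison), drop = FALSE]
  structure(list(runs = runs, summary = summary,
                 comparison = comparison,
                 n_runs = n_runs, n_per_run = n_per_run, seed = seed,
                 wtp = config$experiment$wtp),
            class = "basecase_result")
}

#' @export
print.basecase_result <- function(x, ...) {
  cat(sprintf("Base-case microsimulation: %d runs x %d individuals\n",
              x$n_runs, x$n_per_run))
  keep <- c("score_cum_cvd", "sscore_cum_cvd", "score_treated_fraction",
            "sscore_treated_fraction", "changed_management",
            "delta_cost", "delta_qalys_per_1000", "icer", "inmb", "nns",
            "rrr", "delta_efs_per_1000", "delta_pywll_per_1000")
  s <- x$summary[x$summary$measure %in% keep, ]
  s$mean <- signif(s$mean, 4)
  s$ci_lo <- signif(s$ci_lo, 4)
  s$ci_hi <- signif(s$ci_hi, 4)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Subgroup comparison from a single large microsimulation
#'
#' Filters the per-person results of one microsimulation by age range
#' and/or SCORE class membership and recomputes strategy outcomes and
#' comparison measures on each subgroup. Empty subgroups are flagged and
#' skipped.
#'
#' @param person per-person data.frame from [run_microsim()].
#' @param subgroups named list of filters, each a list with optional
#'   `age_range = c(lo, hi)` and `score_classes` (character subset of
#'   Low/Mod/High/VeryHigh).
#' @param horizon,wtp analysis settings.
#' @return data.frame, one row per non-empty subgroup, with subgroup
#'   name, size and all comparison measures.
#' @export
subgroup_report <- function(person, subgroups, horizon = 10, wtp = 50000) {
  rows <- list()
  for (nm in names(subgroups)) {
    f <- subgroups[[nm]]
    keep <- rep(TRUE, nrow(person))
    if (!is.null(f$age_range)) {
      keep <- keep & person$age_years >= f$age_range[1] &
        person$age_years <= f$age_range[2]
    }
    if (!is.null(f$score_classes)) {
      keep <- keep & person$score_class %in% f$score_classes
    }
    if (!any(keep)) {
      warning("subgroup '", nm, "' is empty; skipped", call. = FALSE)
      next
    }
    sub <- person[keep, , drop = FALSE]
    cmp <- compare_strategies(aggregate_outcomes(sub, "SCORE", horizon),
                              aggregate_outcomes(sub, "S_SCORE", horizon),
                              wtp)
    cmp$changed_management <- mean(sub$changed)
    rows[[nm]] <- cbind(subgroup = nm, n = nrow(sub), cmp)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
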