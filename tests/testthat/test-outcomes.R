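event_free_person <- function(n, horizon = 10) {
  if (n == 0L) {
    return(event_free_person(1, horizon)[0, , drop = FALSE])
  }
  data.frame(
    age_years = rep(50, n),
    treated_score = FALSE, treated_sscore = FALSE, changed = FALSE,
    score_first_event = factor("none", levels = c("none", "chd", "stroke",
                                                  "death_other")),
    score_t_event = horizon, score_fatal = NA, score_t_death = NA_real_,
    score_cvd_death = FALSE, score_cost = 44, score_qalys = 9.6,
    sscore_first_event = factor("none", levels = c("none", "chd", "stroke",
                                                   "death_other")),
    sscore_t_event = horizon, sscore_fatal = NA, sscore_t_death = NA_real_,
    sscore_cvd_death = FALSE, sscore_cost = 69, sscore_qalys = 9.6)
}

test_that("aggregation computes incidences, EFS and working-life years lost", {
  p <- event_free_person(1000)
  # one CVD death at age 60 (event at 5, baseline age 55)
  p$age_years[1] <- 55
  p$score_first_event[1] <- "chd"
  p$score_t_event[1] <- 5
  p$score_fatal[1] <- TRUE
  p$score_t_death[1] <- 5
  p$score_cvd_death[1] <- TRUE
  out <- aggregate_outcomes(p, "SCORE", horizon = 10)
  expect_equal(out$pywll_per_1000, 5)  # 65 - 60 years, 1 per 1000
  expect_equal(out$cum_cvd, 0.001)
  expect_equal(out$cum_chd, 0.001)
  expect_equal(out$cum_cvd_death, 0.001)
  expect_equal(out$efs_per_1000, (999 * 10 + 5) / 1000 * 1000)

  # all event-free
  out0 <- aggregate_outcomes(event_free_person(100), "SCORE", 10)
  expect_equal(out0$efs_per_1000, 10000)
  expect_equal(out0$pywll_per_1000, 0)
  expect_equal(out0$cum_all_cause_death, 0)

  # a non-CVD death at age 60 contributes to mortality but not PYWLL
  q <- event_free_person(1000)
  q$age_years[1] <- 55
  q$score_first_event[1] <- "death_other"
  q$score_t_event[1] <- 5
  q$score_fatal[1] <- TRUE
  q$score_t_death[1] <- 5
  outq <- aggregate_outcomes(q, "SCORE", 10)
  expect_equal(outq$pywll_per_1000, 0)
  expect_equal(outq$cum_all_cause_death, 0.001)
  expect_equal(outq$cum_cvd, 0)
  expect_error(aggregate_outcomes(event_free_person(0), "SCORE", 10), "empty")
})

test_that("comparison measures follow their defining identities", {
  base <- aggregate_outcomes(event_free_person(100), "SCORE", 10)
  alt <- base
  alt$strategy <- "S_SCORE"

  a <- base; b <- alt
  a$cum_cvd <- 0.0538; b$cum_cvd <- 0.0484
  a$mean_cost <- 1349; b$mean_cost <- 1349 + 187
  a$mean_qalys <- 8.214; b$mean_qalys <- 8.214 + 0.007
  cmp <- compare_strategies(a, b, wtp = 50000)
  expect_equal(cmp$arr, 0.0054)
  expect_equal(cmp$nns, 1 / 0.0054)
  expect_equal(cmp$nns * cmp$arr, 1)
  expect_equal(cmp$rrr, 0.0054 / 0.0538)
  expect_equal(cmp$icer, 187 / 0.007)
  expect_equal(cmp$inmb, 50000 * 0.007 - 187)  # = 163 EUR
  expect_equal(cmp$dominance, "none")
  # INMB > 0 iff ICER < WTP when dQALY > 0
  expect_identical(cmp$inmb > 0, cmp$icer < 50000)

  d <- b; d$mean_cost <- 1300
  dom <- compare_strategies(a, d, wtp = 50000)
  expect_equal(dom$dominance, "dominant")
  expect_true(is.na(dom$icer))
  expect_true(dom$inmb > 0)

  e <- b; e$mean_qalys <- 8.2
  ded <- compare_strategies(a, e, wtp = 50000)
  expect_equal(ded$dominance, "dominated")
  expect_true(ded$inmb < 0)

  f <- b; f$cum_cvd <- 0.06
  cmpf <- compare_strategies(a, f, wtp = 50000)
  expect_true(is.na(cmpf$nns))  # ARR <= 0 flags NNS undefined
})

test_that("simple ICER arithmetic", {
  a <- aggregate_outcomes(event_free_person(10), "SCORE", 10)
  b <- a
  b$mean_cost <- a$mean_cost + 100
  b$mean_qalys <- a$mean_qalys + 0.01
  expect_equal(compare_strategies(a, b)$icer, 10000)
})

test_that("the base-case design is reproducible and null under a null configuration", {
  cfg <- small_config(n = 3000L,
                      events = event_model_params(rr_treatment = 1))
  # identical policies: stratified probabilities equal the standard ones
  cfg$policy <- policy_table(
    score = c(Low = 0, Mod = 0, High = 0.5, VeryHigh = 1),
    sscore = c("Low-" = 0, "Low+" = 0, "Low++" = 0,
               "Mod-" = 0, "Mod+" = 0, "Mod++" = 0,
               "High-" = 0.5, "High+" = 0.5, "High++" = 0.5,
               "VeryHigh-" = 1, "VeryHigh+" = 1))
  bc <- run_base_case(cfg, n_runs = 4, n_per_run = 500, seed = 5)
  expect_equal(bc$runs$delta_cost, rep(25, 4))  # troponin assay cost only
  expect_true(all(bc$runs$delta_qalys == 0))
  expect_true(all(bc$runs$arr == 0))
  expect_true(all(bc$runs$changed_management == 0))

  cfg2 <- small_config(n = 3000L)
  b1 <- run_base_case(cfg2, n_runs = 3, n_per_run = 400, seed = 9)
  b2 <- run_base_case(cfg2, n_runs = 3, n_per_run = 400, seed = 9)
  expect_identical(b1$runs, b2$runs)
  b3 <- run_base_case(cfg2, n_runs = 3, n_per_run = 400, seed = 10)
  expect_false(isTRUE(all.equal(b1$runs$delta_cost, b3$runs$delta_cost)))
  expect_warning(run_base_case(cfg2, n_runs = 1, n_per_run = 200, seed = 1),
                 "confidence intervals")
})

test_that("base-case summary intervals bracket the run means", {
  cfg <- small_config(n = 5000L)
  bc <- run_base_case(cfg, n_runs = 6, n_per_run = 1000, seed = 2)
  s <- bc$summary
  for (m in c("delta_cost", "delta_qalys", "score_cum_cvd")) {
    row <- s[s$measure == m, ]
    expect_true(row$ci_lo <= row$mean && row$mean <= row$ci_hi)
  }
})

test_that("subgroup filters partition the cohort and report per-subgroup measures", {
  cfg <- small_config(n = 8000L)
  co <- generate_cohort(cfg$cohort, seed = 17)
  sim <- run_microsim(co, cfg, seed = 17)
  p <- sim$person

  all_in <- subgroup_report(p, list(all = list(age_range = c(20, 85))))
  whole <- compare_strategies(aggregate_outcomes(p, "SCORE", 10),
                              aggregate_outcomes(p, "S_SCORE", 10), 50000)
  expect_equal(all_in$delta_cost, whole$delta_cost)
  expect_equal(all_in$n, nrow(p))

  parts <- subgroup_report(p, list(
    young = list(age_range = c(20, 49.9999)),
    old = list(age_range = c(50, 85))))
  expect_equal(sum(parts$n), nrow(p) - sum(p$age_years > 49.9999 &
                                             p$age_years < 50))
  # the High class carries the largest policy difference
  hi <- subgroup_report(p, list(h = list(score_classes = c("High"))))
  expect_gt(hi$changed_management, mean(p$changed))
  expect_warning(
    none <- subgroup_report(p, list(x = list(age_range = c(0, 1)))),
    "empty")
  expect_null(none)
})

test_that("later events never decrease event-free survival or QALYs", {
  # coupled trajectories: pushing the same person's event later
  u <- utility_params()
  r3 <- discount_spec(0.03)
  set.seed(83)
  for (i in 1:20) {
    t1 <- runif(1, 0.1, 9)
    t2 <- runif(1, t1, 10)
    tr1 <- make_traj("chd", t1, FALSE, NA_real_)
    tr2 <- make_traj("chd", t2, FALSE, NA_real_)
    expect_gte(qalys_for_trajectory(tr2, FALSE, u, r3, 10),
               qalys_for_trajectory(tr1, FALSE, u, r3, 10))
    expect_gte(min(t2, 10), min(t1, 10))
  }
})
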