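no_change <- function(n) {
  data.frame(treated_score = rep(FALSE, n), treated_sscore = rep(FALSE, n),
             changed = rep(FALSE, n))
}

one_male <- function(age = 52) {
  data.frame(id = 1L, sex = factor("male", levels = c("female", "male")),
             age_years = age, score_risk = 0.002, hstni = 1.0)
}

# uniform that makes the default-parameter latent time equal t exactly
u_for <- function(params, event, sex, t) {
  weibull_cdf(weibull_params(params$shape[[event]][[sex]],
                             params$lambda[[event]][[sex]]), t)
}

draws_for_times <- function(params, sex, chd, stroke, death,
                            u_fatal = 0.999, u_post = 0.5) {
  data.frame(u_chd = u_for(params, "chd", sex, chd),
             u_stroke = u_for(params, "stroke", sex, stroke),
             u_death = u_for(params, "death_other", sex, death),
             u_fatal_chd = u_fatal, u_fatal_stroke = u_fatal,
             u_post_chd = u_post, u_post_stroke = u_post)
}

test_that("latent times resolve to the earliest event; censoring at the horizon", {
  params <- event_model_params()
  d <- draws_for_times(params, "male", chd = 3.2, stroke = 7.1, death = 9.0)
  tr <- simulate_trajectories(one_male(), no_change(1), params, draws = d)
  expect_equal(as.character(tr$score_first_event), "chd")
  expect_equal(tr$score_t_event, 3.2, tolerance = 1e-9)
  # unchanged management: both arms identical
  expect_equal(tr$sscore_t_event, tr$score_t_event)
  expect_equal(as.character(tr$sscore_first_event), "chd")

  far <- draws_for_times(params, "male", chd = 11, stroke = 12, death = 13)
  tr2 <- simulate_trajectories(one_male(), no_change(1), params, draws = far)
  expect_equal(as.character(tr2$score_first_event), "none")
  expect_equal(tr2$score_t_event, 10)
  expect_true(is.na(tr2$score_t_death))
  expect_false(tr2$score_cvd_death)
})

test_that("newly treated individuals get latent CHD times stretched by 1/rr", {
  params <- event_model_params()  # rr = 0.65, shape 1
  mgmt <- data.frame(treated_score = FALSE, treated_sscore = TRUE,
                     changed = TRUE)
  d <- draws_for_times(params, "male", chd = 3.2, stroke = 20, death = 20)
  tr <- simulate_trajectories(one_male(), mgmt, params, draws = d)
  expect_equal(tr$score_t_event, 3.2, tolerance = 1e-9)
  expect_equal(tr$sscore_t_event, 3.2 / 0.65, tolerance = 1e-9)
  # withdrawn: risk increases, times shrink by rr
  mgmt_w <- data.frame(treated_score = TRUE, treated_sscore = FALSE,
                       changed = TRUE)
  trw <- simulate_trajectories(one_male(), mgmt_w, params, draws = d)
  expect_equal(trw$sscore_t_event, 3.2 * 0.65, tolerance = 1e-9)
})

test_that("with rr = 1 the two arms are identical realization by realization", {
  params <- event_model_params(rr_treatment = 1)
  cfg <- cohort_config(n = 3000)
  co <- generate_cohort(cfg, seed = 2)
  strat <- stratify_cohort(co)
  pol <- default_policy()
  u <- runif(nrow(co))
  mgmt <- assign_management(unname(pol$score[as.character(strat$score_class)]),
                            unname(pol$sscore[as.character(strat$sscore_class)]),
                            u)
  tr <- simulate_trajectories(co, mgmt, params, seed = 19)
  expect_identical(tr$score_t_event, tr$sscore_t_event)
  expect_identical(tr$score_first_event, tr$sscore_first_event)
  expect_identical(tr$score_t_death, tr$sscore_t_death)
})

test_that("first-event fractions match competing-exponential closed forms", {
  params <- event_model_params()
  n <- 100000
  for (s in c("female", "male")) {
    co <- data.frame(id = seq_len(n),
                     sex = factor(rep(s, n), levels = c("female", "male")),
                     age_years = 50, score_risk = 0.002, hstni = 1)
    tr <- simulate_trajectories(co, no_change(n), params, seed = 23)
    lam <- vapply(c("chd", "stroke", "death_other"),
                  function(ev) params$lambda[[ev]][[s]], numeric(1))
    tot <- sum(lam)
    p_first <- lam / tot * (1 - exp(-tot * 10))
    for (ev in names(p_first)) {
      obs <- mean(tr$score_first_event == ev)
      expect_equal(obs, unname(p_first[ev]),
                   tolerance = 5 * sqrt(p_first[[ev]] / n) / p_first[[ev]])
    }
  }
})

test_that("fatality resolution matches the configured fatal fractions", {
  params <- event_model_params()
  n <- 150000
  co <- data.frame(id = seq_len(n),
                   sex = factor(rep("female", n), levels = c("female", "male")),
                   age_years = 50, score_risk = 0.002, hstni = 1)
  tr <- simulate_trajectories(co, no_change(n), params, seed = 29)
  chd <- tr$score_first_event == "chd"
  frac <- mean(tr$score_fatal[chd])
  p <- params$fatality$chd[["female"]]
  expect_equal(frac, p, tolerance = 4 * sqrt(p * (1 - p) / sum(chd)) / p)
})

test_that("post-event survival uses the age band at the event", {
  params <- event_model_params()
  # male aged 80: CHD at t = 2 puts him in the 75+ band
  lam75 <- params$post_lambda$chd["75+", "male"]
  d <- draws_for_times(params, "male", chd = 2, stroke = 20, death = 20,
                       u_fatal = 0.999,  # non-fatal (fraction 0.28)
                       u_post = 1 - exp(-lam75 * 2.5))
  tr <- simulate_trajectories(one_male(age = 80), no_change(1), params,
                              draws = d)
  expect_false(tr$score_fatal)
  expect_equal(tr$score_t_death, 4.5, tolerance = 1e-9)
  expect_true(tr$score_cvd_death)
  # same draw for a 40-year-old resolves under the <55 band instead; the
  # much lower mortality pushes the death time past the horizon
  lam55 <- params$post_lambda$chd["<55", "male"]
  td55 <- 2 - log1p(-d$u_post_chd) / lam55
  tr2 <- simulate_trajectories(one_male(age = 40), no_change(1), params,
                               draws = d)
  if (td55 <= 10) {
    expect_equal(tr2$score_t_death, td55, tolerance = 1e-9)
  } else {
    expect_true(is.na(tr2$score_t_death))
    expect_false(tr2$score_cvd_death)
  }
})

test_that("lowering rr never increases an individual's events under expansion-only change", {
  cfg <- cohort_config(n = 4000)
  co <- generate_cohort(cfg, seed = 3)
  strat <- stratify_cohort(co)
  pol <- expansion_policy()
  u <- substream_runif(101, "management", nrow(co))
  mgmt <- assign_management(unname(pol$score[as.character(strat$score_class)]),
                            unname(pol$sscore[as.character(strat$sscore_class)]),
                            u)
  expect_true(all(mgmt$treated_sscore | !mgmt$treated_score))  # no withdrawals
  d <- event_draws(nrow(co), 103)
  prev <- NULL
  for (rr in c(1, 0.8, 0.65, 0.5)) {
    params <- event_model_params(rr_treatment = rr)
    tr <- simulate_trajectories(co, mgmt, params, draws = d)
    ev <- tr$sscore_first_event %in% c("chd", "stroke")
    if (!is.null(prev)) expect_true(all(ev <= prev))
    prev <- ev
  }
})

test_that("Kaplan-Meier cumulative incidence matches hand-computed products", {
  # events at 2 and 8, censoring at 5: S(10) = (2/3) * 0 = 0
  expect_equal(km_cumulative_incidence(c(2, 5, 8), c(TRUE, FALSE, TRUE), 10), 1)
  expect_equal(km_cumulative_incidence(rep(10, 5), rep(FALSE, 5), 10), 0)
  expect_equal(km_cumulative_incidence(1, TRUE, 5), 1)
  expect_error(km_cumulative_incidence(numeric(0), logical(0), 5), "empty")
  # agrees with the configured probability on simulated exponential times
  w <- calibrate_scale(0.066, 10, 1)
  set.seed(7)
  t_all <- weibull_quantile(w, runif(40000))
  obs <- pmin(t_all, 10)
  ev <- t_all <= 10
  expect_equal(km_cumulative_incidence(obs, ev, 10), 0.066, tolerance = 0.05)
})

test_that("event draws are reproducible and substream-isolated", {
  a <- event_draws(10, 5)
  b <- event_draws(10, 5)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a, event_draws(10, 6))))
  # management substream does not overlap the event substream
  expect_false(isTRUE(all.equal(a$u_chd, substream_runif(5, "management", 10))))
})
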