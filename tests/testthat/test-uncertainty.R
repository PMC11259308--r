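test_that("second-order families are moment-matched to base and range", {
  # fixed parameters never move
  fixed_spec <- data.frame(parameter = "u_asymptomatic", family = "fixed",
                           base = 0.96, lo = NA, hi = NA)
  draws <- vapply(1:50, function(s) sample_second_order(fixed_spec, s),
                  numeric(1))
  expect_true(all(draws == 0.96))

  # normal: mean matches the base, sd from the 95% range
  norm_spec <- data.frame(parameter = "cost_screening", family = "normal",
                          base = 44, lo = 39, hi = 48)
  d <- vapply(1:5000, function(s) sample_second_order(norm_spec, s),
              numeric(1))
  expect_equal(mean(d), 44, tolerance = 0.1 / 44)
  expect_equal(sd(d), (48 - 39) / 3.92, tolerance = 0.1)

  # beta: support [0, 1], mean equals base, central mass near the range
  beta_spec <- data.frame(parameter = "policy_score_High", family = "beta",
                          base = 0.5, lo = 0.3, hi = 0.75)
  b <- vapply(1:4000, function(s) sample_second_order(beta_spec, s),
              numeric(1))
  expect_true(all(b >= 0 & b <= 1))
  expect_equal(mean(b), 0.5, tolerance = 0.01 / 0.5)
  q <- unname(quantile(b, c(0.025, 0.975)))
  expect_gt(q[1], 0.2)
  expect_lt(q[1], 0.42)
  expect_gt(q[2], 0.62)
  expect_lt(q[2], 0.88)

  # uniform stays inside its bounds
  uni_spec <- data.frame(parameter = "lambda_mult_chd_male",
                         family = "uniform", base = 1, lo = 0.9, hi = 1.1)
  u <- vapply(1:500, function(s) sample_second_order(uni_spec, s), numeric(1))
  expect_true(all(u >= 0.9 & u <= 1.1))
  expect_error(sample_second_order(
    data.frame(parameter = "x", family = "cauchy", base = 1, lo = 0, hi = 2),
    1), "unknown second-order family")
})

test_that("the shipped specification is internally consistent", {
  spec <- second_order_spec()
  expect_true(all(spec$family %in% c("beta", "normal", "uniform", "gamma",
                                     "lognormal", "fixed")))
  ranged <- !is.na(spec$lo)
  expect_true(all(spec$lo[ranged] <= spec$base[ranged] &
                    spec$base[ranged] <= spec$hi[ranged]))
  expect_true(all(c("rr_treatment", "p_male", "cost_hstni",
                    "policy_sscore_Mod+", "discount_rate") %in% spec$parameter))
})

test_that("parameter draws are applied to the right configuration slots", {
  cfg <- run_config()
  mod <- apply_parameters(cfg, c(
    rr_treatment = 0.5, policy_score_High = 0.4, cost_screening = 50,
    u_post_stroke = 0.6, discount_rate = 0.05, p_male = 0.4,
    lambda_mult_chd_female = 1.1, fatality_stroke_male = 0.2,
    post_chd_75p_male = 0.7))
  expect_equal(mod$events$rr_treatment, 0.5)
  expect_equal(unname(mod$policy$score["High"]), 0.4)
  expect_equal(mod$costs$screening, 50)
  expect_equal(mod$utilities$post_stroke, 0.6)
  expect_equal(mod$discount$annual_rate, 0.05)
  expect_equal(mod$cohort$p_male, 0.4)
  # lambda multiplier acts on the calibrated scale: p' = 1 - (1-p)^m
  expect_equal(mod$events$p10$chd[["female"]], 1 - (1 - 0.024)^1.1)
  expect_equal(mod$events$lambda$chd[["female"]],
               1.1 * cfg$events$lambda$chd[["female"]], tolerance = 1e-12)
  expect_equal(mod$events$fatality$stroke[["male"]], 0.2)
  expect_equal(mod$events$post_event$p$chd["75+", "male"], 0.7)
  # recalibration keeps the round trip exact
  expect_equal(weibull_cdf(weibull_params(1, mod$events$post_lambda$chd["75+", "male"]), 5),
               0.7, tolerance = 1e-12)
  expect_error(apply_parameters(cfg, c(not_a_parameter = 1)), "unknown")
  # probabilities are clamped
  cl <- apply_parameters(cfg, c(policy_score_High = 1.7, fatality_chd_female = -0.2))
  expect_equal(unname(cl$policy$score["High"]), 1)
  expect_equal(cl$events$fatality$chd[["female"]], 0)
})

test_that("PSA is reproducible and yields finite incremental results", {
  cfg <- small_config(n = 500L)
  psa1 <- run_psa(cfg, n_iter = 4, n_per_iter = 500, seed = 3)
  psa2 <- run_psa(cfg, n_iter = 4, n_per_iter = 500, seed = 3)
  expect_identical(psa1$iterations, psa2$iterations)
  expect_identical(psa1$draws, psa2$draws)
  expect_true(all(is.finite(psa1$iterations$delta_cost)))
  expect_true(all(is.finite(psa1$iterations$delta_qalys)))
  expect_equal(nrow(psa1$iterations), 4L)
  expect_false(isTRUE(all.equal(psa1$iterations,
                                run_psa(cfg, n_iter = 4, n_per_iter = 500,
                                        seed = 4)$iterations)))
})

test_that("the acceptability curve is the INMB sign frequency over iterations", {
  fake <- structure(list(iterations = data.frame(
    delta_cost = c(100, 100, 100), delta_qalys = c(0.01, 0.01, 0.01)),
    wtp = 50000), class = "psa_result")
  cv <- ceac(fake, wtp_grid = c(0, 5000, 9999, 10001, 50000))
  expect_equal(cv$probability, c(0, 0, 0, 1, 1))  # step at 10,000 EUR/QALY

  dominant <- structure(list(iterations = data.frame(
    delta_cost = c(-5, -10), delta_qalys = c(0.01, 0.02))),
    class = "psa_result")
  expect_true(all(ceac(dominant)$probability == 1))

  mixed <- structure(list(iterations = data.frame(
    delta_cost = runif(50, 0, 400), delta_qalys = runif(50, 0, 0.01))),
    class = "psa_result")
  expect_true(all(diff(ceac(mixed)$probability) >= 0))
  expect_error(ceac(structure(list(iterations = NULL), class = "psa_result")),
               "empty")
})

test_that("univariate analysis orders parameters by influence and respects ranges", {
  cfg <- small_config(n = 1500L)
  params <- data.frame(
    parameter = c("rr_treatment", "cost_hstni", "cost_screening", "no_range"),
    family = c("beta", "normal", "normal", "fixed"),
    base = c(0.65, 25, 44, 1),
    lo = c(0.58, 10, 44, NA),
    hi = c(0.73, 50, 44, NA))
  expect_warning(
    sa <- univariate_sa(cfg, params, n_samples = 1500, seed = 6),
    "no range")
  expect_equal(nrow(sa), 3L)
  # stronger treatment effect (lower rr) favors the stratified strategy
  rr_row <- sa[sa$parameter == "rr_treatment", ]
  expect_gt(rr_row$inmb_at_lo, rr_row$inmb_at_hi)
  # cheaper troponin assay favors the stratified strategy by the cost delta
  tni_row <- sa[sa$parameter == "cost_hstni", ]
  expect_gt(tni_row$inmb_at_lo, tni_row$inmb_at_hi)
  expect_equal(tni_row$inmb_at_hi - tni_row$inmb_at_lo, -40,
               tolerance = 1e-6)
  # zero-width range: both bounds give the same result
  sc_row <- sa[sa$parameter == "cost_screening", ]
  expect_equal(sc_row$inmb_at_lo, sc_row$inmb_at_hi)
})

test_that("discounting reduces both accumulated costs and QALYs", {
  cfg0 <- small_config(n = 2000L, discount = discount_spec(0))
  cfg5 <- small_config(n = 2000L, discount = discount_spec(0.05))
  co <- generate_cohort(cfg0$cohort, seed = 8)
  s0 <- run_microsim(co, cfg0, seed = 8)
  s5 <- run_microsim(co, cfg5, seed = 8)
  expect_lt(mean(s5$person$score_cost), mean(s0$person$score_cost))
  expect_lt(mean(s5$person$score_qalys), mean(s0$person$score_qalys))
})
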