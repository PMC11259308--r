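#' Second-order (parameter-uncertainty) specification
#'
#' One row per model parameter: distribution family (`beta`, `normal`,
#' `uniform`, `gamma`, `lognormal`, `fixed`), base-case value, and
#' sensitivity range `(lo, hi)`. Ranges are interpreted as central 95%
#' intervals for moment matching: normal draws use
#' `sd = (hi - lo)/3.92`; beta and gamma are matched numerically so the
#' mean equals the base and the central 95% interval approximates the
#' range; `+-10%`/`+-25%` ranges expand multiplicatively around the
#' base. Parameters are sampled independently. The `lambda_mult_*`
#' parameters are uniform multipliers (0.9--1.1) on the calibrated
#' time-to-event Weibull scales. The discount rate is fixed in the PSA
#' but carries its 0--5% range for univariate analysis.
#'
#' @return data.frame with columns `parameter`, `family`, `base`, `lo`,
#'   `hi`.
#' @export
second_order_spec <- function() {
  row <- function(parameter, family, base, lo = NA_real_, hi = NA_real_) {
    data.frame(parameter = parameter, family = family, base = base,
               lo = lo, hi = hi, stringsAsFactors = FALSE)
  }
  pm10 <- function(x) c(0.9 * x, 1.1 * x)
  pm25 <- function(x) c(0.75 * x, 1.25 * x)
  rows <- list(
    row("p_male", "beta", 0.487, pm10(0.487)[1], pm10(0.487)[2]))
  for (ev in c("chd", "stroke", "death_other")) {
    for (s in c("female", "male")) {
      rows <- c(rows, list(row(paste("lambda_mult", ev, s, sep = "_"),
                               "uniform", 1, 0.9, 1.1)))
    }
  }
  fat <- list(chd = c(female = 0.327, male = 0.280),
              stroke = c(female = 0.108, male = 0.103))
  for (ev in c("chd", "stroke")) {
    for (s in c("female", "male")) {
      b <- fat[[ev]][[s]]
      rows <- c(rows, list(row(paste("fatality", ev, s, sep = "_"),
                               "normal", b, pm10(b)[1], pm10(b)[2])))
    }
  }
  post <- event_model_params()$post_event$p
  for (ev in c("chd", "stroke")) {
    for (band in c("lt55", "5574", "75p")) {
      for (s in c("female", "male")) {
        b <- post[[ev]][band_label(band), s]
        rows <- c(rows, list(row(paste("post", ev, band, s, sep = "_"),
                                 "normal", b, pm10(b)[1], pm10(b)[2])))
      }
    }
  }
  pol <- list(c("policy_score_High", 0.50, 0.30, 0.75),
              c("policy_sscore_Low+", 0.01, 0.01, 0.25),
              c("policy_sscore_Low++", 0.30, 0.01, 0.50),
              c("policy_sscore_Mod+", 0.75, 0.50, 0.99),
              c("policy_sscore_Mod++", 0.99, 0.50, 0.99),
              c("policy_sscore_High-", 0.30, 0.01, 0.50),
              c("policy_sscore_High+", 0.75, 0.50, 0.99),
              c("policy_sscore_High++", 0.99, 0.75, 0.99),
              c("policy_sscore_VeryHigh-", 0.99, 0.75, 0.99))
  for (p in pol) {
    rows <- c(rows, list(row(p[1], "beta", as.numeric(p[2]),
                             as.numeric(p[3]), as.numeric(p[4]))))
  }
  rows <- c(rows, list(
    row("rr_treatment", "beta", 0.65, 0.58, 0.73),
    row("u_asymptomatic", "fixed", 0.96),
    row("u_acute_chd", "beta", 0.15, 0.13, 0.17),
    row("u_acute_stroke", "beta", 0.19, 0.16, 0.22),
    row("u_post_chd", "beta", 0.82, 0.78, 0.86),
    row("u_post_stroke", "beta", 0.52, 0.44, 0.60),
    row("u_treatment_decrement", "beta", 0.01, 0.008, 0.012),
    row("cost_screening", "normal", 44, 39, 48),
    row("cost_hstni", "normal", 25, 10, 50),
    row("cost_prevention", "normal", 595, 536, 655),
    row("cost_chd_year1", "normal", 15805, 15278, 16332),
    row("cost_chd_year2", "normal", 2318, pm25(2318)[1], pm25(2318)[2]),
    row("cost_chd_later", "normal", 600, pm25(600)[1], pm25(600)[2]),
    row("cost_stroke_year1", "normal", 21724, 19210, 24239),
    row("cost_stroke_year2", "normal", 13528, pm25(13528)[1], pm25(13528)[2]),
    row("cost_stroke_later", "normal", 8571, pm25(8571)[1], pm25(8571)[2]),
    row("discount_rate", "fixed", 0.03, 0, 0.05)))
  out <- do.call(rbind, rows)
  bad <- !is.na(out$lo) & !(out$lo <= out$base & out$base <= out$hi)
  if (any(bad)) stop("invalid second-order spec rows: ",
                     paste(out$parameter[bad], collapse = ", "))
  out
}

band_label <- function(code) {
  c(lt55 = "<55", "5574" = "55-74", "75p" = "75+")[[code]]
}

# beta(mean = base) with concentration chosen so the central 95% interval
# best matches (lo, hi)
match_beta <- function(base, lo, hi) {
  m <- min(max(base, 1e-6), 1 - 1e-6)
  obj <- function(logk) {
    k <- exp(logk)
    (stats::qbeta(0.025, m * k, (1 - m) * k) - lo)^2 +
      (stats::qbeta(0.975, m * k, (1 - m) * k) - hi)^2
  }
  k <- exp(stats::optimize(obj, c(-3, 16))$minimum)
  c(shape1 = m * k, shape2 = (1 - m) * k)
}

# gamma(mean = base) matched the same way
match_gamma <- function(base, lo, hi) {
  obj <- function(loga) {
    a <- exp(loga)
    (stats::qgamma(0.025, a, rate = a / base) - lo)^2 +
      (stats::qgamma(0.975, a, rate = a / base) - hi)^2
  }
  a <- exp(stats::optimize(obj, c(-3, 16))$minimum)
  c(shape = a, rate = a / base)
}

#' Draw one second-order parameter set
#'
#' @param spec data.frame as from [second_order_spec()].
#' @param seed root seed (substream `"secondorder"`).
#' @return Named numeric vector, one value per parameter; `fixed`
#'   parameters return their base value.
#' @export
sample_second_order <- function(spec = second_order_spec(), seed = 1L) {
  substream_eval(seed, "secondorder", function() {
    vals <- numeric(nrow(spec))
    for (i in seq_len(nrow(spec))) {
      fam <- spec$family[i]
      b <- spec$base[i]
      lo <- spec$lo[i]
      hi <- spec$hi[i]
      vals[i] <- switch(
        fam,
        fixed = b,
        normal = stats::rnorm(1, b, (hi - lo) / 3.92),
        uniform = stats::runif(1, lo, hi),
        beta = {
          ab <- match_beta(b, lo, hi)
          stats::rbeta(1, ab[1], ab[2])
        },
        gamma = {
          ar <- match_gamma(b, lo, hi)
          stats::rgamma(1, ar[1], rate = ar[2])
        },
        lognormal = stats::rlnorm(1, log(b), (log(hi) - log(lo)) / 3.92),
        stop("unknown second-order family: ", fam, call. = FALSE))
    }
    names(vals) <- spec$parameter
    vals
  })
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Apply a named parameter draw to a run configuration
#'
#' Each parameter name addresses one model input; probabilities are
#' clamped to `[0, 1]` and costs truncated at zero. Event-model
#' parameters are re-validated and the Weibull scales recalibrated.
#'
#' @param config a [run_config()].
#' @param draws named numeric vector (subset of [second_order_spec()]
#'   parameter names).
#' @return Modified `run_config`.
#' @export
apply_parameters <- function(config, draws) {
  ev <- config$events
  p10 <- ev$p10
  fatality <- ev$fatality
  post <- ev$post_event
  rr <- ev$rr_treatment
  events_touched <- FALSE
  u <- config$utilities
  co <- config$costs

  for (nm in names(draws)) {
    v <- unname(draws[[nm]])
    if (nm == "p_male") {
      config$cohort$p_male <- clamp01(v)
    } else if (startsWith(nm, "lambda_mult_")) {
      parts <- strsplit(sub("^lambda_mult_", "", nm), "_(?=[^_]+$)",
                        perl = TRUE)[[1]]
      p10[[parts[1]]][parts[2]] <-
        clamp01(1 - (1 - p10[[parts[1]]][[parts[2]]])^v)
      events_touched <- TRUE
    } else if (startsWith(nm, "fatality_")) {
      parts <- strsplit(sub("^fatality_", "", nm), "_")[[1]]
      fatality[[parts[1]]][parts[2]] <- clamp01(v)
      events_touched <- TRUE
    } else if (startsWith(nm, "post_")) {
      parts <- strsplit(sub("^post_", "", nm), "_")[[1]]
      post$p[[parts[1]]][band_label(parts[2]), parts[3]] <-
        min(max(v, 1e-6), 1 - 1e-6)
      events_touched <- TRUE
    } else if (nm == "rr_treatment") {
      rr <- max(v, 1e-6)
      events_touched <- TRUE
    } else if (startsWith(nm, "policy_score_")) {
      config$policy$score[sub("^policy_score_", "", nm)] <- clamp01(v)
    } else if (startsWith(nm, "policy_sscore_")) {
      config$policy$sscore[sub("^policy_sscore_", "", nm)] <- clamp01(v)
    } else if (nm == "u_asymptomatic") {
      u$asymptomatic <- clamp01(v)
    } else if (nm == "u_acute_chd") {
      u$acute_decrement_chd <- clamp01(v)
    } else if (nm == "u_acute_stroke") {
      u$acute_decrement_stroke <- clamp01(v)
    } else if (nm == "u_post_chd") {
      u$post_chd <- clamp01(v)
    } else if (nm == "u_post_stroke") {
      u$post_stroke <- clamp01(v)
    } else if (nm == "u_treatment_decrement") {
      u$treatment_annual_decrement <- max(v, 0)
    } else if (nm == "cost_screening") {
      co$screening <- max(v, 0)
    } else if (nm == "cost_hstni") {
      co$hstni_increment <- max(v, 0)
    } else if (nm == "cost_prevention") {
      co$prevention_annual <- max(v, 0)
    } else if (nm == "cost_chd_year1") {
      co$chd_year1 <- max(v, 0)
    } else if (nm == "cost_chd_year2") {
      co$chd_year2 <- max(v, 0)
    } else if (nm == "cost_chd_later") {
      co$chd_later_annual <- max(v, 0)
    } else if (nm == "cost_stroke_year1") {
      co$stroke_year1 <- max(v, 0)
    } else if (nm == "cost_stroke_year2") {
      co$stroke_year2 <- max(v, 0)
    } else if (nm == "cost_stroke_later") {
      co$stroke_later_annual <- max(v, 0)
    } else if (nm == "discount_rate") {
      config$discount$annual_rate <- max(v, 0)
    } else {
      stop("unknown parameter in draw: ", nm, call. = FALSE)
    }
  }
  if (events_touched) {
    config$events <- event_model_params(
      p10 = p10, shape = ev$shape, calib_horizon = ev$calib_horizon,
      fatality = fatality, post_event = post, rr_treatment = rr,
      horizon_years = ev$horizon_years,
      exact_probability_ratio = ev$exact_probability_ratio)
  }
  config$utilities <- u
  config$costs <- co
  config
}

#' Probabilistic sensitivity analysis (second-order Monte Carlo)
#'
#' Each iteration draws one parameter set from the second-order
#' distributions, generates a fresh cohort of `n_per_iter` individuals
#' under the drawn sex split, runs one microsimulation of both
#' strategies, and records the incremental cost and QALYs per person.
#'
#' @param config a [run_config()].
#' @param n_iter number of iterations (default 500).
#' @param n_per_iter individuals per iteration (default 20000).
#' @param seed root seed.
#' @param spec second-order specification (default
#'   [second_order_spec()]).
#' @return Object of class `psa_result`: `iterations` (data.frame with
#'   `delta_cost`, `delta_qalys`, `icer`, `inmb`), `draws` (matrix of
#'   parameter draws), `wtp`.
#' @export
run_psa <- function(config = run_config(), n_iter = 500, n_per_iter = 20000,
                    seed = 1L, spec = second_order_spec()) {
  stopifnot(inherits(config, "run_config"))
  if (n_iter < 1) stop("n_iter must be at least 1", call. = FALSE)
  draws_mat <- matrix(NA_real_, n_iter, nrow(spec),
                      dimnames = list(NULL, spec$parameter))
  rows <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    it_seed <- substream_seed(seed, paste0("psa", i))
    draws <- sample_second_order(spec, it_seed)
    draws_mat[i, ] <- draws
    cfg <- apply_parameters(config, draws)
    cfg$cohort$n <- as.integer(n_per_iter)
    cohort <- generate_cohort(cfg$cohort,
                              seed = substream_seed(it_seed, "psacohort"))
    res <- run_once(cohort, cfg, it_seed)
    rows[[i]] <- data.frame(iteration = i,
                            delta_cost = res$comparison$delta_cost,
                            delta_qalys = res$comparison$delta_qalys,
                            icer = res$comparison$icer,
                            inmb = res$comparison$inmb)
  }
  structure(list(iterations = do.call(rbind, rows), draws = draws_mat,
                 wtp = config$experiment$wtp, seed = seed),
            class = "psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability of being
#' cost-effective is the fraction of PSA iterations with positive net
#' monetary benefit `wtp * dQALY - dCost > 0`.
#'
#' @param psa a `psa_result` from [run_psa()].
#' @param wtp_grid willingness-to-pay grid in Euro per QALY (default 0
#'   to 100,000 in steps of 1,000).
#' @return data.frame with columns `wtp`, `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 100000, by = 1000)) {
  it <- psa$iterations
  if (is.null(it) || nrow(it) == 0L) {
    stop("ceac: empty PSA result", call. = FALSE)
  }
  prob <- vapply(wtp_grid, function(w) {
    mean(w * it$delta_qalys - it$delta_cost > 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' Univariate (tornado) sensitivity analysis
#'
#' For every parameter with a stated range, runs one microsimulation at
#' the lower and one at the upper bound, all other parameters at base,
#' and records the incremental net monetary benefit. All runs share the
#' same cohort and simulation seed (common random numbers), so
#' differences are attributable to the varied parameter.
#'
#' @param config a [run_config()].
#' @param parameters spec data.frame (default [second_order_spec()]);
#'   rows without a range are skipped with a warning.
#' @param n_samples individuals per run (default 100000).
#' @param seed root seed.
#' @param wtp willingness-to-pay for the INMB.
#' @return data.frame with one row per parameter: `parameter`, `lo`,
#'   `hi`, `inmb_at_lo`, `inmb_at_hi`, `base_inmb`, sorted by decreasing
#'   influence (largest absolute deviation from base).
#' @export
univariate_sa <- function(config = run_config(),
                          parameters = second_order_spec(),
                          n_samples = 100000, seed = 1L,
                          wtp = config$experiment$wtp) {
  stopifnot(inherits(config, "run_config"))
  cfg0 <- config
  cfg0$experiment$wtp <- wtp
  cfg0$cohort$n <- as.integer(n_samples)
  cohort_seed <- substream_seed(seed, "sacohort")
  run_inmb <- function(cfg) {
    cfg$experiment$wtp <- wtp
    cfg$cohort$n <- as.integer(n_samples)
    cohort <- generate_cohort(cfg$cohort, seed = cohort_seed)
    run_once(cohort, cfg, seed)$comparison$inmb
  }
  base_inmb <- run_inmb(cfg0)
  rows <- list()
  for (i in seq_len(nrow(parameters))) {
    p <- parameters[i, ]
    if (is.na(p$lo) || is.na(p$hi)) {
      warning("parameter '", p$parameter, "' has no range; skipped",
              call. = FALSE)
      next
    }
    if (p$lo == p$hi) {
      inmb_lo <- inmb_hi <- run_inmb(
        apply_parameters(cfg0, stats::setNames(p$lo, p$parameter)))
    } else {
      inmb_lo <- run_inmb(
        apply_parameters(cfg0, stats::setNames(p$lo, p$parameter)))
      inmb_hi <- run_inmb(
        apply_parameters(cfg0, stats::setNames(p$hi, p$parameter)))
    }
    rows[[p$parameter]] <- data.frame(
      parameter = p$parameter, lo = p$lo, hi = p$hi,
      inmb_at_lo = inmb_lo, inmb_at_hi = inmb_hi, base_inmb = base_inmb,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  influence <- pmax(abs(out$inmb_at_lo - out$base_inmb),
                    abs(out$inmb_at_hi - out$base_inmb))
  out[order(influence, decreasing = TRUE), , drop = FALSE]
}
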