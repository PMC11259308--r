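#' Event-model parameters
#'
#' Houses everything the discrete-event engine needs: sex-specific
#' ten-year cumulative probabilities for the three competing latent
#' events (CHD, stroke, death before CVD) together with Weibull shapes
#' (default 1, i.e. exponential -- only the ten-year probabilities are
#' anchored, and at that horizon the shape is inert); case-fatality
#' fractions for CHD and stroke; post-event mortality by event type, sex,
#' and age band at the event (default: five-year cumulative
#' probabilities, shape 1, optionally replaced by a two-anchor fit via
#' `anchor2`); the preventive-treatment risk ratio; and the simulation
#' horizon.
#'
#' Scales are calibrated at construction with [calibrate_scale()] so that
#' each fitted CDF reproduces its configured probability exactly at the
#' calibration horizon.
#'
#' @param p10 list `chd`, `stroke`, `death_other`, each a named
#'   (`female`, `male`) ten-year cumulative probability.
#' @param shape same structure, Weibull shapes.
#' @param calib_horizon horizon (years) the `p10` probabilities refer to;
#'   stays at 10 even when the simulation horizon is extended.
#' @param fatality list `chd`, `stroke` of per-sex fatal fractions.
#' @param post_event list with `horizon` (reference years, default 5),
#'   `shape`, `p` (list `chd`, `stroke` of 3 x 2 matrices, rows
#'   `<55`, `55-74`, `75+`, columns `female`, `male`), and optional
#'   `anchor2 = list(horizon =, p =)` giving a second anchor point for a
#'   two-point shape fit per cell.
#' @param rr_treatment risk ratio of preventive treatment on CHD and
#'   stroke (default 0.65).
#' @param horizon_years simulation horizon (default 10).
#' @param exact_probability_ratio if `TRUE`, the treated scale is solved
#'   from `F'(T) = rr * F(T)` instead of the literal `lambda' = rr *
#'   lambda` (default `FALSE`, the literal rule).
#' @return An object of class `event_model_params` with calibrated
#'   `lambda` and post-event `post_lambda`/`post_shape` matrices.
#' @export
event_model_params <- function(
    p10 = list(chd = c(female = 0.024, male = 0.066),
               stroke = c(female = 0.008, male = 0.014),
               death_other = c(female = 0.036, male = 0.059)),
    shape = list(chd = c(female = 1, male = 1),
                 stroke = c(female = 1, male = 1),
                 death_other = c(female = 1, male = 1)),
    calib_horizon = 10,
    fatality = list(chd = c(female = 0.327, male = 0.280),
                    stroke = c(female = 0.108, male = 0.103)),
    post_event = list(
      horizon = 5, shape = 1,
      p = list(
        chd = matrix(c(0.116, 0.094, 0.300, 0.290, 0.609, 0.632),
                     nrow = 3, byrow = TRUE,
                     dimnames = list(c("<55", "55-74", "75+"),
                                     c("female", "male"))),
        stroke = matrix(c(0.120, 0.147, 0.353, 0.376, 0.611, 0.682),
                        nrow = 3, byrow = TRUE,
                        dimnames = list(c("<55", "55-74", "75+"),
                                        c("female", "male")))),
      anchor2 = NULL),
    rr_treatment = 0.65,
    horizon_years = 10,
    exact_probability_ratio = FALSE) {
  events <- c("chd", "stroke", "death_other")
  for (ev in events) {
    if (!all(c("female", "male") %in% names(p10[[ev]]))) {
      stop("p10$", ev, " needs names female, male", call. = FALSE)
    }
    if (any(p10[[ev]] <= 0 | p10[[ev]] >= 1)) {
      stop("p10$", ev, " must be in (0, 1)", call. = FALSE)
    }
    if (any(shape[[ev]] <= 0)) {
      stop("shape$", ev, " must be positive", call. = FALSE)
    }
  }
  for (ev in c("chd", "stroke")) {
    if (any(fatality[[ev]] < 0 | fatality[[ev]] > 1)) {
      stop("fatality$", ev, " must be in [0, 1]", call. = FALSE)
    }
    if (any(post_event$p[[ev]] <= 0 | post_event$p[[ev]] >= 1)) {
      stop("post_event$p$", ev, " must be in (0, 1)", call. = FALSE)
    }
  }
  if (!is.finite(rr_treatment) || rr_treatment <= 0) {
    stop("rr_treatment must be positive", call. = FALSE)
  }
  if (horizon_years <= 0) stop("horizon_years must be positive", call. = FALSE)

  lambda <- lapply(events, function(ev) {
    vapply(c("female", "male"), function(s) {
      calibrate_scale(p10[[ev]][[s]], calib_horizon, shape[[ev]][[s]])$scale
    }, numeric(1))
  })
  names(lambda) <- events

  post_lambda <- post_shape <- list()
  for (ev in c("chd", "stroke")) {
    pl <- ps <- post_event$p[[ev]] * 0
    for (band in rownames(pl)) {
      for (s in colnames(pl)) {
        if (!is.null(post_event$anchor2)) {
          w <- fit_weibull_two_points(
            post_event$anchor2$horizon, post_event$anchor2$p[[ev]][band, s],
            post_event$horizon, post_event$p[[ev]][band, s])
        } else {
          w <- calibrate_scale(post_event$p[[ev]][band, s],
                               post_event$horizon, post_event$shape)
        }
        pl[band, s] <- w$scale
        ps[band, s] <- w$shape
      }
    }
    post_lambda[[ev]] <- pl
    post_shape[[ev]] <- ps
  }

  structure(list(
    p10 = p10, shape = shape, calib_horizon = calib_horizon,
    lambda = lambda, fatality = fatality, post_event = post_event,
    post_lambda = post_lambda, post_shape = post_shape,
    rr_treatment = rr_treatment, horizon_years = horizon_years,
    exact_probability_ratio = exact_probability_ratio
  ), class = "event_model_params")
}

age_band <- function(age) {
  cut(age, breaks = c(-Inf, 55, 75, Inf), right = FALSE,
      labels = c("<55", "55-74", "75+"))
}

#' Uniform draws for the event engine
#'
#' One uniform per latent quantity per person, shared between the two
#' strategy arms (common random numbers): latent CHD, stroke and non-CVD
#' death times, CHD and stroke fatality, and post-CHD / post-stroke
#' survival.
#'
#' @param n number of individuals.
#' @param seed root seed (substream `"events"`).
#' @return data.frame of 7 uniform columns.
#' @export
event_draws <- function(n, seed) {
  cols <- c("u_chd", "u_stroke", "u_death", "u_fatal_chd", "u_fatal_stroke",
            "u_post_chd", "u_post_stroke")
  substream_eval(seed, "events", function() {
    out <- as.data.frame(matrix(stats::runif(n * length(cols)), nrow = n,
                                dimnames = list(NULL, cols)))
    out
  })
}

# resolve one strategy arm from latent times + shared resolution draws
resolve_arm <- function(sex_idx, age, t_chd, t_stroke, t_death_other,
                        params, draws) {
  H <- params$horizon_years
  n <- length(t_chd)
  tmin <- pmin(t_chd, t_stroke, t_death_other)
  # tie-break priority chd > stroke > death_other
  first <- ifelse(tmin > H, "none",
                  ifelse(t_chd <= t_stroke & t_chd <= t_death_other, "chd",
                         ifelse(t_stroke <= t_death_other, "stroke",
                                "death_other")))
  t_event <- ifelse(first == "none", H, tmin)
  fatal <- rep(NA, n)
  t_death <- rep(NA_real_, n)
  cvd_death <- rep(FALSE, n)

  i <- first == "death_other"
  fatal[i] <- TRUE
  t_death[i] <- t_event[i]

  for (ev in c("chd", "stroke")) {
    i <- first == ev
    if (!any(i)) next
    uf <- if (ev == "chd") draws$u_fatal_chd else draws$u_fatal_stroke
    up <- if (ev == "chd") draws$u_post_chd else draws$u_post_stroke
    is_fatal <- uf < params$fatality[[ev]][sex_idx]
    fatal[i] <- is_fatal[i]
    cvd_death[i & is_fatal] <- TRUE
    t_death[i & is_fatal] <- t_event[i & is_fatal]
    j <- i & !is_fatal
    if (any(j)) {
      band <- as.character(age_band(age[j] + t_event[j]))
      lam <- params$post_lambda[[ev]][cbind(band, c("female", "male")[sex_idx[j]])]
      shp <- params$post_shape[[ev]][cbind(band, c("female", "male")[sex_idx[j]])]
      t_post <- sample_weibull_times(up[j], lam, shp)
      td <- t_event[j] + t_post
      within <- td <= H
      t_death[j][within] <- td[within]
      cvd_death[j][within] <- TRUE
    }
  }
  data.frame(first_event = factor(first, levels = c("none", "chd", "stroke",
                                                    "death_other")),
             t_event = t_event, fatal = fatal, t_death = t_death,
             cvd_death = cvd_death)
}

#' Simulate paired trajectories under both screening strategies
#'
#' For every individual, latent times to CHD, stroke and non-CVD death
#' are drawn from the sex-specific Weibull distributions. The standard
#' arm uses these times directly (the calibrated distributions represent
#' risk as observed under current practice). In the stratified arm the
#' CHD and stroke times of individuals whose management changed are
#' rescaled through the treatment risk ratio: newly treated individuals
#' get `lambda' = rr * lambda` (later events), withdrawn individuals the
#' reciprocal. The non-CVD death time is never rescaled. All resolution
#' draws (fatality, post-event survival) are shared between arms, so with
#' `rr = 1` the two arms are identical realization by realization.
#'
#' A first event occurring within the horizon is resolved for fatality
#' (one uniform against the sex- and event-specific fatal fraction);
#' survivors draw a post-event survival time from the (event, sex, age
#' band at event) Weibull. CVD-related death means a fatal event or any
#' post-event death within the horizon. Ties between latent times are
#' broken with priority CHD, stroke, then non-CVD death.
#'
#' @param cohort cohort data.frame.
#' @param management data.frame from [assign_management()].
#' @param params an [event_model_params()].
#' @param draws optional data.frame from [event_draws()]; supply to
#'   control the latent uniforms explicitly (tests, common random
#'   numbers across scenarios). Generated from `seed` when `NULL`.
#' @param seed root seed, used when `draws` is `NULL`.
#' @return data.frame with the management columns plus, per arm prefix
#'   (`score_`, `sscore_`): `first_event` (none/chd/stroke/death_other),
#'   `t_event` (years, horizon when censored), `fatal`, `t_death` (NA if
#'   alive at horizon), `cvd_death`.
#' @export
simulate_trajectories <- function(cohort, management, params = event_model_params(),
                                  draws = NULL, seed = NULL) {
  validate_cohort(cohort)
  n <- nrow(cohort)
  stopifnot(nrow(management) == n)
  if (is.null(draws)) {
    if (is.null(seed)) stop("simulate_trajectories needs draws or a seed",
                            call. = FALSE)
    draws <- event_draws(n, seed)
  }
  sex_idx <- as.integer(cohort$sex)

  lam <- function(ev) params$lambda[[ev]][sex_idx]
  shp <- function(ev) params$shape[[ev]][sex_idx]
  t_chd <- sample_weibull_times(draws$u_chd, lam("chd"), shp("chd"))
  t_stroke <- sample_weibull_times(draws$u_stroke, lam("stroke"), shp("stroke"))
  t_death <- sample_weibull_times(draws$u_death, lam("death_other"),
                                  shp("death_other"))

  # scale multiplier in the stratified arm for changed management
  rr_eff <- rep(1, n)
  rr_eff[management$changed & management$treated_sscore] <- params$rr_treatment
  rr_eff[management$changed & !management$treated_sscore] <- 1 / params$rr_treatment

  scale_ratio <- function(ev) {
    if (!params$exact_probability_ratio) return(rr_eff)
    p <- params$p10[[ev]][sex_idx]
    p_new <- pmin(rr_eff * p, 1 - 1e-12)
    log1p(-p_new) / log1p(-p)
  }
  t_chd_alt <- t_chd * scale_ratio("chd")^(-1 / shp("chd"))
  t_stroke_alt <- t_stroke * scale_ratio("stroke")^(-1 / shp("stroke"))

  arm_score <- resolve_arm(sex_idx, cohort$age_years, t_chd, t_stroke,
                           t_death, params, draws)
  arm_sscore <- resolve_arm(sex_idx, cohort$age_years, t_chd_alt,
                            t_stroke_alt, t_death, params, draws)
  names(arm_score) <- paste0("score_", names(arm_score))
  names(arm_sscore) <- paste0("sscore_", names(arm_sscore))
  cbind(management, arm_score, arm_sscore)
}

#' Kaplan-Meier cumulative incidence at a time point
#'
#' One minus the Kaplan-Meier survivor estimate at `eval_t`, with
#' competing events supplied as censorings. Used to validate simulated
#' latent-time samples against configured cumulative probabilities.
#'
#' @param times nonnegative event/censoring times.
#' @param event_flags logical (or 0/1); `TRUE` marks an event.
#' @param eval_t evaluation time.
#' @return Cumulative incidence in `[0, 1]`.
#' @export
km_cumulative_incidence <- function(times, event_flags, eval_t) {
  if (length(times) == 0L) {
    stop("km_cumulative_incidence: empty input", call. = FALSE)
  }
  if (any(times < 0)) stop("times must be nonnegative", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, as.integer(event_flags)) ~ 1)
  s <- summary(fit, times = eval_t, extend = TRUE)$surv
  1 - s
}
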