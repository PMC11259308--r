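#' Health-state utility parameters
#'
#' Utilities are quality-of-life weights per year lived in a state.
#' Asymptomatic life accrues `asymptomatic` (0.96) per year. A non-fatal
#' acute event costs a one-time absolute QALY decrement (back-calculated
#' to the event time), after which the chronic post-event utility applies
#' until death or the horizon. Preventive drug treatment carries a small
#' annual disutility while on treatment.
#'
#' @param asymptomatic annual utility while event-free (0.96).
#' @param acute_decrement_chd,acute_decrement_stroke one-time QALY
#'   decrements for a non-fatal acute event (0.15, 0.19).
#' @param post_chd,post_stroke chronic annual utilities after a non-fatal
#'   event (0.82, 0.52).
#' @param treatment_annual_decrement annual disutility on preventive
#'   treatment (0.01).
#' @param acute_decrement_if_fatal apply the acute decrement to
#'   immediately fatal events? Default `FALSE`: life ends at the event
#'   and the decrement represents the recovery year.
#' @param stop_treatment_at_event treatment disutility (and prevention
#'   cost) stop at the first CVD event (default `TRUE`; post-event
#'   management is inside the event cost/utility estimates).
#' @return An object of class `utility_params`.
#' @export
utility_params <- function(asymptomatic = 0.96,
                           acute_decrement_chd = 0.15,
                           acute_decrement_stroke = 0.19,
                           post_chd = 0.82,
                           post_stroke = 0.52,
                           treatment_annual_decrement = 0.01,
                           acute_decrement_if_fatal = FALSE,
                           stop_treatment_at_event = TRUE) {
  vals <- c(asymptomatic, post_chd, post_stroke)
  if (any(vals < 0 | vals > 1)) {
    stop("utilities must be in [0, 1]", call. = FALSE)
  }
  if (any(c(acute_decrement_chd, acute_decrement_stroke,
            treatment_annual_decrement) < 0)) {
    stop("utility decrements must be nonnegative", call. = FALSE)
  }
  structure(list(asymptomatic = asymptomatic,
                 acute_decrement_chd = acute_decrement_chd,
                 acute_decrement_stroke = acute_decrement_stroke,
                 post_chd = post_chd, post_stroke = post_stroke,
                 treatment_annual_decrement = treatment_annual_decrement,
                 acute_decrement_if_fatal = acute_decrement_if_fatal,
                 stop_treatment_at_event = stop_treatment_at_event),
            class = "utility_params")
}

#' Direct medical cost parameters (2019 Euro)
#'
#' @param screening one-time health check and screening cost (44).
#' @param hstni_increment incremental cost of the troponin assay under
#'   the stratified strategy (25).
#' @param prevention_annual preventive treatment per year (595).
#' @param chd_year1,chd_year2,chd_later_annual CHD treatment cost rates:
#'   first year after the event, second year, and each later year.
#' @param stroke_year1,stroke_year2,stroke_later_annual same for stroke.
#' @param cost_cv person-level coefficient of variation of event costs
#'   (0.10): each person draws one gamma multiplier (mean 1) per event
#'   cost category.
#' @param fatal_full_year1 fatal events incur the full first-year acute
#'   cost at the event time (default `TRUE`): acute-phase resource use
#'   occurs regardless of survival.
#' @param prevention_to_death continue prevention cost after a non-fatal
#'   event until death/horizon (default `FALSE`).
#' @return An object of class `cost_params`.
#' @export
cost_params <- function(screening = 44, hstni_increment = 25,
                        prevention_annual = 595,
                        chd_year1 = 15805, chd_year2 = 2318,
                        chd_later_annual = 600,
                        stroke_year1 = 21724, stroke_year2 = 13528,
                        stroke_later_annual = 8571,
                        cost_cv = 0.10,
                        fatal_full_year1 = TRUE,
                        prevention_to_death = FALSE) {
  vals <- c(screening, hstni_increment, prevention_annual, chd_year1,
            chd_year2, chd_later_annual, stroke_year1, stroke_year2,
            stroke_later_annual, cost_cv)
  if (any(vals < 0)) stop("costs must be nonnegative", call. = FALSE)
  structure(list(screening = screening, hstni_increment = hstni_increment,
                 prevention_annual = prevention_annual,
                 chd_year1 = chd_year1, chd_year2 = chd_year2,
                 chd_later_annual = chd_later_annual,
                 stroke_year1 = stroke_year1, stroke_year2 = stroke_year2,
                 stroke_later_annual = stroke_later_annual,
                 cost_cv = cost_cv, fatal_full_year1 = fatal_full_year1,
                 prevention_to_death = prevention_to_death),
            class = "cost_params")
}

#' Discounting specification
#'
#' Continuous-time discounting with annual-equivalent factor
#' \eqn{(1+r)^{-t}}; event times are continuous in a discrete-event
#' simulation, so no cycle or half-cycle correction is needed.
#'
#' @param annual_rate annual discount rate (default 0.03).
#' @return An object of class `discount_spec`.
#' @export
discount_spec <- function(annual_rate = 0.03) {
  if (annual_rate < 0) stop("discount rate must be nonnegative", call. = FALSE)
  structure(list(annual_rate = annual_rate), class = "discount_spec")
}

#' Present value of a constant flow over an interval
#'
#' Closed form of \eqn{\int_{a}^{b} x (1+r)^{-t} dt =
#' x \frac{(1+r)^{-a} - (1+r)^{-b}}{\ln(1+r)}}, reducing to
#' `x * (b - a)` at `r = 0`. All arguments are vectorized.
#'
#' @param rate_per_year flow rate (QALYs or Euro per year).
#' @param start,end interval bounds in years, `0 <= start <= end`.
#' @param discount a [discount_spec()].
#' @return Present value at time zero.
#' @export
discounted_stream <- function(rate_per_year, start, end,
                              discount = discount_spec()) {
  stopifnot(inherits(discount, "discount_spec"))
  if (any(start < 0) || any(start > end)) {
    stop("need 0 <= start <= end", call. = FALSE)
  }
  r <- discount$annual_rate
  if (r == 0) return(rate_per_year * (end - start))
  lr <- log1p(r)
  rate_per_year * (exp(-lr * start) - exp(-lr * end)) / lr
}

discount_factor <- function(t, discount) {
  (1 + discount$annual_rate)^(-t)
}

#' Discounted QALYs along trajectories
#'
#' Asymptomatic utility accrues from baseline until the first event,
#' death or the horizon. A non-fatal event switches to the chronic
#' post-event utility until death or horizon and charges the one-time
#' acute decrement, discounted to the event time. Treatment disutility
#' runs while on treatment (by default until the first event). Results
#' are floored at zero.
#'
#' @param traj data.frame with columns `first_event`, `t_event`, `fatal`,
#'   `t_death` (one strategy arm of [simulate_trajectories()], prefix
#'   stripped).
#' @param treated logical vector, on preventive treatment in this arm.
#' @param utilities a [utility_params()].
#' @param discount a [discount_spec()].
#' @param horizon horizon in years.
#' @return Numeric vector of per-person discounted QALYs.
#' @export
qalys_for_trajectory <- function(traj, treated, utilities = utility_params(),
                                 discount = discount_spec(), horizon = 10) {
  stopifnot(all(c("first_event", "t_event", "fatal", "t_death") %in%
                  names(traj)))
  n <- nrow(traj)
  end_alive <- pmin(ifelse(is.na(traj$t_death), horizon, traj$t_death), horizon)
  t_first <- pmin(traj$t_event, horizon)
  q <- discounted_stream(utilities$asymptomatic, 0, t_first, discount)

  for (ev in c("chd", "stroke")) {
    u_post <- if (ev == "chd") utilities$post_chd else utilities$post_stroke
    dec <- if (ev == "chd") utilities$acute_decrement_chd else
      utilities$acute_decrement_stroke
    i <- traj$first_event == ev & !is.na(traj$fatal) & !traj$fatal
    if (any(i)) {
      q[i] <- q[i] +
        discounted_stream(u_post, traj$t_event[i], end_alive[i], discount) -
        dec * discount_factor(traj$t_event[i], discount)
    }
    if (utilities$acute_decrement_if_fatal) {
      k <- traj$first_event == ev & !is.na(traj$fatal) & traj$fatal
      q[k] <- q[k] - dec * discount_factor(traj$t_event[k], discount)
    }
  }
  end_trt <- if (utilities$stop_treatment_at_event) t_first else end_alive
  q[treated] <- q[treated] -
    discounted_stream(utilities$treatment_annual_decrement, 0,
                      end_trt[treated], discount)
  pmax(q, 0)
}

#' Per-person event-cost multipliers
#'
#' Gamma-distributed multiplicative factors with mean 1 and coefficient
#' of variation `cv`, one per event cost category (CHD, stroke) per
#' person; `cv = 0` gives unit multipliers.
#'
#' @param n number of individuals.
#' @param cv coefficient of variation.
#' @param seed root seed (substream `"costs"`).
#' @return data.frame with columns `chd`, `stroke`.
#' @export
cost_multipliers <- function(n, cv = 0.10, seed = 1L) {
  if (cv == 0 || n == 0L) {
    return(data.frame(chd = rep(1, n), stroke = rep(1, n)))
  }
  shape <- 1 / cv^2
  substream_eval(seed, "costs", function() {
    data.frame(chd = stats::rgamma(n, shape = shape, rate = shape),
               stroke = stats::rgamma(n, shape = shape, rate = shape))
  })
}

#' Discounted direct medical costs along trajectories
#'
#' Screening is charged at baseline (plus the troponin increment under
#' the stratified strategy). Prevention cost runs as an annual stream
#' while on treatment. Event treatment costs run as piecewise-constant
#' streams: the first-year rate over the year after the event, the
#' second-year rate over the next, the later-years rate thereafter, all
#' truncated at death or horizon and multiplied by the person's category
#' multiplier. Immediately fatal events charge the full first-year acute
#' cost as a lump at the event time (configurable).
#'
#' @param traj one strategy arm as in [qalys_for_trajectory()].
#' @param treated logical, on preventive treatment in this arm.
#' @param strategy `"SCORE"` or `"S_SCORE"` (determines the screening
#'   cost).
#' @param costs a [cost_params()].
#' @param discount a [discount_spec()].
#' @param horizon horizon in years.
#' @param multipliers data.frame from [cost_multipliers()] (unit
#'   multipliers when `NULL`).
#' @return Numeric vector of per-person discounted costs in Euro.
#' @export
costs_for_trajectory <- function(traj, treated,
                                 strategy = c("SCORE", "S_SCORE"),
                                 costs = cost_params(),
                                 discount = discount_spec(), horizon = 10,
                                 multipliers = NULL) {
  strategy <- match.arg(strategy)
  n <- nrow(traj)
  if (is.null(multipliers)) {
    multipliers <- data.frame(chd = rep(1, n), stroke = rep(1, n))
  }
  screen <- costs$screening +
    if (strategy == "S_SCORE") costs$hstni_increment else 0
  total <- rep(screen, n)  # lump at t = 0, discount factor 1

  end_alive <- pmin(ifelse(is.na(traj$t_death), horizon, traj$t_death), horizon)
  t_first <- pmin(traj$t_event, horizon)
  end_prev <- if (costs$prevention_to_death) end_alive else t_first
  total[treated] <- total[treated] +
    discounted_stream(costs$prevention_annual, 0, end_prev[treated], discount)

  for (ev in c("chd", "stroke")) {
    y1 <- if (ev == "chd") costs$chd_year1 else costs$stroke_year1
    y2 <- if (ev == "chd") costs$chd_year2 else costs$stroke_year2
    later <- if (ev == "chd") costs$chd_later_annual else
      costs$stroke_later_annual
    m <- multipliers[[ev]]
    is_ev <- traj$first_event == ev
    i <- is_ev & !is.na(traj$fatal) & !traj$fatal
    if (any(i)) {
      te <- traj$t_event[i]
      e <- end_alive[i]
      total[i] <- total[i] + m[i] * (
        discounted_stream(y1, te, pmin(te + 1, e), discount) +
          discounted_stream(y2, pmin(te + 1, e), pmin(te + 2, e), discount) +
          discounted_stream(later, pmin(te + 2, e), e, discount))
    }
    if (costs$fatal_full_year1) {
      k <- is_ev & !is.na(traj$fatal) & traj$fatal
      if (any(k)) {
        total[k] <- total[k] +
          m[k] * y1 * discount_factor(traj$t_event[k], discount)
      }
    }
  }
  total
}
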