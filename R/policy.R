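#' Preventive-treatment policy table
#'
#' Maps each risk class of each strategy to a probability of being
#' assigned preventive drug treatment. The shipped base case follows
#' guideline practice for the standard strategy (treat half of High, all
#' of VeryHigh, nobody below 5% risk) and shifts probabilities down for
#' troponin-negative and up for troponin-elevated stratified classes.
#'
#' @param score named probabilities for classes Low, Mod, High, VeryHigh.
#' @param sscore named probabilities for the 11 stratified classes.
#' @return An object of class `policy_table`.
#' @export
policy_table <- function(score = c(Low = 0, Mod = 0, High = 0.50, VeryHigh = 1),
                         sscore = c("Low-" = 0, "Low+" = 0.01, "Low++" = 0.30,
                                    "Mod-" = 0, "Mod+" = 0.75, "Mod++" = 0.99,
                                    "High-" = 0.30, "High+" = 0.75,
                                    "High++" = 0.99, "VeryHigh-" = 0.99,
                                    "VeryHigh+" = 1)) {
  if (!identical(sort(names(score)), sort(score_class_levels))) {
    stop("policy: score table needs the four SCORE classes", call. = FALSE)
  }
  if (!identical(sort(names(sscore)), sort(sscore_class_levels))) {
    stop("policy: sscore table needs the 11 stratified classes", call. = FALSE)
  }
  if (any(score < 0 | score > 1) || any(sscore < 0 | sscore > 1)) {
    stop("policy: treatment probabilities must be in [0, 1]", call. = FALSE)
  }
  structure(list(score = score[score_class_levels],
                 sscore = sscore[sscore_class_levels]),
            class = "policy_table")
}

#' Base-case policy table
#' @return The default [policy_table()].
#' @export
default_policy <- function() policy_table()

#' Look up a treatment probability
#'
#' @param policy a [policy_table()].
#' @param strategy `"SCORE"` or `"S_SCORE"`.
#' @param class risk-class label valid for the strategy.
#' @return Probability in `[0, 1]`.
#' @export
treatment_probability <- function(policy, strategy = c("SCORE", "S_SCORE"),
                                  class) {
  stopifnot(inherits(policy, "policy_table"))
  strategy <- match.arg(strategy)
  tab <- if (strategy == "SCORE") policy$score else policy$sscore
  class <- as.character(class)
  if (any(!class %in% names(tab))) {
    stop("unknown risk class for strategy ", strategy, ": ",
         paste(setdiff(class, names(tab)), collapse = ", "), call. = FALSE)
  }
  unname(tab[class])
}

#' Assign treatment status under both strategies
#'
#' By default the two strategies' treatment Bernoullis are coupled
#' comonotonically through one shared uniform per person: a person is
#' treated under a strategy iff `u < p`. A person's propensity to be
#' treated is thus a stable trait, and the probability of changed
#' management equals `|p_score - p_sscore|`, the minimum possible
#' discordance. Independent coupling (a second uniform for the
#' alternative strategy) is available for comparison.
#'
#' @param p_score,p_sscore per-person treatment probabilities (vectorized).
#' @param u shared uniform draw(s) in `[0, 1)`.
#' @param coupling `"comonotonic"` (default) or `"independent"`.
#' @param u2 second uniform vector, required for independent coupling.
#' @return data.frame with logical columns `treated_score`,
#'   `treated_sscore`, `changed` (the XOR of the two).
#' @export
assign_management <- function(p_score, p_sscore, u,
                              coupling = c("comonotonic", "independent"),
                              u2 = NULL) {
  coupling <- match.arg(coupling)
  if (any(u < 0 | u >= 1)) stop("u must be in [0, 1)", call. = FALSE)
  treated_score <- u < p_score
  u_alt <- if (coupling == "comonotonic") {
    u
  } else {
    if (is.null(u2)) stop("independent coupling needs u2", call. = FALSE)
    u2
  }
  treated_sscore <- u_alt < p_sscore
  data.frame(treated_score = treated_score, treated_sscore = treated_sscore,
             changed = xor(treated_score, treated_sscore))
}

#' Changed-management rate of a set of assignments
#'
#' @param assignments data.frame from [assign_management()].
#' @return List with `changed` (total fraction), `to_treatment` (fraction
#'   newly treated under the stratified strategy) and `off_treatment`
#'   (fraction withdrawn); the two components sum to the total.
#' @export
changed_management_rate <- function(assignments) {
  if (is.null(assignments) || nrow(assignments) == 0L) {
    stop("changed_management_rate: empty assignment set", call. = FALSE)
  }
  to_trt <- mean(!assignments$treated_score & assignments$treated_sscore)
  off_trt <- mean(assignments$treated_score & !assignments$treated_sscore)
  list(changed = to_trt + off_trt, to_treatment = to_trt,
       off_treatment = off_trt)
}
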