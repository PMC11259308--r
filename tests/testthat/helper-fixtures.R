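# small hand-built cohort spanning all risk classes and troponin bands
tiny_cohort <- function() {
  data.frame(
    id = 1:6,
    sex = factor(c("female", "male", "female", "male", "female", "male"),
                 levels = c("female", "male")),
    age_years = c(45, 52, 61, 58, 70, 49),
    score_risk = c(0.002, 0.03, 0.06, 0.12, 0.008, 0.055),
    hstni = c(1.0, 7.0, 12.0, 7.0, 4.0, 2.0))
}

# single-arm trajectory data.frame for economics tests
make_traj <- function(first_event, t_event, fatal, t_death) {
  data.frame(
    first_event = factor(first_event,
                         levels = c("none", "chd", "stroke", "death_other")),
    t_event = t_event, fatal = fatal, t_death = t_death)
}

# config scaled down for fast in-test simulation
small_config <- function(n = 4000L, ...) {
  cfg <- run_config(...)
  cfg$cohort$n <- n
  cfg
}

# policy that only expands treatment (no withdrawals), used where a
# property only holds without off-treatment switching
expansion_policy <- function() {
  policy_table(
    score = c(Low = 0, Mod = 0, High = 0.50, VeryHigh = 1),
    sscore = c("Low-" = 0, "Low+" = 0.01, "Low++" = 0.30,
               "Mod-" = 0, "Mod+" = 0.75, "Mod++" = 0.99,
               "High-" = 0.50, "High+" = 0.75, "High++" = 0.99,
               "VeryHigh-" = 1, "VeryHigh+" = 1))
}
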