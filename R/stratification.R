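#' Risk-class and troponin threshold configuration
#'
#' SCORE classes partition the estimated 10-year fatal-CVD risk with
#' half-open, lower-inclusive intervals: Low `[0, 1%)`, Mod `[1%, 5%)`,
#' High `[5%, 10%)`, VeryHigh `[10%, 100%]`. The troponin categories use
#' sex-specific cuts: "minus" below the low cut, "plus" within the closed
#' band `[low, high]`, "plusplus" above the high cut (women 4/10 ng/L,
#' men 6/12 ng/L by default). All values are expressed in ng/L.
#'
#' @param score_cuts three strictly increasing risk fractions
#'   (default `c(0.01, 0.05, 0.10)`).
#' @param tni_low,tni_high per-sex (`female`, `male`) hsTnI cuts in ng/L;
#'   `tni_low < tni_high` elementwise.
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(score_cuts = c(0.01, 0.05, 0.10),
                             tni_low = c(female = 4, male = 6),
                             tni_high = c(female = 10, male = 12)) {
  if (length(score_cuts) != 3L || any(diff(score_cuts) <= 0) ||
      score_cuts[1] <= 0 || score_cuts[3] >= 1) {
    stop("score_cuts must be 3 strictly increasing fractions in (0, 1)",
         call. = FALSE)
  }
  for (v in list(tni_low, tni_high)) {
    if (!all(c("female", "male") %in% names(v))) {
      stop("tni cuts need names female, male", call. = FALSE)
    }
  }
  tni_low <- tni_low[c("female", "male")]
  tni_high <- tni_high[c("female", "male")]
  if (any(tni_low < 0) || any(tni_low >= tni_high)) {
    stop("tni cuts must satisfy 0 <= low < high per sex", call. = FALSE)
  }
  structure(list(score_cuts = score_cuts, tni_low = tni_low,
                 tni_high = tni_high), class = "threshold_config")
}

score_class_levels <- c("Low", "Mod", "High", "VeryHigh")
tni_category_levels <- c("minus", "plus", "plusplus")
sscore_class_levels <- c("Low-", "Low+", "Low++", "Mod-", "Mod+", "Mod++",
                         "High-", "High+", "High++",
                         "VeryHigh-", "VeryHigh+")

#' Classify estimated 10-year risk into a SCORE class
#'
#' @param score_risk risk fraction(s) in `[0, 1]`.
#' @param thresholds a [threshold_config()].
#' @return Factor with levels Low, Mod, High, VeryHigh. Interval bounds
#'   are lower-inclusive: a risk of exactly 5% is High, exactly 10% is
#'   VeryHigh.
#' @export
classify_score <- function(score_risk, thresholds = threshold_config()) {
  stopifnot(inherits(thresholds, "threshold_config"))
  if (any(is.na(score_risk)) || any(score_risk < 0 | score_risk > 1)) {
    stop("score_risk must be in [0, 1]", call. = FALSE)
  }
  idx <- findInterval(score_risk, thresholds$score_cuts) + 1L
  factor(score_class_levels[idx], levels = score_class_levels)
}

#' Classify an hsTnI concentration into a troponin category
#'
#' @param sex factor/character vector with values `female`/`male`.
#' @param hstni hsTnI in ng/L, nonnegative.
#' @param thresholds a [threshold_config()].
#' @return Factor with levels minus, plus, plusplus; the middle band is
#'   closed on both sides (a woman at exactly 10 ng/L is "plus").
#' @export
classify_tni <- function(sex, hstni, thresholds = threshold_config()) {
  stopifnot(inherits(thresholds, "threshold_config"))
  sex <- as.character(sex)
  if (!all(sex %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'", call. = FALSE)
  }
  if (any(is.na(hstni)) || any(hstni < 0)) {
    stop("hstni must be nonnegative", call. = FALSE)
  }
  lo <- thresholds$tni_low[sex]
  hi <- thresholds$tni_high[sex]
  cat <- ifelse(hstni < lo, "minus", ifelse(hstni <= hi, "plus", "plusplus"))
  factor(cat, levels = tni_category_levels)
}

#' Assign the stratified (S-SCORE) risk class
#'
#' Crosses the SCORE class with the troponin category. In the VeryHigh
#' class the "plus" and "plusplus" categories are merged into a single
#' "VeryHigh+" class (treatment is universal there regardless of the
#' degree of elevation), giving 11 stratified classes in total.
#'
#' @param sex,score_risk,hstni individual attributes (vectorized).
#' @param thresholds a [threshold_config()].
#' @return Factor with the 11 stratified class levels.
#' @export
stratify <- function(sex, score_risk, hstni, thresholds = threshold_config()) {
  sc <- classify_score(score_risk, thresholds)
  tc <- classify_tni(sex, hstni, thresholds)
  suffix <- c(minus = "-", plus = "+", plusplus = "++")[as.character(tc)]
  suffix[sc == "VeryHigh" & tc != "minus"] <- "+"
  factor(paste0(as.character(sc), suffix), levels = sscore_class_levels)
}

#' Classify every individual of a cohort under both strategies
#'
#' @param cohort a cohort data.frame ([generate_cohort()]).
#' @param thresholds a [threshold_config()].
#' @return The cohort with added columns `score_class`, `tni_category`,
#'   `sscore_class`.
#' @export
stratify_cohort <- function(cohort, thresholds = threshold_config()) {
  validate_cohort(cohort)
  cohort$score_class <- classify_score(cohort$score_risk, thresholds)
  cohort$tni_category <- classify_tni(cohort$sex, cohort$hstni, thresholds)
  cohort$sscore_class <- stratify(cohort$sex, cohort$score_risk,
                                  cohort$hstni, thresholds)
  cohort
}
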