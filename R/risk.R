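# Individual 5-year absolute lung-cancer risk from gender, age and smoking
# history, in the spirit of the Spitz demographic risk models. The published
# coefficients of those models are not reproduced here; this is a
# configurable parametric family with illustrative defaults on the same
# scale (mean risk of a typical high-risk screening population ~2-3%).

#' Configure the lung-cancer risk model
#'
#' Risk is `min(cap, baseline(gender, age band) * multiplier(smoking) *
#' exp(duration_coefficient * smoking_years))`. Age bands are 5-year bands
#' over 40-84; ages outside are clamped to the nearest band. Multipliers
#' must be ordered never <= ex <= current, and baseline risk must be
#' non-decreasing in age within gender.
#'
#' @param baseline_risk matrix of 5-year absolute risks in `[0,1]` with rows
#'   `male`/`female` and one column per 5-year age band from 40-44 to 80-84.
#' @param smoking_multiplier named vector `c(never=, ex=, current=)` of
#'   relative risk factors.
#' @param duration_coefficient per-year log-risk increment for years smoked.
#' @param cap maximum attainable risk in `(0, 1]`.
#' @return an object of class `risk_model_config`.
#' @export
risk_model_config <- function(baseline_risk = default_baseline_risk(),
                              smoking_multiplier = c(never = 1, ex = 3,
                                                     current = 5),
                              duration_coefficient = 0.01,
                              cap = 0.15) {
  cfg <- structure(list(baseline_risk = baseline_risk,
                        smoking_multiplier = smoking_multiplier,
                        duration_coefficient = duration_coefficient,
                        cap = cap),
                   class = "risk_model_config")
  if (!all(rownames(baseline_risk) == GENDER_LEVELS))
    stop("baseline_risk must have rows male, female", call. = FALSE)
  if (any(baseline_risk < 0 | baseline_risk > 1))
    stop("baseline risks must lie in [0, 1]", call. = FALSE)
  if (any(apply(baseline_risk, 1, function(r) any(diff(r) < 0))))
    stop("baseline risk must be non-decreasing in age within gender",
         call. = FALSE)
  m <- smoking_multiplier
  if (!all(c("never", "ex", "current") %in% names(m)) ||
      m["never"] > m["ex"] || m["ex"] > m["current"] || any(m < 0))
    stop("smoking multipliers must satisfy 0 <= never <= ex <= current",
         call. = FALSE)
  if (cap <= 0 || cap > 1) stop("cap must lie in (0, 1]", call. = FALSE)
  cfg
}

AGE_BANDS <- seq(40, 80, by = 5)

default_baseline_risk <- function() {
  male <- c(0.00125, 0.0019, 0.0025, 0.00375, 0.005, 0.00625, 0.0075,
            0.0094, 0.01125)
  rbind(male = male, female = 0.75 * male)
}

age_band_index <- function(age) {
  pmin(pmax(findInterval(age, AGE_BANDS), 1L), length(AGE_BANDS))
}

risk_vector <- function(age, gender, smoking, smoking_years, config) {
  if (any(smoking == "unknown"))
    stop("smoking status 'unknown': impute a status or exclude these subjects ",
         "before computing risk", call. = FALSE)
  smoking_years[is.na(smoking_years)] <- 0
  base <- config$baseline_risk[cbind(match(gender, GENDER_LEVELS),
                                     age_band_index(age))]
  mult <- config$smoking_multiplier[smoking]
  pmin(config$cap,
       base * mult * exp(config$duration_coefficient * smoking_years))
}

#' Absolute 5-year lung-cancer risk for one subject
#'
#' @param subject a single-row data.frame or list with `age`, `gender`,
#'   `smoking` and `smoking_years` (see [aab_cohort()] subject fields).
#' @param config a [risk_model_config()].
#' @return risk in `[0, 1]`. Errors if smoking status is `"unknown"`.
#' @export
absolute_risk <- function(subject, config = risk_model_config()) {
  stopifnot(inherits(config, "risk_model_config"))
  unname(risk_vector(subject$age, subject$gender, subject$smoking,
                     subject$smoking_years, config))
}

#' Per-subject risks for a whole cohort
#'
#' @param cohort an `aab_cohort`.
#' @param config a [risk_model_config()].
#' @param subset optional subject-id vector to restrict to.
#' @return named numeric vector of risks for the evaluable subjects (those
#'   with known smoking status, age and gender); inevaluable subjects are
#'   dropped.
#' @export
cohort_risks <- function(cohort, config = risk_model_config(), subset = NULL) {
  s <- cohort$subjects
  if (!is.null(subset)) s <- s[s$subject_id %in% subset, , drop = FALSE]
  ok <- s$smoking != "unknown" & !is.na(s$age) & !is.na(s$gender)
  s <- s[ok, , drop = FALSE]
  r <- risk_vector(s$age, s$gender, s$smoking, s$smoking_years, config)
  names(r) <- s$subject_id
  r
}

nearest_rank <- function(x_sorted, p) {
  x_sorted[max(1L, ceiling(p * length(x_sorted)))]
}

#' Risk summary of a cohort
#'
#' Mean, min, 5th percentile, median, 95th percentile and max of per-subject
#' 5-year risks (in percent), over the evaluable subjects. Percentiles use
#' the nearest-rank convention.
#'
#' @param cohort an `aab_cohort`.
#' @param config a [risk_model_config()].
#' @return list with `summary` (named numeric, percent), `n_evaluable` and
#'   `n_excluded`.
#' @export
cohort_risk_summary <- function(cohort, config = risk_model_config()) {
  r <- cohort_risks(cohort, config)
  if (!length(r)) stop("no evaluable subjects for risk summary", call. = FALSE)
  xs <- unname(sort(r)) * 100
  list(summary = c(mean = mean(xs), min = xs[1],
                   p5 = nearest_rank(xs, 0.05),
                   median = nearest_rank(xs, 0.50),
                   p95 = nearest_rank(xs, 0.95),
                   max = xs[length(xs)]),
       n_evaluable = length(r),
       n_excluded = nrow(cohort$subjects) - length(r))
}
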