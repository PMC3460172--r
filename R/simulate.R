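# Synthetic serology cohorts: two-population lognormal RU mixtures per
# antigen, a Gaussian-copula shared "immunogenicity" factor for between-
# antigen elevation correlation, geometric titration decay for genuine
# signals, and occult cancers seeded into the nominally disease-free groups.

default_antigen_rates <- function() {
  # Marginal elevation prevalences per population. Cancer row: percentage
  # positivity of newly diagnosed lung cancers (all types) per antigen;
  # control/at-risk rows: positivity in matched normals. Occult cancers use
  # the cancer row.
  ag <- ANTIGENS
  rates <- rbind(
    cancer  = c(p53 = 0.13, `NY-ESO-1` = 0.10, CAGE = 0.09, `GBU4-5` = 0.03,
                AnnexinI = 0.00, `SOX2-B` = 0.04, `SOX2-N` = 0.04,
                MAGEA4 = 0.12, HuD = 0.05),
    control = c(p53 = 0.03, `NY-ESO-1` = 0.02, CAGE = 0.01, `GBU4-5` = 0.02,
                AnnexinI = 0.00, `SOX2-B` = 0.01, `SOX2-N` = 0.01,
                MAGEA4 = 0.04, HuD = 0.01))
  rates <- rbind(rates, at_risk = rates["control", ])
  rates[, ag]
}

default_demographics <- function() {
  # Case-control arms: mostly male, mean age ~65, current/ex-heavy smoking
  # mix with some unknowns among cases. At-risk arm: the commercial-audit
  # profile (more women, slightly younger, current/ex split near 45/46%).
  list(
    cancer = list(age_mean = 64.8, age_sd = 9, age_range = c(40, 90),
                  p_male = 0.73,
                  smoking = c(current = 0.46, ex = 0.29, never = 0.10,
                              unknown = 0.15)),
    control = list(age_mean = 64.5, age_sd = 9, age_range = c(40, 90),
                   p_male = 0.70,
                   smoking = c(current = 0.35, ex = 0.54, never = 0.11,
                               unknown = 0)),
    at_risk = list(age_mean = 61, age_sd = 10, age_range = c(40, 90),
                   p_male = 0.42,
                   smoking = c(current = 0.451, ex = 0.462, never = 0.087,
                               unknown = 0))
  )
}

#' Configure the synthetic cohort generator
#'
#' Collects every generator parameter into a validated config. Per-antigen
#' RU is a two-component lognormal mixture: a background component and an
#' elevated component that stochastically dominates it; the "true" cutoff
#' sits at the `cutoff_quantile` of the background distribution so that
#' marginal positivity at the true cutoffs equals the configured elevation
#' prevalences by construction. Elevation indicators across antigens share
#' one latent Gaussian factor (correlation `rho`), so panel-level positivity
#' can fall below the independence closed form while marginals are
#' unchanged. Elevated titration series decay geometrically with antigen
#' dilution (the dose response the calling rule tests for); background
#' series are flat apart from multiplicative noise.
#'
#' @param n_cancer,n_control,n_at_risk subject counts per arm.
#' @param antigen_rates population x antigen matrix of elevation prevalences
#'   in `[0,1]` (rows cancer/control/at_risk). Defaults to the published
#'   per-antigen percentage positivity of the optimization-set populations.
#' @param rho shared-latent-factor correlation in `[0,1)` between antigen
#'   elevation indicators (Gaussian copula). Default 0.3.
#' @param background_meanlog,background_sdlog lognormal parameters of the
#'   background RU component (recycled per antigen).
#' @param elevated_meanlog,elevated_sdlog lognormal parameters of the
#'   elevated component; `elevated_meanlog` must exceed `background_meanlog`.
#' @param cutoff_quantile background quantile at which the generating
#'   ("true") cutoff is placed. Default 0.999.
#' @param occult_rate probability that a control or at-risk subject truly
#'   harbors an undiagnosed cancer. Default 0.027, the upper published
#'   estimate for a screening prevalence round.
#' @param titration_decay fractional RU drop per coat-level dilution step
#'   for elevated series. Default 0.4.
#' @param n_coat_levels titration points per series. Default 4.
#' @param dose_noise_sd sd of multiplicative log-noise on non-reference
#'   titration points. Default 0.05.
#' @param demographics per-population list of `age_mean`, `age_sd`,
#'   `age_range`, `p_male` and a `smoking` probability vector.
#' @param seed integer seed; fully determines the generated cohort.
#' @return an object of class `cohort_sim_config`.
#' @seealso [generate_cohort()], [true_cutoffs()]
#' @export
cohort_sim_config <- function(n_cancer = 235, n_control = 266, n_at_risk = 0,
                              antigen_rates = default_antigen_rates(),
                              rho = 0.3,
                              background_meanlog = 0, background_sdlog = 1,
                              elevated_meanlog = 4, elevated_sdlog = 0.5,
                              cutoff_quantile = 0.999,
                              occult_rate = 0.027,
                              titration_decay = 0.4,
                              n_coat_levels = 4L,
                              dose_noise_sd = 0.05,
                              demographics = default_demographics(),
                              seed = 1L) {
  expand <- function(x) {
    x <- rep_len(x, length(ANTIGENS)); names(x) <- ANTIGENS; x
  }
  cfg <- list(n_cancer = as.integer(n_cancer),
              n_control = as.integer(n_control),
              n_at_risk = as.integer(n_at_risk),
              antigen_rates = antigen_rates,
              rho = rho,
              background_meanlog = expand(background_meanlog),
              background_sdlog = expand(background_sdlog),
              elevated_meanlog = expand(elevated_meanlog),
              elevated_sdlog = expand(elevated_sdlog),
              cutoff_quantile = cutoff_quantile,
              occult_rate = occult_rate,
              titration_decay = titration_decay,
              n_coat_levels = as.integer(n_coat_levels),
              dose_noise_sd = dose_noise_sd,
              demographics = demographics,
              seed = as.integer(seed))
  class(cfg) <- "cohort_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (any(c(n_cancer, n_control, n_at_risk) < 0))
      stop("subject counts must be non-negative", call. = FALSE)
    if (!all(rownames(antigen_rates) == COHORT_LEVELS) ||
        !all(ANTIGENS %in% colnames(antigen_rates)))
      stop("antigen_rates must have rows cancer/control/at_risk and all antigen columns",
           call. = FALSE)
    if (any(antigen_rates < 0 | antigen_rates > 1))
      stop("antigen_rates must lie in [0, 1]", call. = FALSE)
    if (rho < 0 || rho >= 1)
      stop("rho must lie in [0, 1)", call. = FALSE)
    if (any(elevated_meanlog <= background_meanlog))
      stop("elevated_meanlog must exceed background_meanlog for every antigen",
           call. = FALSE)
    if (occult_rate < 0 || occult_rate > 1)
      stop("occult_rate must lie in [0, 1]", call. = FALSE)
    if (titration_decay < 0 || titration_decay >= 1)
      stop("titration_decay must lie in [0, 1)", call. = FALSE)
    if (n_coat_levels < 3)
      stop("n_coat_levels must be at least 3 (dose-response check needs 3 points)",
           call. = FALSE)
    if (length(seed) != 1 || is.na(seed))
      stop("seed must be a single integer", call. = FALSE)
  })
  invisible(cfg)
}

#' Generating cutoffs of a simulation config
#'
#' The RU cutoff per antigen at which the generator's marginal positivity
#' equals the configured elevation prevalence: the `cutoff_quantile` of the
#' background lognormal component.
#'
#' @param config a [cohort_sim_config()].
#' @return named numeric vector of RU cutoffs.
#' @export
true_cutoffs <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  stats::qlnorm(config$cutoff_quantile, config$background_meanlog,
                config$background_sdlog)
}

sample_demographics <- function(n, dem, rng_round = TRUE) {
  age <- round(stats::rnorm(n, dem$age_mean, dem$age_sd))
  age <- pmin(pmax(age, dem$age_range[1]), dem$age_range[2])
  gender <- ifelse(stats::runif(n) < dem$p_male, "male", "female")
  smoking <- sample(names(dem$smoking), n, replace = TRUE, prob = dem$smoking)
  smoking_years <- ifelse(smoking %in% c("current", "ex"),
                          pmin(pmax(round(stats::rnorm(n, 35, 12)), 1), 60), 0)
  quit_years <- ifelse(smoking == "ex",
                       pmin(round(stats::rexp(n, 1 / 10)), 40), 0)
  data.frame(age = age, gender = gender, smoking = smoking,
             smoking_years = smoking_years, quit_years = quit_years,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic serology cohort
#'
#' Draws a cohort under a [cohort_sim_config()]: subject demographics per
#' arm, occult-cancer flags for control/at-risk subjects, correlated
#' per-antigen elevation indicators, and full titration series per
#' subject x antigen. Elevated series decline monotonically (up to noise)
#' with antigen dilution; background series are flat. The returned cohort
#' carries a truth table (see [truth_table()]) recording true disease
#' status including occult cancers.
#'
#' The same config (including seed) always yields an identical cohort.
#'
#' @param config a [cohort_sim_config()].
#' @return an [aab_cohort()] with `meta$synthetic = TRUE`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)

  n <- cfg$n_cancer + cfg$n_control + cfg$n_at_risk
  if (n == 0) stop("empty cohort requested", call. = FALSE)
  pop <- rep(COHORT_LEVELS, c(cfg$n_cancer, cfg$n_control, cfg$n_at_risk))
  id <- sprintf("S%05d", seq_len(n))

  # True disease status: all cancer-arm subjects, plus occult cancers among
  # controls/at-risk at the configured rate.
  occult <- pop != "cancer" & stats::runif(n) < cfg$occult_rate
  true_cancer <- pop == "cancer" | occult

  dem <- do.call(rbind, lapply(COHORT_LEVELS, function(p) {
    k <- sum(pop == p)
    if (k == 0) return(NULL)
    sample_demographics(k, cfg$demographics[[p]])
  }))

  subtype <- ifelse(pop == "cancer",
                    sample(c("NSCLC", "SCLC", "other"), n, replace = TRUE,
                           prob = c(0.757, 0.226, 0.017)), "none")
  stage <- ifelse(pop == "cancer",
                  sample(c("early", "late"), n, replace = TRUE), "unknown")
  subjects <- data.frame(
    subject_id = id,
    cohort = pop,
    cancer_status = ifelse(pop == "cancer", "confirmed",
                           ifelse(pop == "control", "none", "unknown")),
    subtype = subtype,
    stage_group = stage,
    dem,
    stringsAsFactors = FALSE)

  # Correlated elevation indicators: one shared latent factor per subject,
  # thresholded per antigen at the marginal prevalence (Gaussian copula).
  A <- length(ANTIGENS)
  rate_row <- ifelse(true_cancer, "cancer", pop)     # occult => cancer rates
  rates <- cfg$antigen_rates[rate_row, ANTIGENS, drop = FALSE]
  u <- stats::rnorm(n)
  z <- sqrt(cfg$rho) * u + sqrt(1 - cfg$rho) * matrix(stats::rnorm(n * A), n, A)
  elevated <- z > stats::qnorm(1 - rates)            # n x A logical

  # Reference-level RU from the mixture.
  bg <- matrix(stats::rlnorm(n * A, rep(cfg$background_meanlog, each = n),
                             rep(cfg$background_sdlog, each = n)), n, A)
  el <- matrix(stats::rlnorm(n * A, rep(cfg$elevated_meanlog, each = n),
                             rep(cfg$elevated_sdlog, each = n)), n, A)
  ru_ref <- ifelse(elevated, el, bg)

  # Titration series, coat level 0 (most dilute) .. k-1 (reference, full
  # strength). Elevated: geometric decay toward dilution; background: flat.
  # The reference level carries ru_ref exactly; other levels get noise.
  k <- cfg$n_coat_levels
  lev <- seq_len(k) - 1L
  decay <- (1 - cfg$titration_decay)^((k - 1L) - lev)       # length k
  ru <- array(0, c(n, A, k))
  for (j in seq_len(k)) {
    f <- ifelse(elevated, decay[j], 1)
    noise <- if (lev[j] == k - 1L) 1 else
      exp(stats::rnorm(n * A, 0, cfg$dose_noise_sd))
    ru[, , j] <- ru_ref * f * noise
  }
  measurements <- data.frame(
    subject_id = rep(id, times = A * k),
    antigen = rep(rep(ANTIGENS, each = n), times = k),
    coat_level = rep(lev, each = n * A),
    ru = as.vector(ru),
    stringsAsFactors = FALSE)

  truth <- data.frame(subject_id = id, cohort = pop,
                      true_cancer = true_cancer, occult = occult,
                      stringsAsFactors = FALSE)
  cohort <- aab_cohort(subjects, order_measurements(measurements),
                       n_coat_levels = k, reference_level = k - 1L,
                       truth = truth)
  cohort$meta$sim_config <- cfg
  cohort
}

#' True disease status of a synthetic cohort
#'
#' Returns the generator's truth table: one row per subject with the cohort
#' label, the true disease status, and whether the subject is an occult
#' cancer (truly diseased but labelled control/at-risk). Only available for
#' cohorts produced by [generate_cohort()].
#'
#' @param cohort an `aab_cohort`.
#' @return data.frame with columns `subject_id`, `cohort`, `true_cancer`,
#'   `occult`.
#' @export
truth_table <- function(cohort) {
  stopifnot(inherits(cohort, "aab_cohort"))
  if (!isTRUE(cohort$meta$synthetic) || is.null(cohort$meta$truth))
    stop("truth_table() is only defined for synthetic cohorts from generate_cohort()",
         call. = FALSE)
  cohort$meta$truth
}
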