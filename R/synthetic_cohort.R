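# Synthetic blunt-trauma hemorrhagic-shock cohorts with known ground truth.
#
# A latent severity factor induces the confounding pattern seen in registry
# data (sicker patients are both likelier to die and likelier to receive
# REBOA); treatment benefit is confined to a physiology-defined subgroup and
# harmful outside it, so the optimal policy is a known function of the
# covariates and every downstream stage can be scored against it.

default_baseline_coeffs <- function() {
  c(sbp_deficit = 0.55, gcs_deficit = 1.30, pulse_absent = 1.10,
    tachycardia = 0.25, age_std = 0.35, pelvic_fx = 0.25, hemothorax = 0.30,
    pneumothorax = 0.15, thoracic_aorta_injury = 0.60,
    rbc_transfusion_1h = 0.30)
}

default_confounding_coeffs <- function() {
  c(sbp_deficit = 0.70, gcs_deficit = 0.80, pulse_absent = 0.70,
    pelvic_fx = 1.20, pneumothorax = 0.50, hemothorax = 0.50,
    thoracic_aorta_injury = 0.70, rbc_transfusion_1h = 0.80)
}

default_missing_rate <- function() {
  c(temperature = 0.10, respiratory_rate = 0.07, pulse_oximetry = 0.07,
    height = 0.08, weight = 0.08, bmi = 0.10, gcs = 0.04)
}

default_filter_noise <- function() {
  c(underage = 0.02, nonblunt = 0.05, no_shock = 0.04, transfer = 0.03,
    missing_age = 0.01, missing_los = 0.015)
}

# Named severity-linked features on which the true outcome and treatment
# mechanisms operate; all are functions of *observed* covariates so that
# treatment is ignorable given the covariate set handed to the models.
risk_feature_names <- function() {
  c("sbp_deficit", "gcs_deficit", "pulse_absent", "tachycardia", "age_std",
    "pelvic_fx", "femur_fx", "hemothorax", "pneumothorax",
    "thoracic_aorta_injury", "rbc_transfusion_1h")
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the joint data-generating mechanism: covariate marginals tied to a
#' latent severity factor, a rare treatment confounded with severity, a
#' heterogeneous binary 24-h mortality outcome in which treatment benefits a
#' physiology-defined subgroup (log-odds shift `effect_benefit` < 0) and
#' harms everyone else (`effect_harm` > 0), missingness, and planted rates of
#' records that fail each study inclusion criterion.
#'
#' @param n Number of encounters to generate.
#' @param seed Integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @param treatment_prevalence Target marginal probability of treatment
#'   (default 0.008, matching the observed REBOA rate; boost for testing).
#' @param baseline_mortality Target marginal untreated 24-h mortality.
#' @param subgroup_rule List with `pulse_absent` (logical: require absent
#'   pulse), `gcs_max` (subgroup has GCS below this), `sbp_max` (subgroup has
#'   SBP below this mmHg; an unobtainable SBP qualifies).
#' @param effect_benefit Log-odds shift of death under treatment inside the
#'   subgroup (must be <= 0).
#' @param effect_harm Log-odds shift outside the subgroup (must be >= 0).
#' @param baseline_coeffs Named log-odds weights (over the internal risk
#'   features) for untreated mortality.
#' @param confounding_coeffs Named log-odds weights for treatment assignment.
#' @param missing_rate Named per-covariate missingness rates in [0, 1).
#' @param missing_mechanism "MAR" (rate modulated by severity, marginally
#'   calibrated) or "MCAR".
#' @param filter_noise Named rates of records planted to fail each inclusion
#'   criterion: underage, nonblunt, no_shock, transfer, missing_age,
#'   missing_los.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 10000L, seed = 1L,
                             treatment_prevalence = 0.008,
                             baseline_mortality = 0.21,
                             subgroup_rule = list(pulse_absent = TRUE,
                                                  gcs_max = 6, sbp_max = 68),
                             effect_benefit = -1.5, effect_harm = 0.8,
                             baseline_coeffs = default_baseline_coeffs(),
                             confounding_coeffs = default_confounding_coeffs(),
                             missing_rate = default_missing_rate(),
                             missing_mechanism = c("MAR", "MCAR"),
                             filter_noise = default_filter_noise()) {
  cfg <- list(
    n = n, seed = seed, treatment_prevalence = treatment_prevalence,
    baseline_mortality = baseline_mortality, subgroup_rule = subgroup_rule,
    effect_benefit = effect_benefit, effect_harm = effect_harm,
    baseline_coeffs = baseline_coeffs,
    confounding_coeffs = confounding_coeffs,
    missing_rate = missing_rate,
    missing_mechanism = match.arg(missing_mechanism),
    filter_noise = filter_noise
  )
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  bad <- function(field, why) {
    stop(sprintf("invalid synthetic_config field '%s': %s", field, why),
         call. = FALSE)
  }
  if (!is.numeric(cfg$n) || length(cfg$n) != 1 || cfg$n < 1 ||
      cfg$n != floor(cfg$n)) {
    bad("n", "must be a positive integer")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    bad("seed", "must be a single integer")
  }
  if (!is.numeric(cfg$treatment_prevalence) ||
      cfg$treatment_prevalence <= 0 || cfg$treatment_prevalence >= 1) {
    bad("treatment_prevalence", "must lie strictly between 0 and 1")
  }
  if (!is.numeric(cfg$baseline_mortality) ||
      cfg$baseline_mortality <= 0 || cfg$baseline_mortality >= 1) {
    bad("baseline_mortality", "must lie strictly between 0 and 1")
  }
  sr <- cfg$subgroup_rule
  if (!is.list(sr) || !all(c("pulse_absent", "gcs_max", "sbp_max") %in%
                           names(sr))) {
    bad("subgroup_rule", "needs pulse_absent, gcs_max, sbp_max")
  }
  if (!is.numeric(sr$gcs_max) || sr$gcs_max < 3 || sr$gcs_max > 16) {
    bad("subgroup_rule", "gcs_max must be in [3, 16]")
  }
  if (!is.numeric(cfg$effect_benefit) || cfg$effect_benefit > 0) {
    bad("effect_benefit", "must be <= 0 (log-odds benefit)")
  }
  if (!is.numeric(cfg$effect_harm) || cfg$effect_harm < 0) {
    bad("effect_harm", "must be >= 0 (log-odds harm)")
  }
  for (fld in c("baseline_coeffs", "confounding_coeffs")) {
    cf <- cfg[[fld]]
    if (length(cf) && (is.null(names(cf)) ||
                       !all(names(cf) %in% risk_feature_names()))) {
      bad(fld, sprintf("names must be among: %s",
                       paste(risk_feature_names(), collapse = ", ")))
    }
  }
  mr <- cfg$missing_rate
  if (length(mr) && (is.null(names(mr)) || any(mr < 0) || any(mr >= 1))) {
    bad("missing_rate", "must be named rates in [0, 1)")
  }
  fn <- cfg$filter_noise
  known <- c("underage", "nonblunt", "no_shock", "transfer", "missing_age",
             "missing_los")
  if (length(fn) && (is.null(names(fn)) || !all(names(fn) %in% known) ||
                     any(fn < 0) || sum(fn) >= 1)) {
    bad("filter_noise", "must be named non-negative rates summing to < 1")
  }
  invisible(cfg)
}

# Truncated normal via the inverse CDF (deterministic under set.seed).
rtnorm <- function(n, mean, sd, lo, hi) {
  qnorm(runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd)), mean, sd)
}

# Solve for the logistic intercept giving a target marginal probability.
calibrate_intercept <- function(lp, target) {
  uniroot(function(c0) mean(plogis(c0 + lp)) - target,
          interval = c(-40, 40), tol = 1e-12)$root
}

risk_features <- function(d) {
  sbp_deficit <- ifelse(d$sbp_unobtainable == 1, 2,
                        pmax(0, 90 - d$sbp_true) / 20)
  cbind(
    sbp_deficit = sbp_deficit,
    gcs_deficit = (15 - d$gcs_true) / 6,
    pulse_absent = as.numeric(d$pulse == 0),
    tachycardia = ifelse(d$pulse > 0, pmax(0, d$pulse - 100) / 30, 0),
    age_std = (d$age_true - 50) / 20,
    pelvic_fx = d$pelvic_fx,
    femur_fx = d$femur_fx,
    hemothorax = d$hemothorax,
    pneumothorax = d$pneumothorax,
    thoracic_aorta_injury = d$thoracic_aorta_injury,
    rbc_transfusion_1h = d$rbc_transfusion_1h
  )
}

linear_predictor <- function(feat, coeffs) {
  if (!length(coeffs)) return(rep(0, nrow(feat)))
  as.numeric(feat[, names(coeffs), drop = FALSE] %*% coeffs)
}

#' Generate a synthetic cohort with potential-outcome ground truth
#'
#' Draws `config$n` encounters: covariates tied to a latent severity factor,
#' treatment Bernoulli in the true (calibrated) propensity, outcome Bernoulli
#' in the true potential-outcome probability under the assigned arm, planted
#' inclusion-criterion failures, and missingness masks. The returned ground
#' truth aligns row-for-row with the cohort.
#'
#' @param config A [synthetic_config()].
#' @return List of class `synthetic_cohort` with elements `cohort`
#'   (data.frame, one row per encounter), `truth` (data.frame with `p0`,
#'   `p1`, `pi_true`, `oracle_action`, `in_subgroup`), and `config`.
#' @export
generate_cohort <- function(config) {
  validate_synthetic_config(config)
  n <- as.integer(config$n)
  set.seed(as.integer(config$seed))

  z <- rnorm(n) # latent severity

  d <- list()
  d$age_true <- round(rtnorm(n, 50, 21, 17, 95))
  sex <- ifelse(runif(n) < 0.65, "male", "female")
  d$pulse_absent <- rbinom(n, 1, plogis(-2.6 + 1.3 * z))
  d$pulse <- ifelse(d$pulse_absent == 1, 0,
                    round(rtnorm(n, 95 + 12 * z, 18, 20, 190)))
  # Pulseless patients are largely unresponsive (GCS 3) and usually have no
  # measurable blood pressure; couple these directly rather than only
  # through the latent severity.
  d$sbp_unobtainable <- rbinom(n, 1, ifelse(d$pulse_absent == 1, 0.70,
                                            plogis(-3.6 + 1.2 * z)))
  d$sbp_true <- round(rtnorm(n, 84 - 6 * z - 12 * d$pulse_absent, 14, 40,
                             140))
  gcs_base <- pmin(15, pmax(3, round(14 - 3.2 * z + rnorm(n, 0, 2))))
  gcs_floor <- rbinom(n, 1, 0.9) == 1 & d$pulse_absent == 1
  d$gcs_true <- ifelse(gcs_floor, 3L, gcs_base)
  temperature <- round(rtnorm(n, 36.3 - 0.15 * z, 0.8, 32, 40), 1)
  respiratory_rate <- round(rtnorm(n, 19 + z, 5, 4, 60))
  pulse_oximetry <- round(pmin(100, rtnorm(n, 96 - 1.5 * z, 5, 50, 104)))
  supplemental_oxygen <- rbinom(n, 1, plogis(0.2 + 0.8 * z))
  intubated_ed <- rbinom(n, 1, plogis(-1.2 + 1.0 * z))
  height <- round(rtnorm(n, 172, 10, 140, 210), 1)
  weight <- round(rtnorm(n, 83, 20, 40, 180), 1)
  bmi <- round(weight / (height / 100)^2, 1)
  signs_of_life <- ifelse(d$pulse_absent == 1, rbinom(n, 1, 0.25),
                          rbinom(n, 1, plogis(2.8 - 0.5 * z)))
  teaching_status <- sample(c("community", "nonteaching", "university"), n,
                            replace = TRUE, prob = c(0.35, 0.12, 0.53))
  acs_level <- sample(c("1", "2", "3"), n, replace = TRUE,
                      prob = c(0.59, 0.26, 0.15))
  chest_tube_1h <- rbinom(n, 1, plogis(qlogis(0.009) + 0.5 * z))
  d$rbc_transfusion_1h <- rbinom(n, 1, plogis(qlogis(0.199) + 0.9 * z))
  whole_blood_1h <- rbinom(n, 1, plogis(qlogis(0.016) + 0.6 * z))
  d$pelvic_fx <- rbinom(n, 1, plogis(qlogis(0.091) + 0.6 * z))
  d$femur_fx <- rbinom(n, 1, plogis(qlogis(0.021) + 0.4 * z))
  d$hemothorax <- rbinom(n, 1, plogis(qlogis(0.069) + 0.7 * z))
  d$pneumothorax <- rbinom(n, 1, plogis(qlogis(0.210) + 0.6 * z))
  d$thoracic_aorta_injury <- rbinom(n, 1, plogis(qlogis(0.024) + 0.7 * z))

  rbc_units_4h <- rpois(n, 2 + 4 * plogis(1.2 * z))
  los_days <- round(rgamma_det(n, shape = 1.2, scale = 6), 1)
  mechanism <- rep("blunt", n)
  transfer_in <- integer(n)

  # Planted inclusion-criterion failures: each record fails at most one
  # criterion (and satisfies all others), so filter-stage exclusion counts
  # match the planted counts exactly.
  fn <- config$filter_noise
  cats <- c("clean", names(fn))
  probs <- c(1 - sum(fn), as.numeric(fn))
  category <- cats[1 + findInterval(runif(n), cumsum(probs)[-length(probs)])]

  i <- category == "underage"
  if (any(i)) d$age_true[i] <- sample(8:16, sum(i), replace = TRUE)
  i <- category == "nonblunt"
  if (any(i)) {
    mechanism[i] <- sample(c("penetrating", "other"), sum(i), replace = TRUE,
                           prob = c(0.8, 0.2))
  }
  i <- category == "no_shock"
  if (any(i)) {
    d$sbp_unobtainable[i] <- 0L
    d$sbp_true[i] <- sample(95:135, sum(i), replace = TRUE)
    rbc_units_4h[i] <- pmin(rbc_units_4h[i], 3L)
  }
  i <- category == "transfer"
  if (any(i)) transfer_in[i] <- 1L
  # Rows that must qualify via the transfusion arm (SBP unobtainable or > 90)
  need_rbc <- category != "no_shock" &
    (d$sbp_unobtainable == 1 | d$sbp_true > 90)
  rbc_units_4h[need_rbc] <- pmax(rbc_units_4h[need_rbc], 4L)

  # Ground truth: potential outcomes, true propensity, oracle action.
  feat <- risk_features(d)
  lp_b <- linear_predictor(feat, config$baseline_coeffs)
  b0 <- calibrate_intercept(lp_b, config$baseline_mortality)
  p0 <- plogis(b0 + lp_b)

  sr <- config$subgroup_rule
  in_subgroup <- (!isTRUE(sr$pulse_absent) | d$pulse == 0) &
    d$gcs_true < sr$gcs_max &
    (d$sbp_unobtainable == 1 | d$sbp_true < sr$sbp_max)
  shift <- ifelse(in_subgroup, config$effect_benefit, config$effect_harm)
  # exact equality under a null effect (qlogis/plogis round-trips are not
  # bit-exact)
  p1 <- ifelse(shift == 0, p0, plogis(qlogis(p0) + shift))

  lp_t <- linear_predictor(feat, config$confounding_coeffs)
  c0 <- calibrate_intercept(lp_t, config$treatment_prevalence)
  pi_true <- plogis(c0 + lp_t)

  treated <- rbinom(n, 1, pi_true)
  death_24h <- rbinom(n, 1, ifelse(treated == 1, p1, p0))

  procedure_codes <- procedure_code_strings(n, treated)

  # Missingness masks (covariate values observed in the emitted table).
  age <- d$age_true
  age[category == "missing_age"] <- NA_integer_
  los_days[category == "missing_los"] <- NA_real_
  sbp <- ifelse(d$sbp_unobtainable == 1, NA_real_, d$sbp_true)
  gcs <- d$gcs_true

  cohort <- data.frame(
    id = seq_len(n), age = age, sex = factor(sex), mechanism = mechanism,
    transfer_in = transfer_in, los_days = los_days,
    rbc_units_4h = rbc_units_4h, sbp = sbp,
    sbp_unobtainable = d$sbp_unobtainable, pulse = d$pulse,
    temperature = temperature, gcs = gcs,
    respiratory_rate = respiratory_rate, pulse_oximetry = pulse_oximetry,
    supplemental_oxygen = supplemental_oxygen, intubated_ed = intubated_ed,
    height = height, weight = weight, bmi = bmi,
    signs_of_life = signs_of_life,
    teaching_status = factor(teaching_status),
    acs_level = factor(acs_level), chest_tube_1h = chest_tube_1h,
    rbc_transfusion_1h = d$rbc_transfusion_1h,
    whole_blood_1h = whole_blood_1h, pelvic_fx = d$pelvic_fx,
    femur_fx = d$femur_fx, hemothorax = d$hemothorax,
    pneumothorax = d$pneumothorax,
    thoracic_aorta_injury = d$thoracic_aorta_injury,
    procedure_codes = procedure_codes, reboa = treated,
    death_24h = death_24h, stringsAsFactors = FALSE
  )

  mr <- config$missing_rate
  if (length(mr)) {
    mar <- config$missing_mechanism == "MAR"
    for (v in names(mr)) {
      if (!v %in% names(cohort)) next
      # MAR modulation by severity with exact marginal rate:
      # E[2 plogis(z)] = 1 for z ~ N(0,1).
      p <- if (mar) pmin(0.95, mr[[v]] * 2 * plogis(z)) else rep(mr[[v]], n)
      mask <- runif(n) < p
      cohort[[v]][mask] <- NA
    }
  }

  truth <- data.frame(
    id = seq_len(n), p0 = p0, p1 = p1, pi_true = pi_true,
    oracle_action = as.integer(p1 < p0), in_subgroup = as.integer(in_subgroup)
  )

  structure(list(cohort = cohort, truth = truth, config = config),
            class = "synthetic_cohort")
}

# Gamma draws routed through runif/qgamma so the draw count is fixed.
rgamma_det <- function(n, shape, scale) {
  qgamma(runif(n), shape = shape, scale = scale)
}

procedure_code_strings <- function(n, treated) {
  out <- character(n)
  ti <- which(treated == 1)
  if (length(ti)) {
    out[ti] <- sprintf("%s@%.2f", sample(REBOA_CODES, length(ti),
                                         replace = TRUE),
                       runif(length(ti), 0, 4))
  }
  # Decoys among the untreated: a REBOA code outside the 4-h window or an
  # unrelated procedure code inside it; neither may label as treated.
  ui <- which(treated == 0)
  decoy <- ui[runif(length(ui)) < 0.03]
  if (length(decoy)) {
    late <- runif(length(decoy)) < 0.5
    out[decoy] <- ifelse(
      late,
      sprintf("%s@%.2f", sample(REBOA_CODES, length(decoy), replace = TRUE),
              runif(length(decoy), 4.01, 24)),
      sprintf("0W9G3ZZ@%.2f", runif(length(decoy), 0, 4))
    )
  }
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic blunt-trauma cohort: %d encounters, %d treated (%.2f%%), %d deaths (24 h)\n",
    nrow(x$cohort), sum(x$cohort$reboa),
    100 * mean(x$cohort$reboa), sum(x$cohort$death_24h)))
  cat(sprintf("Benefit subgroup: %d records (%.2f%%)\n",
              sum(x$truth$in_subgroup), 100 * mean(x$truth$in_subgroup)))
  invisible(x)
}

#' Gold-standard mortality of a policy under the synthetic ground truth
#'
#' Mean over records of the true potential-outcome mortality under each
#' record's assigned action.
#'
#' @param policy_actions Binary vector of actions, aligned with `truth` rows.
#' @param truth Ground-truth data.frame from [generate_cohort()] (columns
#'   `p0`, `p1`).
#' @return Mean true 24-h mortality in [0, 1] the policy would achieve.
#' @export
true_policy_value <- function(policy_actions, truth) {
  if (length(policy_actions) != nrow(truth)) {
    stop(sprintf("alignment error: %d actions for %d ground-truth rows",
                 length(policy_actions), nrow(truth)), call. = FALSE)
  }
  mean(ifelse(policy_actions == 1, truth$p1, truth$p0))
}

#' Write a synthetic cohort to disk
#'
#' Writes `cohort.csv` (missing values as empty fields), `ground_truth.csv`,
#' and a `config.json` sidecar recording the full generator configuration
#' including the seed.
#'
#' @param x A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_cohort <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("cohort.csv", "ground_truth.csv", "config.json"))
  write.csv(x$cohort, paths[1], row.names = FALSE, na = "")
  write.csv(x$truth, paths[2], row.names = FALSE, na = "")
  jsonlite::write_json(unclass(x$config), paths[3], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
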