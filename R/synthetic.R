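#' Synthetic questionnaire generator configuration
#'
#' The generator emulates the latent structure the downstream analysis
#' assumes: a 3-class latent risk-severity mixture. Each respondent belongs
#' to one of three burden classes (high/medium/low); symptom presence is
#' Bernoulli with a class-by-system propensity, severity codes 1-3 are drawn
#' from class-specific weights given presence, binary risk exposures shift
#' the presence propensity of exposed respondents (mean-centred, so class
#' burden targets are preserved), and protective-measure codes combine a
#' per-item usage probability with per-item effectiveness weights.
#'
#' @param n respondents.
#' @param seed master seed; section sub-streams use fixed offsets from it.
#' @param class_proportions 3 probabilities summing to 1.
#' @param class_system_propensity 3 x n_systems matrix of symptom-presence
#'   probabilities (rows: high/medium/low class).
#' @param class_severity_weights 3 x 3 matrix; row c is the distribution of
#'   severity codes 1..3 for class c given presence.
#' @param risk_exposure_probs per-risk-item exposure probabilities.
#' @param risk_effects per-risk-item standardized effect sizes on burden.
#' @param risk_effect_scale relative burden change per unit standardized
#'   effect (see the methods vignette).
#' @param protection_use_probs per-protection-item usage probabilities.
#' @param protection_effectiveness_weights n_protection x 3 matrix; row i is
#'   the distribution of effectiveness codes 1..3 among users of item i.
#' @param class_assignment `"stratified"` (largest-remainder class counts,
#'   order shuffled by the seed; the default) or `"multinomial"` (iid draws).
#' @param demographic_probs named list of per-level probabilities for each
#'   demographic variable.
#' @param cb the codebook the generated dataset must conform to.
#' @return A `ohs_generator_config`.
#' @export
generator_config <- function(n, seed, class_proportions,
                             class_system_propensity, class_severity_weights,
                             risk_exposure_probs, risk_effects,
                             protection_use_probs,
                             protection_effectiveness_weights,
                             risk_effect_scale = 0.4,
                             class_assignment = c("stratified", "multinomial"),
                             demographic_probs = NULL,
                             cb = default_codebook()) {
  class_assignment <- match.arg(class_assignment)
  class_proportions <- as.numeric(class_proportions)
  if (length(class_proportions) != 3 ||
      abs(sum(class_proportions) - 1) > 1e-9)
    stop_ohs("class_proportions must be 3 probabilities summing to 1")
  chk_prob <- function(p, what) {
    if (any(p < 0 | p > 1)) stop_ohs(what, " must lie in [0, 1]")
  }
  class_system_propensity <- as.matrix(class_system_propensity)
  if (!all(dim(class_system_propensity) == c(3, length(cb$systems))))
    stop_ohs("class_system_propensity must be 3 x ", length(cb$systems))
  chk_prob(class_system_propensity, "class_system_propensity")
  class_severity_weights <- as.matrix(class_severity_weights)
  if (!all(dim(class_severity_weights) == c(3, 3)) ||
      any(class_severity_weights < 0) ||
      any(abs(rowSums(class_severity_weights) - 1) > 1e-9))
    stop_ohs("class_severity_weights must be 3 proper distributions over codes 1..3")
  n_risk <- length(item_ids(cb, "risk"))
  n_prot <- length(item_ids(cb, "protection"))
  if (length(risk_exposure_probs) != n_risk ||
      length(risk_effects) != n_risk)
    stop_ohs("risk_exposure_probs and risk_effects must have length ", n_risk)
  chk_prob(risk_exposure_probs, "risk_exposure_probs")
  if (length(protection_use_probs) != n_prot)
    stop_ohs("protection_use_probs must have length ", n_prot)
  chk_prob(protection_use_probs, "protection_use_probs")
  protection_effectiveness_weights <- as.matrix(protection_effectiveness_weights)
  if (!all(dim(protection_effectiveness_weights) == c(n_prot, 3)) ||
      any(protection_effectiveness_weights < 0) ||
      any(abs(rowSums(protection_effectiveness_weights) - 1) > 1e-9))
    stop_ohs("protection_effectiveness_weights must be ", n_prot,
             " proper distributions over codes 1..3")
  dimnames(class_system_propensity) <- list(NULL, cb$systems)
  rownames(protection_effectiveness_weights) <- item_ids(cb, "protection")
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 class_proportions = class_proportions,
                 class_system_propensity = class_system_propensity,
                 class_severity_weights = class_severity_weights,
                 risk_exposure_probs = stats::setNames(
                   as.numeric(risk_exposure_probs), item_ids(cb, "risk")),
                 risk_effects = stats::setNames(
                   as.numeric(risk_effects), item_ids(cb, "risk")),
                 risk_effect_scale = risk_effect_scale,
                 protection_use_probs = stats::setNames(
                   as.numeric(protection_use_probs), item_ids(cb, "protection")),
                 protection_effectiveness_weights = protection_effectiveness_weights,
                 class_assignment = class_assignment,
                 demographic_probs = demographic_probs,
                 codebook = cb),
            class = "ohs_generator_config")
}

# Distribution over severity/effectiveness codes 1..3 with mean m in [1,3]:
# 1 + Binomial(2, (m-1)/2), i.e. weights ((1-a/2)^2, a(1-a/2), (a/2)^2)
# with a = m-1. Used to turn printed mean-effectiveness targets into code
# distributions.
code_weights_for_mean <- function(m) {
  if (any(m < 1 | m > 3)) stop_ohs("target mean code must lie in [1, 3]")
  a <- (m - 1) / 2
  cbind((1 - a)^2, 2 * a * (1 - a), a^2)
}

#' Calibrate class-by-system propensities to burden targets
#'
#' For each class, scales a relative per-system propensity pattern by a
#' multiplier found by bisection so the expected total symptom burden
#' (sum over items of presence probability times expected severity) hits the
#' class target. Propensities are capped at 1, which the search accounts for.
#'
#' @param targets length-3 expected total symptom burden per class.
#' @param severity_weights 3 x 3 matrix of severity-code distributions.
#' @param system_pattern relative propensity pattern over the systems
#'   (any positive scale).
#' @param items_per_system item count per system, aligned with
#'   `system_pattern`.
#' @param tol absolute tolerance on the expected burden.
#' @return 3 x n_systems propensity matrix.
#' @export
calibrate_propensities <- function(targets, severity_weights, system_pattern,
                                   items_per_system, tol = 1e-3) {
  system_pattern <- as.numeric(system_pattern)
  if (any(system_pattern < 0)) stop_ohs("system_pattern must be nonnegative")
  e_sev <- as.numeric(severity_weights %*% (1:3))
  expected_tsb <- function(mult, c) {
    sum(items_per_system * pmin(1, mult * system_pattern)) * e_sev[c]
  }
  out <- matrix(0, 3, length(system_pattern))
  for (c in 1:3) {
    if (targets[c] <= 0) next
    max_tsb <- sum(items_per_system) * 3
    if (all(system_pattern == 0) || targets[c] > expected_tsb(Inf, c) + tol)
      stop_ohs("class ", c, " burden target ", targets[c],
               " is unattainable under the given pattern (max ",
               round(expected_tsb(Inf, c), 2), ", ceiling ", max_tsb, ")")
    lo <- 0; hi <- 1
    while (expected_tsb(hi, c) < targets[c]) hi <- hi * 2
    while (hi - lo > 1e-12 && abs(expected_tsb((lo + hi) / 2, c) - targets[c]) > tol) {
      mid <- (lo + hi) / 2
      if (expected_tsb(mid, c) < targets[c]) lo <- mid else hi <- mid
    }
    out[c, ] <- pmin(1, (lo + hi) / 2 * system_pattern)
  }
  out
}

#' Default generator configuration
#'
#' Study conditions of the emulated cohort: n = 62, latent class shares
#' (0.21, 0.40, 0.39), class mean total symptom burden calibrated to
#' (32.08, 12.44, 2.71), the ten published risk-factor exposure prevalences
#' (e.g. high-altitude hypoxia 0.597) with the remaining items at 0.1, and
#' the ten published protective-measure implementation rates (e.g. health
#' education 0.9032) with the remaining items at 0.4. The per-system
#' propensity pattern follows the published system-prevalence profile; the
#' demographic distributions follow the published cohort table.
#'
#' @param n respondents (default 62).
#' @param seed master seed (default 42).
#' @return A `ohs_generator_config`.
#' @export
default_generator_config <- function(n = 62, seed = 42) {
  cb <- default_codebook()
  # Relative system propensity pattern: published per-system prevalences.
  pattern <- c("Neurological" = 0.677, "Respiratory" = 0.645,
               "Gastrointestinal" = 0.484, "Endocrine" = 0.419,
               "Urological" = 0.145, "Musculoskeletal" = 0.645,
               "ENT & Oral" = 0.613, "Dermatological" = 0.258,
               "Cardiovascular" = 0.194, "Psychological" = 0.435)
  pattern <- pattern[cb$systems]
  counts <- table(factor(item_domains(cb, "symptom"), levels = cb$systems))
  sev_w <- rbind(c(0.50, 0.30, 0.20),   # high-burden class, mean code 1.7
                 c(0.70, 0.25, 0.05),   # medium, mean 1.35
                 c(0.90, 0.10, 0.00))   # low, mean 1.1
  prop <- calibrate_propensities(c(32.08, 12.44, 2.71), sev_w, pattern,
                                 as.numeric(counts))

  risk_ids <- item_ids(cb, "risk")
  risk_p <- stats::setNames(rep(0.1, length(risk_ids)), risk_ids)
  risk_e <- stats::setNames(rep(0.1, length(risk_ids)), risk_ids)
  published <- rbind(
    c("risk_high_altitude_hypoxia", 0.597, 0.70),
    c("risk_irregular_work_rest_schedule", 0.2903, 0.72),
    c("risk_low_humidity", 0.4839, 0.534),
    c("risk_poor_equipment_design", 0.129, 0.886),
    c("risk_inadequate_illumination", 0.1612, 0.662),
    c("risk_excessive_workload_training", 0.129, 0.57),
    c("risk_dust_exposure", 0.1613, 0.52),
    c("risk_microwave_radiation", 0.1613, 0.652),
    c("risk_awkward_postures_movements", 0.0968, 0.69),
    c("risk_low_atmospheric_pressure", 0.3871, 0.49))
  risk_p[published[, 1]] <- as.numeric(published[, 2])
  risk_e[published[, 1]] <- as.numeric(published[, 3])

  prot_ids <- item_ids(cb, "protection")
  prot_p <- stats::setNames(rep(0.4, length(prot_ids)), prot_ids)
  mpe_target <- stats::setNames(rep(1.4, length(prot_ids)), prot_ids)
  tab3 <- rbind(
    c("prot_health_education", 0.9032, 1.50),
    c("prot_scientific_training_protocols", 0.8226, 1.45),
    c("prot_rational_shift_scheduling", 0.8387, 1.31),
    c("prot_ventilation", 0.7903, 1.35),
    c("prot_hazard_protection_education", 0.7419, 1.43),
    c("prot_regular_health_examinations", 0.7742, 1.31),
    c("prot_noise_reduction", 0.4677, 1.86),
    c("prot_publicity_and_enforcement_of_health_standards", 0.6613, 1.34),
    c("prot_monitoring_of_influencing_factors", 0.5323, 1.58),
    c("prot_air_purification", 0.4677, 1.66))
  prot_p[tab3[, 1]] <- as.numeric(tab3[, 2])
  mpe_target[tab3[, 1]] <- as.numeric(tab3[, 3])

  demo_probs <- list(
    age_band = c("<25" = 16, "26-30" = 23, "31-35" = 8, ">35" = 15) / 62,
    gender = c(Male = 1, Female = 0),
    marital_status = c(Married = 34, Other = 28) / 62,
    education = c("Associate degree" = 6, "Bachelor degree" = 55,
                  "Master or PhD" = 1) / 62,
    smoking = c(No = 33, Yes = 29) / 62,
    drinking = c(No = 39, Yes = 23) / 62)

  generator_config(n = n, seed = seed,
                   class_proportions = c(0.21, 0.40, 0.39),
                   class_system_propensity = prop,
                   class_severity_weights = sev_w,
                   risk_exposure_probs = risk_p,
                   risk_effects = risk_e,
                   protection_use_probs = prot_p,
                   protection_effectiveness_weights =
                     code_weights_for_mean(mpe_target),
                   demographic_probs = demo_probs,
                   cb = cb)
}

# Largest-remainder apportionment of n into round(n * p) class counts.
stratified_counts <- function(n, p) {
  base <- floor(n * p)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * p - base
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Generate a synthetic survey dataset
#'
#' Draws a latent burden class per respondent, then symptom presence and
#' severity, risk exposures (shifting the presence propensity of exposed
#' respondents by a mean-centred multiplicative term), protective-measure
#' usage and effectiveness codes, and demographics. Identical configurations
#' yield identical datasets. The true class labels are returned in
#' `$latent_class` (simulation ground truth; not part of the CSV round trip).
#'
#' @param config a `ohs_generator_config`.
#' @return An `ohs_survey`.
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "ohs_generator_config"))
  cb <- config$codebook
  n <- config$n
  sym_ids <- item_ids(cb, "symptom")
  risk_ids <- item_ids(cb, "risk")
  prot_ids <- item_ids(cb, "protection")
  sys_of_item <- match(item_domains(cb, "symptom"), cb$systems)

  # Latent classes (sub-stream offset 0).
  cls <- with_local_seed(config$seed, {
    if (config$class_assignment == "stratified") {
      counts <- stratified_counts(n, config$class_proportions)
      sample(rep(1:3, counts))
    } else {
      sample(1:3, n, replace = TRUE, prob = config$class_proportions)
    }
  })

  # Risk exposures (offset 1).
  risks <- with_local_seed(config$seed + 1L, {
    matrix(stats::rbinom(n * length(risk_ids), 1,
                         rep(config$risk_exposure_probs, each = n)),
           n, length(risk_ids), dimnames = list(NULL, risk_ids))
  })

  # Mean-centred exposure shift on symptom-presence propensity.
  shift <- as.numeric(
    (risks - matrix(config$risk_exposure_probs, n, length(risk_ids),
                    byrow = TRUE)) %*% config$risk_effects) *
    config$risk_effect_scale
  mult <- pmax(0, 1 + shift)

  base_p <- config$class_system_propensity[cls, , drop = FALSE]

  # Symptoms (offset 2): presence then severity given presence.
  symptoms <- with_local_seed(config$seed + 2L, {
    p <- pmin(1, base_p[, sys_of_item, drop = FALSE] * mult)
    pres <- matrix(stats::rbinom(length(p), 1, p), n, length(sym_ids))
    sev <- matrix(0L, n, length(sym_ids))
    for (c in 1:3) {
      idx <- which(pres == 1 & matrix(cls == c, n, length(sym_ids)))
      if (length(idx))
        sev[idx] <- sample(1:3, length(idx), replace = TRUE,
                           prob = config$class_severity_weights[c, ])
    }
    dimnames(sev) <- list(NULL, sym_ids)
    sev
  })

  # Protections (offset 3).
  protections <- with_local_seed(config$seed + 3L, {
    use <- matrix(stats::rbinom(n * length(prot_ids), 1,
                                rep(config$protection_use_probs, each = n)),
                  n, length(prot_ids))
    eff <- matrix(0L, n, length(prot_ids))
    for (j in seq_along(prot_ids)) {
      users <- which(use[, j] == 1)
      if (length(users))
        eff[users, j] <- sample(1:3, length(users), replace = TRUE,
                                prob = config$protection_effectiveness_weights[j, ])
    }
    dimnames(eff) <- list(NULL, prot_ids)
    eff
  })

  # Demographics (offset 4).
  demo_ids <- item_ids(cb, "demographic")
  demographics <- with_local_seed(config$seed + 4L, {
    cols <- lapply(demo_ids, function(id) {
      pr <- config$demographic_probs[[id]]
      if (is.null(pr)) {
        lev <- cb$demographic_levels[[id]]
        pr <- stats::setNames(rep(1 / length(lev), length(lev)), lev)
      }
      sample(names(pr), n, replace = TRUE, prob = pr)
    })
    stats::setNames(as.data.frame(cols, stringsAsFactors = FALSE), demo_ids)
  })

  new_survey(sprintf("R%03d", seq_len(n)), symptoms, risks, protections,
             demographics, latent_class = cls)
}
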