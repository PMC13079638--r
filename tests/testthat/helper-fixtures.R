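# Shared fixtures, built in code at test time.

# Miniature instrument: 2 systems x 2-3 symptom items, 2 risk items,
# 2 protection items, 1 demographic variable.
tiny_codebook <- function() {
  items <- data.frame(
    id = c("s_a1", "s_a2", "s_b1", "s_b2", "s_b3",
           "r_x", "r_y", "p_u", "p_v", "marital_status"),
    label = c("a1", "a2", "b1", "b2", "b3", "x", "y", "u", "v",
              "Marital status"),
    section = c(rep("symptom", 5), rep("risk", 2), rep("protection", 2),
                "demographic"),
    domain = c("A", "A", "B", "B", "B", "Haz", "Haz", "Mgmt", "Mgmt",
               "marital_status"),
    scale_min = c(rep(0L, 9), NA), scale_max = c(rep(3L, 5), 1L, 1L, 3L, 3L, NA),
    stringsAsFactors = FALSE)
  codebook(items, systems = c("A", "B"), risk_categories = "Haz",
           protection_categories = "Mgmt",
           demographic_levels = list(marital_status = c("Married", "Other")))
}

tiny_survey <- function(cb = tiny_codebook(), n = 4) {
  sym <- matrix(c(1L, 0L, 2L, 0L, 3L,
                  0L, 0L, 0L, 0L, 0L,
                  1L, 1L, 0L, 2L, 0L,
                  0L, 2L, 1L, 0L, 1L), nrow = 4, byrow = TRUE,
                dimnames = list(NULL, item_ids_of(cb, "symptom")))
  rsk <- matrix(c(1L, 0L, 0L, 0L, 1L, 1L, 0L, 1L), nrow = 4,
                dimnames = list(NULL, item_ids_of(cb, "risk")))
  prt <- matrix(c(2L, 0L, 1L, 3L, 0L, 0L, 2L, 1L), nrow = 4,
                dimnames = list(NULL, item_ids_of(cb, "protection")))
  demo <- data.frame(marital_status = c("Married", "Other", "Married", "Other"),
                     stringsAsFactors = FALSE)
  ohsurvey:::new_survey(paste0("R", 1:4), sym, rsk, prt, demo)
}

item_ids_of <- function(cb, section) cb$items$id[cb$items$section == section]

# High-separation generator configuration for class-recovery checks: three
# classes with flat, strongly separated presence propensities.
separated_config <- function(n = 62, seed = 1) {
  cb <- default_codebook()
  n_sys <- length(cb$systems)
  generator_config(
    n = n, seed = seed,
    class_proportions = c(0.21, 0.40, 0.39),
    class_system_propensity = rbind(rep(0.85, n_sys), rep(0.35, n_sys),
                                    rep(0.03, n_sys)),
    class_severity_weights = rbind(c(0.2, 0.3, 0.5), c(0.7, 0.25, 0.05),
                                   c(0.9, 0.1, 0)),
    risk_exposure_probs = rep(0.2, 47), risk_effects = rep(0, 47),
    protection_use_probs = rep(0.5, 26),
    protection_effectiveness_weights =
      ohsurvey:::code_weights_for_mean(rep(1.5, 26)),
    cb = cb)
}

# Published composite protective-effectiveness table: implementation rate
# (fraction), mean effectiveness among users, and the printed 2-decimal
# composite, for the ten top-ranked measures.
published_cpe_rows <- function() {
  data.frame(
    measure = c("health education", "scientific training protocols",
                "rational shift scheduling", "ventilation",
                "hazard protection education", "regular health examinations",
                "noise reduction",
                "publicity and enforcement of health standards",
                "monitoring of influencing factors", "air purification"),
    ir = c(0.9032, 0.8226, 0.8387, 0.7903, 0.7419, 0.7742, 0.4677, 0.6613,
           0.5323, 0.4677),
    mpe = c(1.50, 1.45, 1.31, 1.35, 1.43, 1.31, 1.86, 1.34, 1.58, 1.66),
    cpe = c(0.66, 0.62, 0.60, 0.59, 0.58, 0.57, 0.56, 0.53, 0.53, 0.52),
    stringsAsFactors = FALSE)
}
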