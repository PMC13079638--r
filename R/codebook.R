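#' Questionnaire codebook
#'
#' A codebook declares every questionnaire item (id, label, section, domain,
#' legal value range) together with the ordered lists of physiological
#' systems, hazard categories, and control-hierarchy levels that the domains
#' reference. All scoring functions index item columns through the codebook,
#' so item order is codebook order regardless of file column order.
#'
#' @param items data.frame with columns `id`, `label`, `section` (one of
#'   `"symptom"`, `"risk"`, `"protection"`, `"demographic"`), `domain`,
#'   `scale_min`, `scale_max`.
#' @param systems ordered character vector of physiological-system names.
#' @param risk_categories ordered character vector of hazard categories.
#' @param protection_categories ordered character vector of control-hierarchy
#'   levels.
#' @param demographic_levels named list mapping each demographic item id to
#'   its controlled vocabulary of levels.
#' @param expected_counts named integer vector giving the required number of
#'   symptom/risk/protection items, or `NULL` to accept any instrument size.
#' @return An object of class `ohs_codebook`.
#' @export
codebook <- function(items, systems, risk_categories, protection_categories,
                     demographic_levels = list(), expected_counts = NULL) {
  cb <- structure(
    list(items = as.data.frame(items, stringsAsFactors = FALSE),
         systems = as.character(systems),
         risk_categories = as.character(risk_categories),
         protection_categories = as.character(protection_categories),
         demographic_levels = demographic_levels,
         expected_counts = expected_counts),
    class = "ohs_codebook")
  validate_codebook(cb)
}

#' Validate a codebook
#'
#' Checks id uniqueness, section/domain consistency, scale ranges
#' (symptoms 0..3, risks 0..1, protections 0..3), and — when the codebook
#' declares expected section sizes — the item counts. Errors list every
#' offending item id.
#'
#' @param cb an `ohs_codebook`.
#' @return `cb`, invisibly validated.
#' @export
validate_codebook <- function(cb) {
  it <- cb$items
  req <- c("id", "label", "section", "domain", "scale_min", "scale_max")
  miss <- setdiff(req, names(it))
  if (length(miss))
    stop_ohs("codebook items table lacks columns: ", paste(miss, collapse = ", "))

  dup <- unique(it$id[duplicated(it$id)])
  if (length(dup))
    stop_ohs("duplicate item ids in codebook: ", paste(dup, collapse = ", "))

  bad_sec <- unique(it$id[!it$section %in%
                            c("symptom", "risk", "protection", "demographic")])
  if (length(bad_sec))
    stop_ohs("unknown section for items: ", paste(bad_sec, collapse = ", "))

  chk_domain <- function(section, allowed, what) {
    sub <- it[it$section == section, ]
    bad <- unique(sub$id[!sub$domain %in% allowed])
    if (length(bad))
      stop_ohs(section, " items mapped outside the declared ", what, ": ",
               paste(bad, collapse = ", "))
  }
  chk_domain("symptom", cb$systems, "physiological systems")
  chk_domain("risk", cb$risk_categories, "hazard categories")
  chk_domain("protection", cb$protection_categories, "control levels")

  chk_range <- function(section, lo, hi) {
    sub <- it[it$section == section, ]
    bad <- unique(sub$id[sub$scale_min != lo | sub$scale_max != hi])
    if (length(bad))
      stop_ohs(section, " items must use scale ", lo, "..", hi,
               "; offending ids: ", paste(bad, collapse = ", "))
  }
  chk_range("symptom", 0L, 3L)
  chk_range("risk", 0L, 1L)
  chk_range("protection", 0L, 3L)

  if (!is.null(cb$expected_counts)) {
    for (sec in names(cb$expected_counts)) {
      n_have <- sum(it$section == sec)
      n_want <- cb$expected_counts[[sec]]
      if (n_have != n_want)
        stop_ohs("codebook declares ", n_want, " ", sec, " items but has ",
                 n_have)
    }
  }
  invisible(cb)
}

item_ids <- function(cb, section) cb$items$id[cb$items$section == section]

item_domains <- function(cb, section) {
  sub <- cb$items[cb$items$section == section, ]
  stats::setNames(sub$domain, sub$id)
}

slug <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_|_$", "", x)
}

#' Default 66/47/26-item codebook
#'
#' Builds the packaged instrument: 66 symptom items on a 0-3 severity scale
#' grouped into 10 physiological systems, 47 binary workplace risk-factor
#' items in 6 hazard categories, 26 protective-measure items coded 0-3 in the
#' 3 control-hierarchy levels (management control, engineering control,
#' personal protective equipment), and 6 categorical demographic variables.
#'
#' @return An `ohs_codebook`.
#' @export
default_codebook <- function() {
  sys_items <- list(
    "Neurological" = c("memory impairment", "insomnia", "headache",
                       "excessive dreaming", "fatigue", "dizziness",
                       "drowsiness", "difficulty concentrating",
                       "numbness in limbs", "tremor"),
    "Respiratory" = c("cough", "shortness of breath", "dyspnea",
                      "chest tightness", "sputum production", "wheezing",
                      "frequent colds"),
    "Gastrointestinal" = c("decreased appetite", "abdominal pain", "bloating",
                           "constipation", "diarrhea", "nausea"),
    "Endocrine" = c("weight gain", "weight loss", "heat intolerance",
                    "excessive thirst", "excessive sweating"),
    "Urological" = c("frequent urination", "urinary urgency", "nocturia",
                     "painful urination"),
    "Musculoskeletal" = c("neck pain", "lower back pain", "shoulder pain",
                          "knee pain", "wrist pain", "muscle soreness",
                          "joint stiffness", "muscle cramps", "elbow pain",
                          "hip pain", "ankle pain", "muscle weakness",
                          "back stiffness"),
    "ENT & Oral" = c("oral ulcers", "tinnitus", "gum bleeding", "toothache",
                     "dry throat", "hearing loss", "hoarseness", "nosebleed"),
    "Dermatological" = c("hair loss", "dry skin", "skin rash", "itching",
                         "acne"),
    "Cardiovascular" = c("palpitations", "chest pain", "irregular heartbeat",
                         "cold extremities"),
    "Psychological" = c("anxiety", "nervousness", "depressed mood",
                        "irritability"))

  risk_items <- list(
    "Physical" = c("high-altitude hypoxia", "low atmospheric pressure",
                   "low humidity", "ultraviolet radiation", "high temperature",
                   "low temperature", "large diurnal temperature variation",
                   "strong wind", "noise", "vibration",
                   "inadequate illumination", "glare", "inadequate heating",
                   "abrupt weather changes"),
    "Ergonomic & Organizational" = c("irregular work-rest schedule",
                                     "excessive workload/training",
                                     "poor equipment design",
                                     "awkward postures/movements",
                                     "poor ergonomics in operation",
                                     "enclosed work environment",
                                     "prolonged sitting",
                                     "prolonged visual display work",
                                     "night shifts", "insufficient rest breaks",
                                     "monotonous tasks", "time pressure"),
    "Dust & Hazardous Gases" = c("dust exposure", "exhaust gases",
                                 "fuel vapors", "carbon monoxide", "ozone",
                                 "smoke"),
    "Radiological" = c("microwave radiation",
                       "ultra-high frequency electromagnetic fields",
                       "radar radiation", "radiofrequency radiation",
                       "ionizing radiation"),
    "Chemical" = c("organic solvents", "lubricants", "cleaning agents",
                   "battery electrolytes", "paints and coatings"),
    "Biological" = c("bacterial exposure", "viral exposure", "mold exposure",
                     "insect vectors", "rodent exposure"))

  prot_items <- list(
    "Management control" = c("health education", "scientific training protocols",
                             "rational shift scheduling",
                             "hazard protection education",
                             "publicity and enforcement of health standards",
                             "monitoring of influencing factors",
                             "regular safety inspections",
                             "workload management",
                             "psychological counselling services"),
    "Engineering control" = c("ventilation", "noise reduction",
                              "air purification", "oxygen supply equipment",
                              "ergonomic workstation design",
                              "lighting improvement", "temperature control",
                              "humidification"),
    "Personal protective equipment" = c("regular health examinations",
                                        "respiratory protection",
                                        "hearing protection", "cooling devices",
                                        "protective eyewear", "sunscreen",
                                        "protective clothing",
                                        "protective gloves",
                                        "personal oxygen masks"))

  build <- function(lst, section, prefix, lo, hi) {
    do.call(rbind, lapply(names(lst), function(dom) {
      data.frame(id = paste0(prefix, "_", slug(lst[[dom]])),
                 label = lst[[dom]], section = section, domain = dom,
                 scale_min = lo, scale_max = hi, stringsAsFactors = FALSE)
    }))
  }

  demo_levels <- list(
    age_band = c("<25", "26-30", "31-35", ">35"),
    gender = c("Male", "Female"),
    marital_status = c("Married", "Other"),
    education = c("Associate degree", "Bachelor degree", "Master or PhD"),
    smoking = c("No", "Yes"),
    drinking = c("No", "Yes"))
  demo <- data.frame(id = names(demo_levels),
                     label = c("Age (years)", "Gender", "Marital status",
                               "Educational level", "Smoking", "Drinking"),
                     section = "demographic", domain = names(demo_levels),
                     scale_min = NA_integer_, scale_max = NA_integer_,
                     stringsAsFactors = FALSE)

  items <- rbind(build(sys_items, "symptom", "sym", 0L, 3L),
                 build(risk_items, "risk", "risk", 0L, 1L),
                 build(prot_items, "protection", "prot", 0L, 3L),
                 demo)

  codebook(items,
           systems = names(sys_items),
           risk_categories = names(risk_items),
           protection_categories = names(prot_items),
           demographic_levels = demo_levels,
           expected_counts = c(symptom = 66L, risk = 47L, protection = 26L))
}

#' Read a codebook from JSON or YAML
#'
#' The dialect is chosen by file extension (`.json`, `.yaml`/`.yml`). The
#' packaged default codebook is at
#' `system.file("extdata", "codebook_default.json", package = "ohsurvey")`.
#'
#' @param path path to the codebook file.
#' @return A validated `ohs_codebook`.
#' @export
load_codebook <- function(path) {
  if (!file.exists(path)) stop_ohs("codebook file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
             error = function(e) stop_ohs("malformed JSON codebook '", path,
                                          "': ", conditionMessage(e)))
  } else if (ext %in% c("yaml", "yml")) {
    tryCatch(yaml::read_yaml(path),
             error = function(e) stop_ohs("malformed YAML codebook '", path,
                                          "': ", conditionMessage(e)))
  } else {
    stop_ohs("unsupported codebook extension '.", ext, "' (use json or yaml)")
  }
  items <- as.data.frame(raw$items, stringsAsFactors = FALSE)
  items$scale_min <- suppressWarnings(as.integer(items$scale_min))
  items$scale_max <- suppressWarnings(as.integer(items$scale_max))
  counts <- raw$expected_counts
  if (!is.null(counts)) counts <- unlist(counts)
  codebook(items, raw$systems, raw$risk_categories, raw$protection_categories,
           demographic_levels = lapply(raw$demographic_levels %||% list(),
                                       as.character),
           expected_counts = counts)
}

#' Write a codebook to JSON or YAML
#'
#' @param cb an `ohs_codebook`.
#' @param path destination; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_codebook <- function(cb, path) {
  payload <- list(items = cb$items, systems = cb$systems,
                  risk_categories = cb$risk_categories,
                  protection_categories = cb$protection_categories,
                  demographic_levels = cb$demographic_levels,
                  expected_counts = as.list(cb$expected_counts))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(payload, path)
  } else {
    stop_ohs("unsupported codebook extension '.", ext, "'")
  }
  invisible(path)
}

#' @export
print.ohs_codebook <- function(x, ...) {
  n <- table(factor(x$items$section,
                    levels = c("symptom", "risk", "protection", "demographic")))
  cat("<ohs_codebook> ", n[["symptom"]], " symptom / ", n[["risk"]],
      " risk / ", n[["protection"]], " protection items; ",
      length(x$systems), " systems\n", sep = "")
  invisible(x)
}
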