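Package: ohsurvey
Title: Occupational-Health Questionnaire Scoring, Symptom Networks, and Risk Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cross-sectional occupational-health
    questionnaires built around a three-section instrument: symptom severity
    items on a 0-3 Likert scale grouped into physiological systems, binary
    workplace risk-factor items, and 0-3 coded protective-measure items.
    Computes item and system prevalence, symptom severity and total symptom
    burden, symptom co-occurrence networks with topological metrics,
    composite weighted risk-factor importance scores (exposure prevalence,
    Cohen's d effect size on burden, breadth of affected systems by
    Mann-Whitney tests), composite protective-effectiveness scores
    (implementation rate and mean effectiveness), K-means risk
    stratification with elbow-method model selection, Cronbach's alpha
    reliability with Feldt confidence intervals, and noncentral-t power and
    sample-size calculations. Includes a latent-class synthetic-data
    generator so every stage is testable without respondent-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
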