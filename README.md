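# ohsurvey

Scoring and risk stratification for cross-sectional occupational-health
questionnaires.

Occupational-health surveys of specialized workforces (aircrew, remote
operators, high-altitude personnel) typically combine three instruments in
one questionnaire: symptom severity items on a 0–3 Likert scale grouped
into physiological systems, dichotomous workplace risk-factor items, and
0–3 coded ratings of protective-measure effectiveness. `ohsurvey` turns
such respondent-level tables into the standard analysis surface for this
design:

* **Symptom metrics** — item prevalence *Pᵢ*, per-system prevalence
  *PrevS*, symptomatic-only severity *S̄ⱼ*, and total symptom burden
  *TSBₖ* (row sum of severity codes);
* **Symptom co-occurrence network** — nodes are prevalent symptoms, edges
  weighted by co-occurrence counts with only the top 30% of edges by
  weight retained; density, clustering, degree and betweenness centrality;
* **Composite risk score** —
  `CRS = 0.5·|ES|/max|ES| + 0.3·BAPS/10 + 0.2·EP`, where EP is exposure
  prevalence, ES the Cohen's *d* of burden by exposure (pooled SD), and
  BAPS the number of systems whose burden differs by exposure under a
  Mann–Whitney U test at p < 0.05;
* **Composite protective effectiveness** —
  `CPE = 0.4·IR + 0.6·MPE/3` from the implementation rate and the mean
  effectiveness among users;
* **Risk stratification** — population-divisor Z-scores of the 10 system
  burdens, seeded k-means (Lloyd, best of 10 restarts) with elbow-method
  model selection, and cluster profiles renumbered so cluster 0 is the
  highest-burden subgroup;
* **Reliability and power** — Cronbach's alpha with Feldt 95% intervals
  per system; noncentral-*t* power and sample-size calculations.

A latent-class synthetic-data generator (three burden classes with
calibrated mean burdens 32.08/12.44/2.71 and shares 0.21/0.40/0.39 at
n = 62) makes every stage testable without respondent-level data. See the
methods vignette (`vignettes/occupational-health-scoring.Rmd`) for the
models, parameter defaults, and design rationale.

## Worked example

```r
library(ohsurvey)

cfg <- default_generator_config(seed = 42)   # n = 62 study conditions
ds  <- generate_survey(cfg)
ds
#> <ohs_survey> n = 62 respondents; 66 symptom / 47 risk / 26 protection items

sysprev <- system_prevalence(ds$symptoms, cfg$codebook)
head(sysprev[order(-sysprev$prevalence), ], 3)
#>            system n_affected prevalence
#> 1    Neurological         44  0.7096774
#> 6 Musculoskeletal         43  0.6935484
#> 2     Respiratory         36  0.5806452

cooccurrence_network(ds$symptoms, cfg$codebook)
#> <ohs_network> 8 nodes, 11 edges, density 0.393, avg degree 2.75

head(rank_risk_factors(ds, cfg$codebook)[, c("label", "ep", "es", "baps", "crs")], 3)
#>                   label         ep        es baps       crs
#> 1 poor equipment design 0.09677419 1.8662423    8 0.7593548
#> 2 high-altitude hypoxia 0.67741935 0.5888130    2 0.3532375
#> 3           strong wind 0.08064516 0.6659191    3 0.2845408

head(rank_measures(ds, cfg$codebook)[, c("label", "ir", "mpe", "cpe")], 3)
#>                       label        ir      mpe       cpe
#> 1          health education 0.9354839 1.637931 0.7017798
#> 2               ventilation 0.8387097 1.403846 0.6162531
#> 3 rational shift scheduling 0.8225806 1.352941 0.5996205

required_sample_size(target_power = 0.80, d = 0.5, alpha = 0.05)
#> [1] 128
```

Reading the output: 71% of this synthetic cohort report at least one
neurological symptom; the retained co-occurrence graph keeps 8 prevalent
symptoms and the top-weighted 30% of their co-occurrence edges; "poor
equipment design" tops the risk ranking because its exposed respondents
carry a 1.87-SD higher burden spread across 8 of 10 systems; "health
education" leads the protection ranking through near-universal uptake; and
detecting a medium effect (d = 0.5) at 80% power needs 128 participants
(64 per group).

The whole pipeline — loading or generating data, all tables, network
exports, clustering, reliability and power reports, plus a JSON manifest
with the configuration hash — runs as one call:

```r
run_pipeline(pipeline_config(out_dir = "bundle", synthetic = TRUE, seed = 42))
```

A thin command-line wrapper over the same functions is at
`inst/cli/ohsurvey.R` (`run`, `synth`, `validate` subcommands).

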