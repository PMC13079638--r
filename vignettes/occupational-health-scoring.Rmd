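---
title: "Scoring occupational-health questionnaires: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring occupational-health questionnaires: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohsurvey)
```

`ohsurvey` implements a complete scoring pipeline for a three-section
cross-sectional occupational-health instrument: symptom severity items on a
0–3 Likert scale (0 = none, 1 = mild, 2 = moderate, 3 = severe) grouped into
10 physiological systems, dichotomous workplace risk-factor items
(0 = absent, 1 = present) in six hazard categories, and protective-measure
items coded 0–3 (0 = not used, then poor/moderate/high effectiveness) across
the three control-hierarchy levels (management controls, engineering
controls, personal protective equipment). This vignette documents the
statistical model behind each stage, the tunable parameters, the numerical
choices, and what the synthetic-data generator does and does not emulate.

## Symptom metrics

For an $n \times m$ severity matrix $X$ with codes $x_{ki} \in \{0,1,2,3\}$:

* **Item prevalence** $P_i = \frac{1}{n}\sum_k \mathbf{1}[x_{ki} \ge 1]$.
  Presence is code $\ge 1$ throughout the package, because the scale defines
  0 as "none".
* **System prevalence** $\mathrm{PrevS}_s$: the fraction of respondents with
  at least one positive item in system $s$; multiple symptoms in the same
  system count a respondent once.
* **Severity score** $\bar{S}_j$: the mean code among respondents *reporting*
  item $j$ (the symptomatic-only mean), so $\bar{S}_j \in [1, 3]$ and is
  undefined (reported `NA`, with a warning) when nobody reports the item.
  The symptomatic-only denominator is deliberate: severity answers "how bad
  is it for those who have it", independently of how common it is, and keeps
  the score on the interpretable 1–3 scale of the response labels.
* **Total symptom burden** $\mathrm{TSB}_k = \sum_i x_{ki}$, bounded by
  $3m$ (198 for the default 66-item instrument). Per-system burden sums
  conserve the total exactly, a property the test suite asserts.

## Co-occurrence network

Nodes are symptoms whose prevalence reaches `node_min_prevalence`
(default 0.20); the default admits roughly the top-20 prevalence band of a
typical cohort while keeping the graph readable. Edge weight is the count
of respondents reporting both endpoints. Among candidate edges (weight
$\ge 1$), the top `edge_quantile` fraction by weight is retained, with
count $\lceil q \cdot E_\text{cand} \rceil$ (default $q = 0.30$). Ties are
broken by the larger sum of endpoint occurrence counts, then by
lexicographic item-id pair — a total order, so raising the quantile can
only add edges (nestedness, property-tested). Nodes isolated after
filtering are dropped.

Metrics on the retained graph: density $2E/(N(N-1))$, average degree
$2E/N$, average local clustering coefficient (triangles over possible
wedges per node, 0 for degree $< 2$), normalized degree and betweenness
centrality. Betweenness is computed on the *unweighted* retained graph:
edge weights size the drawing, but the hub question — how often a symptom
lies on shortest paths between others — is topological. The spring layout
offered by `export_network()` is presentation only, seeded for
reproducibility, and never enters any metric.

## Composite risk-factor importance

For each binary risk factor:

* **Exposure prevalence** $\mathrm{EP}$ — the column mean.
* **Effect size** $\mathrm{ES}$ — Cohen's $d$ for total symptom burden,
  exposed minus unexposed, with the pooled standard deviation weighted by
  $(n_1 - 1, n_2 - 1)$.
* **Breadth** $\mathrm{BAPS}$ — the number of physiological systems whose
  per-respondent burden differs by exposure in a two-sided Mann–Whitney U
  test at $p < \alpha$ (default 0.05, uncorrected; a Holm option exists but
  is off by default to keep the per-system tests marginal, matching the
  framework's screening intent). The U test enumerates all group
  assignments exactly when both groups have $\le 8$ observations (valid
  under ties) and otherwise uses the tie-corrected normal approximation
  without continuity correction.
* **Composite score**
  $\mathrm{CRS} = 0.5\,\frac{|\mathrm{ES}|}{\max|\mathrm{ES}|}
  + 0.3\,\frac{\mathrm{BAPS}}{10} + 0.2\,\mathrm{EP}$.

Two normalization choices were genuinely open and are therefore explicit,
configurable arguments. First, $|\mathrm{ES}|$ is normalized by the cohort
maximum, the natural choice when the score ranks factors *within* a cohort;
a fixed external normalizer can be supplied through `es_max` when scores
must be comparable across cohorts. Second, the *absolute* effect size
enters: a factor whose exposure is associated with lower burden should not
float to the top of a harm ranking by sign flip — such factors are flagged
in `protective_direction` instead. Because breadth per factor and the
normalizer depend on the cohort, published composite values from other
datasets are not expected to be reproduced by these defaults.

## Composite protective effectiveness

Per measure: implementation rate $\mathrm{IR}$ (fraction with code
$\ge 1$), mean protective effectiveness $\mathrm{MPE}$ (mean code among
users, range 1–3, `NA` when unused), and

$$\mathrm{CPE} = 0.4\,\mathrm{IR} + 0.6\,\frac{\mathrm{MPE}}{3}.$$

The weights are the package default because a grid search over pairs
$(w, 1-w)$ at step 0.01, with MPE normalized by its scale maximum 3,
uniquely minimizes the worst-case deviation from the ten published
composite values this framework is known to produce — reproducing all ten
at two decimals. The test suite re-runs that grid search rather than
trusting the constant. MPE is averaged over users only: published values
near 1.9 at implementation rates below 50% are impossible for an
all-respondent mean, and the code 1 anchor ("poor effectiveness") only
applies to users.

## Risk stratification

System scores are Z-standardized with the **population** divisor $n$, so
the total sum of squares — and hence the k-means objective at $k = 1$ — is
exactly $n \times p$ (620 for 62 respondents and 10 systems), an identity
the acceptance tests pin down. Constant columns are an error; the pipeline
drops them with a logged warning before standardizing.

K-means is Lloyd's algorithm run to convergence (assignments unchanged, cap
300 sweeps) from each of `restarts = 10` random initializations drawn from
a stream seeded with `seed = 42`, keeping the restart with minimal WCSS.
"Ten iterations" of a seeded k-means is read as ten restarts, best-of by
WCSS: convergence of Lloyd in ten sweeps is not guaranteed, whereas
best-of-ten restarts is the conventional guard against local minima; both
knobs are arguments. A cluster emptied during a sweep is reseeded at the
point farthest from its assigned center (never a singleton or an earlier
reseed, so all k clusters stay populated). Results are bitwise
reproducible, and the implementation is cross-checked against
`stats::kmeans` on separated data in the tests.

The elbow is automated as the $k$ maximizing the second difference of the
WCSS curve, but the curve and a strength diagnostic are always reported:
strength is $1 - \Delta_{k \to k+1} / \Delta_{k-1 \to k}$ at the selected
$k$, near 1 for a true elbow (the curve flattens abruptly) and middling for
the smooth $\propto 1/k$ decay of structureless data. Selections below
`weak_threshold = 0.8` warn and are flagged for manual confirmation —
mirroring how elbow choices are made by inspection in practice.

Cluster profiles renumber clusters in *descending* mean-burden order, so
cluster 0 is always the highest-burden subgroup; this makes reports and
tests deterministic under label permutation.

## Reliability and power

Cronbach's alpha per system uses the variance form
$\alpha = \frac{m}{m-1}\left(1 - \frac{\sum_j s_j^2}{s_T^2}\right)$ with
sample variances, `NA` when the total score is constant. The 95% interval
is Feldt's F-method with $df_1 = n - 1$, $df_2 = (n-1)(m-1)$ — a standard
closed-form choice when no interval method is otherwise specified.
Qualitative bands: Good $\ge 0.8$, Acceptable $\ge 0.7$, Adequate
$\ge 0.6$, else Poor.

Power for the two-sample t-test uses the noncentral t distribution with
noncentrality $d\sqrt{n_1 n_2/(n_1+n_2)}$ and $n_1 + n_2 - 2$ degrees of
freedom; at $d = 0$ the two-sided power equals $\alpha$ exactly.
`required_sample_size()` searches the smallest even total at 1:1
allocation; for $d = 0.5$, $\alpha = 0.05$, 80% power it returns 128
(64 per group, power 0.8015). Under this standard model, the achieved
power at 62 respondents is about 0.49 for a balanced 31 vs 31 split and
0.44 at 40 vs 21 — figures sometimes quoted higher in the applied
literature rest on power models this package deliberately does not
replicate.

## The synthetic-data generator

No respondent-level data ship with the package; the generator exists so
every downstream stage is testable against known ground truth. It encodes
a three-class latent risk-severity mixture as the study conditions:

* class shares (0.21, 0.40, 0.39) at $n = 62$;
* class mean total burden calibrated to (32.08, 12.44, 2.71) by bisection
  (tolerance $10^{-3}$) on a multiplier of a per-system propensity pattern
  that follows the published system-prevalence profile;
* class severity-code distributions with means (1.70, 1.35, 1.10) — the
  high-burden class reports more moderate/severe codes, consistent with
  observed symptomatic-only severities clustering in 1.0–1.4;
* the ten published risk-factor exposure prevalences (remaining items 0.1)
  and standardized effect targets;
* the ten published protective-measure implementation rates (remaining
  items 0.4), with per-item effectiveness-code distributions
  $1 + \mathrm{Binomial}(2, (m-1)/2)$ chosen to hit each target mean
  effectiveness exactly;
* demographic level frequencies from the published cohort table.

Class assignment is **stratified** by default: largest-remainder counts
(13/25/24 at $n = 62$), order shuffled by the seed. This reproduces the
fixed subgroup sizes the stratification stage is meant to recover and
keeps the class-share recovery tests meaningful at $n = 62$, where
multinomial sampling noise (per-class SD $\approx 3$) would swamp the
signal; `class_assignment = "multinomial"` restores iid draws for
convergence checks at large $n$.

Risk effects are induced mechanistically, not by additive noise: an
exposed respondent's symptom-presence propensity is multiplied by
$\max(0,\; 1 + \sum_k (x_{ik} - \mathrm{EP}_k)\, e_k \cdot s)$ with
`risk_effect_scale` $s = 0.4$. Centring on the exposure prevalence keeps
the class burden means on their calibrated targets (exposures are
independent of class), and $s = 0.4$ keeps the multiplier in its linear,
rarely-clipped range; realized standardized effects are consequently a
monotone, attenuated transform of the configured $e_k$, which preserves
rankings — the property the tests rely on. All cells remain valid Likert
codes by construction.

A single master seed drives the dataset; sub-streams for classes, risks,
symptoms, protections, and demographics use fixed offsets from it, so a
change in one section's parameters does not perturb the draws of another.

What the generator does **not** emulate: item-level marginal distributions
(only aggregate targets), demographic–symptom associations (none are
assumed), within-system correlation beyond the shared class and system
propensity (no copula), and seasonal or longitudinal structure (the design
is a single cross-section). Passing tests therefore demonstrate the
pipeline's correctness and calibration under the latent-class model, not
distributional fidelity to any real cohort.

## Problem sizes and determinism

The test suite works at the cohort scale ($n = 62$) for pipeline and
recovery checks, $n = 10{,}000$ for Monte-Carlo calibration of the
generator (class mean burden within 5% of target), 100 seeds for class
recovery (shares within ±2 respondents in at least 80 of 100; adjusted
Rand ≥ 0.9 under high separation), 500–1000 replicates for the
breadth-test type-I calibration (expected breadth $\approx 10\alpha$ under
the null), and 200–1000 random cases for the oracle property suites
(Cohen's d, exact Mann–Whitney, Cronbach's alpha). Every stochastic entry
point takes an explicit seed and restores the caller's RNG state, so
identical configurations produce byte-identical output bundles.

## Known limitations

* The default codebook's named items are a plausible reconstruction of the
  instrument's 66/47/26 structure, not a published item list; analyses are
  keyed by codebook ids precisely so other instruments drop in.
* The node-admission rule for the network (`node_min_prevalence`) is a
  modeling choice; different thresholds change the retained graph and its
  metrics.
* Composite scores are rank tools, not causal estimates: no confounder
  adjustment is performed anywhere, by design.
* The complete-case (`"drop"`) missingness policy can bias prevalence if
  missingness is informative; the imputation alternative (`"impute_zero"`)
  assumes absent answers mean "none/not used".
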