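---
title: "Coupling-strength comorbidity networks and differential omics screening"
author: "comorbnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling-strength comorbidity networks and differential omics screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbnet)
```

## The problem

Hospital cohorts of a chronic inflammatory index disease — here modelled
on psoriasis vulgaris — accumulate dozens of comorbid diagnoses per
patient. Frequency rankings alone conflate common-but-independent
conditions with genuinely interacting ones. `comorbnet` implements a
network view borrowed from statistical mechanics: each comorbidity is a
binary "spin" (present/absent), and the pairwise association between two
comorbidities is summarised by a coupling strength on which a weighted
network, centrality analysis, module detection and a core/hub/peripheral
hierarchy are built. A companion omics arm screens differential serum
proteins and lipid-mediator metabolites around a treatment contrast,
with OPLS-DA providing multivariate importance scores.

## The coupling model

For comorbidities $i, j$ with marginal prevalences $P(i), P(j)$ and
co-occurrence probability $P(i \cap j)$, all estimated by maximum
likelihood from a binary patient-by-comorbidity matrix, the coupling is
the pointwise mutual information

$$J_{ij} = \log \frac{P(i \cap j)}{P(i)\,P(j)},$$

the log-likelihood ratio of observed against independence
co-occurrence. $J_{ij} = 0$ under exact independence, $J_{ij} > 0$ for
synergistic co-occurrence and $J_{ij} < 0$ for avoidance. Temperature
and external-field terms of the physical spin model are deliberately
absent: cross-sectional data support association, not dynamics. An
audit-only `formula = "literal"` variant computes
$\log(P(i)P(j)P(i\cap j))$ instead; it is never the default because the
product form is not zero under independence and therefore cannot mean
"nonrandom co-occurrence".

Three numerical choices matter:

* **Degenerate columns.** $J$ is undefined when a prevalence is 0 or 1,
  so `filterComorbidities()` always drops such columns before
  estimation, alongside a configurable low-frequency cutoff
  (`minCount`, no default beyond 0 — extracts differ too much for a
  universal value).
* **Zero joint counts.** A pair never observed together has
  $\hat J = -\infty$ under the raw MLE. The default policy masks the
  pair (no edge, flagged in the object) rather than smoothing, so the
  network stays finite without inventing a prior. Additive smoothing
  (`pseudocount` $c$: marginals $(n_i + c)/(n + 2c)$, joints
  $(n_{ij} + c)/(n + 4c)$) is available and required by
  `zeroPolicy = "smooth"`.
* **Log base.** Natural log by default; base 10 is available and every
  downstream threshold is configurable so either convention can be
  matched.

## Network topology

The coupling matrix becomes an undirected weighted graph (weights
$J_{ij}$, masked pairs omitted). Per node, four centralities:

* **strength** $\sum_j |w_{ij}|$ (degree centrality in the weighted
  sense);
* **expected influence** $\sum_j w_{ij}$, the signed one-step variant
  (a two-step variant is available by flag);
* **betweenness** and **closeness** from exact all-pairs shortest
  paths with distance $d_{ij} = 1/|w_{ij}|$ — the network-psychometrics
  convention for turning association strength into path length.
  Negative edges contribute to strength and expected influence but are
  excluded from path computations; equal-cost paths receive fractional
  Brandes credit; closeness is reachable-count over summed distance,
  with isolated nodes scoring 0.

Disease modules are connected components after keeping edges with
$J$ strictly above a threshold (default 0.5, the conventional
strong-association cutoff here); components of size one are reported as
singletons, and centralities are always computed on the full
(unthresholded) network. Tier classification uses strict inequalities:
strength > 10 marks *core* comorbidities, otherwise betweenness > 60
marks *hubs* (with a user-supplied exclusion list for composite
diagnoses such as benign tumours), all else *peripheral*; closeness >
0.0125 flags high information-transmission efficiency. These cutoffs
ride on the natural-log coupling scale and are all arguments, not
constants.

Stability is assessed by splitting the cohort on a covariate (e.g.
discharge year at 2014), re-estimating each subset's couplings over the
columns non-degenerate in both, and correlating upper-triangle edge
weights and node strengths, with 95% Fisher-z intervals
($\tanh(\mathrm{atanh}\,r \pm 1.96/\sqrt{n-3})$) and top-$k$
strength-ranking overlap (default $k = 10$; Kendall's $\tau$ reported
alongside). The paired count for the edge correlation uses only edges
unmasked in both subsets, since masked pairs carry no weight. Baseline
comparability tables use 2x2 chi-square (no continuity correction) with
Cramér's V and Welch t with Cohen's d, banded at the usual
0.1/0.3/0.5 and 0.2/0.5/0.8 cutpoints, uncorrected by default
(descriptive use; BH optional).

A practical caveat discovered while testing the readers: long-format
extracts record presences only, so patients with *no* comorbidity are
invisible in them. Reading such a file conditions every probability on
"at least one diagnosis", which shifts all couplings down by roughly
$\log(1 - P(\text{no comorbidity}))$. When zero-diagnosis patients
belong on the roster, supply the wide format (auto-detected), which
preserves them.

## Omics screening

Fold change is the ratio of raw-scale group means
(comparison/reference) — verified choice: the shipped worked-example
tables reproduce their printed FCs from printed means at 3 decimal
places for all but five rows, which are flagged `fc_consistent = FALSE`
as rounding artifacts of the source tables. Tests are Welch t
(unpaired) or paired t on subject-matched differences, with rank-sum
alternatives and an optional log transform; BH adjustment is the
standard step-up. The default screening gate mirrors exploratory
practice with small groups: FC $\ge$ 1.20 or $\le$ 0.86, raw $p <
0.05$, and VIP > 1 when a multivariate model is fitted; FDR-gated mode
is available and reported alongside, since with $n = 10$ per group
FDR-corrected screens are typically empty.

### OPLS-DA

`fitOplsda()` implements two-class O-PLS by NIPALS-style deflation: the
$\pm 1$-encoded response spans rank one, so there is exactly one
predictive component; each orthogonal component splits the
Y-orthogonal part off the X loading and deflates it from X before the
predictive component is extracted. Unit-variance scaling is the default
(Pareto available), zero-variance features are dropped with a message,
and the fit is deterministic given input order. VIP is computed over
the predictive component — with normalised weights this is
$\sqrt{p}\,|w_k|$, so mean squared VIP is exactly 1; a total variant
spreading importance over orthogonal components sits behind a flag.
Validation is stratified k-fold cross-validation ($Q^2 = 1 -
\mathrm{PRESS}/\mathrm{SSY}$, centering and scaling recomputed per
training fold, folds redrawn if a training set would lose a class) and
label permutation with $p = (1 + \#\{Q^2_{perm} \ge
Q^2_{obs}\})/(n_{perm} + 1)$. The orthogonal-component count can be
chosen by CV-$Q^2$ maximisation (`nOrtho = "auto"`, capped at 3).

## Synthetic cohorts

Because the hospital extract behind the motivating analysis is not
deposited, every stage is exercised on generators:

* `sampleIsingCohort()` Gibbs-samples $\{0,1\}$ spins with conditional
  log-odds $h_i + \sum_j J_{ij} s_j$; one independent chain per patient
  (sweeps vectorise across patients), burn-in 500 sweeps by default —
  generous for the $p \le 20$ fixtures used here — with a thinned
  single-chain mode by flag. The mandated oracle for trusting it is
  exact enumeration of all $2^p$ Boltzmann states
  (`exactIsingDistribution()`), and `exactPairwisePMI()` derives the
  population PMI the estimator should converge to — deliberately *not*
  the generative $J$, which a marginal pairwise statistic does not
  recover.
* `samplePlantedModules()` draws, per patient, a latent activation per
  module; nodes of active modules fire at `boostProb`, others at
  `baselineProb`. The defaults (activation 0.3, baseline 0.05, boost
  0.8) were fixed up front to emulate distinct disease modules of a
  realistic prevalence: they put within-module PMI near 0.94 nats and
  cross-module PMI at 0, so the 0.5 threshold separates cleanly.
* `sampleOmicsTable()` draws log-normal intensities with per-feature
  baselines, planted $\log$-scale shifts of $\ln(\mathrm{FC})$, noise
  SD 0.3 (matching the ~30% coefficients of variation typical of the
  summary tables this emulates), defaults of 1181 features and 10
  samples per group, and an optional shared subject effect for paired
  designs.

What these generators do **not** emulate: ICD coding drift and
measurement error in diagnosis assignment, covariate-dependent
prevalence trends (era effects are modelled only as two parameter
sets), correlated noise across omics features, and batch effects.
Passing tests therefore demonstrate correctness of the estimators and
procedures under their stated models, not robustness to those
real-data pathologies.

## Problem sizes and reproducibility

The test-suite and acceptance-script simulations use cohorts of
5,000–50,000 patients for sampler and recovery checks (two to ten
nodes), 200 random graphs of at most 7 nodes for the exhaustive
centrality oracle, 1,000-feature null tables for screening calibration,
and 200 repeated small OPLS-DA fits for permutation-p calibration —
sizes chosen so each property is measured well inside its Monte-Carlo
error. All randomness flows through explicit seeds; identical seed and
specification give bit-identical outputs, and both pipeline drivers
write their effective configuration next to their outputs.

## Known limitations

* The coupling statistic is marginal PMI, not an inverse-Ising joint
  fit; conditional couplings (pseudolikelihood, regularised graphical
  models) are out of scope by design.
* Module detection is threshold components, not community detection;
  it answers "which comorbidities are pairwise strongly coupled", not
  "what is the best partition".
* The closeness normalisation and the signed-vs-absolute convention
  behind published strength values cannot be cross-checked without the
  original patient-level data; this package fixes them as documented
  above and keeps every cutoff configurable.
* With $n = 10$ per group the omics screen is exploratory: raw-p gates
  control the per-feature error rate only, and the package prints the
  FDR-gated column for honesty.
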