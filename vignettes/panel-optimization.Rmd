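---
title: "Multimarker panel optimization at fixed specificity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimarker panel optimization at fixed specificity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelmmc)
```

## The problem

Screening for pancreatic ductal adenocarcinoma with serum biomarkers must
operate at very high specificity: the disease is rare, so even a few percent
of false positives would swamp true detections. The analyses this package
implements therefore evaluate candidate markers and marker panels by their
*sensitivity at a fixed, predetermined specificity* (typically 95%), rather
than by global summaries such as the AUC alone. The data model is a nested
case-control design: cases with prediagnostic serum draws from a prospective
cohort, each matched to several controls on age (within 5 years), sex, race,
and calendar date of blood draw in 2-month blocks.

The package provides the full analysis chain: per-marker screening,
multimarker panel optimization, correlated-classifier inference,
level-versus-time-to-diagnosis ("velocity") regression, duplicate-sample
assay QC, and a blinded multi-step training/validation protocol — plus a
synthetic cohort generator so that every stage can be exercised and validated
without access to any restricted dataset.

## Scoring functions and the MMC optimizer

A panel of markers $m_1,\dots,m_k$ is scored per sample as a linear
combination of log concentrations,

$$ SF(c) = \sum_{i=1}^{k} w_i \,\ln c_i , $$

and a sample is called a case when $SF(c) \ge t$. The threshold $t$ is
calibrated empirically: the smallest observed control score such that the
fraction of calibration controls at or above it does not exceed
$1 - SP_{target}$. Ties among control scores push the threshold upward, so
achieved specificity on the calibration controls is never below target. When
no observed value qualifies (e.g. all control scores equal), the threshold is
placed just above the largest control score — implemented as
$t = v + \max(|v|, 1)\cdot 10^{-9}$ in both the R and the compiled code path
so the two stay bit-identical.

The coefficients $w$ are assigned by a Metropolis algorithm with Monte-Carlo
optimization (MMC). Starting from unit weights, one coefficient at a time is
perturbed by a $\mathrm{Normal}(0, \sigma_p)$ step; the move is accepted when
the objective improves and otherwise with probability
$\exp(\Delta/T)$ under a geometrically cooling temperature
$T \leftarrow \gamma T$. The incumbent (best-seen) state is returned, so the
reported objective is monotone in the iteration count.

**Objective.** The objective of a weight vector is its *cross-validated
sensitivity*: over `n_cv` stratified random subsampling splits (two-thirds
train, one-third test by default), the threshold is re-calibrated on each
split's training controls at the target specificity and sensitivity is
measured on the held-out cases; the objective is the mean. The weights are
shared across splits within one objective evaluation — refitting weights
inside every Metropolis step would nest an optimizer inside the objective and
multiply the cost by `n_cv` without changing what is being estimated (the
panel's out-of-split sensitivity at controlled specificity). Setting
`n_cv = 0` selects a resubstitution objective (train = test = all data),
which is what the brute-force comparison tests use because it makes the
objective a deterministic function of the weights.

`cross_validate()` is the stricter companion: it *refits* the weights on each
training split (with a resubstitution inner objective — nested
cross-validation inside each replicate would be disproportionate to the
granularity of the SN estimate) and records held-out sensitivity and
specificity, giving the spread of panel performance under repeated 2:1
train/test splits.

**Exhaustive search.** `search_panels()` enumerates every combination of the
requested sizes (2-4 by convention; larger panels overfit) and fits each by
MMC. One split set is drawn per call and shared by all panels so that ranking
differences reflect the panels rather than split noise. The defaults
(`n_iterations = 2000`, `proposal_sd = 0.25`, `temperature = 1` percentage
point of sensitivity, `cooling = 0.995`, `n_cv = 500`) are package
conventions — nothing in the MMC procedure itself fixes the proposal,
schedule, iteration count, or split geometry — and a full-registry
search at those settings (all 2/3/4-marker panels over 67 markers with 500
splits) is an overnight batch job. The examples, tests and the acceptance
script use reduced, documented settings (typically `n_iterations` of 60-300
and `n_cv` of 25-50 for searches; single fits tolerate much longer chains)
chosen as the package's own working scale; panel *ranking* for well-separated
signals is insensitive to chain length because even the unit-weight starting
point discriminates.

## Univariate screening

Per-marker case/control differences use the Mann-Whitney U test with ties
counted 1/2. For $n_1 n_2 \le 64$ the two-sided p-value is computed by exact
enumeration of all labelings; above that, by the tie-corrected normal
approximation with a continuity correction of 1/2 (the convention is not
fixed by the method's description; ours matches `wilcox.test`). False
discovery is controlled by the Benjamini-Hochberg step-up rule
$p_{(i)} \le i\,q/m$ with an explicit $m$ (the total number of comparisons;
67 for a full marker registry) and the *realized* significance threshold — the
largest flagged p-value — is reported rather than hard-coding any derived
cutoff. Single-marker cut-points at a target specificity mirror the panel
threshold rule: the smallest observed value (largest, for markers depressed
in cases, such as prolactin) at which the allowed fraction of controls is not
exceeded, which maximizes sensitivity among qualifying values.

## Correlated-classifier inference

Two classifiers evaluated on the same cases are compared on sensitivity by
McNemar's test for correlated proportions, $\chi^2 = (b-c)^2/(b+c)$ over the
discordant counts with **no continuity correction** — the conventional 3.841
cutoff (the 95th percentile of $\chi^2_1$) corresponds to the plain
statistic. The plain statistic is mildly anti-conservative relative to the
exact binomial sign test; in simulation every disagreement at $b+c \ge 25$
falls in the narrow band where the exact p-value lies in (0.05, 0.08), and
the tests agree everywhere else.

AUC differences on the same subjects use the Hanley-McNeil approach:
$SE^2 = [A(1-A) + (n_1-1)(Q_1-A^2) + (n_0-1)(Q_2-A^2)]/(n_1 n_0)$ with
$Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$, and
$z = (A_a - A_b)/\sqrt{SE_a^2 + SE_b^2 - 2 r\, SE_a SE_b}$, significant at
$|z| \ge 2$. The correlation $r$ between the two score sets is estimated as
the mean of the within-case and within-control Pearson correlations and used
directly in the denominator; the tabulated mapping from score
correlation to AUC correlation that sometimes accompanies this method is
deliberately not reproduced (it changes $z$
only in the second decimal for the score correlations arising here), and the
`r` argument lets callers substitute any convention.

## Velocity analysis

For each marker, the (optionally log) concentration among cases is regressed
by ordinary least squares on days to diagnosis, with the slope's two-sided
p-value from the t distribution with $n-2$ df. Days to diagnosis grows
*away* from diagnosis, so a marker that rises as the cancer approaches
diagnosis has a negative slope. The screen runs per stratum — the complete
case set and the draws taken 12+ months before diagnosis — and reports
markers significant *only* in the far stratum, the pattern of interest for
detecting resectable disease. No multiplicity correction is applied at this
screen — it is a hypothesis-generating pass, not a confirmatory one — and the
report is explicit about that.

Months-to-diagnosis strata use MTD = floor(days/30.44): "1-12 months" means
under 365 days and "12-35 months" means 365-1064 days; the two partition the
admissible window exactly.

## Duplicate-sample QC

Reproducibility is summarised by the coefficient of variation of each
duplicate pair, $CV = 100\,s/m$ with $m$ the pair mean and $s = |x_1 -
x_2|/\sqrt2$ the pair sample SD — the natural convention when replicates
come in pairs. Per-marker CV ranges and means are reported,
and, given a scoring function, the consistency of the case/control call
within each pair.

## The synthetic cohort generator

The generator emulates the structure the analysis assumes so that every
downstream stage is testable, and records ground truth for parameter
recovery:

- 135 cases with 4:1 matched controls agreeing on sex, race, age within
  5 years, and 2-month draw-date block (blocks anchored at January 1);
- 67 log-normal markers; log-normality is the simplest model consistent with
  a scoring function that is linear in log concentrations and with
  concentration ranges spanning orders of magnitude;
- eight informative markers (seven elevated, prolactin-like one depressed)
  whose case shifts are calibrated as $\delta = \sqrt2\,\Phi^{-1}(AUC)\cdot
  \sigma$ so their single-marker AUCs land in the 0.52-0.66 band typical of
  prediagnostic serum markers;
- negative log-level-versus-days slopes of $-1.5\times10^{-3}$ per day for
  six markers — a convention sized to be detectable at $n = 135$ cases with
  roughly 98% power — a convention, not an estimate of any real assay;
- CEA- and CA 125-like markers correlated with the CA 19-9-like anchor
  through a single shared latent Gaussian factor (correlations 0.83 and 0.73,
  i.e. $r^2 \approx 0.69$ and $0.53$ on the log scale); the full 67x67
  correlation structure is deliberately not modelled;
- days to diagnosis uniform on [30, 1065); real case mixes are often
  front-loaded (half or more of draws within 12 months of diagnosis), which
  uniform sampling does not reproduce (about 32% fall under 365 days);
- 17 duplicate aliquots (7 case / 10 control) whose values are the source
  sample's multiplied by $e^{\varepsilon}$,
  $\varepsilon \sim N(0, \sigma_m)$ with
  $\sigma_m = \text{target}\cdot\sqrt{\pi}/100$ so the *expected* pair CV
  equals a per-marker target drawn uniformly from the 1.0-7.8% band. With 17
  pairs the observed per-marker mean CV scatters around its target (standard
  error about 18% of the target), so individual cohorts can show means
  slightly outside the band.

What the generator does **not** emulate — and hence what passing tests do not
establish about real sera: heavy-tailed or bimodal marker distributions
(real CA 19-9 is famously bimodal by Lewis-antigen status), assay batch and
plate effects, covariate effects of age/sex/BMI/smoking on marker levels,
informative missingness, or any dependence between matching covariates and
concentrations. Parameter-recovery results therefore validate the *code
paths and statistical behaviour*, not field performance.

## Blinded protocol

`run_protocol()` replays the five-step design: (1) train panels on an
external retrospective-style cohort; (2) score the first, blinded half of the
study cohort and adjudicate against the key; (3) retrain on the unblinded
first half over the full registry; (4) score the second, blinded half;
(5) retrain on the entire study cohort. Blinding is structural: `blind()`
strips status, days to diagnosis, survival category *and the match groups*
(group membership would identify the case in each group), and every training
entry point refuses a cohort containing blinded samples, so the only route
from submitted diagnoses to truth is `adjudicate()`, which returns
sensitivity, specificity and AUC per stratum and nothing else. The study
halves are split by match group so no control is separated from its case;
the split fraction is configurable, since real blinded designs often use
uneven halves (e.g. 56/79 cases).

## Numerical and degenerate-input choices

- Concentrations at or below zero (or below a supplied limit of detection)
  are replaced by LOD/2, with the default LOD the smallest positive observed
  value per marker, so logarithms are always defined; replacements are
  counted and attached to the cohort.
- Thresholds and cut-points always resolve ties in the specificity-protective
  direction.
- A constant response in the velocity regression returns slope 0 with p = 1;
  a constant predictor (all draws the same day) is an error.
- McNemar with no discordant pairs returns 0 with a warning rather than 0/0.
- All randomized procedures (generation, splits, Metropolis walks) consume
  the R RNG under an explicit seed stored in their config objects; the C++
  core draws from the same stream, so results are reproducible end to end.

## Known limitations

- Under repeated subsampling with refitting on a *fixed finite sample*, the
  held-out sensitivity of a null panel sits *below* the nominal
  $1 - SP$ false-positive rate: selecting weights on the training portion
  preferentially routes the sample's extreme values into the training side,
  depleting the held-out side. The package's null-calibration tests assert
  the defensible one-sided property (held-out SN at or below nominal, SP near
  target) rather than an idealized equality.
- The threshold is calibrated only on control scores; a single-marker
  univariate cut-point chosen among *all* observed values can exceed the
  corresponding score-function sensitivity by up to one case.
- Short Metropolis chains are adequate for ranking well-separated panels but
  under-optimize coefficients; confirmatory fits of a selected panel should
  use the full default chain length.
- Exhaustive search over all 2/3/4-marker panels of a 67-marker registry at
  `n_cv = 500` is an overnight job; the packaged examples run reduced
  problem sizes (documented above) and a production run should schedule the
  full settings.
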