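---
title: "Methods: differential PTM-site quantification and lipidomics class analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential PTM-site quantification and lipidomics class analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmlipidr)
```

# Overview

ptmlipidr implements a two-armed differential analysis used in stress
biology and related PTM-omics settings:

1. a **PTM arm** that quantifies site-level modified-peptide intensities
   (e.g. lysine crotonylation in label-free mode, phosphorylation in TMT
   mode), normalizes them, and calls differential sites with a fold-change
   plus coefficient-of-variation rule; and
2. a **lipidomics arm** that analyses metabolite peak areas with OPLS-DA,
   VIP scores, permutation validation, fold-change calling, lipid-class
   composition summaries, and a three-group control/stress/rescue reversal
   analysis.

This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic-data generator does and does not emulate.

# The PTM quantification chain

## Centralization

Each site's intensity vector is divided by its own across-sample mean
(computed over observed cells only):
$R_{ij} = I_{ij} / \operatorname{mean}_i(I_{ij})$. This removes the
site-specific intensity scale (ionization efficiency, peptide
detectability) while preserving between-sample structure. Centralization is
idempotent, and after it every row of relative values averages to exactly 1.
Rows with no observed cell cannot be centralized and are dropped with a
logged count. Missing cells are excluded from all means; the package never
imputes site intensities.

## Protein normalization

Modification intensity confounds two signals: per-site occupancy and host
protein abundance. When a protein-level table from the same cohort is
available, each site's relative value is divided by the protein's
centralized relative value in the same sample. Cells whose protein value is
unavailable keep the unnormalized value and the row is flagged
`protein_normalized = FALSE`; we prefer this fallback over dropping the
site, because normalization is conditional on protein coverage, which
enrichment-based PTM workflows do not guarantee. A protein relative value of
exactly 0 would make the quotient infinite, so that cell becomes missing
(logged). Whether calling is performed before or after protein
normalization is the caller's choice: both orders are supported, and the
coupled site+protein scenario (a modification change dragging whole-protein
abundance with it, as with an ATP5O-like site) is exactly the case where
they differ.

## Fold change and the CV criterion

The fold change is the **ratio of group means** of relative values, not the
mean of pairwise ratios; the significance index is the **CV of
replicate-paired ratios** (samples paired across groups by
`replicate_index`). The asymmetry is deliberate: the two statistics are
defined that way, and with two replicates they are not interchangeable. Two
numerical conventions needed fixing:

* the CV uses the sample standard deviation (n−1 denominator), the standard
  CV definition; with two replicate pairs a population-SD convention would
  scale every CV by 1/sqrt(2), which materially changes how often CV < 0.1
  holds;
* all PTM thresholds are strict inequalities (`fc > 1.3`, `cv < 0.1`), so a
  fold change sitting exactly on a cutoff is not significant.

Sites with fewer than two usable ratio pairs, or with no observed value in
one group, are `undetermined` rather than `ns` — absence of evidence is
labelled as such. Pairs with a zero denominator are excluded with a log
message.

Default regimes: label-free 1.3 / 0.77, TMT 1.2 / 0.833 (looser because
isobaric labeling compresses reporter ratios toward 1), both with CV < 0.1.
Metabolite ratio calling uses inclusive cutoffs 1.5 / 0.67, matching how
such thresholds are conventionally quoted ("≥ 1.5 or ≤ 0.67").

## Site-to-protein aggregation

A protein is counted per direction when it carries at least one
differential site in that direction; a protein can be both up and down.
This is the weakest aggregation rule consistent with per-direction protein
counts never exceeding site counts, and it is a package design decision —
site-level and protein-level counts answer different questions and both are
reported.

# The lipidomics arm

## Preprocessing

Peak areas are log2-transformed and column mean-centered, with **no**
unit-variance scaling — centering-only follows the stated preprocessing of
the upstream workflow this package mirrors, and it keeps high-abundance
lipid classes from being artificially equalized with noise-level compounds.
Missing areas are imputed with half the metabolite's minimum observed area,
the usual detection-floor surrogate in targeted metabolomics; the package
is silent about *why* a value is missing, so a floor is the conservative
choice.

## OPLS-DA

The fit extracts `k_ortho` components of X-variation orthogonal to the
class vector, deflates them, then fits one predictive PLS component on the
deflated matrix. With `k_ortho = 0` the model collapses to single-component
PLS, whose closed form (weights proportional to X'y) serves as an
independent oracle in the test suite. The default `k_ortho = 1` is the
common choice for two-class metabolomics; it is an explicit argument, as is
everything else the upstream description leaves open (fold count,
permutation statistic). The fit is deterministic — there is no random
initialization — and the predictive score vector is orthogonal to every
orthogonal score vector by construction, which the tests assert on every
fit.

VIP scores are computed from the predictive component only; orthogonal
components are y-uncorrelated by construction and contribute nothing to
discrimination. With one predictive component and unit-norm weights,
VIP_j = sqrt(p)·|w_j| and mean(VIP²) = 1 exactly.

## Validation: Q² and permutations

Q² = 1 − PRESS/TSS over class-stratified folds (7 by default, capped at the
smaller class size so every training fold keeps both classes; fold
assignment is seed-controlled). The permutation test refits the model under
`n_perm` uniformly random label permutations (default 200) and reports
p = (1 + #{permuted ≥ observed}) / (1 + n_perm) for both R2Y and Q²; the
add-one rule keeps p strictly positive, with floor 1/201 at 200
permutations. A permuted labeling can have exactly zero covariance with X;
such a fit explains nothing and is scored R2Y = 0 with class-mean
predictions in cross-validation, rather than raising an error mid-test.

## Differential calling, class summaries, rescue

Two calling criteria exist and the choice is always an explicit argument,
never inferred: the multivariate rule (VIP ≥ 1 and |log2FC| ≥ 1) and the
plain ratio rule (≥ 1.5 / ≤ 0.67). Metabolite fold changes are ratios of
raw-area group means, not log-space means, because the quantification is by
integrated peak area and fold changes are reported on that scale.

Lipid classes are taken from an explicit annotation when present, otherwise
by longest-prefix match of the display name against
{LPC, LPE, LPA, PC, PE, PI, PA, TG, SM} (so LPC wins over PC); anything
else is `other`. Composite views — phospholipid = {PE, PC, PI},
lysophospholipid = {LPE, LPC, LPA} — are computed on demand and never
stored. Percentages are rounded **half-up** at the reported precision
(half-to-even, R's default, does not reproduce conventionally reported
percentages).

The rescue analysis is a two-step gate: a metabolite must first be
differential between stress and control (ratio rule), then reversed in the
rescue arm relative to stress (rescue/stress ≥ 1.5 after a down change, or
≤ 0.67 after an up change). Raising the rescue threshold can only shrink
the recovered set, a monotonicity the tests check.

A generic hypergeometric enrichment utility (one-sided tail,
Benjamini–Hochberg adjustment) is provided for user-supplied category maps;
the package deliberately performs no live pathway-database lookups.

# The synthetic-data generator

The generator is first-class, tested code that produces the data structure
the analysis assumes:

* log-normal protein baselines (`baseline_log_sd` 1.0);
* per-site occupancies drawn from a Beta distribution with mean
  `occupancy_mean`;
* site intensity = baseline × protein group effect × occupancy × site group
  effect × cell-level log-normal noise (`noise_log_sd`, default 0.15 —
  a typical label-free replicate CV of ~15%; no noise magnitude is
  prescribed by the upstream workflow, so this is a simulator convention);
* injected up/down site effects of size `effect_fold`, optionally coupled
  to the host protein (`coupled_protein_effect`), and optionally compressed
  as `fold^(1−tmt_compression)` — the simplest monotone model of TMT ratio
  compression;
* independent Bernoulli missingness at `missing_rate`;
* metabolite matrices with class-structured multiplicative stress effects
  (defaults: phospholipids down 0.4–0.5×, lysophospholipids up 2–2.5×,
  matching the direction of effects in the stress-lipidome setting the
  package targets) and a third rescue group in which a fraction
  `rescue_fraction` of affected metabolites returns to the control
  baseline.

Replicate pairing follows generation order, giving the paired ratios the CV
statistic presumes. Every generator takes an explicit seed (default
20221124) and is bit-reproducible given it.

**What the generator does not emulate:** batch effects, retention-time or
m/z structure, correlated missingness (censoring at the detection limit),
multiply-modified peptides collapsing onto one site row, partial rescue
levels between stress and control, and biological covariance between
metabolites. Passing tests therefore demonstrate correctness of the
computational chain under the stated generative model, not robustness to
every artefact of real acquisitions.

# Problem sizes and test design

The test suite exercises the formulas against independent brute-force
implementations (row-by-row loops over the printed definitions) on 200
random small tables at tolerance 1e-10; PLS closed-form equivalence on 50
random instances up to 10×10; permutation calibration on 100 null datasets
(60 permutations each, with the full 200 used for the strong-signal floor);
and power/type-I characteristics over 20 seeds at 200 proteins × 2 sites,
2 replicates per group. These sizes give stable assertions while keeping
the default suite fast.

One acceptance property deserves an honest note: at effect fold 2, cell
noise sd 0.1 (natural log) and two replicates per group, each paired ratio
has log-sd 0.1·sqrt(2), so the two-ratio sample CV is distributed
approximately as |N(0, 0.1·sqrt(2))| and P(CV < 0.1) ≈ 0.52. The CV
criterion's sensitivity under these conditions is therefore ~0.5 — the
filter is built for very low false-positive rates (measured ≈ 0.005), not
for power at this noise level — and the suite's sensitivity-≥-0.9 assertion
at those exact conditions fails by design of the criterion itself. Power
reaches 0.9 only when the per-cell noise sd drops below ≈ 0.04 or more
replicate pairs are available.

# Known limitations

* The reader accepts a MaxQuant-style sites-table dialect but does not
  handle multiply-modified peptide rows; the generic dialect assumes one
  row per site.
* The CV criterion has no notion of statistical significance in the
  p-value sense; it is a reproducibility filter, and no FDR control is
  attempted (deliberately out of scope).
* OPLS-DA here is two-class only; multi-class designs must be analysed as
  pairwise contrasts.
* Fold changes on raw-area means are sensitive to single extreme
  replicates in small groups; the CV filter catches this on the PTM side,
  while the lipid arm relies on VIP or the ratio threshold alone.
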