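---
title: "Methods: sequence-based prediction of the ssDNA-SWCNT protein corona"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-based prediction of the ssDNA-SWCNT protein corona}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coronaRF)
```

## The problem

When nanoparticles enter a biofluid, endogenous proteins adsorb onto
their surface and form a *protein corona* that largely determines the
particle's biological identity. For single-walled carbon nanotubes
functionalized with single-stranded DNA — a widely used nanosensor
scaffold — corona formation both fouls the sensor and offers a handle
for rational protein–nanotube conjugate design. Characterizing the
corona experimentally requires LC-MS/MS proteomics for every
nanoparticle–biofluid pair; `coronaRF` instead models in/out-of-corona
placement from the protein's amino-acid sequence alone, so that new
candidate proteins can be screened in silico.

The pipeline has four stages: (1) sequence featurization, (2) corona
labeling from quantitative abundances, (3) imbalance-corrected
random-forest classification, (4) feature analysis. A synthetic-data
generator reproduces the statistical structure of the inputs so all of
it is testable offline.

## Featurization

Each protein is described by 75 descriptors computed from its sequence
(`featurize_set()`), organized in a fixed registry
(`default_registry()`):

* **20 amino-acid fractions** over standard residues.
* **8 global descriptors**: length; molecular weight (average residue
  masses minus one water per peptide bond, Da); aromaticity (fraction
  of F/W/Y); Guruprasad instability index (10/L times the sum of
  dipeptide DIWV weights); GRAVY (mean Kyte–Doolittle hydropathy);
  isoelectric point (bisection of the Henderson–Hasselbalch net-charge
  curve with the Bjellqvist pKa set, 0.01 pH tolerance); net charge at
  pH 7; mean flexibility (Vihinen normalized B-factor scale, nine-residue
  sliding window with center-peaked weights 0.25, 0.4375, 0.625,
  0.8125, 1 mirrored and normalized to sum 1, averaged over all full
  windows — sequences shorter than one window fall back to the
  unweighted per-residue mean, with a message).
* **4 secondary-structure propensity fractions**: helix set
  {V,I,Y,F,W,L}, turn set {N,P,G,S}, sheet set {E,M,A,L}, and
  *nonstructure* = the fraction of residues in none of the three. The
  sets deliberately overlap (L is helix- and sheet-associated, A is
  sheet-associated), so the four fractions need not sum to 1.
* **43 solvent-exposure descriptors** from per-residue relative/absolute
  solvent accessibility: for each amino acid, the exposed count
  normalized by all residues (`exp_total_*`) or by exposed residues
  only (`exp_exposed_*`) — the two normalizations carry different
  information about surface composition — plus mean RSA, total ASA, and
  the overall exposed fraction.

These scale and set choices are the de-facto conventions of the
standard sequence-analysis toolkits; all constants are embedded in the
package. Ambiguity codes (X/B/Z/U/O) are retained in sequences but
excluded from every numerator *and* denominator, which keeps all
fractions normalized over standard residues. The exact composition of
the descriptor set is an open design point — published corona
classifiers differ in minor members — so the registry is an explicit,
configurable object rather than a hard-coded list.

Exposure input is the CSV export of NetSurfP 2.0 (`read_netsurfp()`),
with a residue called exposed at RSA ≥ 0.25 (NetSurfP's own
exposed/buried convention; inclusive boundary; configurable). When no
exposure file is available, `featurize_set()` falls back to a
deterministic heuristic predictor (`heuristic_exposure()`: exposure
probability = logistic(−hydropathy)) and flags this in the
`exposure_source` column. The heuristic is explicitly **not** a
scientific substitute — it exists so fixtures and tests run offline;
real analyses should ingest NetSurfP output.

Features are min-max scaled to [0, 1]. By default the scaler is fitted
on the complete table before any train/test splitting, replicating the
processing order of the original workflow; a fit-on-train-only mode
(`scale_mode = "train"` in `validate()`) is provided and is the
leak-free choice we recommend for new work, but it is off by default to
preserve fidelity. Constant features map to 0 and unseen values are
clipped into [0, 1].

## Corona labeling

Labels come from quantitative LC-MS/MS abundances via two criteria
(`fit_threshold()`, `assign_labels()`):

1. **Enrichment**: a protein with corona abundance above its
   biofluid-only control (`a_corona > a_biofluid`) is in the corona.
2. **Abundance threshold**: the remaining (non-enriched) proteins'
   corona abundances are fitted by an exponential decay
   `n = n0 · exp(−kA)`; the threshold is placed where the decay falls
   to `n0 · exp(−p)`, i.e. `A_threshold = p/k`, and any protein with
   `a_corona > A_threshold` is also in the corona. The default power
   `p = 2.25` is the value at which downstream classifier performance
   peaks in the power sweep (`threshold_sweep()` reproduces the sweep
   mechanics; the count of in-corona proteins is monotone
   non-increasing in `p`).

Numerical choices: the default rate fit is the maximum-likelihood
estimator of an exponential rate, `k = 1/mean(a_corona)` over
non-enriched proteins with positive corona abundance — bin-free,
deterministic, and unit-covariant, which makes the labels exactly
invariant to rescaling the abundance columns (the quantification unit
of LC-MS/MS tables is arbitrary, so this invariance matters). A
histogram mode (least squares on log bin counts) is retained for
fidelity experiments; it estimates the same `p/k` scaling but is
bin-width dependent. The fit uses *corona* abundances because the
threshold is compared against corona abundance. Both comparisons are
strict: a tie at exactly `A_threshold` is out of the corona, and an
undetected, non-enriched protein (`a_corona = 0`) is always out.

## Classification

The classifier is a random forest of 700 trees behind a pluggable
configuration object (`classifier_config()`), fitted by `ranger`.
Classification splits use the Gini impurity: the R random-forest
implementations do not offer entropy-based splitting, and the two
impurity measures are well documented to produce practically
indistinguishable forests; the configuration records the criterion
explicitly rather than silently aliasing one to the other.

Class imbalance (~30% of proteins in-corona) is corrected with SMOTE
(`smote()`): synthetic minority points `x_i + u · (x_j − x_i)` with
`x_j` one of the `k = 12` nearest minority neighbors (Euclidean
distance in min-max-scaled space, neighbors computed within the
minority class only) and `u ~ Uniform(0,1)`, up to a minority/majority
ratio of 0.7:1. SMOTE is applied to the *training split only*; a
SMOTE-before-splitting leakage mode exists purely for fidelity
experiments and is expected to inflate recall.

Validation (`validate()`) is a stratified shuffle split repeated 100
times with a 10% test fraction: per split the classifier is reset,
trained on the SMOTE-augmented 90%, and scored on the held-out 10% for
accuracy, AUC, precision, and recall, with in-corona as the positive
class. AUC is the Mann–Whitney rank statistic of the predicted
probabilities (invariant under monotone probability transforms); a
split whose test set is single-class records a missing AUC, excluded
from aggregation. Aggregates are means with percentile 95% confidence
intervals over splits (the CI construction is not dictated by the
protocol; the percentile interval is assumption-free at 100 splits). A
protein is called in-corona at predicted probability ≥ 0.5 (inclusive).

Cross-biofluid transfer (`cross_biofluid_validate()`) trains on all of
one biofluid's data and repeatedly tests stratified subsets of the
other, with the tested fraction scaled as `0.1 × n_total/n_B` so the
test set keeps the size of a 10% split of the combined data (for the
plasma/CSF datasets this reproduces the published scaling factors 1.55
and 2.81). `grid_search()` wraps validation over a hyperparameter grid
and optimizes precision by default, breaking ties toward fewer trees
and shallower depth; the shipped default grid is deliberately modest
and is not a reconstruction of any published grid.

## Feature analysis

`anova_rank()` scores each feature with the two-group one-way ANOVA F
statistic, computed from its definition (between-group over
within-group mean square; equal to the squared pooled-variance
two-sample t, which the tests verify numerically). The ranking is
scale-free under positive affine transforms. `staged_feature_curve()`
unmasks features from highest to lowest rank and revalidates at each
prefix; under a shared seed the full prefix reproduces a plain
validation run bit-for-bit. In staged runs on the real datasets a
38-feature prefix is the published performance optimum; the staged
curve is the tool to re-derive that operating point on new data.
`impurity_importances()` returns normalized mean-impurity-decrease
importances, and `class_kde()` computes class-conditional Gaussian
kernel densities of scaled features on a 256-point grid over [0, 1]
(bandwidth by `bw.nrd0`, configurable), renormalized by the trapezoid
rule so that boundary mass at 0/1 does not bias comparisons.

## The synthetic-data generator

`gen_scenario()` emulates the statistical structure of the real inputs,
and its defaults are the package's study conditions:

* **Sequences** (`gen_proteins()`): residues i.i.d. from class-specific
  frequency vectors — baseline = UniProt-wide average composition;
  in-corona class has glycine frequency ×2 and leucine ×0.5
  (renormalized), mirroring the direction of the reported top corona
  discriminators; lengths uniform on 100–400 residues. Defaults of
  120 in-corona / 280 out-of-corona proteins give the ~30% minority
  fraction of the real corona datasets.
* **Abundances** (`gen_abundances()`): non-enriched proteins draw
  `a_corona ~ Exp(k = 0.01)` with controls 1–3× higher; the enriched
  subset (coupled to the in-corona class) draws its control from the
  same exponential with corona abundance 1.5–5× higher. The true rate
  is returned for recovery tests.
* **Exposure**: sampled-mode heuristic calls.

What the generator deliberately does **not** emulate: dipeptide
structure (residues are i.i.d., so the instability index carries no
class signal), realistic MS noise (missing-value mechanisms, batch
effects), biofluid-specific proteome composition, or any real
protein–nanotube physics. Passing tests on this scenario therefore
demonstrate that the pipeline's machinery — featurization, labeling,
imbalance correction, validation, ranking — recovers planted signal of
the reported kind and size; they are not evidence about real corona
biology, which requires the real LC-MS/MS datasets, UniProt sequences,
and NetSurfP runs.

Problem sizes used in the shipped tests and in `scripts/acceptance.R`
(400-protein scenarios, 100-repeat validations, forests of 150–700
trees) were chosen as the smallest sizes at which the statistical
checks are stable; all generators and the full pipeline are
deterministic given a seed.

## Known limitations

* The 75-feature registry is a documented reconstruction of the
  descriptor families named in the corona-classification literature,
  not a byte-exact copy of any published 91-feature table; the registry
  is configurable for exact matching if such a table is available.
* Gini rather than entropy splitting (see above).
* The heuristic exposure predictor is a plumbing stand-in only.
* Probabilities are raw tree-vote fractions; no calibration is
  performed.
* Thresholding alternatives that were discarded upstream (e.g. Otsu's
  method) are not implemented.
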