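---
title: "Localizing proteins from co-fractionation profiles: models and choices"
author: "cofrac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing proteins from co-fractionation profiles: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofrac)
```

# The problem

A cell lysate separated on a density gradient distributes each protein
across fractions according to the sedimentation behavior of the structure
it belongs to. Proteins that reside together co-fractionate: their
relative-abundance profiles along the gradient are similar. When the
fractions are labeled with a 10-plex isobaric tag set and analyzed by
tandem MS, each identified spectrum carries ten reporter-ion intensities —
one per fraction — and the profile of a protein can be read directly from
its spectra. `cofrac` implements the downstream computation for a design
with ten fractions and two biological replicates, as used to map the
proteome of a cyanobacterial cell over five subcellular niches: thylakoid
membrane (TM), plasma membrane (PM), the soluble fraction (cytosol,
thylakoid lumen and periplasm pooled), and the small and large ribosomal
subunits.

The pipeline is: reporter normalization and per-protein aggregation →
replicate merging → PCA map → marker-trained classification → per-class
FDR threshold calibration → final assignment with an "unclassified"
category.

# From spectra to profiles

Each peptide-spectrum match (PSM) is normalized ratio-to-sum: the ten
reporter intensities are divided by their total, making the spectrum a
composition on the 10-simplex. A protein's per-replicate profile is the
channel-wise **median** across its accepted PSMs; medians of sum-to-one
vectors need not sum to one, so the median vector is renormalized (a
config switch, `renormalize`, on by default — the downstream classifier
assumes compositional profiles, and whether the original analysis
renormalized after the median is not documented). PSMs with non-finite
values, negative entries or zero total are rejected with a recorded
reason rather than an error; aggregation is invariant to PSM order.

Only proteins quantified in **both** replicates enter the analysis; the
merged object holds the concatenated 20-channel profile (rep1 ‖ rep2) and
the single-replicate proteins are kept in a dropped-proteins log. The
container is a `SummarizedExperiment` subclass (`FractionProfileSet`)
whose validity enforces the two sum-to-one blocks at tolerance `1e-9`.

# The organelle map

For visualization the combined 20-channel profiles are projected on their
first two principal components. Channels are mean-centered but not scaled
to unit variance: all channels are already on the common compositional
scale, and scaling would inflate near-empty fractions (a `scale.` switch
is provided). PCA is sign-indeterminate, so a deterministic convention is
applied — the largest-magnitude loading of each component is made
positive — which makes coordinates identical across runs and platforms.

# Classification

A support vector machine with a radial basis function kernel is trained
on curated marker proteins over the 20-channel profiles. Class weights
are inversely proportional to class frequencies (normalized to mean 1),
so the small ribosomal classes are not swamped by the soluble class.

Hyperparameters (cost, kernel width γ) are chosen by repeated stratified
partitioning: in each outer round the markers are split 80/20 with class
stratification, an inner *k*-fold cross-validation on the 80% picks the
best grid pair by mean macro-F1, and that pair is scored on the held-out
20%. The defaults are 9 × 9 log₂-spaced grids from 2⁻⁴ to 2⁴, 100 outer
rounds and 5 inner folds, all configurable. The refit model uses the pair
selected most often across rounds, with ties broken toward the smallest
cost and then the smallest γ (preferring smoother models); the mean
held-out macro-F1 across rounds is reported as the generalization
estimate. All partitioning is driven by a single seed, making tuning
reproducible.

## Confidence scores

Every protein — markers included — receives class-membership
probabilities, and the winning probability is its score on [0, 1]. The
probabilities are computed from the SVM's one-vs-one decision values by
per-pair Platt sigmoids coupled into a multiclass vector with the
standard fixed-point iteration. Two numerical details matter:

* The sigmoids are fitted by Newton descent on the regularized
  cross-entropy with smoothed targets $(N_+ + 1)/(N_+ + 2)$ and
  $1/(N_- + 2)$, which keeps the fit well-posed even when the decision
  values are perfectly separated — the situation in the zero-noise
  degenerate limit, where naive sigmoid fitting diverges or flips sign.
* The sigmoids are fitted on the training decision values of the refit
  model, not on internally cross-validated ones. On tiny classes,
  cross-validated decision values are noisy enough to invert the
  probability ordering of a well-separated class pair, which would break
  the invariant that the predicted class is the argmax of the score
  vector. In-sample fitting is slightly optimistic about score
  magnitudes, which is acceptable here because assignments never use raw
  scores directly — they pass through threshold calibration on held-out
  annotation (below).

By construction the predicted class equals the argmax of the per-class
scores, the scores sum to 1, and in the zero-noise limit the SVM's
predictions coincide with a nearest-centroid classifier on all proteins
that belong to a compartment.

# Threshold calibration and assignment

A protein is only assigned if its score reaches its predicted class's
threshold; otherwise it is "unclassified". Two threshold modes exist:

* **FDR mode** (default): per class, the threshold is the smallest
  candidate cutoff at which the empirical false discovery rate — the
  fraction of discordant labels among annotated proteins predicted to
  that class and scoring at or above the cutoff — does not exceed the
  target (default 7.5%). Candidates are the observed scores of the
  class's annotated predictions plus 1.0, since the empirical FDR is a
  step function that changes only at observed scores; the FDR of an
  empty selection is defined as 0. If no cutoff attains the target the
  threshold is set just above 1 and the class assigns nothing, with a
  warning. Thresholds are monotone: tightening the target never lowers
  any threshold.
* **Fixed mode**: user-supplied per-class cutoffs, defaulting to 0.75
  for TM, PM and both ribosomal subunits and 0.65 for the soluble class —
  the cutoffs used for the published cyanobacterial map. The
  relationship between those fixed cutoffs and the FDR-calibrated ones
  is not documented in the original analysis, so both modes are
  first-class and selectable in the configuration.

The annotation used for calibration must be a labeled set *distinct from
the training markers*: the classifier fits its markers almost perfectly,
so reusing them would underestimate the FDR and produce permissive
thresholds. In real runs the interface takes an annotation file; in
simulated runs a second labeled sample is drawn from the ground truth
(default 20 proteins per class).

Marker proteins always carry their curated label in the final table
regardless of score, and per-class counts therefore include the markers
themselves.

# The synthetic data generator

The generator exists so the full pipeline — including calibration, which
needs held-out labels — can be exercised end-to-end with known ground
truth. It emulates:

* **Compartment-characteristic profiles.** Each compartment is a
  template: a mean profile on the 10-simplex and a Dirichlet
  concentration. Default templates are discretized Gaussian bumps
  peaking at distinct fractions — soluble at the light end (fractions
  1–2), small and large ribosomal subunits at intermediate densities
  (3–4 and 5), PM at fraction 7 and the dense, chlorophyll-rich TM at
  fraction 9 — mirroring the qualitative order in which these
  structures sediment.
* **Compositional within-class noise.** A protein's replicate profile is
  a Dirichlet draw with parameter `concentration × meanProfile`; the two
  replicates are independent draws around the same template. The default
  concentration of 60 (per-channel s.d. ≈ 0.06 at a 0.35 peak) was
  chosen once so that held-out marker recall sits in the 0.9–1.0 range —
  the regime a well-executed fractionation experiment reaches — and is
  deliberately not tuned further.
* **PSM-level replication with outliers.** Each PSM is a Dirichlet draw
  around the protein's replicate profile (concentration 120), scaled by
  a log-normal total intensity; 2% of PSMs are outliers drawn from a
  flat Dirichlet.
* **Structure-free proteins.** "Noise" proteins are drawn from a
  symmetric Dirichlet (α = 0.8 per channel): spiky profiles resembling
  no compartment, exercising the unclassified path.
* **Single-replicate dropout.** Each protein is absent from replicate 2
  with probability `fracRep1Only` (default 5%), exercising the
  both-replicates rule.

The default design is 20 markers plus 100 unknowns per class and 10
noise proteins (~610 proteins), sized like a desk-scale version of a
real gradient experiment. A fixed seed makes the output byte-identical.

What the generator does **not** emulate: chromatographic or labeling
artifacts (isotopic impurity, co-isolation interference), missing
individual channels, correlated replicate noise, genuinely
multi-localized proteins, or the long-tailed class imbalance of a real
proteome (a real soluble class is several times larger than the
membrane classes; the generator's classes are balanced unless
configured otherwise). Passing tests on synthetic data therefore
demonstrate the correctness and calibration of the computation, not the
biological accuracy of any particular real-data map.

# Degenerate inputs and edge conventions

* All-zero or negative spectra: rejected with a reason, never an
  exception mid-pipeline.
* Empty replicate intersection: a hard error naming the merge stage.
* A marker class with fewer than two quantified members: a hard error
  (stratified training and per-class calibration are impossible).
* Constant profiles: PCA refuses (zero variance).
* A class with no annotated predictions at calibration: threshold just
  above 1, warning, class assigns nothing.
* Ties in the score argmax: first class in canonical order wins.

# Problem sizes and runtimes

The test suite and the acceptance script run the full design (~610
proteins) with a reduced 3 × 3 hyperparameter grid and 100 outer rounds
— about half a minute on one core — and the unit tests use a 52-protein
miniature with 2–3 rounds. The full 9 × 9 default grid at 100 rounds is
a few minutes and is left to real analyses.

# Known limitations

* Exactly two replicates; other designs are rejected rather than
  half-supported.
* No multi-localization modelling: a genuinely dual-localized protein
  will either land on one compartment or fall below threshold.
* No novelty detection: a coherent cluster that belongs to none of the
  five classes (e.g. a storage granule) can only surface as
  "unclassified"; inspecting unclassified proteins on the PCA map is
  the intended workflow for spotting such groups.
* In-sample Platt fitting makes raw score magnitudes optimistic;
  compare scores through calibrated thresholds, not across differently
  trained models.
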