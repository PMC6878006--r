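# cofrac

Subcellular localization of proteins from density-gradient
co-fractionation profiles.

## What this is for

In a LOPIT-style spatial proteomics experiment, a whole-cell lysate is
separated on a density gradient, the fractions are labeled with a
10-plex isobaric tag set, and every identified spectrum carries ten
reporter-ion intensities — the protein's relative abundance across the
gradient. Proteins residing in the same subcellular structure
co-fractionate, so a protein's profile is a fingerprint of where it
lives. `cofrac` turns spectrum-level quantitation tables from such an
experiment (10 fractions × 2 biological replicates) into per-protein
compartment assignments over five niches of a cyanobacterial cell —
thylakoid membrane (TM), plasma membrane (PM), soluble, and the small
and large ribosomal subunits — with an explicit "unclassified" category
for proteins whose profile matches none of them. It is aimed at
proteomics analysts working with prokaryotic gradient fractionation
data, and ships a synthetic data generator with known ground truth so
the entire pipeline can be exercised and validated without any
experimental data.

## The method

1. **Normalization** — each PSM's ten reporters are divided by their
   sum, giving a composition on the 10-simplex:
   `x_i = r_i / Σ_j r_j`.
2. **Aggregation** — a protein's per-replicate profile is the
   channel-wise median over its accepted PSMs, renormalized to sum 1.
3. **Replicate merging** — only proteins quantified in *both* replicates
   are kept; profiles are concatenated to 20 channels.
4. **Organelle map** — centered (unscaled) PCA of the combined profiles,
   with a deterministic sign convention, for visualization and export.
5. **Classification** — an RBF-kernel SVM trained on curated marker
   proteins with class weights `w_c ∝ 1/n_c` (mean 1) against class
   imbalance. Cost and γ are selected by 100 rounds of stratified 80/20
   partitioning with 5-fold inner grid search, scored by macro-F1.
   Every protein receives Platt-scaled, pairwise-coupled class
   membership probabilities; the winning probability is its SVM score
   in [0, 1].
6. **FDR threshold calibration** — per class *c*, the threshold is the
   smallest cutoff *t* such that among annotated proteins predicted *c*
   with score ≥ *t*, the fraction annotated otherwise is ≤ the target
   (default 7.5%). A fixed-cutoff mode (0.75 per membrane/ribosomal
   class, 0.65 for soluble) is also provided.
7. **Assignment** — a protein below its class threshold is
   "unclassified"; markers always keep their curated label.

Dataset comparison utilities (protein-list overlap, cross-study
assignment concordance) are included.

## Worked example

A complete simulated study — 5 compartments, 20 markers plus 100
unknowns per class, 10 structure-free noise proteins — through the whole
pipeline:

```r
library(cofrac)

cfg <- list(simulation = list(),       # default synthetic study design
            classifier = list(costGrid = 2^c(0, 2, 4),
                              gammaGrid = 2^c(-2, 0, 2),
                              cvOuterRounds = 100, cvInnerFolds = 5),
            calibration = list(mode = "fdr", fdr_target = 0.075),
            seed = 7)
res <- runPipeline(cfg)

res$profiles
#> FractionProfileSet: 589 proteins x 20 channels (2 replicates x 10 fractions)
#>   markers: 94 ( large_ribosomal:18, PM:20, small_ribosomal:18, soluble:19, TM:19 )
res$model
#> TrainedClassifier: RBF SVM, 5 classes
#>   cost = 1 | gamma = 0.25 | CV macro-F1 = 1
res$thresholds
#> ThresholdSet (fdr mode, FDR target 0.075):
#>   TM=0.813, PM=0.7813, soluble=0.8059, small_ribosomal=0.7811, large_ribosomal=0.7768
res$summary$counts
#>              TM              PM         soluble small_ribosomal large_ribosomal
#>             116             118             115             112             114
#>    unclassified
#>              14
```

Reading the output: 610 proteins were simulated, 589 survived the
both-replicates rule (94 of them markers — a few markers fell in the
dropped set). The tuned SVM reached a held-out macro-F1 of 1.0 across
the 100 partitioning rounds, the calibrated per-class score thresholds
sit near 0.78–0.81, and 14 proteins — mostly the flat-profile noise
proteins — end up unclassified. Individual rows carry the score and the
threshold that was applied:

```r
head(res$assignments[!res$assignments$is_marker,
                     c("protein_id", "final_label", "score", "threshold")], 4)
#>    protein_id final_label     score threshold
#> 20    syn0021          TM 0.8421924 0.8129806
#> 21    syn0022          TM 0.8724740 0.8129806
#> 22    syn0023          TM 0.8556475 0.8129806
#> 23    syn0024          TM 0.8631932 0.8129806
```

Setting `cfg$output_dir` additionally writes the profile table, PCA
coordinates, the organelle map image (PNG/SVG), the score and
assignment tables, and a JSON summary with a config hash. Real data
enters through `inputs$psm_table` (columns `protein_group_id`,
`replicate`, `reporter_01..reporter_10`) or a protein-level
`inputs$profile_table`, plus a `markers` CSV (`protein_id`, `class`).

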