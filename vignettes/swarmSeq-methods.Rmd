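---
title: "swarmSeq: models and methods"
author: "swarmSeq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{swarmSeq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

swarmSeq builds diagnostic RNA classifiers from blood-platelet RNA
sequencing profiles. Platelets take up and process tumour-derived signals,
so their spliced RNA repertoire carries disease information; counting only
intron-spanning reads restricts the signal to genuinely spliced RNA and
keeps contaminating plasma DNA out of the analysis. The package covers the
full chain: cohort quality control, confounder-aware normalization,
negative-binomial differential-splicing analysis, a particle-swarm
optimized SVM classifier, and companion analyses (RNA-binding-protein motif
scanning in UTRs, percent-spliced-in statistics, correlation signatures
around a target gene such as P-selectin).

# Data model

`SplicedCounts` extends `SummarizedExperiment`: one integer `counts` assay
(genes x samples), sample annotation in `colData` (group, age, blood
storage stratum, smoking, gender, cohort role, site) and a `lib_size`
column that is kept equal to the column sums by construction, including
after subsetting. Gene and sample order is never silently changed, so every
deterministic tie-break downstream is reproducible from the input files.

# Cohort quality control

Three filters, applied in this order:

1. **Low-abundance genes.** A gene is dropped when it has fewer than
   `min_count` (default 30) intron-spanning reads in more than `frac`
   (default 90%) of samples. Both comparisons are strict, so at n = 10 a
   gene below threshold in exactly nine samples survives.
2. **Detected genes per sample.** Samples with fewer than 750 genes with at
   least one read are dropped (strict `<`).
3. **Leave-one-sample-out cross-correlation.** Each sample's CPM profile is
   correlated (Pearson) against the per-gene median CPM of all other
   samples; samples below r = 0.5 are removed in a single pass, without
   recomputing references after removals. The CPM here is plain
   counts-per-million on raw counts: the filter runs before any model is
   fitted and must stay label-agnostic, whereas the full normalization
   depends on training-cohort choices and would make the filter circular.
   No log transform is applied by default (a `log` flag exists).

`runQC()` also records what the alternative order (samples first, genes
second) would have retained, for audit.

# Normalization: locked TMM plus iterative RUV correction

The correction module removes technical and demographic variation while
protecting the group signal. All of its choices are locked on the training
cohort; held-out samples are processed by projection only, so their labels
cannot influence anything (`applyNormalization` is bit-reproducible for a
held-out sample regardless of how the rest of the cohort is labelled).

1. **Stable genes.** Genes whose raw counts have Pearson r >= 0.8 with the
   intron-spanning library size and |r| <= 0.2 with age. Genes tracking
   library size are exactly the genes that become flat after CPM
   normalization, hence good negative controls. The age criterion is the
   complementary direction — a gene tracking age is not stable; the two
   criteria are intersected (AND), since stability must hold across all
   confounders considered. Both thresholds are plain arguments (the
   P-selectin analysis, for instance, uses 0.9 for the library-size
   threshold).
2. **Latent factors.** SVD of the per-gene centred log(counts + 1) matrix
   restricted to the stable genes; the first k = 3 left-singular vectors
   are the per-sample factor scores (the RUVg construction, implemented
   here directly from its SVD-on-control-genes recipe). The right singular
   vectors, singular values and centring are retained so new samples can be
   projected onto the same directions.
3. **Factor assignment.** A factor is removed only if (a) it is *not*
   associated with the group (two-sided t-test p > 1e-5 — this floor
   protects biological signal) and (b) it *is* associated with at least one
   continuous confounder (library size, age; correlation-test p < 0.01).
   We read the published inequality as: removal requires the group p-value
   to exceed the floor. Samples with missing age are skipped pairwise in
   age correlations but still corrected.
4. **Correction.** Per gene, log(counts + 1) is regressed on the removed
   factor scores and the fitted component subtracted; values are
   back-transformed (exp − 1) and clipped at zero. Correction operates on
   the log scale because the batch model is additive there. Corrected
   library sizes are the column sums of the corrected values.
5. **TMM with a locked reference.** The reference sample is the training
   candidate whose 75th-percentile CPM is closest to the candidates' mean
   (ties to the first in sample order) and is then locked. Factors are the
   classical doubly-trimmed (30% by M, 5% by A) inverse-variance-weighted
   mean of M-values, computed pairwise against the locked reference
   (delegated to edgeR's `calcNormFactors`), and rescaled by the training
   geometric mean so training factors multiply to 1 — the rescaling
   constant is locked too, keeping held-out samples out of the training
   factors.
6. **logCPM.** `log2(1e6 (y + 0.5) / (efflib + 1))` with efflib =
   corrected library size x TMM factor. Pseudocounts: +1 inside logs for
   factor estimation, +0.5/+1 in logCPM — standard, documented, and
   configurable where they matter.

`rleStats()` quantifies the improvement: per-sample |median RLE − overall
median| before vs after, compared by a paired t-test.

# Differential splicing

Negative-binomial GLMs with log link and effective-library-size offsets,
likelihood-ratio tested against the reduced design (chi-squared, df = 1; a
single two-level group coefficient — the default design is group-only).
Dispersion is estimated as common, trended and tagwise with empirical-Bayes
shrinkage toward the trend; the shrinkage prior is fixed at 10 prior
degrees of freedom (a package default has to be pinned for
reproducibility; it is an argument). Estimation and testing are delegated
to edgeR; the likelihood-ratio statistics are verified in the test suite
against an independent grid/golden-section NB likelihood maximization.

Multiple testing is Benjamini-Hochberg; significant genes are FDR < 0.01
with logCPM >= 3. For signal exploration the RUV-corrected counts are used;
for classifier training the raw counts are used (reproducibility of the
classification input), exposed as `use_corrected`. Clustering diagnostics
use Ward linkage on 1 − Pearson distances with a two-sided Fisher's exact
test on the cluster-by-group table.

# The classifier

Training composes, on training samples only:

1. iterative correction (above), locked;
2. **ANOVA ranking** — the NB LRT on raw training counts; panel = genes
   with FDR below the panel threshold, ordered by LR;
3. **correlation filter** — greedy removal: while any pair of panel genes
   exceeds the cutoff in |Pearson r|, drop from the worst pair the gene
   with the larger mean absolute correlation (ties to the later panel
   position). Redundant genes add noise to SVM models;
4. **SVM-RFE** — iteratively fit a linear-kernel SVM, rank genes by squared
   weight, drop the lowest 10% (at least one) until the target size
   remains. The linear kernel supplies the weight criterion even though the
   final classifier is RBF — the standard SVM-RFE construction;
5. **grid search** — RBF SVM over gamma in 2^(-20..0) and cost in
   2^(0..20) with stratified 2-fold internal cross-validation ("two-times
   internal cross validation" is read as 2-fold); ties break to smaller
   cost, then larger gamma;
6. **inner PSO refinement** — continuous swarm over (log2 gamma, log2 cost)
   in a +/-2 box around the grid optimum, with the grid optimum seeded as a
   particle, so the refined configuration can never be worse;
7. final RBF fit on all training samples; scores come from a Platt sigmoid
   `1/(1 + exp(A d + B))` fitted on the training decision values with
   Platt's smoothed targets. The smoothed-target fit stays well behaved
   under perfect separation (where a plain logistic fit diverges) and is
   monotone in the decision value; the class call is made at 0.5 by
   default, with the accuracy-optimal training threshold available via
   `bestAccuracy()`.

The model stores per-panel-gene training median counts; at prediction,
counts between 0 and the trigger (inclusive — "between zero and 12" is
read inclusively; 12 for the matched design, 2 for the full design) are
replaced by those medians before normalization, because undetected genes in
a validation cohort otherwise distort the corrected library sizes.

The **outer swarm** optimizes four pipeline hyperparameters — stable-gene
library-size threshold, ANOVA FDR threshold, correlation cutoff, RFE panel
size (rounded at evaluation) — minimizing 1 − AUC on a disjoint evaluation
cohort. Published designs use 100 particles x 10 iterations (matched) and
200 x 7 (full). The swarm is the canonical inertia-weight form (inertia
0.72, cognitive = social = 1.49, velocity clamped to 20% of the box width)
— constriction-equivalent values chosen because the optimizer itself has no
published coefficients. The bounds default to libsize in [0.5, 0.95], FDR
in [1e-4, 0.2], correlation cutoff in [0.5, 1], panel size in [10, 1000],
spanning the operating points used elsewhere in the pipeline (0.8/0.9
thresholds, FDR 0.01, panels of several hundred genes); the published
ranges themselves were never printed. A particle whose pipeline fails
(e.g. an empty panel) scores objective 1. The stable-gene selection is
recomputed for every particle, since the first optimized parameter is
exactly that threshold.

Failure containment and leakage: the trained model is a pure function of
the training samples — the test suite asserts that editing validation
counts leaves the serialized model bytes unchanged.

# Performance measures

AUC is the Mann-Whitney probability with ties counted one half (pROC
supplies the ROC machinery; the tests check it against an all-pairs
enumeration oracle). DeLong confidence intervals come from placement-value
variances, truncated to [0, 1]; perfect separation degenerates to a
zero-width interval with a warning. LOOCV refits *only* the SVM per round —
panel, normalization and cost/gamma stay locked, matching the stated inputs
of the procedure. The permutation null permutes training labels with the
panel maintained and uses the add-one estimator
p = (1 + #{AUC_perm >= AUC_obs}) / (1 + n_perm); permutation replicates do
not refit cost/gamma. Resampling stability redraws training cohorts
(stratified) with the validation cohort and panel fixed.

# RBP motif engine

IUPAC motifs are expanded by Cartesian product over the degeneracy map
(U normalized to T) and deduplicated per RBP. Hits are counted
non-overlapping, left-to-right (overlapping mode behind a flag), and `N`
never matches. UTR sequences are concatenated per transcript and side in
transcript orientation (minus strand reverse-complemented); GTFs with
explicit five/three-prime UTR features are used directly, generic `UTR`
features are classified relative to the CDS. Coverage gates are inclusive:
5' UTRs need >= 3 reads, 3' UTRs >= 5 (the higher 3' threshold reflects
oligo-dT amplification bias). Gene-level hits are summed over a gene's
surviving transcripts (a mean mode exists behind a flag). Correlation of
per-gene site counts with differential logFC is Pearson by default with a
Spearman option (the two appear in different places in the source
literature), with BH-FDR within each UTR side.

# Splice events and signatures

Isoform analysis mirrors the gene pipeline (<10 reads in >90% filter, NB
LRT, FDR < 0.01 and logCPM > 1 selection) and classifies multi-isoform loci
by the signs of per-isoform group-median differences: all same sign =
concordant, mixed = alternatively spliced; zero differences count as
concordant with either sign. Exon-skipping events need >10 assigned reads
in >60% of samples *with both inclusion and exclusion support* — we read
the published rule as a conjunction; the strictly-greater boundaries are
kept. PSI group comparisons use Welch's t-test (the default of the
environment the method was developed in; pooled variance behind a flag)
with BH correction; delta-PSI is the difference of group medians. Missing
PSI values are excluded pairwise, never imputed. The target-gene signature
correlates every gene's logCPM with the target's, keeping positive,
FDR < 0.01 genes, and reports the overlap with an up-regulated set.

# Synthetic data

The generators are first-class, tested code and define the study
conditions for every verification in the package:

* `simulateCounts()` — NB counts (variance mu + phi mu^2, matching the GLM
  parameterization) over a log-normal baseline at the scale of the spliced
  platelet repertoire (default 4,500 genes); group fold-changes on a random
  gene subset; log-normal library-size factors (sd 0.3), decorrelated from
  age within each cohort-role stratum — library size is a technical factor
  assumed independent of demographics, and the emulated study age-matches
  its cohorts, so the planted stable genes realize their claimed
  age-independence in every cohort rather than only in expectation; planted
  stable
  genes (high-abundance, phi = 0.005, so their counts track library size);
  an additive-on-log-scale latent batch factor (matching the RUV model) on
  5% of genes; age coupling on 2% of genes. The truth record lists every
  planted membership.
* `simulateUTRFixture()` — random UTR sequences with a planted RBP whose
  inserted motif count follows each gene's logFC; backgrounds are
  regenerated until the assembled UTR contains exactly the inserted number
  of hits, so the generator/scanner round trip is exact.
* `simulatePSIFixture()` — beta PSI values with a planted group shift
  (shifted events draw baselines with headroom so the shift is realized
  unclipped) and binomial inclusion/exclusion counts.

What these fixtures do *not* emulate: GC and length biases, sample-specific
dispersion, correlated gene modules beyond the single batch factor,
realistic annotation complexity, or cohort-level class imbalance. Passing
tests therefore demonstrate algorithmic correctness and statistical
calibration under the stated model, not clinical performance on real
cohorts — reproducing the published cohort results requires the deposited
count tables and hours of swarm compute, which is outside the scope of the
test suite.

# Numerical choices and problem sizes

* Ties: TMM reference — first sample; grid search — smaller cost, then
  larger gamma; correlation filter — later panel position; best-accuracy
  threshold — lowest.
* Degenerate inputs: zero-variance genes are excluded from stable-gene
  selection and correlation analyses with warnings; samples with undefined
  leave-one-out correlation fail the filter; perfect separation yields a
  degenerate DeLong interval; an all-zero library gets TMM factor 1 with a
  warning.
* All stochastic functions take explicit seeds and are pure functions of
  (inputs, seed).
* The test suite and the acceptance script run the classifier on compact
  cohorts (hundreds of genes, tens of samples) with a coarsened SVM grid
  (every fourth power of two) and small swarms; grid resolution and swarm
  size are runtime knobs that do not change any modelling decision, and the
  full 21 x 21 grid and published swarm sizes remain the defaults.

# Known limitations

* On strongly separable synthetic cohorts the permutation null is bimodal:
  a label-permuted SVM can still recover the dominant cluster axis with a
  random sign, piling permuted AUC values near 0 and 1. The permutation
  p value is then conservative and the permuted-AUC median unstable. Real
  cohorts with weak signal do not show this artifact.
* The outer swarm's objective is a single evaluation-cohort AUC; with
  small evaluation cohorts it is a noisy objective and the swarm will
  happily overfit it — the held-out validation cohort is the only honest
  performance estimate.
* The RUV correction assumes unwanted variation is additive on the log
  scale and visible in the stable genes.
* The exact probability calibration of the original platform is not
  published; Platt scaling on training decision values is this package's
  choice and is documented as such.
* Multi-level group designs are out of scope (df = 1 tests throughout).
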