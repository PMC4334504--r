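---
title: "Methods: hybrid feature encoding and imbalance-aware ensemble classification of ECM proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid feature encoding and imbalance-aware ensemble classification of ECM proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Extracellular matrix (ECM) proteins — collagens, proteoglycans,
matricellular proteins — are secreted into the space between cells, where
they organize tissue mechanics and signaling. Predicting whether a protein
is an ECM component from its sequence is a binary classification task with
two structural difficulties: no single representation captures the relevant
biology (composition, physicochemistry, evolutionary conservation and
structure all carry signal), and curated datasets are heavily imbalanced —
around eleven non-ECM proteins per ECM protein — so a classifier trained
naively learns to say "negative". `ecmforest` addresses both: a
315-dimensional hybrid encoding, information-gain-ratio feature selection,
and an undersampling random-forest ensemble evaluated by balanced accuracy.

## Input sanitation

Sequences are restricted to the 20 standard residues (ambiguity codes
B, J, O, U, X, Z are parse errors, enforced once at record construction)
and length-filtered to the inclusive window [50, 3000] residues by
`sanitize_dataset()`. Filtering is reported, not raised: each dropped
record carries a machine-readable reason.

## The feature encoding

All encoders are pure functions of their inputs; identical input and
configuration give bit-identical output. Blocks are concatenated in a fixed
canonical order (`ffg`, `entropy`, `dist`, `trans`, `pseaac`, `dwt`,
`pssm`, `diso`, `ssi`, `fdi`) with stable namespaced feature names, so
column layout is reproducible across runs and serializable with models.

**Functional groups (10).** The 20 amino acids partition into ten
side-chain chemistry groups (phenyl F/W/Y, carboxyl D/E, imidazole H,
primary amine K, guanidino R, thiol C, sulfur M, amido Q/N, hydroxyl S/T,
non-polar A/G/I/L/V/P); the block is the per-group residue fraction and
sums to exactly 1.

**Entropies (2).** Shannon entropy, base 2, of the amino-acid composition
and of the dipeptide composition over the L−1 overlapping pairs
(0·log 0 := 0). Bounds log₂20 and log₂400 are asserted as properties.

**Distribution (20).** For each amino acid, the population variance
(denominator N, the occurrence count) of the distances from each occurrence
to the first occurrence. Zero or one occurrence gives 0. Using the
population rather than the sample denominator follows the defining formula
as printed in the descriptor literature; it also keeps the statistic total
(defined for N = 1).

**Transition (45).** For each unordered pair of distinct functional groups,
the count of adjacent residue pairs crossing between them (either
direction) divided by L — the full sequence length, not L−1, again as the
descriptor is conventionally printed. Component order is lexicographic over
group indices.

**PseAAC (40).** Type-I pseudo amino-acid composition with η = 20
correlation tiers and weight w = 0.05. The tier-k factor averages
Θ(Rⱼ, Rⱼ₊ₖ) over positions, Θ being the mean squared difference of four
standardized property values. The four properties are hydrophobicity
(Kyte–Doolittle), flexibility (Bhaskaran–Ponnuswamy average flexibility
index), net side-chain charge, and accessible surface area (Chothia
extended-tripeptide values). The literature on this encoder names the
properties but rarely the tables; we chose these widely used published
scales, standardize each to zero mean and unit population SD over the 20
amino acids (so only relative values matter), and expose the matrix as a
replaceable argument. The 40 components sum to 1 by construction, a tested
invariant. Sequences must be longer than η.

**DWT (42).** Three per-residue signals (standardized hydrophobicity,
flexibility, surface area) are decomposed with the Daubechies-4 (8-tap)
wavelet to level 4 under half-point symmetric boundary extension (the
padding is part of the configuration; results are bit-reproducible). A
level-4 decomposition yields five sub-bands; summarizing all five would
give 66 features, so to match the advertised 14 per property (2 raw-signal
statistics + 4 per band × 3 bands) we summarize the three coarsest bands
{cA4, cD4, cD3} — the low-frequency content that large-scale periodicity
(for example collagen-like repeats) lives in. The selection is
configurable. Minimum admissible length is 2^level = 16 residues; shorter
input errors with a suggestion to lower the level. Because the high-pass
filter has zero sum and the symmetric extension of a constant is constant,
homopolymer signals produce exactly zero detail coefficients — a tested
identity.

**PSSM (80).** Raw log-odds scores from a PSI-BLAST ASCII matrix are
squashed elementwise by the sigmoid 1/(1+e^{−x}) *before* differencing
(the normalization is stated ahead of the descriptor definition in the
method literature, and we follow that order); then for each amino-acid
column i and lag λ = 1..4, θᵢ^λ is the mean squared difference of
normalized scores λ positions apart. Output is lag-major. A profile with
identical rows maps to the zero vector.

**Disorder (8), secondary structure (51).** Run-length statistics over the
per-residue tracks. Disorder calls use a configurable threshold of 0.5 —
the conventional cutoff for VSL2-style predictors; the choice is not
prescribed by the descriptor definitions, so it is a documented default.
Absent segment classes report 0 for their length statistics rather than
NA, keeping vectors total. For secondary structure, the positional
"distribution" of each state reuses the same population-variance statistic
as the sequence-level distribution block (the descriptor is named but not
formalized in the source literature; reusing the one defined formula is
the parsimonious reading), and the 30-cell (group × state) block is
normalized by L so it forms a proper joint distribution summing to 1 —
also a deliberate choice where the normalizer was unstated.

**Functional domains (variable, 17 in the reference configuration).** The
vocabulary is *derived*, not hard-coded: accessions annotated on at least
`min_count` distinct positive proteins (default 25, the reference rule at
410 positives), ordered by descending count with string tie-break for
determinism, and serialized with any model. Features are binary presence
indicators.

## Feature selection

IGR(F) = (H(C) − H(C|F)) / H(F), base-2, computed on discretized features;
constant features (H(F) = 0) score 0 by convention and the score is clipped
to [0, 1]. The entropies presuppose discrete value sets, which the source
formulation leaves unspecified for continuous features; we default to
10-bin equal-frequency binning learned on the training matrix (robust to
the heavy skew of count-derived features), with equal-width binning as an
option. Ranking is descending with stable ties in canonical column order.

Incremental feature selection evaluates rank prefixes k = step, 2·step, …,
d with a cross-validated evaluator and selects the smallest k whose
balanced accuracy is within δ = 0.001 of the maximum — the printed
tolerance of the reference procedure. The evaluator reuses one seed for
every prefix so all prefixes are compared on identical folds. The `step`
argument permits coarse scans; the reference procedure scans every prefix.

## The ensemble and its evaluation

`make_undersampled_subsets()` shuffles the negatives (seeded), splits them
into K = round(|neg|/|pos|) near-equal groups (sizes differ by ≤ 1,
minimum K = 1), and joins each group with all positives. At the reference
410/4464 composition, K = 11. One forest per subset is trained
(`randomForest`, defaults 10 trees and ⌊log₂ d⌋+1 split candidates,
mirroring the WEKA-era defaults the approach was developed with; both
configurable), and prediction is by majority vote. Even-K ties go to the
positive class — a documented convention favoring minority recall;
K = 11 cannot tie. `single_forest()` is implemented as the forced-K = 1
path of the same code, so the "no ensemble" baseline and a one-member
ensemble are identical by construction.

Stratified k-fold cross-validation splits each class independently into
near-equal folds and pools all test predictions into a single confusion
matrix before computing Sn, Sp, Acc and BAcc. Pooling (rather than
averaging per-fold rates) is a documented choice — per-fold rates are
unstable when a fold holds only a handful of positives — and the per-fold
trace is attached for inspection. Degenerate truth (a class absent from
the test labels) yields an explicit `NA`, never a silent 0.

`ratio_sweep()` reproduces the imbalance-pathology experiment: for each
negative:positive ratio r = 1..10 it redraws `repeats` datasets (all
positives + r·|pos| random negatives) and cross-validates a *single*
forest, isolating the effect of imbalance from its ensemble fix. The
expected signature — specificity and accuracy inflate with r while
sensitivity collapses — is asserted as a Spearman sign test.

## The synthetic data generator

`synth_config()` / `generate_dataset()` produce labeled datasets with a
single class-signal dial s ∈ [0, 1]. Positives are biased toward
glycine/proline-rich composition, coil-heavy secondary structure, higher
disorder, and carriage of 17 synthetic signature domain accessions
(`SYNDOM…`, explicitly synthetic identifiers) — a caricature of
collagen-like ECM proteins chosen so that every feature block carries
class information. At s = 0 the two classes are generated identically;
the mixing is linear in s. PSSM files are stubs (one-hot log-odds plus
integer-rounded Gaussian noise consistent with each sequence): the
encoders only require the file contract, and no claim is made that stubs
resemble PSI-BLAST output statistically. Default lengths are 60–300
residues, inside the sanitation window and long enough for every encoder's
minimum-length precondition.

What passing tests on this generator shows: that the implementation
recovers planted class structure through the *entire* pipeline (files →
encoding → selection → ensemble → metrics) and behaves at chance when no
structure exists. What it does not show: performance on real proteomes,
where class signal is weaker, correlated across blocks in unknown ways,
and entangled with homology between training and test proteins. Reported
synthetic balanced accuracies are properties of the generator, not of ECM
biology.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, the
package's own choice of default experiment size: planted-signal and null
recovery at 100+100 proteins (signal 1.0 and 0.0, 10-fold CV); the
imbalance sweep on 30 positives + 300 negatives at signal 0.3 with 3
repeats and 5-fold CV per ratio. The sweep fixture uses a moderate signal
deliberately: at full signal both the single forest and the ensemble are
perfect and the pathology is invisible; at s = 0.3 the classes overlap
enough that sensitivity visibly collapses with imbalance and the ensemble
visibly restores it. The domain-vocabulary min-count scales with the
positive-set size (25-of-410 reference rule; 25-of-100 and 8-of-30 in the
fixtures).

Other numerical conventions, collected: text feature matrices round-trip
at 10 significant digits; all RNG flows through a single integer seed per
entry point (generation, fold assignment, negative partition, forest
training each derive sub-seeds deterministically); IGR ties break by
canonical column order; vocabulary ties by accession string; vote ties to
positive; absent-segment statistics are 0; division-by-zero rates are NA.

## Known limitations

- The auxiliary profiles (PSSM, secondary structure, disorder, domains)
  are *inputs*; the package does not run PSI-BLAST, PSIPRED, VSL2 or
  InterProScan, and prediction quality on real data inherits whatever
  those tools produce.
- The PseAAC property tables and the DWT sub-band selection are principled
  defaults, not uniquely determined by the method's published description;
  both are configurable and serialized with models.
- The forest member count K is derived from the training composition; no
  attempt is made to recalibrate vote thresholds for test sets whose class
  prior differs from training.
- Binary domain indicators ignore domain multiplicity and architecture.
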