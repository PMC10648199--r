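---
title: "Local structure with protein blocks: assignment, features, and sequence-based prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local structure with protein blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pblocks)
```

## The model

A protein block (PB) is a five-residue backbone conformation prototype.  The
standard 16-letter alphabet ('a'–'p') refines the classical secondary
structure classes: 'm' is the central α-helix, 'd' the core β-strand, and
the remaining letters cover caps, turns and coil variants.  Each block is
defined by eight dihedral angles (ψ1, φ2, ψ2, φ3, ψ3, φ4, ψ4, φ5); with
bond lengths and angles fixed, those angles determine a 15-atom N/Cα/C
backbone up to a rigid motion.

Two metrics compare five-residue fragments:

* **RMSDA**, the root-mean-square deviation of the 2(M−1) = 8 dihedral
  angles, every difference wrapped to (−180°, 180°];
* **RMSD**, the root-mean-square Cartesian deviation over the 3M = 15
  backbone atoms, minimized over proper rotations and translations
  (Kabsch's closed-form SVD solution, reflections excluded so chirality is
  preserved).

Assigning a fragment means finding the prototype with the smallest
distance.  Retaining the whole 16-vector of RMSDs — the fragment's
*structural coordinates* — keeps strictly more information than the single
letter: it is a distance-based embedding of the local conformation from
which backbone coordinates can in principle be re-derived.

The package predicts structural coordinates (and from them PB labels, or
DSSP classes in a one-hot mode) from amino-acid sequence alone, with no
evolutionary information:

1. candidate features are generated from physicochemical property scales
   and from occurrence statistics of resolved structures;
2. a stepwise bidirectional regression selects statistically significant
   features per regression target (one per block);
3. a shallow four-hidden-layer sigmoid network maps the selected features,
   expanded over a 9-residue view field, to the 16 structural coordinates.

## Prototype geometry

`backbone_geometry()` fixes N–Cα 1.458 Å, Cα–C 1.525 Å, C–N 1.329 Å, bond
angles N–Cα–C 111.2°, Cα–C–N 116.2°, C–N–Cα 121.7°, and ω = 180°
(trans).  These are standard peptide values; all are overridable.  With
them, the packaged dihedral table reproduces the familiar inter-prototype
distances — RMSD(c,d) ≈ 0.65 Å, RMSD(a,g) ≈ 1.03 Å with 'a' and 'g'
mutual nearest neighbours, and a matrix maximum of ≈ 3.48 Å for (d,o):

```{r distmat, eval = FALSE}
D <- pb_distance_matrix()
round(D[c("a", "c", "d", "o"), c("a", "c", "d", "g", "o")], 3)
autoplot(D)
```

Ties in the argmin assignment (below 10⁻⁶ Å) go to the alphabetically
first letter and are flagged; they essentially never occur with the
canonical alphabet.

## Features

The candidate pool is declared by `feature_registry()` as one row per
feature, fully parameterized, so every matrix is recomputable bit-for-bit
from its registry, the packaged scales, and the occurrence tables.  The
default families (216 candidates in total):

* positional scale values (7 packaged scales × 5 positions) — hydropathy,
  hydrophilicity, flexibility, volume, polarity, isoelectric point, helix
  propensity; AAindex1 flat files extend the set via `read_aaindex()`;
* window means of each scale;
* harmonic periodicity magnitudes at T = 2 (strand alternation) and
  T = 3.6 (helix period):
  √((Σₖ Hₖ cos 2πk/T)² + (Σₖ Hₖ sin 2πk/T)²).
  On a five-residue window this magnitude is exactly phase-invariant only
  when the analysis period completes whole cycles (T = 2.5, 5/3, …); at
  other periods the conjugate-frequency term leaks, so matched-period
  maximality holds in the phase-averaged sense.  Both properties are
  asserted in the tests exactly as stated here;
* pairwise scale products and adjacent-position autocorrelations;
* occurrence statistics: fragments are grouped by a subsequence window of
  their 5-mer (the full 5-mer and the three trimers by default), and each
  group records the mean and population standard deviation of the 16
  RMSDs.  Trimer windows give the statistics useful coverage on 5-mers
  never seen in training; a per-window "unseen" indicator marks backoff
  to the table-wide mean.  Unknown residues ('X') take the scale mean for
  physicochemical features and are treated as unseen by occurrence
  features.

## Feature selection

`stepwise_select()` implements forward entry / backward removal driven by
the partial F-statistic of the nested-model RSS comparison (1 numerator
df).  Defaults: `f_enter` 4, `f_remove` 3.9 for the iterative phase —
deliberately permissive — with the final threshold F > 100 applied
afterwards, then ranking by descending F and greedy deduplication of pairs
with |Pearson r| > 0.9 (the higher-F member survives).  Columns are
standardized internally so F values are comparable across transforms.
The per-target runs (16 targets) are merged by maximum F.

A subtlety worth recording: if the occurrence tables are computed on the
same rows used in the regression, the per-5-mer mean *is* the empirical
conditional mean of the response — a sufficient statistic.  Selection then
keeps exactly one occurrence feature per target and nothing else, and a
network trained on such features memorizes the training split while
generalizing poorly.  `pb_pipeline()` therefore cross-fits: training
chains are divided into two folds, each fold's features are computed with
the other fold's occurrence tables, while held-out chains (and the
deployed model) use tables from the full training split.  This keeps the
selection statistics and the training distribution honest about what
occurrence features look like on new chains, at no cost in training rows.

## The network

`mlp_spec()` declares four sigmoid hidden layers (library default
512-256-128-64; the pipeline's desk-scale default is 128-96-64-48) with a
linear output layer, mean-squared-error loss, and He-uniform
initialization.  Classification (DSSP-3/8) uses the same architecture on
one-hot targets with the same MSE loss; the label is the argmax output,
while in regression mode it is the argmin predicted RMSD.

Training (`train_mlp()`) uses Adam from 10⁻², dividing the rate by 5
whenever the monitored loss fails to improve by `min_delta` for
`patience` epochs, down to a floor of 10⁻⁵; a plateau at the floor stops
training.  Inside the pipeline the monitored loss is the test split, and
the validation split is reserved for reporting (the naming follows the
dataset-role convention used throughout the package).  In regression mode
the pipeline optimizes per-target z-scored outputs
(`standardize_targets`): RMSDs to compact helix-adjacent blocks span a
much narrower range than RMSDs to extended blocks, and without the
balancing the low-variance targets are under-fitted; predictions are
always returned in Å.  Training is deterministic for a fixed seed under
single-threaded BLAS.

If no feature passes the final F filter, the pipeline degenerates to the
no-information predictor: structural coordinates at the training mean and
the majority training label as the class output.  (The argmin of a *mean*
distance vector is not the majority class — means of distances are not
distances of means — so the fallback classifier is defined explicitly.)

## Synthetic data

`generate_dataset()` builds fully synthetic labelled chains so the entire
pipeline is testable without downloads:

* a first-order letter chain with strong self-transition for 'm' (0.9)
  and 'd' (0.7), moderate (0.5) elsewhere — helices form long runs, the
  stationary distribution is 'm'-dominated (~25% of fragments);
* per-residue dihedrals are the circular mean of the prototype constraints
  imposed by the letters whose five-residue windows cover the position
  (overlapping windows share angles, so fragments cannot replicate
  prototypes exactly; single-letter helix fragments sit ~0.03 Å from the
  'm' prototype);
* *true* labels are defined as the RMSD assignment of the noise-free
  backbone, making recovery exact at σ = 0 by construction;
* wrapped Gaussian noise (default σ = 5°) is added in dihedral space —
  never Cartesian — so every generated fragment remains a valid backbone;
  at σ = 5° the assignment of the noisy structure agrees with the true
  label for ≈ 90% of fragments;
* the amino-acid sequence is drawn per residue from
  softmax(β · propensity), with a packaged, version-pinned 16×20
  propensity table (one modal residue per block, two weak secondaries);
  β = 5 concentrates ≈ 92% of positions on the modal residue, β = 0
  gives a uniform sequence independent of structure.

What the fixture does **not** emulate: real amino-acid and block frequency
statistics, long-range structural context (disulfides, inter-chain
contacts), missing-density patterns, or homology structure between chains.
Passing the end-to-end checks therefore demonstrates that the machinery —
features, selection, training, evaluation — recovers a planted
sequence-to-structure signal at desk scale; it does not certify accuracy
on real proteins.

## Study sizes and reference results

The packaged end-to-end experiment uses 300 chains of 30–80 residues
(≈ 15,000 fragments, split 6:3:1 by chain so overlapping windows never
straddle splits), the 216-candidate registry, selection on 8,000
cross-fitted training rows, and the 128-96-64-48 network.  On the held-out
validation chains this run reaches Q16 ≈ 80% (chance 6.25%, majority
≈ 26%) and a mean per-block observed-vs-predicted profile correlation of
≈ 0.91 (per-block range ≈ 0.83–0.97; the irregular, rarely observed
blocks sit at the low end).  With β = 0 the selection keeps nothing, the
constant fallback engages, and accuracy collapses to the majority-class
rate — no signal, no skill.  These numbers are recomputed by the test
suite; the deterministic prototype-geometry quantities are recomputed by
`scripts/acceptance.R`.

## Numerical choices and edge cases

* Angular differences are wrapped to (−180°, 180°] before squaring;
  both RMSDA and the dihedral-noise generator use the same wrap.
* The Kabsch implementation corrects the SVD determinant, so reflections
  are never used; collinear point sets are flagged `degenerate` (the
  minimizing rotation is then a family, the RMSD still unique).
* `assign_pb()` computes the 16 distances through the trace identity
  (singular values only), which equals the explicit superposition path to
  ~10⁻¹⁴ Å and is several-fold faster.
* Fragments are dropped whenever a window touches a residue with missing
  backbone atoms or a numbering gap; a fully resolved chain of length L
  yields exactly L − 4 fragments.
* Population (not sample) standard deviations in occurrence tables;
  singleton classes get sd = 0 and a flag.
* Stepwise entry rejects candidates numerically collinear with the active
  set; constant columns are excluded with a warning.
* View-field blocks that fall off the chain repeat the nearest valid
  window and are recorded in a padding mask.

## Limitations

The desk-scale defaults are sized for a single CPU; reproducing the
published full-scale benchmarks (training on ~17,000 PISCES chains,
scoring CB513/CASP14) requires downloading those datasets and scaling the
selection and training configuration accordingly — the code paths are the
same, only the sizes change.  The synthetic generator's sequence coupling
is far stronger than real sequence-structure statistics; real Q16 from
sequence alone is a much harder problem than the fixture suggests.
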