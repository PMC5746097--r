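---
title: "Methods: fused PseAAC/PsePSSM descriptors, 2-D wavelet denoising, and one-vs-one SVM localization"
author: "PseLocWD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fused PseAAC/PsePSSM descriptors, 2-D wavelet denoising, and one-vs-one SVM localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PseLocWD)
```

# The prediction problem

Apoptosis proteins act at specific subcellular locations (cytoplasm,
membrane, nucleus, mitochondria, secreted, endoplasmic reticulum), and
knowing the location constrains both function and drug-target reasoning.
Given only a primary sequence — and, when available, an evolutionary
profile from an iterative database search — the task is to assign one of
k location classes. PseLocWD implements a classical and still widely
used recipe for this task: fuse a composition-plus-order descriptor of
the sequence with a profile-derived descriptor, denoise the resulting
dataset-level feature matrix with a 2-D wavelet transform, and classify
with a one-vs-one multiclass SVM evaluated by the jackknife.

# Descriptors

## Pseudo-amino-acid composition (PseAAC)

A sanitized sequence of length $L$ over the 20-letter alphabet is mapped
to $20 + \lambda$ components. The first 20 are the weighted residue
frequencies $f_u$; the remaining $\lambda$ are sequence-order
correlation factors

$$\tau_k \;=\; \frac{1}{L-k}\sum_{i=1}^{L-k}\Theta(R_i, R_{i+k}),
\qquad k = 1,\dots,\lambda,$$

with the type-1 correlation function
$\Theta(R_i,R_j) = \tfrac13\!\sum_{p}\,[P_p(R_j)-P_p(R_i)]^2$ over three
standardized physicochemical properties $P_p$: hydrophobicity,
hydrophilicity and side-chain mass. Every component is divided by the
common denominator $\sum_u f_u + \omega \sum_k \tau_k$, so the vector is
non-negative and sums to one — an invariant the tests assert for random
sequences. Standardization is the usual convention: each property column
is centred and scaled to unit *population* SD over the 20 amino acids.

The property values are bundled as a plain-text fixture
(`inst/extdata/aa_properties.tsv`, the canonical table used by the
PseAAC web server) and can be overridden via `aaPropertyTable(path)`.
Defaults: $\lambda = 15$ and $\omega = 0.05$, the operating point; both
are arguments everywhere they matter. $\lambda$ must be smaller than
the sequence length, so the shortest admissible benchmark sequence
($L = 50$) caps $\lambda$ at 49.

Non-standard residues are resolved before feature extraction:
B→D, Z→E, U→C, O→K preserve length where the chemistry is inferable;
X and anything else is removed (`sanitizeSequence()`).

## Pseudo-PSSM (PsePSSM)

A PSI-BLAST profile is an $L \times 20$ matrix of log-odds scores
$P_{i,j}$ (column order A R N D C Q E G H I L K M F P S T W Y V). Each
entry is squashed into $(0,1)$ by the sigmoid $f(x) = 1/(1+e^{-x})$.
The descriptor concatenates the 20 column means $\bar P_j$ (the
PSSM-ACC part) with, for each lag $t = 1,\dots,\xi$,

$$\theta_j^{t} \;=\; \frac{1}{L-t}\sum_{i=1}^{L-t}
\bigl(f(P)_{i,j} - f(P)_{i+t,j}\bigr)^2,$$

tier-major (all 20 columns of lag 1, then lag 2, …), giving
$20 + 20\,\xi$ values; $\xi = 10$ (the operating point) gives 220.
Row order matters for $\theta$ but not for $\bar P$ — a property the
tests check by permuting profile rows.

Real profiles are parsed from the PSI-BLAST ASCII dialect
(`readPssm()`). Because running PSI-BLAST against nr is out of scope, a
surrogate generator (`surrogatePssm()`) substitutes the BLOSUM62 row of
each residue plus rounded Gaussian noise (SD 1 by default) — realistic
score ranges and residue-dependent structure without any database. The
surrogate is clearly a synthetic stand-in: it carries composition
information but no true evolutionary conservation.

## Fusion

`buildFeatureMatrix()` concatenates PseAAC then PsePSSM per protein:
$d = (20+\lambda) + (20+20\,\xi)$, i.e. $35 + 220 = 255$ at the
operating point. Block spans and parameters travel with the
`FeatureMatrix` object, and no additional scaling is applied — the two
blocks already live on comparable $[0,1]$-ish scales by construction.

# 2-D wavelet denoising

The dataset matrix (proteins × features) is treated as one 2-D signal
$s(i,j) = f(i,j) + \sigma e(i,j)$ and denoised in three steps:
multilevel separable DWT; thresholding of the horizontal, vertical and
diagonal detail subbands at every level (the approximation is never
touched); inverse transform.

Implementation choices, all testable and all tested:

* **Families.** db1/db4/db8, sym3/sym7, coif2/coif4, bior1.1/2.4/3.3.
  Filter banks are the standard published coefficients, frozen in
  `R/wavelet-filters.R`; a frozen reference transform from an
  independent implementation pins the convention, and perfect
  reconstruction (≤ 1e−8 max-abs) is asserted for every family at
  levels 3–5 on the 317 × 255 geometry.
* **Boundary policy.** Half-point symmetric extension by default. Each
  analysis step keeps $\lfloor (N + \ell - 1)/2 \rfloor$ coefficients
  per branch ($\ell$ = filter length), which makes the transform
  slightly redundant but exactly invertible for arbitrary, non-dyadic
  sizes — exactly what a 317 × 255 matrix needs. A `periodic`
  (circular) policy is also provided for orthogonal families on even
  lengths; that variant is orthonormal, so Parseval energy conservation
  holds exactly and is asserted there. Under symmetric extension
  Parseval cannot hold exactly (boundary redundancy), which is why the
  energy test uses the periodic mode.
* **Admissible level.** Decomposition may continue while the running
  approximation stays longer than $\ell - 1$ in both dimensions (the
  fixed point of the length recursion). At 255 columns this admits
  level 5 for every supported family; a too-deep request errors with
  the maximum stated. Practically: db8 at level 4 (the operating point)
  needs roughly 50+ rows, so very small datasets should use a shorter
  filter or a lower level.
* **Thresholds.** The default `universal` rule is the single global
  threshold $\hat\sigma\sqrt{2\ln n}$ with
  $\hat\sigma = \mathrm{median}(|d^{1,D}|)/0.6745$ (MAD on the finest
  diagonal subband, $n$ = element count) — the standard behavior behind
  toolbox "default threshold" denoising. The `birge-massart` rule is
  per-level, per-direction: level $t$ (1 = finest) keeps the
  $\mathrm{round}(M/(J+2-t)^{\alpha})$ largest-magnitude coefficients
  ($M$ = finest-subband size, $\alpha = 1.5$ by default, $\alpha > 1$
  enforced), the threshold being the magnitude of the next coefficient.
  Soft shrinkage $\mathrm{sign}(x)\max(|x|-\mathrm{thr},0)$ is the
  default mode; hard is available.
* **Efficacy.** On seeded low-rank-plus-noise fixtures at the 317 × 255
  geometry, 2-D denoising at the operating point reduces MSE against
  the clean matrix in 10/10 seeds (ratio ≈ 0.004).

## The leakage caveat, measured

Denoising the *entire* matrix before the jackknife means every training
fold has already seen smoothed information from the held-out row. Worse,
2-D smoothing couples *neighbouring rows*, and in class-sorted datasets
neighbours share the class label. On synthetic data with **zero** class
signal, a kNN classifier after full-matrix 2-D denoising reaches ~94%
jackknife accuracy purely from this row-coupling; shuffling the rows
before denoising restores chance (~22–25%). This package therefore
defaults to the faithful protocol (denoise everything, then jackknife)
but provides `leakFree = TRUE`, which refits the denoiser inside every
fold on the training rows only and applies a 1-D denoise with the
training-derived threshold to the held-out row. Any accuracy quoted
from the faithful protocol should be read with this caveat in mind.

A second artifact matters for no-signal controls: leave-one-out plus
one-vs-one max-margin SVMs *anti-learns* on signal-free data. The
held-out sample's class is always the training minority (29 vs 30), the
underfit binary machines degenerate to majority voting, and accuracy
drops to ~0 rather than 1/k. Chance-level recovery is therefore checked
with the kNN baseline (no majority bias) on undenoised features, while
the SVM is required not to exceed chance — together these verify that
the generator and pipeline leak no signal, without misreading the
well-known LOOCV artifact as a defect.

# Classification

For k classes, $k(k-1)/2$ binary soft-margin SVMs are trained (LIBSVM
via e1071, features unscaled), one per unordered class pair; prediction
counts votes, and ties fall to the largest aggregate signed decision
value (remaining exact ties to the lexicographically first class, with
a warning). Kernels: linear (default), cubic polynomial, RBF, sigmoid;
$\gamma$ defaults to $1/d$, coef0 to 0, and $C$ to 1 (the toolbox
default — the original study never reports $C$). One consequence worth
knowing: with $C = 1$ and these small-scale features the fit does not
always realize the hard-margin limit, so the textbook "resubstitution
is perfect on separable data" ceiling is only guaranteed at large $C$;
the acceptance checks use $C = 100$ for that specific property.

Baselines mirror their stated settings: kNN with 3 Euclidean
neighbours, random forest with 100 trees (seeded), Gaussian naive
Bayes, and a decision tree with impurity defaults. For ROC purposes the
SVM per-class score is the vote count plus a bounded margin-sum term in
$(-0.5, 0.5)$; baselines use their native class scores, except kNN,
where only the winning-class vote fraction is available and the
remaining mass is spread uniformly — kNN ROC is accordingly coarse.

# Evaluation

Jackknife (exactly n leave-one-out folds) and self-consistency
(resubstitution). From the k × k confusion matrix each class is
collapsed one-vs-rest; Sens = TP/(TP+FN), Spec = TN/(TN+FP), MCC from
the standard binary formula with the 0/0 convention MCC = 0 plus a
warning. Overall accuracy is trace/n, and the single summary MCC is the
macro-average of the per-class values (the aggregation is otherwise
ambiguous). ROC uses the one-vs-rest strategy: per-class staircases are
interpolated onto a common 101-point FPR grid, macro-averaged, and the
AUC is the trapezoidal area of the averaged curve; a class with
constant scores contributes the chance diagonal with a warning.

# The synthetic-data module

`syntheticProteinSet()` emulates what the benchmark datasets look like
to this pipeline: k labeled classes, variable lengths (uniform 50–150,
respecting the λ ≤ 49 bound), class-conditional residue-composition
bias, and per-sequence profiles. One base residue distribution is drawn
from a symmetric Dirichlet (concentration 2) per seed; class c
upweights a class-specific residue triplet by $1 + \mathrm{separation}$
(disjoint triplets up to k = 6). `separation = 0` makes classes exactly
exchangeable — the chance-level control; the default 10 concentrates
roughly two-thirds of the composition on the triplet, the
strongly-separated regime. Defaults (k = 4, 30 per class, n = 120) are
the regime the recovery checks run at.

What the generator does *not* emulate: homology structure, real
evolutionary conservation (surrogate profiles carry only residue
identity plus noise), database-dependent profile quality, and class
imbalance. Passing recovery tests therefore demonstrates that the
pipeline extracts planted composition/profile signal — not that it
reproduces benchmark accuracies on real SWISS-PROT data, which would
require the original sequences and PSI-BLAST-vs-nr profiles.

`makeNoiseFixture()` provides the signal-plus-noise model for the
denoising tests: a rank-r sum of smooth outer products plus
$\sigma\,N(0,1)$ noise at the 317 × 255 geometry.

# Problem sizes and runtime choices

The test suite and the acceptance script run entirely on synthetic
data: dimension and formula checks on sequences of length 25–200 and
profiles of 6–20 rows; wavelet integrity on 317 × 255 matrices;
recovery runs at n = 120 (jackknife, 3–10 seeds) and n = 60
(self-consistency). These sizes keep a full run in the minutes range on
one CPU while exercising the exact non-dyadic geometry the method
operates on.

# Known limitations

* Benchmark accuracies on CL317/ZW225/ZD98 are not reproduced here —
  they require the original accession lists and PSI-BLAST profiles.
* The faithful denoising protocol leaks across folds by construction
  (measured above); use `leakFree = TRUE` for honest generalization
  estimates.
* Wavelet-packet default thresholds and translation-invariant
  (cycle-spinning) denoising are not implemented.
* The kNN score matrix is a coarse reconstruction (winning-class vote
  fraction only).
* `periodic` extension is restricted to orthogonal families and even
  per-level lengths; it exists to make the orthogonality/Parseval
  property testable, not as a denoising default.
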