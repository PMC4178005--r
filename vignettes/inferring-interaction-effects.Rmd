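---
title: "Inferring activating and inhibiting interaction effects from knockdown phenotypes"
author: "ppisign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring activating and inhibiting interaction effects from knockdown phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Signaling pathways annotate each protein-protein interaction (PPI)
with a sign: A activates B, or A inhibits B. High-throughput screens
discover *that* two proteins interact, but not the sign. `ppisign`
infers the sign from single-gene RNAi knockdown phenotypes in
live-imaging screens, on the premise that knocking down either member
of an activating interaction perturbs the same downstream process and
therefore produces **similar** cell populations, while the members of
an inhibiting interaction pull the process in opposite directions and
produce **dissimilar** populations.

The pipeline has five stages.

1. **Cell phenotyping.** Nuclei are segmented by Otsu thresholding
   (the grey-level threshold maximizing between-class variance of the
   histogram); touching nuclei are deliberately not split, because
   clusters of cells form their own morphological class. Each object
   is described by a fixed ~30-feature registry: intensity summaries,
   shape descriptors, 13 Haralick texture features, a subset of six
   Zernike moment magnitudes and edge features, and classified into
   four morphological classes (interphase, apoptosis, mitosis, shape)
   by a one-vs-one SVM trained on annotated nuclei.

2. **Pair descriptors.** For a gene pair (A, B) four feature families
   are concatenated:
   * *fraction features* - absolute differences of the per-class cell
     fractions, overall cell count and intensity median/SD;
   * *maxima features* - for seven canonical mitotic-screen
     phenotypes, the maximal knockdown-minus-control count difference
     over the time course and its time point, differenced between A
     and B;
   * the *LDA-performance feature* - the held-out accuracy of a
     linear discriminant trained to tell A-cells from B-cells. An
     accuracy near 0.5 means the populations are statistically
     indistinguishable (candidate activation); accuracy near 1 means
     clearly separable (candidate inhibition). This turns classifier
     performance itself into a similarity measure;
   * *proximity features* - |sim(A, r) - sim(B, r)| against a common
     reference gene set r, measured once by LDA performance and once
     by Euclidean distance between maxima profiles.

3. **Effect classifier.** An ensemble of RBF-kernel SVMs is trained on
   descriptors of reference activating and inhibiting PPIs under
   repeated stratified cross-validation; each SVM casts one
   activation vote on each held-out pair. Vote-count thresholds are
   then calibrated on the held-out votes to a target precision
   (default 0.8) and applied to interactions of unknown sign.

4. **ESR.** The Effect Similarity Rate of genes i and j is
   `tanh(5 X)` with X the difference between the fractions of third
   genes receiving concordant and discordant calls from i and j. It
   is bounded in [-1, 1], odd and strictly increasing in X. Genes are
   clustered on the distance `d = (1 - ESR) / 2`.

5. **Enrichment validation.** Predictions are checked against
   functional classes derived from Pfam domains: for each unordered
   class pair, the enrichment is the fraction of activating
   predictions containing the pair over the corresponding inhibiting
   fraction, with a Pearson chi-square p-value on the 2x2 table.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `trainFrac` | 0.6 | fraction of time points training each pairwise discriminant; the rest is the held-out test portion |
| `lastNTimepoints` | 40 | trailing time-point window used by the discriminants, where the knockdown phenotype is expressed |
| `nRef` | 10 | reference genes for the proximity features |
| `stratumSize` | 40 (scaled); 80-400 at full scale | pairs per class in each balanced SVM training sample |
| `nRepeats`/`nFolds`/`svmsPerFold` | 2/5/5 (scaled); 10/10/10 at full scale | ensemble layout; the full-scale product is a 1000-SVM ensemble |
| `gridExp` | -5..5 | C and gamma searched over 2^n by inner 5-fold cross-validation |
| `targetPrecision` | 0.8 | precision the vote cutoffs are calibrated to |
| `effectSize` | 6 | synthetic-screen centroid separation of inhibiting pairs, in units of the within-gene noise SD |

Vote cutoffs are stored as *fractions* of the total votes so scaled
ensembles remain comparable with the full-scale convention (cutoffs
920/1000 for activation and 88/1000 for inhibition at 80% precision).

## The synthetic screen generator

Real screens of this design image each knockdown over 96 time points
(48 h at 30 min intervals); the generator reproduces that layout with
a configurable number of cells per time point. Each gene receives a
latent Gaussian phenotype centroid. Genes joined by activating edges
share a centroid exactly (union-find over activating edges); an
inhibiting edge places the two activation components `effectSize *
noiseSd` apart along a random unit vector, propagated breadth-first
so chains of constraints stay consistent. Cycles that cannot all be
satisfied keep the breadth-first placement; their residual distances
are of the right order, and they are rare in sparse networks. At
`effectSize = 0` every labeled pair collapses onto one centroid, so
activating and inhibiting pairs are statistically indistinguishable -
the null condition used to verify that the classifier does not
invent signal.

Class-count time series interpolate linearly from a common start
mixture (mostly interphase) to a gene-specific end mixture obtained
by a softmax perturbation of the control mixture driven by the gene's
centroid; counts are multinomial draws. This ties the fraction and
maxima features to the same latent phenotype that drives the per-cell
features, without modeling mitosis mechanistically. The reported
intensity tracks the first latent coordinate. All randomness flows
from one integer seed through deterministic per-gene sub-seeds, so a
screen is bit-reproducible from its seed.

What the generator does *not* emulate: chromatin texture (the image
fixtures are geometric phantoms), cell tracking, time-correlated
noise, batch effects or off-target knockdown. Passing tests therefore
demonstrate that the pipeline recovers planted effect structure of
this generative form - not performance on real screen images.

## Numerical and design choices

* **Discriminant regularization.** Cell-feature covariances are
  routinely singular; the pooled within-class covariance is shrunk
  toward its diagonal with the smallest shrinkage weight (from a
  fixed ladder) that yields a well-conditioned solve, with a ridge
  fallback. A singular covariance therefore degrades gracefully.
* **Split granularity.** The 60/40 discriminant split assigns whole
  time points - the same time points for both genes - so
  near-duplicate cells of one frame never straddle the split, and the
  result is exactly symmetric under swapping the two genes. Whether
  the original procedure split per image or per cell is not
  documented; per-time-point is this package's documented choice.
* **Ties.** Maxima peak times take the earliest maximum. Grid-search
  ties take the smallest C, then the smallest gamma (the smoother
  model). Leaf order in ESR clustering is the deterministic
  `hclust` merge order.
* **Fold assignment** is stratified per class, keeping every training
  complement balanced enough to supply the stratum; each held-out
  pair collects votes only from the SVMs of its own fold across
  repeats, so no classifier votes on a pair it saw. (The alternative
  reading, in which every pair receives all ensemble votes,
  leaks training pairs into their own prediction and is not used.)
* **ESR denominator.** "Fractions of similar and dissimilar effects"
  is read over *all* third genes of the universe; third genes with a
  `none` call dilute X toward zero. The alternative - confident calls
  only - is available as `denominator = "confident"`.
* **Reference genes** for the proximity features default to a seeded
  random sample outside the evaluated pairs; the selection rule is
  configurable because the criterion used at full scale is not
  specified by the method's public description.
* **Chi-square** is plain Pearson without continuity correction (the
  correction is a flag); expected-zero cells yield a flagged NA
  rather than a number.
* **Subset ESR comparisons** use a one-sided Wilcoxon rank-sum test
  with normal approximation (ESR values tie heavily at saturation).
* **Phenotype map.** The seven canonical phenotype scores are sourced
  from the four morphological classes many-to-one (mitotic delay and
  dynamic change from mitosis; grape and cell death from apoptosis;
  binuclear, polylobed and large from shape); screens emitting the
  seven classes directly can pass an identity map.

## Problem sizes used in the shipped checks

The test suite exercises the full pipeline at desk scale: screens of
115 genes with 50 activating and 50 inhibiting pairs, 4 cells per
time point over 96 time points, 8 latent dimensions, 5 reference
genes, and a 2x5x5 ensemble with stratum 40. The strong-effect
condition uses `effectSize = 6`; the null condition (`effectSize =
0`) is replicated ten times and its mean cross-validated AUC checked
against the chance band. The inner grid search runs the full 11x11
exponent grid for the strong-effect run and a coarse 3x3 grid for the
null replicates, where no parameter choice can create signal.

## Known limitations

* Constraint cycles mixing activating and inhibiting edges may be
  unsatisfiable in the generator; they keep breadth-first placement.
* A gene's centroid, not a mechanistic cell model, drives its class
  mixture; absolute fraction values are not meant to match real
  screens.
* The sign-score baseline implements the published z-score/correlation
  procedure on this package's features; its published performance
  numbers depend on data this package does not ship.
* Full-scale reference results (AUC 0.75/0.82, cutoffs 920/88,
  precision 92.9% at full stringency) require the original screen
  images and curated interaction sets; they are reference behavior,
  not shipped checks.
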