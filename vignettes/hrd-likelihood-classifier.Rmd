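---
title: "Likelihood-based HRD classification from sparse mutation catalogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood-based HRD classification from sparse mutation catalogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdsig)
```

## The model and its assumptions

`hrdsig` assigns a tumour's somatic mutation catalog to one of K
signature phenotypes — clusters of tumours with a shared profile of
mutational-signature activity — and reports the posterior probability that
the tumour belongs to an HRD-associated phenotype. The generative
assumption is deliberately simple: conditional on phenotype membership,
the n observed mutations are independent draws from the phenotype's mean
spectrum, a probability vector over 179 mutation categories (96
trinucleotide-context substitutions + 83 indel contexts). The likelihood
of a catalog is then the product of per-category template probabilities,
and Bayes' theorem with cluster-size priors yields the posterior over
phenotypes. p(HRD) is the posterior mass on the flagged clusters, and the
HRD call uses a strict cutoff (default 0.79, an F-score-optimal operating
point; `call_hrd()` exposes the cutoff as an argument).

The independence assumption ignores mutation-rate heterogeneity along the
genome and between samples; what it buys is well-posedness at arbitrarily
low mutation counts — every mutation simply adds one term to a sum of
log-probabilities — which is precisely the exome regime (tens of SNVs,
a median of a few indels) where per-sample signature fitting breaks down.

Category definitions follow the field's conventions. Substitutions are
reported on the pyrimidine strand with their two flanking bases.
Indels: 1 bp events are labeled by base (purines complemented onto the
C/T channels) and homopolymer context; longer deletions are tested first
for a tandem-repeat context (≥2 copies of the deleted unit, counting the
deleted copy and 3'-adjacent copies), then for flanking microhomology
(longest shared prefix of the deleted sequence with the 3' flank, or
shared suffix with the 5' flank, whichever is longer), and fall back to
the repeat-count-1 bin; longer insertions are binned by pre-existing unit
copies, with no-context insertions in the count-0 bin. Homopolymer and
repeat counting runs 3' of the event on the reported strand, which is
exact for left-aligned (VCF-normalized) alleles. Bins cap at the scheme's
terminal categories (6+ for deletion contexts, 5+ for insertion contexts,
microhomology capped per deletion-length class), giving exactly
12 + 12 + 24 + 24 + 11 = 83 indel labels.

## Coordinates

All positions are 1-based inclusive, exactly as in VCF, from the readers
through the classifiers; there is no internal conversion step. R's native
indexing is 1-based, so a 0-based internal convention would require a
translation at every substring operation — keeping a single convention
end-to-end removes the off-by-one surface entirely. MAF's `"-"` indel
dialect is re-anchored to VCF-style alleles at the reader boundary using
the reference sequence, because context classification requires anchored
alleles.

## Building models

Cluster templates are the arithmetic mean of member samples' *proportion*
vectors, not pooled counts: pooling would let hypermutated samples
dominate a phenotype's template. Templates are floored at a smoothing
constant (default 1e-6) and renormalized, so the likelihood never hits a
hard zero for a category unseen in a small training cluster; after
renormalization entries sit at floor/(1 + 179·floor), i.e. strictly
positive. Priors are cluster sizes over the cohort and always sum to 1;
when degenerate (singleton) clusters are discarded upstream, priors are
recomputed over the retained clusters.

Spectra can be normalized for exome/genome composition: each category
count is multiplied by a user-supplied exome-to-genome frequency ratio
before renormalization. The ratio tables are genome-build artifacts, so
the package ships only the all-ones default (`uniform_factors()`) and
reads real tables from TSV. Normalization is applied to each sample
*before* cluster means are taken, so templates live on the exome scale
their application targets.

Exposure fitting (`fit_exposures()`) uses non-negative least squares on
proportion vectors rather than iterative signature-subtraction
heuristics: the objective is the same Euclidean reconstruction error,
but NNLS solves it exactly and deterministically. SBS and indel exposures
are fitted separately on their channels and concatenated. Clustering of
exposure profiles (`cluster_exposures()`) is Gaussian-mixture modelling
with the number of clusters and the covariance family (spherical,
diagonal, full) selected jointly by BIC, via mclust; singleton clusters
are flagged for the caller to discard.

## Numerical choices

* All probability arithmetic is in log space; posteriors are normalized by
  log-sum-exp. Catalogs of 10^5 mutations remain exactly normalized.
* Posterior ties break toward the lowest cluster index;
  `optimize_threshold()` ties break toward the smallest threshold.
* An empty catalog is an error, never an HR-proficient call: a
  mutation-free sample carries no evidence either way, and defaulting
  would bias cohort summaries.
* `reweight_indels(factor = 1)` returns the input model bit-for-bit.
  For other factors the indel entries are multiplied and each template
  renormalized (default); a `"raw"` mode leaves templates unnormalized,
  multiplying the per-mutation likelihood terms directly. Renormalizing
  keeps the generative reading valid and both modes coincide at factor 1.
* The constrained downsampler draws round(n·prop) indel events
  (round-half-to-even) and the remainder from the SBS channel, each
  multinomially on the row's within-channel proportions.
* One root seed drives every experiment; each (size, proportion,
  iteration) grid cell derives its own child stream, so partial reruns
  reproduce exactly, and the weight sweep scores the *same* downsampled
  catalogs under every factor, isolating the weighting effect.

A structural fact about the weight sweep is worth recording: with
renormalized reweighting, a fixed downsample size n, and clusters of
*equal* indel mass, the factor cancels exactly — per-category ratios
within the indel channel are unchanged, and the channel-mass penalty
n·log(1 − I + f·I) is identical across clusters — so AUC is provably
invariant. The weighting effect only manifests when cluster indel masses
are heterogeneous (as they are in real phenotype models, where HRD
clusters are indel-rich), which is how the package's shipped sweep study
is constructed: six clusters of unequal indel mass, two HRD-flagged, with
an uninformative shared indel profile in the data. There, mean AUC peaks
at factor 1 and declines monotonically above it.

## The transcriptional signature

Gene selection is repeated k-fold cross-validated multinomial elastic-net
regression (grouped penalty: a gene's class coefficients enter or leave
together) with re-randomized folds, keeping the genes selected at
lambda.min in *every* iteration. Two choices deserve note:

* Cross-validated error is measured as misclassification rate
  (`type.measure = "class"`). With multinomial deviance the CV curve is
  monotone decreasing on separable low-dimensional problems, so its
  minimum degenerates to the smallest lambda and selects nearly every
  gene; the misclassification curve has a genuine minimum and glmnet
  tie-breaks toward the stronger penalty.
* "Selected" means a nonzero coefficient in any class; under the grouped
  penalty this coincides with all-class selection.

The intersection-over-iterations rule is a stability filter, not a
significance test: with a fixed data matrix, genes with spuriously large
class differences can survive every fold split, so on pure-noise input
the consensus shrinks to a handful of chance genes rather than emptying
entirely. Class weighting (`"balanced"`) is inverse class frequency
normalized to mean 1.

Scoring is nearest-centroid: per-group mean expression over the signature
genes, Pearson correlation of a new profile against each template, and
for the two-group variant an HRD score r(HRD) − r(HR-proficient).
Templates record the expression scale they were built on (default
log-type scales; training and scoring scales must match — Pearson r is
invariant to per-sample affine maps, which limits the damage of scale
mismatches, but pinning one scale keeps results reproducible). Genes
absent from a sample are dropped from the correlation for that sample
only; samples with fewer than 3 usable genes or zero variance are flagged
unusable, never silently scored 0. Single cells pass a standard QC filter
(200–6000 detected features, mitochondrial fraction strictly below 15%,
then per-cell scaling and log1p); a cell is HRD iff its score is strictly
positive, and per-sample summaries report the HRD-cell proportion and
mean score.

## What the synthetic generators emulate — and what they do not

`generate_cluster_model()`/`generate_catalogs()` emulate the data regime
the classifier targets: cluster-structured cohorts with Dirichlet-drawn
templates (sharpness set by the concentration), a controllable indel
probability mass, and negative-binomial per-sample loads with mean 50 and
dispersion 1 — the low-count, overdispersed exome regime that motivates
phenotype-level classification. `generate_expression()` plants
class-shifted genes in Gaussian log-scale noise;
`generate_cell_cohort()` gives each sample an HRD-fraction parameter θ
and mixes cells from HRD-like and HR-proficient-like programmes with
negative-binomial depth and dropout. `generate_reference_and_variants()`
engineers a ~10 kb reference of context blocks (homopolymers of length
1–8, tandem repeats of unit 2–5, microhomology-flanked deletion sites,
SNV contexts on both strands) where each variant's category is known *by
construction*, giving a truth tally that never touches the classifier
code.

These generators match the model's assumptions by design, so passing
tests demonstrate correctness of the machinery — not that real tumours
satisfy the independence assumption, that real cluster templates are
Dirichlet-like, or that real expression noise is Gaussian. Cohort-level
performance numbers on consortium data (controlled-access ICGC/TCGA) are
out of the package's testable scope; the simulation studies reproduce the
qualitative phenomena (indel inclusion improves low-count classification;
over-weighting uninformative indels degrades it) at desk scale.

## Problem sizes used in the shipped experiments

The package's own experiments run at sizes chosen to make the statistical
behaviour visible while staying desk-scale: simulation grids of 100
iterations over 11 indel proportions at load 50 on 30-sample cohorts;
recovery curves of 1000 draws per load; consensus selection with 20
iterations of 10-fold CV on 200 samples × 100 genes; single-cell cohorts
of 10 samples × 200 cells. The full-scale procedure (1000 CV iterations,
thousands of genes) is a parameter change, not a code change.

## Known limitations

* Doublet-base substitutions are not classified; catalogs are SBS + indel
  only.
* The ID83 context conventions (3' counting, both-flank microhomology
  with maximum) are pinned and oracle-tested, but other implementations
  differ in edge cases (non-left-aligned input, nested repeats);
  inputs should be VCF-normalized.
* Exome/genome ratio tables are inputs; the package does not derive them
  from an annotation.
* Expression deconvolution is an input contract: scoring accepts any
  matrix, deconvolved or not, and records which it was given.
* The classifier's accuracy claims on real cohorts depend on the quality
  of the cluster model supplied; the package validates the machinery, not
  any particular published model.
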