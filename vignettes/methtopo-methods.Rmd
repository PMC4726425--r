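---
title: "Predicting CpG methylation state from sequence and 3D genome topology"
author: "methtopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting CpG methylation state from sequence and 3D genome topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methtopo)
```

## The prediction problem

Bisulfite sequencing determines the methylation state of only a fraction
of the genome's CpG dinucleotides. methtopo predicts the binary state
(methylated / un-methylated) of a CpG site from two kinds of evidence:

* **sequential neighbourhood** — the DNA sequence composition of a
  fixed-size window (*window-A*, 500–1000 nt) centred on the target CpG,
  and optionally the averaged RRBS percent-methylation of the CpG sites
  inside it;
* **spatial neighbourhood** — Hi-C contacts place distal genomic regions
  next to the target in three-dimensional space. Each qualifying contact
  end defines a *window-B* of the same size, and the composition and
  averaged methylation of all window-Bs enter the feature vector.

The premise is that spatially proximate regions tend to share chromatin
state, so the methylation of 3D neighbours is informative about a site
whose sequential neighbourhood alone is ambiguous.

## Feature schemes

Two fixed feature schemes are supported, selected by `scheme` in
`build_feature_matrix()`:

* **Scheme 1 (23 features).** Window-A: the four nucleotide ratios, eight
  IUPAC pattern frequencies (AAWGGR, TGRAAT, AAT, ATGVAA, ACG, GC, CG,
  TG) and the window methylation average (`Ave_meth`). Window-B block:
  four ratios, five pattern frequencies and the methylation average, each
  averaged over all window-Bs. Window-Bs are anchored by contacts with
  one end in window-A; a window-B within 1000 nt (nearest edge) of the
  target on the same chromosome is discarded, so this block never
  restates the sequential neighbourhood. Sites without any window-B are
  skipped.
* **Scheme 2 (109 features).** `Ave_meth` is removed — the model never
  sees the methylation of the sequential neighbourhood — and the window-A
  description is widened: 13 pattern frequencies and 74 pseudo
  trinucleotide composition (PseTNC) components. Window-Bs are collected
  through a *Hi-C range* (an interval of `hic_range` nt centred on the
  target, typically 10–50 kb); only contacts whose ends are separated by
  more than the range (or on different chromosomes) are kept, so all
  retained neighbours are genuinely long-range. A site with no qualifying
  contact keeps a zero window-B block with `n_window_b = 0`.

Pattern frequencies divide the overlapping match count by the number of
alignment positions (`L - k + 1`), which bounds them by 1 and makes
windows of different (clipped) lengths comparable; window-B features are
averaged after this per-window normalisation. Matching is on the forward
strand; positions containing N never match.

### PseTNC

The PseTNC vector combines the 64 trinucleotide frequencies with
`lambda = 10` sequence-order correlation tiers. Tier *j* is the mean over
window positions *i* of the squared property distance between the
trinucleotides starting at *i* and *i + j*, averaged over properties;
both blocks share the denominator `1 + w * sum(theta)` with weight
`w = 0.05`, so the 74 components sum to 1. The property table is a
configuration input (`pse_tnc_config()`). The default shipped table is
built programmatically from interpretable quantities: unified
nearest-neighbour duplex thermodynamics (enthalpy, entropy and free
energy at 37 °C, summed over the trinucleotide's two dinucleotide steps)
plus GC fraction, purine fraction and CpG-step count, each standardised
to zero mean and unit variance over the 64 trinucleotides. Users with a
preferred published property set can substitute it directly.

## Labeling

Percent-methylation is continuous in [0, 1]; two rules convert it to
balanced binary classes:

* **alpha/beta rule** (`b1_alpha_beta`): sites below `beta = 0.01` are
  un-methylated; `alpha` is then computed on the labeling population so
  the methylated class (`pm > alpha`) matches the un-methylated count as
  closely as possible (within one sample). Both inequalities are strict,
  so no site can receive two labels. When training and test populations
  are separate, the training alpha is reused for the test set.
* **fixed rule** (`b2_fixed`): exactly 0 is un-methylated, at least 0.9
  is methylated, everything else is unlabeled.

Class balancing for training uses `downsample()` (drop random
majority-class samples; used for the SVM) or `upsample()` (duplicate
random minority samples; used for the deep model, whose test folds stay
unbalanced).

## Models

### Stacked denoising autoencoder

The deep model is a stack of tied-weight denoising autoencoders with a
softmax top layer. Pre-training is layer-wise and unsupervised: each
layer corrupts its input by masking (every component independently zeroed
with probability `corruption`, default 0.1), encodes with a sigmoid,
reconstructs with the transposed weights, and descends the reconstruction
cross-entropy by minibatch gradient descent (learning rate 0.01,
minibatch 20). Fine-tuning then trains the whole network plus the softmax
layer on the class labels with one global learning rate, early-stopping
on validation zero-one error.

Numerical choices worth knowing:

* Tied decoder weights (`W' = t(W)`) are the default; the reconstruction
  bias is separate.
* Hidden weights start from a uniform Glorot-style draw scaled ×4 for the
  sigmoid; all biases and the softmax layer start at zero, so an
  untrained model outputs uniform probabilities and ties resolve to the
  negative class.
* Reconstructions are clamped to `[1e-7, 1 - 1e-7]` inside the
  cross-entropy; gradients are verified against finite differences to
  1e-5 relative error in the test suite.
* Early stopping keeps the best-validation parameters. The patience
  default is 100 epochs against the 1000-epoch cap: small up-sampled
  validation folds often reach zero error within a few epochs, and an
  aggressive patience would return a model whose training had barely
  begun. With shorter epoch budgets (e.g. the 10/100 protocol used for
  scheme-2 evaluation) this effectively trains to the epoch cap.
* One master seed drives initialisation, corruption and shuffling, so
  training is bit-reproducible.

Inputs must lie in [0, 1] for the cross-entropy to be meaningful. All
features of both standard schemes are in [0, 1] by construction (ratios,
frequencies, methylation averages, PseTNC components), so the pipeline
feeds the matrix unscaled. Min–max rescaling of the near-constant PseTNC
components would amplify noise dimensions — it measurably degrades the
RBF-kernel SVM — so `fit_scaler()`/`apply_scaler()` exist for
out-of-range custom features but are not applied to the standard schemes.

### SVM baseline

The baseline is a kernel SVM (libsvm backend): polynomial kernel
`(u·v + 1)^3` with `C = 5` for scheme 1, RBF kernel with `gamma = 9` and
the backend default `C` for scheme 2. Its real-valued decision output is
cut at `mu` (default 0) to classify, and sweeping `mu` over [-2, 2]
yields ROC curves. The backend's decision-value sign depends on the order
classes appear in the training data, so `train_svm()` orients it on the
training rows once, making positive values always favour the positive
class.

## Evaluation protocols

* `loocv_b1()` — leave-one-out: each site is predicted once; for the deep
  model the remaining sites are split 50/50 into fine-tuning and
  validation halves and the fine-tuning half doubles, unlabeled, as the
  pre-training set; the SVM trains on all remaining sites. Confusion
  counts are pooled over rounds (the per-round mean is also reported).
* `kfold_b2()` — stratified 5-fold: per round one fold is the untouched
  test set; the deep model fine-tunes on three up-sampled folds with one
  up-sampled validation fold (pre-training on a separate unlabeled matrix
  when provided), the SVM trains on four down-sampled folds. Metrics are
  reported per fold, as the fold mean, and pooled.
* `holdout()` — blind test with explicit train/test row sets, reusing the
  same balancing and validation mechanics.

Folds are stratified by class; at desk-scale sample sizes unstratified
folds would regularly lose a class entirely. Matthews correlation is
defined as 0 when any factor of its denominator vanishes.

## The synthetic data generator

`simulate_dataset()` produces a genome (FASTA), a percent-methylation
track, a Hi-C contact list and a domain annotation that contain, by
construction, exactly the structure the predictor exploits:

* the genome is tiled with exponential-length methylation domains
  (mean 20 kb), each hypo- or hyper-methylated (`p_hypo = 0.5`);
* CpG sites are true CG dinucleotides subsampled to `cpg_rate` per kb;
  each draws a propensity from its domain (Beta(1, 20) hypo,
  Beta(20, 1) hyper — the bimodal histogram real RRBS tracks show), adds
  truncated Gaussian noise (`noise_sd = 0.05`), and is observed as a
  binomial read fraction at `read_depth = 20`. Read sampling is what
  produces sites with percent-methylation exactly 0 or exactly 1, which
  the fixed-threshold labeling rule requires; a continuous draw would
  almost never hit them;
* contact distances follow a power law (`P(d) ~ 1/d`, d > 1 kb) and
  same-domain pairs are enriched `within_domain_contact_boost`-fold
  (default 8), so a site's spatial neighbours share its methylation
  state; hypo domains get CpG-island-like CG enrichment
  (`island_gc_boost = 3`);
* setting both boosts to 1 removes every planted signal and is the
  negative control.

The default scale is one 3 Mb chromosome with 0.4 CpG sites per kb
(about 1200 sites, of which roughly 600–800 receive a fixed-rule label)
and 20 000 contacts. The genome must be large relative to the Hi-C
range: random control windows are forbidden to overlap the target's
range, and on a genome only tens of kilobases long that exclusion removes
a noticeable, label-correlated slice of the sampling space and biases the
control windows' methylation average away from the target's domain. At
3 Mb the excluded 10 kb is 0.3 % of the chromosome and the control is
clean. A single chromosome is used for the same reason: with few domains
per chromosome, the per-chromosome class mix itself becomes an
(unintended) predictive signal visible to same-chromosome random windows.

What the generator does **not** emulate: chromatin compartments and TADs
beyond flat domains, restriction-site geometry of real Hi-C libraries,
sequence context effects on methylation beyond CpG-island GC enrichment,
and chromosome-specific methylation patterns. Passing the planted-signal
tests therefore demonstrates that the pipeline recovers spatial
methylation structure when it exists and reports chance performance when
it does not — it does not certify accuracy figures on real ENCODE-scale
data.

## Verification at a glance

The test suite pins the numerics: PseTNC against a nested-loop oracle and
its sum-to-one identity; pattern frequencies against hand counts;
confusion metrics against per-sample enumeration and the published
leave-one-out table (from printed Se/Sp under balanced classes, the
metrics module reproduces the printed Acc to half an ulp of the third
decimal and MCC to 0.001 or better, the residue being the rounding of the
printed inputs); autoencoder gradients against finite differences; ROC
monotonicity and endpoints; indexed contact queries against linear scans;
and the full pipeline on the planted-signal dataset, where both models
must beat their permuted-label baselines by at least 0.25 accuracy with
Hi-C windows and collapse to baseline with random windows on unplanted
data. `scripts/acceptance.R` recomputes all of these quantities from
scratch.
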