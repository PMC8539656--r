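---
title: "Methods: chemogenomic screening for longevity-gene regulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemogenomic screening for longevity-gene regulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gerochem)
```

This vignette is the package's own account of its modeling choices: the
procedure and its assumptions, the parameters that matter, what the
synthetic data generator does and does not emulate, and the numerical
decisions taken where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The screening model

The unit of analysis is the D–G–C triple: one drug perturbing one gene's
expression in one cell line, summarized by a Z-score. The pipeline turns a
long table of such records into (i) direction-labeled training samples,
(ii) a supervised model predicting regulation from descriptors alone, and
(iii) repurposing read-outs: drug rankings and normal-cell prediction
pools.

### Condition filtering and percentile labeling

Records are first restricted to a single treatment condition — 24-hour
exposure and micromolar ("µM") dosing — so Z-scores are comparable across
records; the unit comparison treats the micro sign and the Greek small mu
as the same character, and matching is otherwise an exact string test.
Within each cell line, the upregulation labeler marks exactly
`floor(fraction * n)` records with the largest Z-scores positive
(`fraction = 0.05` by default); the downregulation labeler mirrors this on
the smallest. All remaining records are negatives: their regulating effect
is *unknown*, and the model treats unknown as non-regulating. Two
consequences of implementing the percentile as rank selection rather than
an interpolated quantile: the positive count per cell line is exact by
construction, and ties cannot inflate it — tied Z-scores are resolved by
`(drug_id, gene_symbol)` lexical order, which also makes labeling invariant
to input row order. The 5% tail is pooled across all genes and drugs of a
cell line, not computed per gene; the per-cell-line pooling matches how the
labeling fraction is defined here.

Dose replicates of the same triple are kept as separate records through
labeling; dataset assembly later collapses them to the record with the most
extreme Z in the model's direction, so identical feature rows cannot carry
conflicting labels (switchable via `dedup = FALSE`).

### Descriptors

**Genes** are one-hot vectors over a GO-term vocabulary. Terms annotating
fewer than `min_genes = 3` of the modeled genes are dropped; annotations
are used exactly as given — no ancestor propagation over the GO graph (a
deliberate default: propagation densifies vectors and changes the
vocabulary in ways that should be an explicit user decision, not a side
effect).

**Drugs** are binary Morgan (circular) fingerprints, radius 2, folded to
`n_bits = 2048`. SMILES are canonicalized with OpenBabel before hashing, so
notational variants of one molecule give identical vectors. The
neighborhood-hashing itself is implemented in the package: ECFP-style atom
invariants (atomic number, heavy degree, attached hydrogens, formal
charge, ring membership), per-radius identifier updates over bond-ordered
neighbor lists, and deduplication of environments covering an already-seen
bond set. Folding collisions are accepted as-is; bit positions are
implementation-specific, so tests freeze reference *set-bit counts* rather
than positions. Unparseable SMILES produce per-drug failure records and the
drug is excluded downstream, with a message.

**Cell lines** concatenate a binary mutation-marker block with a
methylation block. Beta values are computed from channel intensities as
`max(m,0) / (max(m,0) + max(u,0) + alpha)`; `alpha` defaults to 100, the
constant conventionally used for Illumina array beta values, and is
configurable. Site selection is FCBF against the cell lines' histology
class: sites are ranked by symmetrical uncertainty with the class
(plug-in entropies in bits; SU defined as 0 when either variable is
constant), thresholded at `delta = 0.6`, and a ranked scan removes every
site dominated by a stronger kept site (SU between sites at least the
later site's SU with the class). FCBF needs discrete inputs; continuous
beta values are discretized by three equal-width bins on [0, 1] (`bins` is
a knob — three bins map naturally onto low/intermediate/high methylation).
SU rank ties are broken by site name, lexically, so selection is invariant
to column order. Normal (non-cancer) cell lines carry no mutation
annotation and are encoded with an all-zero mutation block; their beta
values must be supplied for the selected sites — a missing site is an
error, never imputed.

### Model layouts and learners

Eight layouts cross the prediction direction (up/down), the cell scope
(all cell lines vs a named two-line subset), class balancing, and three
feature sets (with/without the methylation or mutation block). The two
all-cell-line models balance classes by downsampling negatives uniformly,
jointly across cell lines, to the positive count. Design matrices always
concatenate blocks in the order gene | drug | cell, and the width is
derived from the actual blocks rather than fixed ahead of time.

The DNN has layers `[w, w, w, 2]` where `w` is the input width: SELU on
the first hidden layer, ReLU on the second (the order is a config switch),
inverted dropout at rate 0.5 after each hidden layer, softmax output,
cross-entropy loss, Adam (learning rate 1e-3, batch 128, at most 100
epochs), and early stopping (patience 10) on validation loss with
best-epoch weight restoration. Inputs are standardized on training-set
statistics stored with the network — SELU's self-normalizing behavior
assumes roughly unit-scale inputs, and the raw blocks mix {0,1} indicators
with [0,1] beta values. Weight initialization is normal with standard
deviation `1/sqrt(fan_in)`. Benchmarks: random forest (500 trees),
Gaussian naive Bayes (appropriate because the methylation block is
continuous; a small standard-deviation floor of 1e-3 keeps constant binary
columns from producing degenerate densities), and ridge logistic
regression (`glmnet`, `alpha = 0`, fixed `lambda = 0.01` — the L2 penalty
exists to survive the heavily collinear binary blocks).

Cross-validation is stratified 3-fold (stratification protects the
minority class in the imbalanced layouts); each fold's held-out part
doubles as the early-stopping monitor and the fold's evaluation set. The
final model refits on all rows, holding out a random 15% for early
stopping.

### Evaluation

`evaluate()` reports confusion counts at a fixed threshold (0.5 on the
positive-class probability; a score equal to the threshold counts as
positive), accuracy, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, ROC-AUC
via the rank statistic (ties counted half), and APR by step interpolation
of the precision–recall curve over distinct score thresholds. Under the
5%-positive regime accuracy and AUC are dominated by the majority class,
so APR is the metric that decisions are based on. Note one definitional
trap: recall is the proportion of actual positives recovered,
`TP/(TP+FN)` — not the proportion of predicted positives that are correct,
which is precision. With a single-class truth vector AUC and APR are
reported as `NA` rather than an arbitrary number.

### Repurposing

Interaction counting is pair-level: a drug's "# interactions" is its
number of unique positive (gene, cell) pairs of the desired kind
(upregulated pro-longevity or downregulated anti-longevity genes), so dose
replicates never inflate counts — the only definition under which the
interaction, unique-gene and unique-cell counts are mutually consistent.
The diversity filters are strict inequalities (more than `min_genes`
genes AND more than `min_cells` cell lines), rankings sort by interaction
count with lexical tie-break, and the up/down rankings intersect by drug
identity ordered by combined count. Prediction pools are exact Cartesian
products; per-drug positive rates at the 0.5 threshold (configurable) are
the final repurposing read-out.

## The synthetic world

`gen_world()` draws every input table under one seed. The defaults are the
package's study conditions and were fixed once:

| parameter | default | rationale |
|---|---|---|
| drugs × genes × cells | 40 × 50 × 5 | smallest screen in which per-cell 5% tails, multi-cell ranking filters and CV are all non-degenerate |
| `planted_pairs` | 220 (110 per direction) | 5.5% of the 2000 drug–gene pairs per direction — slightly above the 5% labeling fraction, so each cell line's labeled tail is saturated by true signal |
| planted structure | product set | per direction, a few active drugs × a responsive gene module (as when a compound class hits a co-regulated pathway); the signal is then recoverable by a shallow drug-AND-gene rule from descriptors, not only by memorizing pair identities |
| `effect_size` | 5 | a strong, unambiguous Z shift, as seen for potent on-target perturbagens; well clear of the ~2.3–3 background extremes among ~1600 per-cell records |
| dose/time noise | 10% "nM", 10% 6 h | exercises the condition filters with realistic contamination |
| `frac_pro`, `frac_anti` | 397/889, 492/889 | the canonical pro/anti proportions of the human-mapped aging-gene set; an 889-gene world reproduces the 397 + 492 split exactly |
| informative CpG fraction | 30% | informative sites get histology-dependent intensity levels (0.15/0.5/0.85 beta targets) that land in distinct thirds of [0,1], so FCBF has real signal; the rest share a common random level |

Intensities are nonnegative gamma draws per channel — beta values are
*computed* from them downstream, so the stabilized ratio is genuinely
exercised rather than bypassed. SMILES come from a built-in pool of 50
well-known neutral drug-like molecules, extended beyond 50 by an
enumerated N-alkyl benzamide series; all are verified parseable. Normal
cell lines appear in the intensity tables only.

What the generator does **not** emulate: landmark-gene inference and
replicate collapsing of real expression platforms, binary signature
containers, per-gene percentile structure, dose–response monotonicity,
realistic GO term hierarchy or co-annotation, linkage between mutations
and histology, or the real catalogs' sample-count asymmetries across cell
lines. Passing tests on these worlds therefore demonstrate the *pipeline's
correctness and recoverability of planted signal*, not field performance
on real perturbation corpora.

## Problem sizes used by tests and the acceptance script

The default world (above) is used end to end; fingerprints are folded to
256 bits in the synthetic screen (the 2048-bit default stays asserted in
the fingerprint contract tests) to keep the DNN input width near 325, and
model-1 training with 3-fold CV then takes well under a minute on one
core. Ranking recovery is measured over ten seeded world replicates with
the diversity filters scaled to the toy world (`min_genes = 2`,
`min_cells = 2`, strict). The acceptance script additionally generates one
889-gene world to recompute the longevity-label counts and the
10 × 397 × 2 = 7940 and 10 × 492 × 2 = 9840 pool cardinalities.

## Known limitations

* The Morgan implementation shares rdkit's invariants in spirit but not
  its hash, so bit *positions* (and occasionally set-bit counts on
  aromatic systems, which are kekulized here) differ across toolkits;
  within the package they are stable and canonical-SMILES-invariant.
* Formal-charge handling covers charges recorded in the molfile charge
  block; exotic valence states outside the supported element set are
  rejected rather than guessed.
* The Gaussian naive Bayes benchmark treats binary indicators as
  Gaussians; a Bernoulli variant on binarized features would be the
  natural alternative and can be emulated by passing binarized matrices.
* FCBF on few cell lines is noisy: with a handful of samples, spurious
  sites can reach the 0.6 relevance cutoff. That mirrors the small-sample
  reality of cell-line panels; the selection is deterministic and
  seed-stable either way.
* `read_perturbations()` expects the long format written by
  `write_world()`; converters from binary signature containers are out of
  scope and would sit naturally upstream of this package.
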