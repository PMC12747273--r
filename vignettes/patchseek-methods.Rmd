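---
title: "patchseek: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{patchseek: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchseek)
```

patchseek is a desk-scale engine for content-based retrieval of
hematoxylin-and-eosin (H&E) histology patches and for linking tissue
morphology to molecular readouts. This vignette explains the models and
procedures it implements, the tunable parameters that matter, what the
synthetic-data generators do and do not emulate, and the numerical and design
choices made where the design was genuinely open.

## The pipeline at a glance

1. **Tissue segmentation and patching** — HSV-saturation segmentation of a
   slide image, then fixed-size non-overlapping patch extraction on a grid.
2. **Encoding** — a pluggable patch encoder produces raw feature vectors,
   a single fully connected layer projects them to a shared space, and
   every vector is scaled to unit length.
3. **Attention-MIL** — a gated-attention multiple-instance model aggregates
   a slide's patch vectors into one slide-level vector and feeds multi-task
   heads: three-class mutation classifiers and continuous gene-set
   expression regressors.
4. **Indexing and retrieval** — exact, IVF-PQ, or ITQ-LSH indexes over the
   unit-norm vectors; retrieval hits carry empirical significance scores
   (z, p) against a fixed background sample, and whole slides are ranked by
   summed rank scores.
5. **Evaluation protocols** — leave-one-out mAP@5 over patch labels and
   leave-one-slide-out label matching with mosaic-selected query patches.
6. **Spatial-transcriptomics association** — per-profile clustering of
   spot-patch embeddings, per-(gene, cluster) Cohen's d and Wilcoxon
   rank-sum statistics with BH-FDR, gene queries over the resulting tables,
   and permutation gene-set enrichment on score profiles.

## Tissue segmentation and patching

`segment_tissue()` converts RGB to HSV, median-blurs the saturation channel
(`blur_kernel_px`, default 7 px), thresholds it, and closes small holes
(`closing_kernel_px`, default 9 px disc). Stained tissue is saturated;
glass background is near-white with near-zero saturation, which is what the
threshold separates.

* **Threshold default.** No fixed saturation threshold is universally right
  across scanners and stains, so the default is Otsu's method on the blurred
  channel, overridable by a fixed `sat_threshold`. A constant-saturation
  image (no two populations to separate) yields an empty mask rather than an
  arbitrary split.
* **Tile keeping.** `extract_patches()` anchors the grid at the image origin
  (no offset search — deterministic, and non-overlapping by construction),
  discards partial edge tiles, and keeps a tile when its mask coverage is at
  least `min_tissue_frac` (default 0.5, a symmetric choice that avoids
  background-dominated patches).
* **Conventions.** All pixel boxes are 0-based, half-open, y increasing
  downward — one convention across every module.
* **Segmentation resolution.** On large images segmentation may run on an
  area-averaged downsample (`seg_downsample`); coverage tests map tile boxes
  into mask coordinates, so patch extraction is downsample-aware.
* **ST spot patches.** The spot patch side is `2^ceiling(log2(64 / mpp))`
  pixels — the power of two covering 64 microns at the stated resolution
  (64 px at 1 micron/px, 256 px at 0.25). Spots whose square would exit the
  image are clamped to the boundary, never dropped, preserving the
  one-to-one spot-to-patch mapping the association statistics need.

## Encoding and the unit-norm contract

The engine is encoder-agnostic: `encoder_spec(kind = "external", fn = ...)`
accepts any function mapping patches to an N×d matrix. The bundled
`toy_histogram` encoder (per-channel 8-bin colour histograms plus four
gradient-magnitude texture summaries, passed through a fixed seeded random
projection) exists so that every downstream component — indexing, retrieval,
evaluation — runs deterministically without pretrained weights. It is not a
substitute for a real backbone's representational power, and nothing
downstream depends on which encoder produced the vectors.

After projection, every vector is scaled to unit length
(`unit_normalize()`). On unit vectors
\\(\lVert u - v\rVert^2 = 2 - 2\,u\cdot v\\), so Euclidean distance is a
monotone transform of cosine similarity and the two produce identical top-K
lists. Normalization happens in exactly one place — after projection, before
indexing and before attention scoring — so the invariant is established once.

## Gated-attention multiple-instance learning

For a bag \\(H \in \mathbb{R}^{N\times d}\\) of patch vectors, the gate
scores patch \\(n\\) as

$$s_n = \mathrm{softmax}_n\!\left(W_a\,\big(\tanh(V_a h_n^\top)\odot
\sigma(U_a h_n^\top)\big)\right),$$

with \\(W_a \in \mathbb{R}^{1\times d}\\),
\\(V_a, U_a \in \mathbb{R}^{d\times d}\\), and the slide vector is the
convex combination \\(h = \sum_n s_n h_n\\). The softmax uses
max-subtraction stabilization. Bias terms are included in all layers
(standard layer form; zero biases reproduce the weight-only algebra).

Heads are one \\(d\times 3\\) classifier per mutation task (classes 0/1/2:
wild-type-or-unknown, functional mutation, other) and one \\(d\times 1\\)
regressor per expression task; task counts are parameters, not constants.
The loss is the plain sum over tasks of class-weighted cross-entropy
(weights \\(w_c = 1/p_c\\), the inverse training-set class frequencies) and
squared error; a slide's missing label for a task contributes zero. Training
uses Adam (defaults: lr 1e-4, beta1 0.9, beta2 0.999, L2 weight decay 1e-5),
whole slides as the batch unit with gradient averaging across
`grad_accum_subbatches` sub-batches, and returns the parameters of the epoch
maximizing the overall score — the sum of per-task one-vs-rest AUCs and
Spearman correlations — on the monitoring split, earliest epoch on ties.

Design choices worth flagging:

* **AUC for 3-class labels** is computed one-vs-rest on the class-1
  (functional mutation) probability. This is a documented default for
  reducing a 3-class head to a binary report, not the only defensible one.
* **Splits** are patient-level (all slides of a patient in one partition),
  sized by largest remainder, and resampled until every partition holds at
  least one positive (class-1) label per task and the training partition
  holds all three classes — without which class weights are undefined.
* **Gradients** are hand-derived matrix algebra, verified in the test suite
  against central finite differences on every parameter block.
* **Desk-scale dimensions.** The reference configuration uses a
  256-dimensional shared space; `d_model` is a parameter, and the package's
  tests use 16–32 dimensions with bags of 16–32 patches and cohorts of
  100–200 slides, which a laptop trains in seconds. The recovery behaviour
  (planted-signal AUC, chance-level nulls, attention ≥ mean pooling when
  signal is concentrated in few patches) is what transfers, not wall-clock
  parity with GPU-scale cohorts.

## Vector indexes

Three backends share one search interface, all over unit-norm vectors, all
returning ascending distances with deterministic id tie-breaks:

* **exact** — brute force; the oracle every approximate backend is measured
  against, and the default at small scale.
* **ivfpq** — coarse k-means into `nlist` inverted lists; residuals (item
  minus coarse centroid) are product-quantized with `m` sub-quantizers and
  `ksub` centroids per sub-space; queries probe the `nprobe` nearest lists
  and rank by asymmetric (ADC) distance. Residual encoding is the default
  (`encode = "direct"` is available): the reference description does not fix
  residual-versus-direct, and residual encoding is the standard choice that
  improves accuracy. Coarse centroids are found by exact scan: with
  `nlist` ≤ 256 a navigable-graph accelerator over a few hundred centroids
  buys nothing, so graph construction is out of scope; the composition, not
  the graph, is the point.
* **itq_lsh** — PCA to `n_bits` dimensions (zero-padded if the data has
  fewer), then iterative quantization: alternating sign assignment and
  orthogonal-Procrustes rotation, whose quantization error is non-increasing
  by construction (`n_iter` default 50, an unstated constant chosen well past
  observed convergence). Codes are compared by Hamming distance.

All k-means in the package use seeded k-means++ initialization feeding
Lloyd iterations (25 max), ties to the lowest centroid id; `nstart`
restarts keep the lowest within-SS solution where local optima matter
(spot clustering uses 5).

**Mosaic subsampling** (`mosaic_select()`) reduces the indexed set to the
most representative patches: k-means over z-scored features concatenated
with z-scored spatial coordinates (standardized separately — the source
procedures differ on this, and separate z-scoring keeps either block from
dominating), then the top `fraction` of each cluster by centroid proximity,
rounded up, at least one per non-empty cluster. `fraction` covers both the
5% and 20% regimes quoted for mosaic-based engines. The single "most
representative" patch used by the leave-one-slide-out protocol is the patch
nearest its own cluster centroid globally — the mosaic ranking's top-1,
which the protocol description leaves open.

## Retrieval significance and slide ranking

For each cohort a background of up to 10,000 patches is sampled once,
without replacement, with a stored seed — so z and p are reproducible across
queries. For a hit at distance \\(d\\) against background distances
\\(d_{bg}\\):

$$z = \frac{d - \mathrm{mean}(d_{bg})}{\mathrm{sd}(d_{bg})},\qquad
p = \frac{\#\{d_{bg} \le d\}}{|bg|}.$$

More negative z is a stronger match. The p-value is the exact empirical
fraction — deliberately **not** the smoothed \\((r+1)/(n+1)\\) estimator —
so p = 0 is attainable; this follows the stated formula at the cost of a
slight anti-conservative bias at the extreme.

Slide ranking: a hit at rank \\(r\\) contributes \\(K + 1 - r\\) to its
slide; slides sort by total score, ties toward the smaller best-hit
distance. "Sum of rank scores" admits several readings; this one is
integer-valued, monotone in both hit count and hit quality, and bounded by
\\(K(K+1)/2\\).

## Evaluation protocols

`ap_at_5()` implements
\\(AP@5 = \sum_{i=1}^{5}\mathrm{Precision}_i\,\mathrm{Rel}_i / 5\\); the
test suite checks it against brute-force evaluation of all \\(2^5\\)
relevance patterns. `map_at_5()` averages per class and summarises by the
**median** across classes and datasets. Relevance is exact label equality —
no ontology partial credit; for mutation matching, relevance is the binary
mutation status of the queried gene. In leave-one-out evaluation the
self-match is removed **before** the top-5 truncation; a fixture in the test
suite demonstrates the inflation the other order causes.

## Spatial-transcriptomics association

Per profile: spot-patch embeddings are clustered with k-means (k = 8 by
default) — per profile and never pooled, because pooled embeddings cluster
by sample (batch effects) rather than by morphology. For each gene and each
cluster, expression of in-cluster spots is compared against all other spots
of the same profile: two-sided Wilcoxon rank-sum p-value and Cohen's d with
the pooled SD. Three openly ambiguous choices, resolved as follows:

* **Cohen's d variant**: classical pooled-SD two-sample form (the control
  group variant is a one-line change; pooled is the symmetric default).
* **BH scope**: per profile across all gene×cluster tests, because a gene
  query compares clusters relative to the other clusters of the same parent
  slide. The correction is a wrapper over `stats::p.adjust(method = "BH")`
  with NaN propagation; tests verify it against an independent step-up
  transcription.
* **Expression scale**: `log1p` of raw counts, with no depth normalization —
  the statistics path specifies none, and rank-sum p-values are invariant to
  monotone transforms anyway; variance-stabilizing transforms remain a
  visualization concern outside this package.

The Wilcoxon test uses `stats::wilcox.test` conventions (exact below 50 per
group without ties, normal approximation with tie correction otherwise).
Gene queries return clusters with d above `d_min` (default 1) and q below
`q_max` (default 0.05). `matched_spot_expression()` maps retrieval hits back
to spots and keeps genes detected in at least 75% of the matched spots.

`gsea()` is the classic unweighted running sum — +1/|set| at members,
−1/(N−|set|) elsewhere, ES = the maximum — with a one-sided permutation
p-value over random same-size gene sets (default 1000 permutations). The
unweighted form is used because no weighting exponent is specified for the
association profiles; hand-computed small cases anchor the implementation
and null calibration is checked by KS distance to uniformity.

## The synthetic-data generators

Every input class the engine consumes has a seed-deterministic generator
with planted ground truth, so the full pipeline is testable offline:

* `gen_slide()` — saturated discs/rects on a near-white background with
  Gaussian pixel noise; ground-truth mask and label map returned. This
  emulates exactly what saturation segmentation keys on, and nothing else:
  no chromatin texture, no stain variation, no pen or blur artifacts. A
  segmentation result on these images says the pipeline's order and
  thresholds are right, not that it is robust to real-world artifacts.
* `gen_mil_cohort()` — per-slide bags of isotropic Gaussian patch vectors;
  in class-1 slides a `signal_fraction` of patches is shifted `effect_size`
  noise-SDs along a task direction (class-2 along an orthogonal one);
  regression targets are linear in the slide's mean embedding plus noise
  (SD 0.1). Class priors default to (0.5, 0.3, 0.2). The geometry is
  deliberately linear-separable at large effect so that recovery failures
  indict the trainer, not the generator.
* `gen_st_profile()` — grid-arranged spots, separable embedding clusters
  (centre separation 10 within-cluster SDs by default; "well-separated"
  fixtures use 20), and counts as rounded log-normal intensities:
  per-(gene, spot) values drawn Normal(`baseline_mean` = 2,
  `baseline_sd` = 0.5) on the log1p scale, shifted by
  `d × baseline_sd` for planted (gene, cluster) pairs, then
  `round(expm1(·))`. Cohen's d targets are thus met in expectation on the
  very scale the statistics use, up to rounding — the reason intensities are
  log-normal rather than Poisson, where the planted d would depend on the
  mean. Real ST data's depth variation, zero inflation and gene–gene
  correlation are *not* emulated; null-calibration results here show the
  statistical machinery is correct, not that real profiles are this clean.
* `gen_clustered_vectors()` — unit vectors around random unit centres.
  For index-recall checks the package uses clusters of average size ≈ 10
  (e.g. 1000 clusters of 10 for a 10,000-vector set, noise SD 0.02),
  mirroring the near-duplicate redundancy of patch collections and matching
  the K of recall@10: recall against an exact oracle is only a meaningful
  target when the planted neighbourhood scale is resolvable by the code
  length in use — with a handful of broad clusters, no 8-byte code can
  order ~500 near-equidistant neighbours.

One global seed expands into per-component substreams through a
counter-based hash, so adding a generator never perturbs another's draws,
and every generator is bit-reproducible from its spec.

## Problem sizes

The test suite and the acceptance script run, by design, at sizes a single
CPU core handles in about a minute each: 10,000 indexed vectors for recall,
cohorts of 100–200 slides for MIL recovery (10-seed null and ablation
loops), 400-spot profiles over 50–100 seeds for ST recovery, and 500
replicates for the two null-calibration checks. These sizes were chosen so
Monte-Carlo bands are tight enough to be meaningful while the whole suite
stays interactive.

## Known limitations

* The toy encoder carries colour/texture information only; retrieval quality
  claims on real H&E require an external backbone behind `encoder_spec()`.
* The IVF coarse search is an exact centroid scan; at `nlist` far beyond
  desk scale a graph-based accelerator would be needed.
* The empirical p-value is unsmoothed (p = 0 attainable), per the stated
  formula.
* Mutation-task AUC reduces 3-class heads to class-1-vs-rest; per-class
  AUCs are available from the prediction tibble if wanted.
* Real-data confounders — stain variation, scanner differences, batch
  effects beyond the per-profile clustering guard — are out of the
  generators' scope, so passing tests bound correctness, not robustness.
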