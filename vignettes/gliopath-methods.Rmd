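---
title: "Methods: quantitative pathology and expression stratification of glioblastoma progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative pathology and expression stratification of glioblastoma progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliopath)
```

## The problem

After chemoradiation, recurrent glioblastoma patients frequently develop new
contrast-enhancing lesions that are either true progression (PD, regrowing
tumor requiring treatment revision) or pseudoprogression (psPD,
treatment-related change managed conservatively). Histology of second-surgery
tissue is the deciding evidence, but the assessment — atypical proliferating
cells (Ki67, Olig2, p53) versus immune infiltration (CD163) — is subjective
and often confounded by admixed tissue. `gliopath` implements the two
quantitative arms that support this call:

1. an **image arm** that turns brightfield IHC tiles into per-cell features,
   two image-level statistics (the mean distance to the 100th nearest
   neighboring nucleus as a cellularity measure, and the ratio of
   DAB-positive to hematoxylin-positive pixels as a staining burden), and
   morphology phenotype clusters tested for uneven PD/psPD distribution; and
2. an **expression arm** that stratifies samples by signature-gene
   expression with kMeans (k chosen by silhouette), validates the clustering
   by permutation, tests cluster-vs-diagnosis concordance with a Yates 2x2
   chi-square, and imputes genes failing QC on one platform from a reference
   cohort via housekeeping normalization, shadow-feature predictor selection
   and random-forest regression.

Both arms are exercised end to end on synthetic data whose ground truth is
known analytically, so each stage's accuracy is a measurable quantity rather
than an assumption.

## Image model

Brightfield absorbance is modelled by the Beer-Lambert law. A pixel with
transmitted intensity $I$ against incident intensity $I_0$ has optical
density $OD = -\log_{10}((I+\varepsilon)/(I_0+\varepsilon))$ per channel
($\varepsilon = 1$ intensity unit guards saturated black pixels). Stain
concentrations mix linearly in OD space: with unit stain vectors as the rows
of $M$ (the published Ruifrok-Johnston vectors for hematoxylin, eosin and
DAB; the third row is the normalized cross product of the named pair),
$od = c\,M$, and deconvolution solves for $c$ per pixel. Negative solutions
— from noise or off-model pigments — are clamped to zero and the clamp rate
is reported on the image, so silent model violations are visible.

The synthetic generator (`simulateIHCImage()`) renders nuclei as filled
ellipses with uniform interior concentration, which keeps every downstream
quantity analytic: areas, centroids, eccentricities and stain pixel counts
are exact functions of the configuration. Ellipses use the geometric-mean
radius $r=\sqrt{ab}$ and eccentricity $e=\sqrt{1-(b/a)^2}$. In
non-overlap mode, placement is rejection sampling (capped at 10,000
attempts per cell, then a deterministic error naming the attempted density)
with a 2 px padding between bounding circles so that "non-overlapping"
also means background-separated — the condition under which the
segmentation count is well-defined and must equal the drawn count exactly.
Decoy artifacts are rendered at 20% of the hematoxylin OD by default,
giving the artifact classifier a learnable but non-trivial margin. RGB
output is 8-bit quantized; with the default stain ODs (about 0.6–0.7)
quantization contributes well under 0.01 OD of error, which is why the
noise-free concentration-recovery contract is 0.02 OD.

What the generator does *not* emulate: chromatin texture inside nuclei,
out-of-focus blur, illumination gradients, overlapping nuclei clumps, and
eosin-rich cytoplasm. Tests passing on these images therefore demonstrate
the correctness of the computational chain, not robustness to every
property of scanned FFPE tissue.

## Segmentation and features

Otsu thresholding is implemented against a fixed 256-bin histogram of the
$[0,1]$ domain; the returned threshold is the bin edge maximizing the
between-class variance $w_0 w_1 (\mu_0 - \mu_1)^2$, with ties broken toward
the lowest edge and binarization strictly `>`. These pins make the operation
bit-for-bit reproducible, and the test suite holds it equal to an exhaustive
search over every candidate edge. Connected components (4- or 8-connectivity,
default 8 — the common choice for nucleus blobs) are labelled in raster-scan
order of their first pixel. No watershed splitting is attempted: the
thresholding chain is deliberately simple, and overlap handling is delegated
to the generator's non-overlap mode for testing. For markers with heavy
background (CD163 in practice), externally produced CNN probability maps for
cell bodies and processes are thresholded at a single global value and
merged (`mergeMasks()`); training such a network is out of scope here, the
package consumes its output.

Per-object features combine EBImage's shape descriptors (area, boundary
perimeter, boundary-radius statistics) and second-moment ellipse
(centroid, major axis, eccentricity, orientation) — with coordinates
re-based to 0-based (cx = column, cy = row) — plus intensity summaries
(mean, sd, 5th/95th percentiles) and four gray-level co-occurrence (GLCM)
texture scalars (contrast, correlation, energy, homogeneity). The GLCM is
restricted to pixel pairs entirely inside the object, symmetric,
normalized, quantized over the fixed $[0,1]$ domain into 16 levels, and
averaged over the offsets (0,1) and (1,0); objects with no interior pair
are flagged degenerate with zero features. The texture set is deliberately
small and fixed so the morphology-clustering input stays stable.

## Artifact filtering

Low-intensity artifacts are removed by a random-forest classifier (200
trees, seed-pinned) trained on labelled feature rows to call objects
positive or negative for true signal, followed by removal of objects whose
area falls below a minimum (default 1 px², the literal reading of
"zero-area" removal; real deployments will likely raise it). Filtering is
idempotent and never alters feature values; removal counts are logged per
image. In tests the labels come from the generator's artifact flags, with
training and evaluation on disjoint synthetic draws.

## Spatial statistics

`knnMeanDistance()` computes each cell's Euclidean distance to its $k$-th
nearest other cell (default $k=100$) with an exact kd-tree and returns the
image mean. When an image has $k$ or fewer cells the value is *missing*
with an explicit flag rather than silently substituting a smaller $k$,
which would bias the statistic. The DAB:hematoxylin ratio divides post-Otsu
DAB-positive pixels by hematoxylin-positive pixels; a zero denominator is
again an explicit missing flag. Both statistics are verified against
brute-force oracles and against generator truth through the full chain.

## Morphology clustering

Per stain: an equal number of cells per group (default 8,000; controls
group imbalance), shape and moment features minus x/y positions, per-column
z-scoring (the features span orders of magnitude), UMAP to 2-D, and DBSCAN.
DBSCAN's `eps` is a required user parameter — the field provides no default
that generalizes across stains — with `suggestEps()` offering the
k-distance-knee heuristic as a starting point. Clusters below the minimum
retained size (default 160 cells) are relabelled to noise and reported as
omitted. The retained clusters-by-group table is tested against even
distribution with the uncorrected Pearson chi-square, noise excluded. The
2x2 *diagnosis* test in the expression arm instead uses the Yates
continuity correction; on the reconstructed 48-sample concordance table
([[22,4],[5,17]] from 27 PD / 21 psPD, 85% and 77% cluster purities) the
corrected statistic is 16.12 where the uncorrected one would be 18.55 —
only the corrected variant matches the value the workflow is expected to
reproduce, which is why the correction is pinned there.

## Expression clustering and its permutation validation

Samples are clustered on the signature-subset matrix (log-transformed by
default; expression noise is multiplicative) by kMeans, with k selected
from 2–10 by the maximum mean silhouette width. Validation builds a null
by scrambling: each gene's values are permuted independently across
samples, destroying the covariance that real clusters ride on while
preserving every gene's marginal distribution exactly. Each scrambled
dataset is re-clustered with the same k (a flag allows reusing the
observed labels instead; re-clustering is the default because the
observed statistic also benefited from cluster optimization) and the
separation statistic — mean between-cluster minus mean within-cluster
distance, estimated from up to 10,000 sampled pairs of each kind, in the
expression space, not the 2-D embedding — is recomputed. The one-sided
empirical p-value is $(1 + \#\{null \ge observed\})/(n_{perm}+1)$, never
exactly zero. Calibration is a tested property: on i.i.d. noise data with
kMeans-derived labels the test rejects at the nominal rate.

## Cross-platform imputation

Genes failing QC on a spatial profiling platform are imputed from a bulk
reference cohort. Both datasets are first made comparable by a shared
housekeeping gene: candidates must be present with all-nonzero expression
and sit in the lower 20th variance percentile *in both datasets*
(variance on raw values by default, matching how such panels are screened;
a log-scale flag exists), and the normalizer minimizes the summed variance
rank across the two datasets, with lexicographic tie-break. Every value in
a sample is divided by that sample's housekeeping value — the only reading
that cancels per-sample platform scale, and provably invariant to any
common per-sample rescaling.

Predictors are selected by the shadow-feature scheme: each round appends a
freshly column-permuted copy of every predictor, fits a random forest, and
counts which real predictors beat the maximum shadow importance; cumulative
hit counts are tested against chance by two-sided binomial tests at
$\alpha = 0.01$, Bonferroni-corrected across the predictors still undecided
in that round. A caveat the package documents deliberately: the binomial
test controls only the per-round testing error. A predictor that is
*spuriously* correlated with the target in the given finite sample beats
the shadows persistently — its hit probability conditional on the dataset
genuinely exceeds one half — so the per-predictor false-confirmation rate
on null data is governed by the tail of the spurious-association
distribution and by the iteration budget, not by $\alpha$ alone. With the
calibration design used in the tests (10 predictors, n = 200, 40
iterations) the measured null confirmation rate sits near 2%, and it grows
with `maxIter`; users screening many targets should treat confirmations
from short-n references accordingly.

The per-gene imputer is a random forest of the target on its confirmed
predictors over the normalized reference; a 25% held-out split reports
Pearson correlation on the log scale (the scale on which the generator's
$R^2$ is defined and on which quality is interpretable for multiplicative
data), models below r = 0.5 are flagged low-quality, and every imputed
output vector carries an `imputed = TRUE` flag so downstream analyses can
label it explicitly.

## Synthetic expression model

`simulateExpression()` draws log-normal expression: per-gene baselines
$\mu_g \sim N(4, 1)$ in natural-log space, residual log-sd 0.5, signature
genes shifted by the effect size in their (round-robin assigned) cluster,
housekeeping genes at the common baseline with log-sd
$\sqrt{\log(1+cv^2)}$ so their coefficient of variation equals the
configured value exactly in expectation, and imputation targets built from
named predictor genes (linear sum or pairwise interaction of log values)
with noise scaled to hit the requested log-space $R^2$. Passing one
cohort's `baseMean` into a second call generates a matched cohort — the
same gene-level biology measured again — which is the regime cross-dataset
imputation assumes. Defaults (109 samples, 83-gene signature, k = 3) mirror
the sizes this workflow is typically run at.

## Numerical choices and problem sizes

* Otsu ties break to the lowest qualifying edge; binarization is strict
  `>`; component labels follow raster order — all pinned for bit-exact
  tests.
* kMeans uses 25 restarts for primary fits and 5 within each permutation
  replicate; `iter.max = 100`.
* The calibration experiments in the tests use deliberately small designs —
  24 samples x 10 genes for the 400-replicate permutation type-I study,
  10 predictors x 200 samples for the 100-replicate null Boruta study,
  300 cells for the 1,000-replicate chi-square independence study — chosen
  as the smallest sizes at which the asymptotics they probe are expected
  to hold.
* UMAP runs single-threaded with a pinned seed; t-SNE likewise. Determinism
  of every stage under a fixed seed is itself a tested property.

## Known limitations

* The stain vectors are the published defaults, not estimated per slide;
  strongly divergent staining will raise the clamp rate, which is the
  signal to supply custom vectors.
* No watershed: touching nuclei segment as one object.
* DBSCAN `eps` must be chosen per stain; the knee heuristic is a
  suggestion, not an estimator.
* The synthetic generators validate the computation, not biological
  realism; conclusions about real tissue require real tissue.
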