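---
title: "Selecting the ICA dimensionality of an expression compendium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting the ICA dimensionality of an expression compendium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optica)
```

## The model

Independent component analysis (ICA) of a transcriptomic compendium models
the log-scale expression matrix $X$ (genes $\times$ samples) as a linear
mixture

$$X \approx M A,$$

where the columns of $M$ (genes $\times k$) are statistically independent,
non-Gaussian *gene-weight sources* and the rows of $A$ ($k \times$ samples)
are their condition-dependent *activities*.  The set of significantly
weighted genes in one component is its **iModulon** — a data-driven
counterpart of a regulon, the gene set controlled by one transcriptional
regulator.  The one free specification in this model is $k$, the
dimensionality: too few components merge independent regulatory signals,
too many shatter them into biologically meaningless single-gene
components.  This package implements the full selection workflow: robust
multi-restart ICA across a grid of dimensionalities, component tracking
across the grid, component classification, and three selection rules
(OptICA, the cumulative-variance PCA baseline, and a stability baseline).

## Robust components

FastICA is stochastic, so each requested dimensionality is decomposed
with `n_runs` random restarts (symmetric extraction, logcosh contrast,
PCA whitening; tolerance `1e-7`, at most 200 iterations per restart).
The pooled components of all restarts are clustered with DBSCAN on the
sign-invariant distance

$$d_{x,y} = 1 - |\rho_{x,y}|,$$

with $\rho$ the Pearson correlation between two gene-weight vectors
(components are defined up to sign, so $v$ and $-v$ are identical).
Defaults follow the published operating point: `eps = 0.1` and a minimum
cluster seed of half the restarts (`ceiling(0.5 * n_runs)`, i.e. 50 of
100), so reduced-restart configurations keep the same proportion.  A
**robust component** is the centroid of a cluster after flipping every
member to correlate positively with the cluster's first member (the
canonical direction — any choice changes only a global sign).  Cluster
members that recur in fewer than half the restarts are noise and are
discarded, which is why the number of robust components at a dimension
can be smaller than the dimension (it can never be larger: in the rare
case density-chaining produces more clusters than requested components,
the largest are kept).

Beyond the true model order the whitened space contains near-Gaussian
directions on which the symmetric FastICA update has no fixed point to
find, so formal convergence becomes rare.  A restart that misses the
tolerance is retried once with a fresh derived seed; if the retry also
fails its components are kept (with a warning and a convergence count in
the result), mirroring the behaviour of the reference FastICA
implementations that return their state at the iteration cap.  Discarding
such runs instead would empty exactly the over-decomposed dimensions
whose component census the selection rules need.

Activities for the robust subset are recovered by least-squares
projection, $A = M^{+} X$, since the centroid matrix is generally not
square; the per-sample gene means removed by whitening are stored as
`sample_offsets`, so the fitted model is $X \approx M A + \mathbf{1}\,
\mathrm{offsets}^\top$.

## Tracking components across dimensionalities

Components computed at different dimensionalities are compared by the
absolute cosine of their full gene-weight vectors (called the
*correlation* here; the absolute value keeps the measure consistent with
the sign-invariant clustering distance).  Two structures are derived:

* the **dimensionality tree**, linking components of adjacent grid
  dimensions whenever their correlation strictly exceeds 0.3 — new
  components appear as parentless nodes, component splitting as a parent
  with two or more children;
* the **conservation profile**: each component of the final (largest)
  decomposition is matched to its best-correlated component at every
  preceding dimension.

Pooling those best correlations across all preceding dimensions gives a
sharply bimodal distribution: matches of components that already exist at
a dimension sit near 1, everything else far below.  The conserved
threshold is placed at the knee of the descending-sorted pooled values —
both axes normalised to $[0,1]$, knee at the point of maximum distance
above the chord joining the endpoints (the Kneedle construction with
sensitivity 1), clamped to $[0.3, 0.99]$.  On an exactly linear curve
every point is equidistant from the chord; ties within $10^{-12}$ of the
maximum resolve to the middle tied index, so a featureless curve knees at
its midpoint.  With fewer than 10 pooled values, or a perfectly flat
distribution, a fixed 0.7 fallback is used with a warning.  A final
component is **conserved** at dimension $d$ when its best correlation
there strictly exceeds the threshold.

Because conservation is defined against the largest decomposition, the
scan computes the final grid dimension first (`mode = "conserved"`).  An
`"online"` mode instead measures conservation against the highest
dimension computed so far and re-evaluates as the scan advances; it
supports incremental stop rules at the cost of a moving reference.

## Classifying components

* **Single-gene** (the over-decomposition signature): the largest absolute
  gene weight strictly exceeds twice the second largest.  Magnitudes are
  used because component signs are arbitrary.  Non-single-gene counts are
  `n_robust - n_single_gene` by definition.
* **Significant genes / iModulon**: 1-D $k$-means on the absolute gene
  weights with $k = 3$ (background, intermediate, high — the smallest $k$
  that separates a background mode from two signal tiers; exposed as
  `kmeans_k`), keeping the union of the top two clusters by centroid.
  The clustering is solved exactly by dynamic programming on the sorted
  values (optimal 1-D clusters are contiguous), which makes the
  extraction deterministic — no dependence on initialisation.  Degenerate
  vectors reduce $k$ to the number of distinct magnitudes (floor 2, top
  cluster only at $k = 2$); an all-equal vector returns every gene with a
  warning.
* **Regulatory**: each iModulon is tested against every regulon of a
  known regulatory network with the two-sided Fisher's exact test
  (hypergeometric enumeration with the conventional $1 + 10^{-7}$
  relative tie tolerance), p-values Benjamini–Hochberg-adjusted across
  all component-by-regulon tests of the dimension (the paper names only
  "FDR"; within-dimension pooling keeps dimensions comparable as the
  scan grows).  A component is regulatory when its best q-value is below
  $10^{-5}$; precision, recall and their harmonic mean F1 are reported
  for the best regulon (lowest q, ties by highest F1 then regulator
  name, so results do not depend on regulon ordering).

## Selecting the dimensionality

**OptICA** selects the dimension where the number of non-single-gene
components equals the number of conserved components — below it,
conserved components are still being discovered; above it, additional
components are increasingly single-gene artifacts.  Implemented as the
smallest grid dimension at which the rising conserved curve reaches the
non-single-gene curve.  The first meeting point is used because the
conserved count at the final dimension equals its robust count by
construction (every final component matches itself), so the two curves
always re-meet trivially at the end of any grid; taking the last
crossing would select that artifact.  If the curves never meet, the
closest-gap dimension is returned with a warning (ties to the smaller
dimension).

**PC-VA** returns the number of principal components needed to reach a
cumulative explained-variance target (default 99%; `pcva_target`).

**MSTD** is reimplemented only as a comparison baseline, to the fidelity
of its two-sentence summary in the source describing it: the stability
of a robust component is the mean $|\rho|$ of its cluster members to the
centroid; a dimension's stable fraction is the share of its *requested*
components that came back robust with stability above 0.8, and MSTD is
the largest dimension before that fraction first drops below 0.5.  When
the fraction never drops, MSTD does not converge and `NA` is returned —
a documented outcome, not an error.  Full replication of the original
MSTD method is out of scope; both cutoffs are exposed in the
configuration.

## The synthetic-data generator

`generate_compendium()` emulates exactly the abstraction ICA assumes:
$X = M A + \varepsilon$ with sparse independent sources, i.i.d. standard
normal activities and Gaussian noise.  Supports are drawn uniformly
(default 5–25 genes of 500) and may overlap; member weights have
magnitude `min_effect + Exp(1)` (a Laplace tail shifted away from zero)
with random signs — super-Gaussian, so the sources are ICA-identifiable,
and bounded away from zero, so membership in a source is a detectable
effect, as membership in a regulon implies.  Sources are redrawn until
all pairwise $|\rho| < 0.15$: any decorrelating method is bounded by the
sample correlation between sources, so chance overlaps would otherwise
silently cap recovery below what the mixture model promises.  Each
source's support doubles as a ground-truth regulon; optional single-gene
sources plant the over-decomposition signature.

The generator deliberately omits RNA-seq count statistics, library-size
and batch effects, and non-linear regulation.  Passing tests therefore
demonstrate correctness of the decomposition and selection machinery on
the model's own terms, not robustness to everything real compendia
contain; on real data the practical safeguards are the robustness
clustering and the conserved/single-gene census itself.

## Problem sizes, defaults and numerical choices

Test and acceptance runs use a 500-gene × 150-sample compendium with 20
planted sources, 10 restarts per dimension and a 5-step grid from 5 to
50 — small enough to iterate on while leaving the full published
operating point (100 restarts, step-1 grids to $n-2$) available through
the configuration.  Expression input is taken as already log-transformed
and is mean-centered per gene before ICA (required for whitening; the
correlation and cosine metrics downstream are location/scale-invariant,
and `--no-center` is available).  Delimiters are inferred from file
extensions.  Matrices are written at full double precision (`%.17g`) so
cached and fresh scans round-trip bit-identically; per-dimension seeds
derive deterministically from the base seed, making every pipeline
output reproducible from the configuration alone.  The OptICA selection
needs no regulatory network: without one the regulatory columns are
reported as absent (`NA`) and the selection is unchanged.

## Known limitations

* Conservation is relative to the largest computed decomposition; a grid
  truncated far below the sample count changes what "conserved" means.
* The MSTD baseline is approximate by design (see above).
* Fisher enrichment tests one regulon at a time; combined
  (intersection/union) regulations are not modelled.
* The dense restart-by-restart distance matrix is quadratic in
  `n_runs * dimension`; published-scale scans (hundreds of dimensions,
  100 restarts) are feasible but slow in a single process.
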