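---
title: "Reconstructing tissue geometry from cell-bead tagging networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing tissue geometry from cell-bead tagging networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Slide-tags-style experiments cleave barcoded oligonucleotides from a
decoded bead array and let them diffuse into a tissue section, where they
tag nuclei. Because diffusion is imprecise, each bead tags several nearby
cells and each cell is tagged by several nearby beads. The resulting
many-to-many association table is a bipartite *cell-bead network* whose
edges (UMI-supported tagging events) form almost exclusively between
physically close partners. That makes it a spatial network: its topology
alone constrains the relative 2D positions of all nodes, so cell positions
can be recovered without the optical decoding step that conventional
pipelines rely on.

beadnet implements the full reconstruction pipeline: network ingestion and
filtering, topology-to-position reconstruction, transform-invariant quality
metrics, density-based edge refinement, boundary-constrained shape
regularization, a physical model of the bead diffusion cloud, and a
ground-truthed simulator used to validate all of the above.

## The reconstruction model

Reconstruction works in three stages.

1. **Random-walk visitation sampling** (`sample_walks()`). From every node
   we run fixed-length random walks with uniform (optionally UMI-weighted)
   transitions. The empirical visitation frequencies estimate the
   probability of reaching node $v_j$ from $v_i$, which for a spatial
   network decays with physical distance; walks therefore carry both local
   and global structure. The package verifies the sampler against the
   analytic stationary law (visit frequency proportional to degree) in its
   test suite.

2. **Skip-gram embedding** (`train_embedding()`). Walks are treated as
   sentences and each node receives a vector $z_i$ chosen to maximize the
   likelihood of observing its walk neighborhood $N(v_i)$,
   $$\mathcal{L} = \sum_{v_i} \sum_{v_j \in N(v_i)}
     -\log \frac{\exp(z_i^\top z_j)}{\sum_{v_n} \exp(z_i^\top z_n)}.$$
   The softmax normalizer is replaced by negative sampling (five noise
   nodes per positive pair, unigram^0.75 noise distribution), the standard
   tractable approximation of this objective. Training is single-threaded
   and fully deterministic for a fixed seed. One embedding dimension is
   always absorbed by a shared "frequency" direction of skip-gram vectors,
   so the dimension must exceed the target geometry; the default of 32 is
   far above that floor.

3. **Neighbor-preserving 2D projection** (`project_2d()`). A k-nearest-
   neighbor graph over the embedding vectors (cosine metric, since the
   vectors are inner-product-trained) is converted to smooth membership
   weights, and a 2D layout is optimized by stochastic gradient descent
   with attraction along graph edges and sampled repulsion elsewhere - the
   UMAP family of layouts, implemented in compiled code. The layout is
   initialized by landmark classical MDS on hop geodesics of that same kNN
   graph: geodesic initialization carries the *global* arrangement (which
   purely local optimization can fold or twist), and the SGD then sharpens
   local neighborhoods. On inputs where the kNN graph is disconnected the
   initialization falls back to PCA. We checked this projection against
   the reference UMAP implementation on identical embeddings; the two
   agree to within 0.01 CPD.

`reconstruct()` composes the three stages per connected component (largest
by default), records every parameter and derived seed in a provenance
block, and returns positions for cells *and* beads - the bead positions
drive the refinement described below.

The output layout is defined only up to similarity transform: scale,
rotation and mirroring carry no meaning. Every quality statement about a
reconstruction therefore goes through the transform-invariant metrics.

## Fidelity metrics

* **CPD** (`cpd()`): the squared Pearson correlation between all pairwise
  distances in the reference layout and in the reconstruction; global
  fidelity. Exhaustive up to 20,000 nodes, a seeded 10^7-pair subsample
  beyond.
* **KNN score** (`knn_score()`): per node, the intersection-over-union of
  its K = 15 nearest-neighbor sets in the two layouts, averaged; local
  fidelity. The score converges to 1 as K approaches n - 1. Note the IoU
  form is stricter than the "fraction of K retained" convention: an IoU
  of 0.55 corresponds to about 80% of neighbors retained. Distance ties
  are broken by node id so scores are exactly reproducible.
* **Alignment and distortion** (`align()`, `distortion()`): both clouds
  are centered, scaled to unit radius (max distance from centroid),
  optionally hull-matched (area rescale plus hull-centroid centering -
  done per cloud so the step stays rotation-equivariant), and the optimal
  orthogonal map (reflections allowed) is taken from the SVD of the
  cross-covariance with a Frobenius-norm scale. Distortion is the
  per-point Euclidean displacement in reference units.

The convex-hull adjustment is deliberately minimal: hull-area matching
plus hull-centroid centering, with a flag to disable. It corrects density
mismatch between point clouds without fitting any non-rigid map.

## Iterative DBSCAN refinement

Noise edges - tagging events between spatially unrelated partners - exert
long-range attractive forces that compress and distort the layout. Since
the bipartite reconstruction positions beads too, each cell's connected
beads should form one tight cluster; beads that land far from that
cluster mark noise edges. `dbscan_edge_filter()` clusters each cell's
bead positions with DBSCAN (eps = 5% of the maximum reconstructed
pairwise extent, the cloud diameter computed exactly via the convex
hull), keeps edges only to the largest cluster (ties broken by total UMI,
then bead id), removes cells that produce no cluster, and retains all
bead nodes. `min_samples` defaults to the value maximizing the number of
single-cluster cells over 2..20 (`auto_min_samples()`). `iterative_refine()`
alternates reconstruction and pruning; on simulated networks with 10%
noise edges a single round removes about 90% of the noise edges while
keeping most spatial ones.

A practical note on `min_samples`: the single-cluster-maximization rule
was developed on tissue networks with several hundred edges per cell; on
the package's simulated networks (post-filter cell degree around 60) it
selects values of 13-16 and prunes satellite spatial beads along with the
noise, which costs local fidelity. For the simulator-based validation
experiments we therefore fix `min_samples = 5` - roughly the size of the
smallest genuine bead clump in those clouds - and the refinement then
improves both the global and the local score when there is headroom to
gain. When a single pass is already near its ceiling (low noise, dense
network), pruning has nothing left to remove and the second pass simply
reproduces the first to within seed variance.

DBSCAN itself is implemented in the package (no clustering dependency is
used): closed eps-balls, neighborhoods including the point itself,
matching the semantics of the common library implementations.

For sparse networks where whole-sample reconstruction fails, the
`threshold_subgraphs()` / `enrich_subgraph()` pair extracts strongly
connected cell subgraphs at a high shared-bead threshold (7 in the
published mouse analyses) and enriches them with within-subgraph edges at
a lower threshold, baseline 2 - single-shared-bead edges are
disproportionately numerous and largely random, so enrichment at 1
requires an explicit override. `coherence_score()` provides a proxy for
spatial coherence (mean overlap between graph neighborhoods and layout
neighborhoods); it is labeled a proxy because the original coherence
formula is defined in work not reproduced here.

## Shape regularization

When the sample's gross shape is known (a disc for a tonsil section), a
soft warp toward that shape removes residual large-scale distortion.
`morph()` detects the reconstructed boundary with alpha shapes (an edge
is kept when one of the two circles of radius 1/alpha through the pair is
empty; implemented from the empty-circle principle with exact linear
blocking intervals, numerically stable down to the convex-hull limit),
projects each boundary landmark radially onto the circle of radius r (the
maximum centroid distance, after Eq.-style centroid/radius estimation),
and applies a thin-plate-spline warp (U(d) = d^2 log d, exact affine
reproduction, stiffness-regularized for "soft" mode). Any star-convex
polygon can replace the circle as target.

Two practical caveats, both visible in the tests: `alpha = "auto"`
bisects to the largest alpha that still yields a single closed boundary
cycle, which follows fine detail; for morphing, a coarser boundary (alpha
around 0.1-2 divided by the cloud radius) is usually the better choice.
And because r is the *maximum* centroid distance, the sampled boundary
lies slightly inside the target circle, so morphing an already-circular
cloud still dilates it by roughly the boundary sampling deficit (1-2% of
r at a few thousand points, vanishing with density) - the warp is
idempotent only in the dense limit.

## Bead diffusion model

Pooling, over all beads, the displacement vectors to their tagged cells
yields a radial profile with a sharp local component and a broad
background. The local component is Fickian: a point release of M
molecules diffusing in 2D for time t has concentration
$$C(r, t) = \frac{M}{4 \pi D t} \exp\!\left(-\frac{r^2}{4 D t}\right),$$
(`gaussian2d_density()`, mass-conserving to 1e-9 under radial
quadrature). The background matches the distance of two uniform random
points in a disc of radius R (`chord_pdf()`), verified against a 10^6-pair
Monte-Carlo oracle.

`fit_profile()` fits the mixture to a distance histogram. One modeling
decision deserves emphasis: a *distance* histogram carries the 2D
Jacobian, so the diffusion component must enter as the Rayleigh-type
density $(r / 2Dt)\exp(-r^2/4Dt)$ next to the chord density - mixing a
planar density with a distance density in one sum leaves the two terms on
different measures and biases D. The Jacobian-corrected mixture is the
default (`jacobian = TRUE`); the literal planar form is available for
profiles normalized per unit area. The diffusion time t is a fixed
experimental input (480 s for the published protocol: photo-cleavage plus
incubation), never fitted jointly with D, because only the product Dt is
identified. The fit is weighted nonlinear least squares (bins weighted by
sample count) with a multistart over a log-spaced D grid.

On simulated networks the fit recovers D to a few percent from the
event-level distance distribution. Heavily re-tagged networks bias the
*edge-level* histogram outward (duplicate tags collapse into one edge),
so diffusion fits are best read from lightly tagged networks or
event-weighted profiles.

## The simulator

`simulate_network()` generates ground-truthed networks mirroring the
hypothesized physical process: cells and beads uniform in a 3 mm disc;
per bead, a truncated-power-law number of tagging rounds; each round tags
one cell with probability proportional to the Fickian kernel
exp(-d^2/4Dt) (cells beyond six diffusion lengths pruned - their weight
is below 1e-8 of the peak); one UMI per round; then a chosen fraction of
distinct edges replaced by uniformly random pairs. Every edge carries a
spatial/noise label in the returned truth object, and a fixed seed
reproduces the network byte for byte.

Defaults are the package's study conditions: 4000 cells, 8000 beads,
D = 26 um^2/s, t = 480 s, noise ratio 0.1, and tagging rounds from a
discrete power law with exponent 1.2 truncated at 1000. The tagging
distribution was chosen once so the generated networks emulate the
empirical samples: mean cell degree ~70 (the published samples range from
~79 to ~208), a unimodal, bounded cell degree distribution, and
heavy-tailed bead UMI totals with the power-law-like appearance that
motivates the bead-UMI filtering step. Much lighter tagging (e.g.
exponent 2.5 capped at 100) produces networks with mean cell degree below
4 that fragment into hundreds of components and resemble no published
sample; both parameters remain exposed in `sim_config()`.

What the simulator does *not* model: transcript capture and expression,
sequencing error, barcode collisions, anisotropic or heterogeneous
diffusion, uneven cell density, tissue holes, and 3D effects. Passing
tests on simulated networks therefore demonstrate the pipeline's
correctness under the stated physical model, not performance on any
particular tissue.

Two finite-size caveats, quantified in the tests: per-bead weight
normalization over a sparse local cell field fattens the distance tail
relative to the continuum Rayleigh law (the law is recovered for dense
cell fields), and duplicate-edge collapse under heavy tagging shifts the
edge-level distance histogram outward.

`image_network()` builds the idealized benchmark: points scattered over a
raster image (a procedurally generated double-helix test pattern by
default), colored by the underlying pixels, and connected by contact
tessellation - the adjacency of the regions around each point, computed
via the exact empty-circumcircle edge test restricted to nearest-neighbor
candidates. Exactly cocircular quads (as in a perfect square) admit both
diagonals; the implementation resolves such ties by dropping the longer
of any two crossing edges, so four corner points yield the four sides
plus one diagonal.

## The standard pipeline and its defaults

The full pipeline for a raw association table is:

1. `read_edgelist()` - collapse duplicates, reject malformed rows.
2. `drop_singleton_beads()` - degree-1 beads carry no relative-position
   information. Single pass by default.
3. `filter_bead_umi()` - remove beads whose UMI total exceeds a
   per-sample threshold chosen from the count distribution, slightly
   above where it departs from its power-law-like shape (presets 1500 /
   800 / 500 for the published tonsil / embryonic brain / hippocampus
   samples; `bead_umi_knee()` automates the eyeball rule but is never
   auto-applied). This step matters: on simulated networks, leaving the
   heavy-tail hub beads in drops single-pass CPD from ~0.85 to ~0.5,
   because a bead tagging hundreds of cells across several diffusion
   lengths blurs every neighborhood it touches.
4. `reconstruct()` - bipartite by default (the refinement needs bead
   positions); walk defaults 10 walks per node of length 20, window 5,
   dimension 32, 3 epochs, 200 layout epochs. These sizes were chosen for
   single-CPU runs of networks around 10^4 nodes and a few 10^5 edges
   (roughly a minute per pass); all are exposed in `strnd_config()` and
   heavier settings buy modest quality gains.
5. `iterative_refine()` - default two pruning rounds; one round already
   removes most noise edges.
6. `morph()` - optional, when the sample shape is known.
7. `fidelity_report()` against a reference layout, when one exists.

Metrics are evaluated on cells (reference layouts position cells only);
reconstructions cover beads as well, and bead positions are consumed by
the refinement, not by the metrics.

## Numerical choices and degenerate inputs

* Neighbor ties (KNN sets, DBSCAN largest-cluster, tessellation
  diagonals) are broken deterministically - by node id, UMI mass, or edge
  length - so every result is bit-reproducible under a fixed seed.
* `cpd()` refuses zero-variance distance sets (an error, never a silent
  0); `align()` warns on nearly collinear clouds but still returns;
  `tps_warp()` refuses collinear landmarks (singular system).
* All randomness flows through explicit seed arguments; replicated
  experiments derive per-replicate seeds by an arithmetic ladder
  (`derive_seeds()`) so any replicate can be regenerated in isolation.
* Downsampling along the UMI axis draws a sequential multivariate
  hypergeometric sample, so the surviving total equals the target
  exactly.

## Known limitations

* Local fidelity is bounded by physics, not only by the algorithm: a
  bead's tagging radius (~sqrt(4Dt) = 224 um at the fitted coefficients)
  spans many cell diameters, so neighborhoods below the diffusion scale
  are fundamentally blurred. On dense simulated networks the K = 15 score
  tops out far below 1 even at zero noise.
* Global fidelity saturates with edge density: on dense simulated
  networks, CPD is nearly unchanged when three quarters of the edges are
  removed, while the local KNN score halves. CPD is therefore the wrong
  metric for detecting moderate data loss; watch the local score.
* Under heavy noise the single pass occasionally produces globally folded
  layouts (a minority of seeds); the DBSCAN refinement rescues those runs
  and stabilizes the global score, but it prunes spatial edges along with
  the noise (two to four times more of them, at the prescribed eps), so
  it does not raise the local score when the single pass was already
  sound.
* Merging independently reconstructed subgraphs into one global map is
  out of scope; thresholded subgraph reconstruction recovers local, not
  global, structure.
* The simulator's noise model (uniform random rewiring) is the simplest
  adversary; convection-like structured noise would be harder and is not
  modeled.
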