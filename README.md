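# beadnet

Reference-free spatial reconstruction of cell–bead tagging networks from
Slide-tags-style spatial transcriptomics data.

## The problem

Slide-tags experiments release barcoded oligonucleotides from a decoded
bead array into a tissue section, tagging nuclei with spatial barcodes.
Because diffusion reaches several cells per bead (and several beads per
cell), the tagging events form a bipartite **cell–bead network** whose
edges overwhelmingly connect physically close partners. The network is
therefore spatial: its topology alone constrains the relative positions of
all nodes. beadnet recovers 2D cell (and bead) positions from that
topology, with no reference map, and quantifies how well it did when a
reference exists.

For cells and beads `V` with tagging edges, the reconstruction estimates
random-walk visitation probabilities `P(v_i, v_j)`, trains a skip-gram
embedding `z_i` maximizing the likelihood of each node's walk neighborhood
`N(v_i)` (negative-sampling approximation of the softmax objective), and
projects to 2D with a neighbor-preserving layout initialized by landmark
MDS on kNN-graph geodesics. Reconstruction quality is measured by

* **CPD** — squared Pearson correlation between all pairwise distances of
  the reference and reconstructed layouts (global fidelity), and
* **KNN score** — mean per-node intersection-over-union of K = 15 nearest
  neighbor sets (local fidelity),

both invariant to rotation, translation, mirroring and uniform scaling.
Refinement prunes noise edges with per-cell DBSCAN on reconstructed bead
positions; `morph()` softly warps a reconstruction onto known sample
geometry (alpha-shape boundary + thin-plate spline); `fit_profile()`
extracts a diffusion coefficient from the bead→partner displacement
profile via a Fickian + disc-chord mixture model; `simulate_network()`
generates ground-truthed networks for validation.

## Worked example

Simulate a disc-shaped tissue (4000 cells, 8000 beads, 3 mm disc, 10%
noise edges), run the standard pipeline, and score against the simulated
ground truth:

```r
library(beadnet)

sim <- simulate_network(sim_config(), seed = 42)
sim$network
#> bead_network: 4000 cells, 8000 beads, 282187 edges, 550956 total UMIs

## initial filtering: drop uninformative and hub beads
net <- drop_singleton_beads(sim$network)
net <- filter_bead_umi(net, bead_umi_knee(net))
net <- drop_singleton_beads(net)
#> [drop_singleton_beads] cells 4000 -> 4000 | beads 8000 -> 7918 | edges 282187 -> 282112
#> [filter_bead_umi] cells 4000 -> 4000 | beads 7918 -> 7748 | edges 282112 -> 247026

## single-pass reconstruction (cells AND beads get positions)
rec <- reconstruct(net, strnd_config(), seed = 7)

## score against the true cell positions
truth <- sim$truth$positions[net$cells, ]
cpd(truth, rec$points)
#> [1] 0.708
knn_score(truth, rec$points)$score
#> [1] 0.324

## one round of DBSCAN edge pruning and re-reconstruction
pruned <- dbscan_edge_filter(net, rec, min_samples = 5)
#> [dbscan_edge_filter] cells 4000 -> 4000 | beads 7748 -> 7748 | edges 247026 -> 198378
rec2 <- reconstruct(pruned, strnd_config(), seed = 8)
cpd(truth, rec2$points)
#> [1] 0.874
knn_score(truth, rec2$points)$score
#> [1] 0.355
```

A CPD above 0.7 means large-scale geometry (relative orientation,
tissue-scale organization) is essentially recovered from topology alone;
the pruning round removes most of the injected noise edges and lifts both
scores. The KNN score is bounded by physics — a bead's tagging radius
(≈ √(4Dt) ≈ 224 µm) spans many cell diameters, so sub-diffusion-scale
neighborhoods are intrinsically blurred.

Real data enters through `read_edgelist()` (cell barcode, bead barcode,
UMI count; TSV/CSV) and `read_positions()` for reference layouts; see the
vignette in `vignettes/reconstruction-methods.Rmd` for the full model, the
parameter meanings and the design decisions.

There is also a thin command-line interface over the same functions:

```sh
beadnet simulate --cells 4000 --beads 8000 --noise 0.1 --seed 7 -o run/
beadnet reconstruct --net run/edges.tsv -o run/rec/
beadnet metrics --ref ref.tsv --rec run/rec/positions.tsv -K 15
```

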