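# Iterative DBSCAN-based edge pruning of the bipartite network using
# reconstructed bead positions, and the theta/theta2 subgraph procedure for
# sparse networks.

# Classic DBSCAN on a small 2D point set. Neighborhoods are closed balls of
# radius eps and include the point itself (the convention of the common
# library implementations, which the published filtering used). Returns
# integer labels, 0 = noise.
dbscan_points <- function(X, eps, min_samples) {
  n <- nrow(X)
  if (n == 0) return(integer(0))
  D <- as.matrix(dist(X))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  dbscan_from_neighbors(nb, min_samples)
}

# DBSCAN given precomputed eps-neighbor lists; lets callers sweep
# min_samples without recomputing distances.
dbscan_from_neighbors <- function(nb, min_samples) {
  n <- length(nb)
  core <- lengths(nb) >= min_samples
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  labels
}

# eps-neighbor lists of each cell's connected beads in the reconstruction,
# computed once and shared by the min_samples sweep and the edge filter
cell_bead_neighbors <- function(net, bead_xy, eps) {
  idx_by_cell <- split(seq_len(nrow(net$edges)), net$edges$cell)
  nbs <- lapply(idx_by_cell, function(rows) {
    X <- bead_xy[net$edges$bead[rows], , drop = FALSE]
    D <- as.matrix(dist(X))
    lapply(seq_len(nrow(X)), function(i) which(D[i, ] <= eps))
  })
  list(rows = idx_by_cell, neighbors = nbs)
}

# maximum pairwise extent (diameter) of a point cloud; exact via the convex
# hull, whose vertex count stays tiny even for large clouds
cloud_diameter <- function(X) {
  h <- grDevices::chull(X)
  V <- X[h, , drop = FALSE]
  max(dist(V))
}

#' Choose DBSCAN min_samples maximizing single-cluster cells
#'
#' Sweeps the candidate range and returns the value for which the largest
#' number of cells yields exactly one DBSCAN cluster over its connected
#' beads' reconstructed positions. Ties go to the smallest candidate.
#'
#' @param net a [bead_network()].
#' @param rec a `reconstruction` covering the beads of `net`.
#' @param eps DBSCAN radius (same units as the reconstruction).
#' @param search_range candidate integers (default 2:20).
#' @param cache precomputed per-cell eps-neighbor lists (internal reuse by
#'   [dbscan_edge_filter()]); leave `NULL`.
#' @return the selected `min_samples` (integer), with the per-candidate
#'   single-cluster cell counts as attribute `"counts"`.
#' @export
auto_min_samples <- function(net, rec, eps, search_range = 2:20,
                             cache = NULL) {
  if (!length(search_range)) stop("empty min_samples search range")
  if (is.null(cache)) {
    bead_xy <- rec_bead_positions(rec, net)
    cache <- cell_bead_neighbors(net, bead_xy, eps)
  }
  counts <- setNames(integer(length(search_range)),
                     as.character(search_range))
  for (nb in cache$neighbors) {
    for (s in seq_along(search_range)) {
      lab <- dbscan_from_neighbors(nb, search_range[s])
      if (length(unique(lab[lab > 0])) == 1L)
        counts[s] <- counts[s] + 1L
    }
  }
  best <- search_range[which.max(counts)]  # which.max: first (smallest) tie
  structure(as.integer(best), counts = counts)
}

rec_bead_positions <- function(rec, net) {
  pts <- rec$points
  missing <- setdiff(net$beads, rownames(pts))
  if (length(missing))
    stop("reconstruction lacks positions for ", length(missing),
         " bead(s); refine on the reconstructed component only")
  unclass(pts)[net$beads, , drop = FALSE]
}

#' Prune long-range edges by per-cell DBSCAN on reconstructed bead positions
#'
#' For every cell, the reconstructed positions of its connected beads are
#' clustered with DBSCAN; edges are kept only to beads in the largest
#' cluster (ties broken by higher total edge UMI, then bead id). Beads
#' flagged as noise mark noise-associated connections and those edges are
#' removed, while the bead nodes themselves remain in the network. A cell
#' that produces no cluster at all (including cells with fewer beads than
#' `min_samples`) is removed together with its edges.
#'
#' @param net a [bead_network()].
#' @param rec a `reconstruction` of `net` (bipartite mode, so bead positions
#'   exist).
#' @param eps_fraction DBSCAN eps as a fraction of the maximum pairwise
#'   extent of the reconstructed cloud (default 0.05).
#' @param min_samples integer, or `"auto"` to maximize single-cluster cells
#'   over `search_range`.
#' @param search_range candidates for `min_samples = "auto"`.
#' @param verbose log removal counts.
#' @return filtered [bead_network()] with attributes `eps`, `min_samples`,
#'   `cells_removed`, `edges_removed`.
#' @export
dbscan_edge_filter <- function(net, rec, eps_fraction = 0.05,
                               min_samples = "auto", search_range = 2:20,
                               verbose = TRUE) {
  stopifnot(eps_fraction > 0, eps_fraction < 1)
  eps <- eps_fraction * cloud_diameter(unclass(rec$points))
  bead_xy <- rec_bead_positions(rec, net)
  cache <- cell_bead_neighbors(net, bead_xy, eps)
  if (identical(min_samples, "auto"))
    min_samples <- auto_min_samples(net, rec, eps, search_range,
                                    cache = cache)
  before <- net_counts(net)
  keep_rows <- logical(nrow(net$edges))
  removed_cells <- character(0)
  idx_by_cell <- cache$rows
  for (cell in names(idx_by_cell)) {
    rows <- idx_by_cell[[cell]]
    beads <- net$edges$bead[rows]
    lab <- dbscan_from_neighbors(cache$neighbors[[cell]], min_samples)
    cl <- unique(lab[lab > 0])
    if (!length(cl)) { removed_cells <- c(removed_cells, cell); next }
    if (length(cl) > 1L) {
      size <- vapply(cl, function(k) sum(lab == k), 0L)
      top <- cl[size == max(size)]
      if (length(top) > 1L) {  # tie: higher total UMI, then bead id order
        umi <- vapply(top, function(k) sum(net$edges$umi[rows][lab == k]), 0)
        top <- top[umi == max(umi)]
        if (length(top) > 1L) {
          firstbead <- vapply(top, function(k) min(beads[lab == k]), "")
          top <- top[order(firstbead)][1]
        }
      }
      best <- top[1]
    } else best <- cl
    keep_rows[rows[lab == best]] <- TRUE
  }
  out <- net
  out$edges <- net$edges[keep_rows, , drop = FALSE]
  out$cells <- setdiff(net$cells, removed_cells)
  rownames(out$edges) <- NULL
  log_stage("dbscan_edge_filter", before, net_counts(out), verbose)
  structure(out, eps = eps, min_samples = as.integer(min_samples),
            cells_removed = length(removed_cells),
            edges_removed = before["edges"] - nrow(out$edges))
}

#' Iterative reconstruction with DBSCAN edge pruning
#'
#' Alternates [reconstruct()] and [dbscan_edge_filter()]: long-range noise
#' edges compress and distort a first-pass layout, so pruning them against
#' the reconstructed bead positions and re-reconstructing yields a clearer
#' second pass. Each round re-reconstructs the current network. Rounds stop
#' early when the fraction of removed edges falls below `tol`. If pruning
#' disconnects the network the loop continues on the largest component
#' (with a message).
#'
#' @param net a [bead_network()].
#' @param config a [strnd_config()] (bipartite mode required, since bead
#'   positions drive the pruning).
#' @param rounds number of prune-and-reconstruct rounds (default 2); the
#'   returned reconstruction is of the final pruned network, so `rounds = 1`
#'   means two reconstruction passes in total.
#' @param eps_fraction,min_samples,search_range see [dbscan_edge_filter()].
#' @param tol convergence tolerance on the removed-edge fraction.
#' @param ref optional reference [point_map()]; when given, a
#'   [fidelity_report()] is computed for every round.
#' @param seed master seed (per-round seeds derived).
#' @param verbose log progress.
#' @return list with `reconstruction` (final), `network` (final), and
#'   `rounds` (per-round provenance: edges removed, cells removed, optional
#'   fidelity reports, seeds).
#' @export
iterative_refine <- function(net, config = strnd_config(), rounds = 2,
                             eps_fraction = 0.05, min_samples = "auto",
                             search_range = 2:20, tol = 0, ref = NULL,
                             seed = 1, verbose = TRUE) {
  stopifnot(rounds >= 1, config$mode == "bipartite")
  seeds <- derive_seeds(seed, rounds + 1)
  history <- list()
  for (r in seq_len(rounds)) {
    rec <- reconstruct(net, config, seed = seeds[r], verbose = verbose)
    if (nrow(rec$points) < length(net$cells) + length(net$beads)) {
      if (verbose)
        message("iterative_refine: continuing on the reconstructed ",
                "(largest) component")
      net <- induce_subgraph(net, rownames(rec$points))
    }
    pruned <- dbscan_edge_filter(net, rec, eps_fraction, min_samples,
                                 search_range, verbose = verbose)
    frac <- as.numeric(attr(pruned, "edges_removed")) /
      max(1, nrow(net$edges))
    history[[r]] <- list(
      round = r, seed = seeds[r],
      edges_before = nrow(net$edges), edges_after = nrow(pruned$edges),
      removed_fraction = frac,
      cells_removed = attr(pruned, "cells_removed"),
      eps = attr(pruned, "eps"), min_samples = attr(pruned, "min_samples"),
      fidelity = if (!is.null(ref)) fidelity_report(ref, rec$points))
    net <- pruned
    if (frac < tol) break
  }
  final <- reconstruct(net, config, seed = seeds[length(seeds)],
                       verbose = verbose)
  if (!is.null(ref))
    history$final_fidelity <- fidelity_report(ref, final$points)
  list(reconstruction = final, network = net, rounds = history)
}

#' Strongly connected cell subgraphs at a weight threshold
#'
#' Keeps unipartite edges with at least `theta1` shared beads and returns
#' the connected components of the thresholded graph, largest first. Sparse
#' noisy networks fall apart into locally coherent subgraphs under a high
#' threshold (7 shared beads per edge was used for the published mouse
#' samples), which can then be reconstructed individually.
#'
#' @param g a [cell_graph()].
#' @param theta1 minimum shared-bead count (positive integer).
#' @return list of character vectors (cell ids), ordered by decreasing
#'   size; cells isolated by the threshold appear as singletons.
#' @export
threshold_subgraphs <- function(g, theta1) {
  stopifnot(theta1 >= 1)
  e <- g$edges[g$edges$w >= theta1, , drop = FALSE]
  ig <- igraph::graph_from_data_frame(e[c("ci", "cj")], directed = FALSE,
                                      vertices = data.frame(name = g$cells))
  comp <- igraph::components(ig)
  comps <- split(igraph::V(ig)$name, comp$membership)
  comps[order(vapply(comps, length, 0L), decreasing = TRUE)]
}

#' Enrich a thresholded subgraph with lower-threshold edges
#'
#' Within the node set of a component found at the primary threshold, pull
#' back all edges of weight at least `theta2 < theta1`. Single-shared-bead
#' edges are disproportionately numerous and largely randomly formed, so
#' `theta2 >= 2` is the baseline; explicitly pass `allow_theta2_1 = TRUE`
#' to override. Edges to cells outside the component are never added.
#'
#' @param component character vector of cell ids (from
#'   [threshold_subgraphs()]).
#' @param g the full [cell_graph()].
#' @param theta2 enrichment threshold, `2 <= theta2 < theta1` by default.
#' @param allow_theta2_1 permit `theta2 = 1`.
#' @return induced [cell_graph()] on `component` with all edges of weight
#'   `>= theta2`.
#' @export
enrich_subgraph <- function(component, g, theta2, allow_theta2_1 = FALSE) {
  if (theta2 < 2 && !allow_theta2_1)
    stop("theta2 must be >= 2 (single-bead edges are mostly random); ",
         "set allow_theta2_1 = TRUE to override")
  keep <- g$edges$w >= theta2 & g$edges$ci %in% component &
    g$edges$cj %in% component
  cell_graph(g$edges[keep, , drop = FALSE], cells = component)
}

#' Spatial-coherence proxy score for a subgraph and its reconstruction
#'
#' Mean intersection-over-union between each node's strongest graph
#' neighbors (top K by shared-bead weight, ties by id) and its K nearest
#' neighbors in the reconstructed layout. This is a proxy for spatial
#' coherence - a pluggable stand-in used to compare candidate thresholds,
#' not a published formula.
#'
#' @param g a [cell_graph()].
#' @param rec_points [point_map()] of reconstructed positions.
#' @param K neighborhood size.
#' @return mean overlap in `[0, 1]`.
#' @export
coherence_score <- function(g, rec_points, K = 15) {
  ids <- sort(intersect(g$cells, rownames(rec_points)))
  n <- length(ids)
  if (K >= n) stop("K must be smaller than the node count")
  nn <- cpp_knn(unclass(rec_points[ids, , drop = FALSE]), K)
  adj <- list()
  for (r in seq_len(nrow(g$edges))) {
    ci <- g$edges$ci[r]; cj <- g$edges$cj[r]; w <- g$edges$w[r]
    adj[[ci]] <- rbind(adj[[ci]], data.frame(j = cj, w = w))
    adj[[cj]] <- rbind(adj[[cj]], data.frame(j = ci, w = w))
  }
  per <- vapply(seq_len(n), function(i) {
    a <- adj[[ids[i]]]
    if (is.null(a)) return(0)
    a <- a[order(-a$w, a$j), , drop = FALSE]
    gset <- match(head(a$j, K), ids)
    gset <- gset[!is.na(gset)]
    if (!length(gset)) return(0)
    rset <- nn[i, ]
    length(intersect(gset, rset)) / length(union(gset, rset))
  }, 0)
  mean(per)
}
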