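# Network-to-position reconstruction: random-walk visitation sampling,
# skip-gram embedding of walk neighborhoods, and neighbor-preserving
# reduction to 2D. Positions are recovered for cells AND beads, which the
# density-based edge refinement relies on.

# ---- internal graph plumbing ------------------------------------------------

# CSR adjacency over a unified node table. For a bead_network, nodes are
# c(cells, beads) and edges connect across classes (weights = UMI counts);
# for a cell_graph, nodes are the cells (weights = shared-bead counts).
as_csr <- function(graph) {
  if (inherits(graph, "bead_network")) {
    nodes <- c(graph$cells, graph$beads)
    classes <- c(rep("cell", length(graph$cells)),
                 rep("bead", length(graph$beads)))
    i <- match(graph$edges$cell, nodes)
    j <- match(graph$edges$bead, nodes)
    w <- graph$edges$umi
  } else if (inherits(graph, "cell_graph")) {
    nodes <- graph$cells
    classes <- rep("cell", length(nodes))
    i <- match(graph$edges$ci, nodes)
    j <- match(graph$edges$cj, nodes)
    w <- graph$edges$w
  } else stop("unsupported graph type")
  n <- length(nodes)
  src <- c(i, j); dst <- c(j, i); ww <- c(w, w)
  o <- order(src, dst)
  src <- src[o]; dst <- dst[o]; ww <- ww[o]
  deg <- tabulate(src, nbins = n)
  xadj <- c(0L, cumsum(deg))
  cumw <- as.numeric(unlist(lapply(split(ww, factor(src, levels = seq_len(n))),
                                   cumsum), use.names = FALSE))
  # re-express per-node cumulative sums as a global running vector aligned
  # with adjncy, as the walker expects
  if (length(cumw)) {
    offs <- rep(c(0, head(cumsum(as.numeric(
      vapply(split(ww, factor(src, levels = seq_len(n))), sum, 0))), -1)),
      times = deg)
    cumw <- cumw + offs
  }
  list(nodes = nodes, classes = classes, xadj = xadj,
       adjncy = as.integer(dst - 1L), cumw = cumw, deg = deg)
}

#' Sample random-walk visitation corpora from a graph
#'
#' Runs `walks_per_node` uniform (or weight-biased) random walks of
#' `walk_length` steps from every node. The visitation frequencies of these
#' walks estimate the probability that one node is encountered from another,
#' which captures the local and global structure of a spatial graph.
#'
#' @param graph a [bead_network()] or [cell_graph()]; must be a single
#'   connected component with no isolated nodes (split components upstream,
#'   see [reconstruct()]).
#' @param walks_per_node,walk_length walk count per start node and number of
#'   steps per walk (a walk visits `walk_length + 1` nodes).
#' @param weighted bias transitions by edge weight (UMI count / shared-bead
#'   count) instead of uniform neighbor choice.
#' @param seed RNG seed; fixed seed reproduces the corpus exactly.
#' @return a `walk_corpus`: integer matrix of node indices (one walk per
#'   row) plus the node table and parameters.
#' @export
sample_walks <- function(graph, walks_per_node = 10, walk_length = 20,
                         weighted = FALSE, seed = 1) {
  stopifnot(walks_per_node >= 1, walk_length >= 1)
  csr <- as_csr(graph)
  if (any(csr$deg == 0))
    stop("graph has isolated node(s), e.g. ",
         csr$nodes[which(csr$deg == 0)[1]],
         "; split connected components before walking")
  walks <- cpp_sample_walks(csr$xadj, csr$adjncy, csr$cumw, weighted,
                            as.integer(walks_per_node),
                            as.integer(walk_length), as.double(seed)) + 1L
  structure(list(walks = walks, nodes = csr$nodes, classes = csr$classes,
                 params = list(walks_per_node = walks_per_node,
                               walk_length = walk_length,
                               weighted = weighted, seed = seed)),
            class = "walk_corpus")
}

#' Train a skip-gram embedding on a walk corpus
#'
#' Maximizes (approximately) the log-likelihood of observing each node's
#' walk neighborhood given its vector representation, with the softmax
#' normalizer replaced by negative sampling (unigram^0.75 noise
#' distribution) for tractability. Training is single-threaded and
#' deterministic for a fixed seed.
#'
#' @param corpus a `walk_corpus` from [sample_walks()].
#' @param dim embedding dimension.
#' @param window context window half-width (actual window sampled uniformly
#'   from 1..window per token, as in standard skip-gram training).
#' @param epochs passes over the corpus.
#' @param negative negative samples per positive pair.
#' @param lr initial learning rate (linearly decayed).
#' @param seed RNG seed.
#' @return a `node_embedding`: matrix (nodes x dim, rownames = node ids)
#'   with the per-epoch loss trace and parameters in attributes.
#' @export
train_embedding <- function(corpus, dim = 32, window = 5, epochs = 3,
                            negative = 5, lr = 0.025, seed = 1) {
  stopifnot(inherits(corpus, "walk_corpus"), dim >= 2)
  if (length(corpus$nodes) < 2) stop("need at least 2 nodes")
  if (nrow(corpus$walks) == 0) stop("empty corpus")
  fit <- cpp_sgns(corpus$walks - 1L, length(corpus$nodes), as.integer(dim),
                  as.integer(window), as.integer(epochs),
                  as.integer(negative), lr, lr * 1e-3, as.double(seed))
  emb <- fit$embedding
  rownames(emb) <- corpus$nodes
  structure(emb, class = c("node_embedding", class(emb)),
            loss = fit$loss, classes = corpus$classes,
            params = list(dim = dim, window = window, epochs = epochs,
                          negative = negative, lr = lr, seed = seed))
}

#' Project a high-dimensional node embedding to 2D
#'
#' Neighbor-preserving reduction: a k-nearest-neighbor graph over the
#' embedding vectors is converted to smooth membership weights, the layout
#' is initialized from the first two principal components, and refined by
#' stochastic gradient descent with attractive forces along graph edges and
#' sampled repulsion elsewhere (the UMAP family of layouts). Pairs with high
#' mutual random-walk visitation probability are close in the embedding and
#' therefore end up close in 2D.
#'
#' @param emb a `node_embedding` (or plain matrix with rownames).
#' @param n_neighbors neighborhood size of the kNN graph.
#' @param min_dist target minimum separation in the output (shapes the
#'   low-dimensional similarity curve).
#' @param epochs SGD epochs.
#' @param negative repulsive samples per attractive update.
#' @param metric `"cosine"` (vectors length-normalized first; natural for
#'   inner-product trained embeddings) or `"euclidean"`.
#' @param init `"lmds"` (landmark multidimensional scaling on kNN-graph
#'   geodesics; recovers global structure before the SGD refines local
#'   neighborhoods) or `"pca"` (first two principal components of the
#'   embedding).
#' @param lr initial SGD learning rate.
#' @param seed RNG seed.
#' @return a [point_map()] (arbitrary units) over all embedded nodes.
#' @export
project_2d <- function(emb, n_neighbors = 15, min_dist = 0.1, epochs = 200,
                       negative = 5, metric = c("cosine", "euclidean"),
                       init = c("lmds", "pca"), lr = 1, seed = 1) {
  metric <- match.arg(metric)
  init <- match.arg(init)
  X <- unclass(emb)
  attr(X, "loss") <- attr(X, "params") <- attr(X, "classes") <- NULL
  if (nrow(X) < 3) stop("need at least 3 nodes")
  if (!all(is.finite(X))) stop("non-finite embedding vectors")
  if (metric == "cosine") {
    nrm <- sqrt(rowSums(X^2))
    X <- X / pmax(nrm, 1e-12)
  }
  k <- min(n_neighbors, nrow(X) - 1)
  nn <- cpp_knn(X, k)
  nnd <- matrix(0, nrow(X), k)
  for (c in seq_len(k)) {
    d <- X - X[nn[, c], , drop = FALSE]
    nnd[, c] <- sqrt(rowSums(d^2))
  }
  W <- cpp_smooth_knn_weights(nnd)
  i <- rep(seq_len(nrow(X)), k)
  j <- as.vector(nn)
  w <- as.vector(W)
  A <- Matrix::sparseMatrix(i = i, j = j, x = w,
                            dims = c(nrow(X), nrow(X)))
  S <- A + Matrix::t(A) - A * Matrix::t(A)       # fuzzy union
  S <- methods::as(Matrix::triu(S, k = 1), "TsparseMatrix")
  ab <- find_ab_params(min_dist)
  xy0 <- NULL
  if (init == "lmds")
    xy0 <- lmds_init(nn, nnd, nrow(X), seed = seed)
  if (is.null(xy0)) xy0 <- prcomp(X, rank. = 2)$x
  xy0 <- xy0 / max(abs(xy0)) * 10                # standard init extent
  xy <- cpp_layout(S@i, S@j, S@x, xy0, as.integer(epochs),
                   as.integer(negative), ab[1], ab[2], lr, as.double(seed))
  point_map(xy, ids = rownames(emb), units = "arbitrary")
}

# Landmark classical MDS on geodesic distances over the kNN graph of the
# embedding. Geodesics along the neighborhood graph track manifold (hence
# tissue) distances far better than straight-line distances in embedding
# space, so this initialization carries the global arrangement; the SGD
# then sharpens local neighborhoods. Edges are weighted by embedding
# distance: weighted geodesics are markedly more robust to shortcut edges
# (noise contamination) than hop counts. Returns NULL (caller falls back
# to PCA) when the kNN graph is disconnected.
lmds_init <- function(nn, nnd, n, n_landmarks = 300, seed = 1) {
  el <- cbind(rep(seq_len(n), ncol(nn)), as.vector(nn))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$weight <- pmax(as.vector(nnd), 1e-12)
  g <- igraph::simplify(g, edge.attr.comb = "min")
  if (igraph::components(g)$no > 1) return(NULL)
  m <- min(n_landmarks, n)
  lm <- with_seed(seed, sort(sample.int(n, m)))
  Dl <- igraph::distances(g, v = lm)        # m x n hop distances
  Dm2 <- Dl[, lm, drop = FALSE]^2
  J <- diag(m) - 1 / m
  B <- -0.5 * J %*% Dm2 %*% J
  eg <- eigen(B, symmetric = TRUE)
  if (eg$values[2] <= 0) return(NULL)
  V <- eg$vectors[, 1:2]
  lam <- eg$values[1:2]
  # out-of-sample triangulation from squared landmark distances
  proj <- sweep(t(V), 1, sqrt(lam), `/`)    # 2 x m
  delta_bar <- rowMeans(Dm2)
  xy <- -0.5 * t(proj %*% (Dl^2 - delta_bar))
  xy
}

# Least-squares fit of the low-dimensional similarity curve
# 1/(1 + a d^(2b)) to the piecewise target exp(-(d - min_dist)) beyond
# min_dist, 1 inside it.
find_ab_params <- function(min_dist, spread = 1) {
  d <- seq(0, spread * 3, length.out = 300)
  target <- ifelse(d < min_dist, 1, exp(-(d - min_dist) / spread))
  obj <- function(p) {
    a <- exp(p[1]); b <- exp(p[2])
    sum((1 / (1 + a * d^(2 * b)) - target)^2)
  }
  p <- optim(c(log(1.5), log(1)), obj)$par
  exp(p)
}

#' STRND-style reconstruction configuration
#'
#' Bundles every tunable of the reconstruction pipeline. The defaults are
#' sized for networks of up to a few tens of thousands of nodes on a single
#' CPU; all of them matter mainly through the walk corpus size
#' (`walks_per_node * (walk_length + 1) * n_nodes` tokens).
#'
#' @param walks_per_node,walk_length,weighted see [sample_walks()].
#' @param dim,window,epochs,negative,lr see [train_embedding()].
#' @param n_neighbors,min_dist,layout_epochs,metric see [project_2d()].
#' @param mode `"bipartite"` reconstructs the full cell-bead network
#'   (default; bead positions are required by the density-based refinement);
#'   `"unipartite"` reconstructs the shared-bead cell-cell projection.
#' @param all_components reconstruct every connected component (returned as
#'   a list) instead of the largest only.
#' @return a `strnd_config` list.
#' @export
strnd_config <- function(walks_per_node = 10, walk_length = 20,
                         weighted = FALSE, dim = 32, window = 5, epochs = 3,
                         negative = 5, lr = 0.025, n_neighbors = 15,
                         min_dist = 0.1, layout_epochs = 200,
                         metric = "cosine", mode = c("bipartite", "unipartite"),
                         all_components = FALSE) {
  mode <- match.arg(mode)
  structure(as.list(environment()), class = "strnd_config")
}

#' Reconstruct 2D positions from network structure
#'
#' Composition of [sample_walks()], [train_embedding()] and [project_2d()]
#' on the largest connected component (others are reported and skipped
#' unless `config$all_components`). The output layout is defined only up to
#' similarity transform - scale, rotation and mirroring carry no meaning -
#' so quality must be assessed with transform-invariant metrics ([cpd()],
#' [knn_score()]).
#'
#' @param net a [bead_network()] (already initial-filtered) or a
#'   [cell_graph()].
#' @param config a [strnd_config()].
#' @param seed master seed; walk, training and layout seeds are derived from
#'   it and recorded in the provenance.
#' @param verbose report skipped components.
#' @return a `reconstruction`: `points` ([point_map()], arbitrary units,
#'   covering cells and beads of the reconstructed component), `classes`
#'   (named `"cell"`/`"bead"` vector), and `provenance` (input hash, full
#'   parameter set, seeds, component sizes). With `all_components = TRUE`, a
#'   list of such objects.
#' @export
reconstruct <- function(net, config = strnd_config(), seed = 1,
                        verbose = TRUE) {
  stopifnot(inherits(config, "strnd_config"))
  graph <- net
  if (inherits(net, "bead_network") && config$mode == "unipartite")
    graph <- project_unipartite(net)
  comps <- graph_components(graph)
  sizes <- vapply(comps, length, 0L)
  o <- order(sizes, decreasing = TRUE)
  comps <- comps[o]; sizes <- sizes[o]
  if (verbose && length(comps) > 1)
    message("reconstruct: ", length(comps), " components (sizes ",
            paste(head(sizes, 5), collapse = ", "),
            if (length(sizes) > 5) ", ..." else "", "); ",
            if (config$all_components) "reconstructing all"
            else "reconstructing the largest")
  run_one <- function(ids, comp_seed) {
    sub <- induce_subgraph(graph, ids)
    seeds <- derive_seeds(comp_seed, 3)
    corpus <- sample_walks(sub, config$walks_per_node, config$walk_length,
                           config$weighted, seed = seeds[1])
    emb <- train_embedding(corpus, dim = config$dim, window = config$window,
                           epochs = config$epochs,
                           negative = config$negative, lr = config$lr,
                           seed = seeds[2])
    pts <- project_2d(emb, n_neighbors = config$n_neighbors,
                      min_dist = config$min_dist,
                      epochs = config$layout_epochs,
                      negative = config$negative, metric = config$metric,
                      seed = seeds[3])
    structure(list(
      points = pts,
      classes = setNames(corpus$classes, corpus$nodes),
      provenance = list(
        net_hash = if (inherits(net, "bead_network")) net_hash(net) else NA,
        config = unclass(config), seed = comp_seed, stage_seeds = seeds,
        component_sizes = sizes, n_nodes = length(ids),
        loss = as.numeric(attr(emb, "loss")))),
      class = "reconstruction")
  }
  if (config$all_components) {
    seeds <- derive_seeds(seed, length(comps))
    return(mapply(run_one, comps, seeds, SIMPLIFY = FALSE))
  }
  run_one(comps[[1]], seed)
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf(
    "reconstruction: %d nodes (%d cells, %d beads), seed %s, hash %s\n",
    nrow(x$points), sum(x$classes == "cell"), sum(x$classes == "bead"),
    format(x$provenance$seed), format(x$provenance$net_hash)))
  invisible(x)
}

graph_components <- function(graph) {
  if (inherits(graph, "bead_network")) {
    g <- igraph::graph_from_data_frame(
      graph$edges[c("cell", "bead")], directed = FALSE,
      vertices = data.frame(name = c(graph$cells, graph$beads)))
  } else {
    g <- igraph::graph_from_data_frame(
      graph$edges[c("ci", "cj")], directed = FALSE,
      vertices = data.frame(name = graph$cells))
  }
  comp <- igraph::components(g)
  split(igraph::V(g)$name, comp$membership)
}

induce_subgraph <- function(graph, ids) {
  if (inherits(graph, "bead_network")) {
    keep <- graph$edges$cell %in% ids & graph$edges$bead %in% ids
    bead_network(graph$edges[keep, , drop = FALSE],
                 cells = intersect(graph$cells, ids),
                 beads = intersect(graph$beads, ids))
  } else {
    keep <- graph$edges$ci %in% ids & graph$edges$cj %in% ids
    cell_graph(graph$edges[keep, , drop = FALSE],
               cells = intersect(graph$cells, ids))
  }
}

#' Write a reconstruction to delimited text plus a provenance sidecar
#'
#' @param rec a `reconstruction`.
#' @param path output table path (`node_id`, `class`, `x`, `y`); the full
#'   parameter set and seeds go to `<path>.json`.
#' @export
write_reconstruction <- function(rec, path) {
  data.table::fwrite(
    data.frame(node_id = rownames(rec$points),
               class = unname(rec$classes[rownames(rec$points)]),
               x = rec$points[, 1], y = rec$points[, 2]),
    path, sep = "\t")
  jsonlite::write_json(rec$provenance, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
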