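# Unipartite cell-cell projection and the edge-distance profile.

#' Construct a weighted cell-cell graph
#'
#' @param edges data.frame with columns `ci`, `cj`, `w` (shared-bead counts,
#'   positive integers). Stored with `ci < cj`; self-edges are forbidden.
#' @param cells optional full node list (isolated cells allowed).
#' @return a `cell_graph` object.
#' @export
cell_graph <- function(edges, cells = NULL) {
  stopifnot(all(c("ci", "cj", "w") %in% names(edges)))
  edges$ci <- as.character(edges$ci)
  edges$cj <- as.character(edges$cj)
  edges$w <- as.numeric(edges$w)
  if (nrow(edges) > 0) {
    if (any(edges$ci == edges$cj)) stop("self-edges are not allowed")
    if (any(edges$w < 1)) stop("edge weights must be >= 1")
    flip <- edges$ci > edges$cj
    tmp <- edges$ci[flip]; edges$ci[flip] <- edges$cj[flip]; edges$cj[flip] <- tmp
    key <- paste(edges$ci, edges$cj, sep = "\r")
    if (anyDuplicated(key)) stop("duplicate cell pairs in edge list")
    edges <- edges[order(edges$ci, edges$cj), , drop = FALSE]
  }
  cells <- sort(unique(c(as.character(cells %||% character()),
                         edges$ci, edges$cj)))
  rownames(edges) <- NULL
  structure(list(edges = edges[c("ci", "cj", "w")], cells = cells),
            class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("cell_graph: %d cells, %d weighted edges\n",
              length(x$cells), nrow(x$edges)))
  invisible(x)
}

#' Project the bipartite network onto its cell nodes
#'
#' Two cells are connected if they share at least one bead neighbor; the
#' edge weight W_ij is the number of beads adjacent to both. Beads and their
#' edges are absent from the output. Computed as the sparse cross-product of
#' the bead-by-cell incidence pattern.
#'
#' @param net a [bead_network()].
#' @return a [cell_graph()] over all cells of `net` (cells sharing no bead
#'   are isolated nodes).
#' @export
project_unipartite <- function(net) {
  if (nrow(net$edges) == 0)
    return(cell_graph(data.frame(ci = character(), cj = character(),
                                 w = numeric()), cells = net$cells))
  bi <- match(net$edges$bead, net$beads)
  ci <- match(net$edges$cell, net$cells)
  A <- Matrix::sparseMatrix(i = bi, j = ci,
                            dims = c(length(net$beads), length(net$cells)),
                            x = 1)
  W <- Matrix::crossprod(A)  # cells x cells, shared-bead counts
  W <- methods::as(Matrix::triu(W, k = 1), "TsparseMatrix")
  cell_graph(data.frame(ci = net$cells[W@i + 1L], cj = net$cells[W@j + 1L],
                        w = W@x),
             cells = net$cells)
}

#' Edge frequency as a function of cell-cell distance
#'
#' For each distance bin, the number of unipartite edges whose endpoints are
#' that far apart in the reference layout, divided by the number of all
#' possible cell pairs at that distance, so the profile is the probability
#' that a pair at a given separation is connected. Only cells present in
#' `ref` participate. Pair enumeration is exhaustive up to
#' `max_exact` positioned cells and switches to a seeded subsample (with the
#' pair counts rescaled) above that, to bound the O(n^2) cost.
#'
#' @param g a [cell_graph()].
#' @param ref reference [point_map()] (micrometers).
#' @param bin_width bin width in the units of `ref`.
#' @param max_exact exhaustive-enumeration ceiling (number of cells).
#' @param seed seed for the subsampled regime.
#' @return an `edge_distance_profile` data.frame: `lower`, `upper`,
#'   `observed`, `possible`, `frequency`.
#' @export
edge_distance_profile <- function(g, ref, bin_width, max_exact = 20000,
                                  seed = 1) {
  stopifnot(bin_width > 0)
  pos_cells <- intersect(g$cells, rownames(ref))
  if (length(pos_cells) < 2) stop("need at least 2 positioned cells")
  P <- ref[pos_cells, , drop = FALSE]
  use <- g$edges$ci %in% pos_cells & g$edges$cj %in% pos_cells
  e <- g$edges[use, , drop = FALSE]
  elen <- sqrt(rowSums((P[e$ci, , drop = FALSE] - P[e$cj, , drop = FALSE])^2))
  maxd <- max(dist_range_upper(P), if (length(elen)) max(elen) else 0)
  breaks <- seq(0, maxd + bin_width, by = bin_width)
  # left-closed bins, right edge closed: identical convention to the pair
  # counter so boundary ties cancel in the ratio
  obs <- tabulate(findInterval(elen, breaks, rightmost.closed = TRUE),
                  nbins = length(breaks) - 1)
  if (nrow(P) <= max_exact) {
    poss <- cpp_pair_dist_hist(unclass(P), breaks)
    scale <- 1
  } else {
    idx <- with_seed(seed, sample.int(nrow(P), max_exact))
    poss <- cpp_pair_dist_hist(unclass(P)[idx, , drop = FALSE], breaks)
    scale <- (nrow(P) * (nrow(P) - 1)) / (max_exact * (max_exact - 1))
  }
  poss <- poss * scale
  freq <- ifelse(poss > 0, obs / poss, 0)
  structure(
    data.frame(lower = head(breaks, -1), upper = breaks[-1],
               observed = obs, possible = poss, frequency = freq),
    class = c("edge_distance_profile", "data.frame"),
    n_cells = nrow(P), n_edges = nrow(e), subsampled = scale != 1)
}

# conservative upper bound for the largest pairwise distance: diameter of
# the bounding box
dist_range_upper <- function(P) {
  sqrt(sum((apply(P, 2, max) - apply(P, 2, min))^2))
}
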