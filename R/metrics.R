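# Transform-invariant reconstruction fidelity metrics and alignment of a
# reconstruction onto a reference frame.

#' Correlation of pairwise distances (global fidelity)
#'
#' The square of the Pearson correlation between all pairwise distances of
#' the common nodes in the reference layout and in the reconstruction. A
#' similarity transform (rotation, translation, mirroring, uniform scaling)
#' of either layout leaves the value unchanged, which is why it is the
#' global score for layouts whose absolute frame is meaningless.
#' All pairs are enumerated exactly up to `max_exact` nodes; above that a
#' seeded subsample of `n_pairs` pairs is used.
#'
#' @param ref,rec [point_map()]s sharing at least 3 node ids.
#' @param max_exact node-count ceiling for exhaustive enumeration.
#' @param n_pairs number of sampled pairs beyond the ceiling.
#' @param seed seed for the sampled regime.
#' @return squared Pearson correlation in `[0, 1]`.
#' @export
cpd <- function(ref, rec, max_exact = 20000, n_pairs = 1e7, seed = 1) {
  ids <- common_ids(ref, rec)
  if (length(ids) < 3) stop("need at least 3 common nodes")
  P <- ref[ids, , drop = FALSE]
  Q <- rec[ids, , drop = FALSE]
  n <- length(ids)
  if (n <= max_exact) {
    d <- as.vector(dist(P))
    dh <- as.vector(dist(Q))
  } else {
    ij <- with_seed(seed, {
      i <- sample.int(n, n_pairs, replace = TRUE)
      j <- sample.int(n, n_pairs, replace = TRUE)
      keep <- i != j
      cbind(i[keep], j[keep])
    })
    d <- sqrt(rowSums((P[ij[, 1], ] - P[ij[, 2], ])^2))
    dh <- sqrt(rowSums((Q[ij[, 1], ] - Q[ij[, 2], ])^2))
  }
  if (sd(d) == 0 || sd(dh) == 0)
    stop("pairwise distances have zero variance; CPD undefined")
  cor(d, dh)^2
}

#' K-nearest-neighbor overlap score (local fidelity)
#'
#' For each common node, the K nearest neighbors (self excluded) are found
#' in both layouts and compared as intersection over union; the layout score
#' is the mean over nodes. Converges to 1 as K approaches the number of
#' common nodes minus one. Distance ties at the K-th neighbor are broken by
#' sorted node-id order, deterministically (this only matters at machine
#' precision or on degenerate layouts).
#'
#' @param ref,rec [point_map()]s sharing more than `K` node ids.
#' @param K neighborhood size (default 15).
#' @return list with `score` (mean) and `per_node` (named vector).
#' @export
knn_score <- function(ref, rec, K = 15) {
  ids <- common_ids(ref, rec)
  n <- length(ids)
  stopifnot(K >= 1)
  if (K >= n) stop("K must be smaller than the number of common nodes")
  nn_ref <- cpp_knn(unclass(ref[ids, , drop = FALSE]), K)
  nn_rec <- cpp_knn(unclass(rec[ids, , drop = FALSE]), K)
  per <- vapply(seq_len(n), function(i) {
    a <- nn_ref[i, ]; b <- nn_rec[i, ]
    length(intersect(a, b)) / length(union(a, b))
  }, 0)
  list(score = mean(per), per_node = setNames(per, ids))
}

#' Align a reconstruction onto a reference frame
#'
#' Both point clouds (restricted to common nodes) are centered and scaled to
#' unit radius (radius = maximum distance from the centroid), optionally
#' adjusted so their convex hulls match (hull-area rescale plus hull-centroid
#' re-centering), and the optimal orthogonal map (rotation or reflection) is
#' taken from the SVD of the cross-covariance, with a uniform scale equal to
#' the point-cloud Frobenius-norm ratio. The aligned reconstruction is
#' returned in the original reference coordinates (micrometers when the
#' reference is physical), ready for per-point distortion measurement.
#'
#' @param rec reconstruction [point_map()].
#' @param ref reference [point_map()].
#' @param hull_adjust apply the convex-hull matching adjustment (on by
#'   default; set `FALSE` to align on unit-radius normalization alone).
#' @return list with `aligned` (rec mapped into ref coordinates, common
#'   nodes only), `transform` (orthogonal matrix, scale, translation) and
#'   `ids`.
#' @export
align <- function(rec, ref, hull_adjust = TRUE) {
  ids <- common_ids(ref, rec)
  if (length(ids) < 3) stop("need at least 3 common nodes")
  P <- unclass(ref[ids, , drop = FALSE])   # reference
  Q <- unclass(rec[ids, , drop = FALSE])   # reconstruction
  ctr <- function(X) sweep(X, 2, colMeans(X))
  P0 <- ctr(P); Q0 <- ctr(Q)
  radius <- function(X) max(sqrt(rowSums(X^2)))
  rp <- radius(P0); rq <- radius(Q0)
  if (rp == 0 || rq == 0) stop("degenerate (single-point) cloud")
  Pn <- P0 / rp; Qn <- Q0 / rq
  if (collinear(Pn) || collinear(Qn))
    warning("nearly collinear point cloud; alignment is ill-conditioned")
  hcP <- c(0, 0)
  if (hull_adjust) {
    # hull matching must stay rotation-equivariant (the rotation is only
    # removed afterwards): rescale rec to the reference hull area and
    # center each cloud on its own hull centroid
    hp <- hull_poly(Pn); hq <- hull_poly(Qn)
    if (hq$area > 0 && hp$area > 0) {
      Qn <- Qn * sqrt(hp$area / hq$area)
      hq <- hull_poly(Qn)
      hcP <- hp$centroid
      Pn <- sweep(Pn, 2, hcP)
      Qn <- sweep(Qn, 2, hq$centroid)
    }
  }
  s <- svd(crossprod(Qn, Pn))
  R <- s$u %*% t(s$v)                  # orthogonal, reflection allowed
  scale <- norm(Pn, "F") / norm(Qn, "F")
  An <- sweep((Qn %*% R) * scale, 2, hcP, `+`)
  A <- sweep(An * rp, 2, colMeans(P), `+`)
  list(
    aligned = point_map(A, ids = ids, units = pm_units(ref)),
    transform = list(rotation = R, scale = scale * rp / rq,
                     ref_centroid = colMeans(P), rec_centroid = colMeans(Q),
                     ref_radius = rp, rec_radius = rq),
    ids = ids)
}

collinear <- function(X) {
  sv <- svd(sweep(X, 2, colMeans(X)))$d
  sv[2] < 1e-10 * max(sv[1], 1e-300)
}

# convex hull area (shoelace) and polygon centroid
hull_poly <- function(X) {
  h <- grDevices::chull(X)
  V <- X[h, , drop = FALSE]
  n <- nrow(V)
  if (n < 3) return(list(area = 0, centroid = colMeans(X)))
  x <- V[, 1]; y <- V[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  area <- sum(cr) / 2
  cx <- sum((x + xn) * cr) / (6 * area)
  cy <- sum((y + yn) * cr) / (6 * area)
  list(area = abs(area), centroid = c(cx, cy))
}

#' Per-point distortion after alignment
#'
#' Euclidean distance between each aligned reconstructed point and its true
#' reference position, in the units of the reference.
#'
#' @param aligned aligned [point_map()] (see [align()]).
#' @param ref reference [point_map()].
#' @return named vector of distances with a `summary` attribute
#'   (mean/median/max).
#' @export
distortion <- function(aligned, ref) {
  ids <- common_ids(aligned, ref)
  d <- sqrt(rowSums((unclass(aligned[ids, , drop = FALSE]) -
                       unclass(ref[ids, , drop = FALSE]))^2))
  structure(setNames(d, ids),
            summary = c(mean = mean(d), median = median(d), max = max(d)))
}

#' Full fidelity report for a reconstruction against a reference
#'
#' @param ref,rec [point_map()]s.
#' @param K neighborhood size for the local metric.
#' @param ... passed to [cpd()].
#' @return a `fidelity_report` list: `cpd`, `knn` (mean), `knn_per_node`,
#'   `distortion` (per-point, via [align()]), `n`.
#' @export
fidelity_report <- function(ref, rec, K = 15, ...) {
  ids <- common_ids(ref, rec)
  kn <- knn_score(ref, rec, K = K)
  al <- align(rec, ref)
  structure(list(cpd = cpd(ref, rec, ...), knn = kn$score,
                 knn_per_node = kn$per_node,
                 distortion = distortion(al$aligned, ref),
                 K = K, n = length(ids)),
            class = "fidelity_report")
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat(sprintf(
    "fidelity: CPD R^2 = %.3f | KNN(K=%d) = %.3f | mean distortion = %.3g (n = %d)\n",
    x$cpd, x$K, x$knn, attr(x$distortion, "summary")["mean"], x$n))
  invisible(x)
}

#' Write a fidelity report as JSON plus a per-node table
#' @param report a `fidelity_report`.
#' @param path base path: JSON summary to `path`, per-node table to
#'   `<path>.nodes.tsv`.
#' @export
write_fidelity_report <- function(report, path) {
  jsonlite::write_json(
    list(cpd = report$cpd, knn = report$knn, K = report$K, n = report$n,
         distortion = as.list(attr(report$distortion, "summary"))),
    path, auto_unbox = TRUE, digits = NA)
  data.table::fwrite(
    data.frame(node_id = names(report$knn_per_node),
               knn = report$knn_per_node,
               distortion = report$distortion[names(report$knn_per_node)]),
    paste0(path, ".nodes.tsv"), sep = "\t")
  invisible(path)
}
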