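# Boundary-constrained shape regularization: alpha-shape boundary
# detection and thin-plate-spline warping of the reconstructed cloud onto a
# target shape (circle by default, any star-convex polygon optionally).

#' Centroid and radius of a point cloud
#'
#' The centroid is the coordinate mean; the radius is the maximum distance
#' from the centroid to any point.
#'
#' @param points [point_map()] or 2-column matrix.
#' @return list with `centroid` (length-2) and `r`.
#' @export
centroid_radius <- function(points) {
  X <- unclass(points)
  stopifnot(nrow(X) >= 1)
  ctr <- colMeans(X)
  list(centroid = ctr, r = max(sqrt(colSums((t(X) - ctr)^2))))
}

#' Alpha-shape boundary of a 2D point cloud
#'
#' A point pair is an alpha-shape boundary edge when one of the two circles
#' of radius 1/alpha through the pair contains no other point; alpha
#' controls the level of detail, with the alpha -> 0 limit recovering the
#' convex hull and larger alpha following concavities. The boundary edges
#' must form a single closed cycle; `alpha = "auto"` bisects to the largest
#' alpha that still yields one, and an explicit alpha that disintegrates the
#' shape fails with the largest usable alpha named in the error.
#'
#' @param points [point_map()] or matrix (>= 4 points).
#' @param alpha positive scalar (units of 1/distance) or `"auto"`.
#' @return an `alpha_boundary`: list with `indices` (boundary rows of
#'   `points`, ordered along the boundary), `coords`, `alpha`.
#' @export
alpha_boundary <- function(points, alpha = "auto") {
  X <- unclass(points)
  stopifnot(nrow(X) >= 4)
  if (identical(alpha, "auto")) {
    alpha <- auto_alpha(X)
    cyc <- boundary_cycle(X, alpha)
  } else {
    stopifnot(is.numeric(alpha), alpha > 0)
    cyc <- boundary_cycle(X, alpha)
    if (is.null(cyc)) {
      usable <- auto_alpha(X, hi = alpha)
      stop(sprintf(
        "alpha = %g disintegrates the shape; largest usable alpha found by bisection: %g",
        alpha, usable))
    }
  }
  structure(list(indices = cyc, coords = X[cyc, , drop = FALSE],
                 alpha = alpha),
            class = "alpha_boundary")
}

# Single closed boundary cycle at a given alpha, or NULL if the alpha-edge
# graph is not one simple cycle covering the outline.
boundary_cycle <- function(X, alpha) {
  E <- cpp_alpha_edges(X, alpha)
  if (nrow(E) < 3) return(NULL)
  verts <- sort(unique(c(E[, 1], E[, 2])))
  deg <- tabulate(c(E[, 1], E[, 2]), nbins = nrow(X))
  if (any(deg[verts] != 2)) return(NULL)
  # walk the cycle
  adj <- split(c(E[, 2], E[, 1]), c(E[, 1], E[, 2]))
  start <- verts[1]
  cyc <- start
  prev <- NA_integer_
  cur <- start
  repeat {
    nbrs <- adj[[as.character(cur)]]
    nxt <- if (is.na(prev)) nbrs[1] else nbrs[nbrs != prev]
    if (length(nxt) != 1) return(NULL)
    if (nxt == start) break
    cyc <- c(cyc, nxt)
    prev <- cur; cur <- nxt
    if (length(cyc) > length(verts)) return(NULL)
  }
  if (length(cyc) != length(verts)) return(NULL)  # multiple loops
  cyc
}

# Largest alpha yielding a single closed boundary, by bisection between the
# hull regime and disintegration. lo is derived from the cloud radius (a
# circle of radius 2r always sees a hull-like boundary).
auto_alpha <- function(X, hi = NULL, iters = 25) {
  r <- centroid_radius(X)$r
  lo <- 0.25 / r
  if (is.null(boundary_cycle(X, lo))) {
    # even the near-hull regime failed (rare, degenerate input): shrink
    for (k in 1:10) {
      lo <- lo / 4
      if (!is.null(boundary_cycle(X, lo))) break
    }
    if (is.null(boundary_cycle(X, lo))) stop("no usable alpha found")
  }
  if (is.null(hi)) hi <- 200 / r
  if (!is.null(boundary_cycle(X, hi))) return(hi)
  for (k in seq_len(iters)) {
    mid <- sqrt(lo * hi)
    if (is.null(boundary_cycle(X, mid))) hi <- mid else lo <- mid
  }
  lo
}

#' Project boundary landmarks radially onto a target shape
#'
#' Each source landmark at angle phi = atan2(y - yc, x - xc) maps to the
#' target boundary along the same ray: for the default circular target,
#' (xc + r cos phi, yc + r sin phi); for a star-convex polygon target, the
#' ray-polygon intersection. Landmarks coincident with the centroid have an
#' undefined angle and are dropped with a warning.
#'
#' @param boundary an [alpha_boundary()] (or 2-column matrix of ordered
#'   boundary points).
#' @param centroid,r circle center and radius (see [centroid_radius()]).
#' @param target `"circle"` or a star-convex polygon as a 2-column vertex
#'   matrix (centered on `centroid`).
#' @return a `boundary_landmarks`: `source`, `target` matrices (row-matched),
#'   `centroid`, `r`, `phi`.
#' @export
make_target_landmarks <- function(boundary, centroid, r, target = "circle") {
  src <- if (inherits(boundary, "alpha_boundary")) boundary$coords
         else as.matrix(boundary)
  rel <- sweep(src, 2, centroid)
  len <- sqrt(rowSums(rel^2))
  bad <- len < 1e-12
  if (any(bad)) {
    warning(sum(bad), " landmark(s) coincident with the centroid dropped")
    src <- src[!bad, , drop = FALSE]
    rel <- rel[!bad, , drop = FALSE]
  }
  phi <- atan2(rel[, 2], rel[, 1])
  if (identical(target, "circle")) {
    tgt <- cbind(centroid[1] + r * cos(phi), centroid[2] + r * sin(phi))
  } else {
    poly <- as.matrix(target)
    tgt <- t(vapply(phi, function(a)
      ray_polygon(centroid, a, poly), numeric(2)))
  }
  structure(list(source = src, target = tgt, centroid = centroid, r = r,
                 phi = phi),
            class = "boundary_landmarks")
}

# first intersection of the ray from `origin` at angle `a` with the polygon
ray_polygon <- function(origin, a, poly) {
  d <- c(cos(a), sin(a))
  n <- nrow(poly)
  best <- Inf; hit <- c(NA_real_, NA_real_)
  for (i in seq_len(n)) {
    p <- poly[i, ]; q <- poly[if (i == n) 1 else i + 1, ]
    e <- q - p
    den <- d[1] * (-e[2]) - d[2] * (-e[1])
    if (abs(den) < 1e-14) next
    rhs <- p - origin
    t1 <- (rhs[1] * (-e[2]) - rhs[2] * (-e[1])) / den
    t2 <- (d[1] * rhs[2] - d[2] * rhs[1]) / den
    if (t1 > 0 && t2 >= 0 && t2 <= 1 && t1 < best) {
      best <- t1
      hit <- origin + t1 * d
    }
  }
  if (!is.finite(best)) stop("ray misses target polygon (not star-convex?)")
  hit
}

#' Thin-plate-spline warp driven by landmark correspondences
#'
#' Computes the TPS map (global affine part plus radial-basis bending terms
#' U(d) = d^2 log d) that carries the source landmarks to the target
#' landmarks while minimizing bending energy, and applies it to every point.
#' With `stiffness = 0` the landmarks are interpolated exactly; a positive
#' stiffness regularizes the system (scaled by the squared mean landmark
#' spacing so the parameter is dimensionless) and yields a softer warp that
#' only approaches the targets. Landmark sets related by an affine map are
#' reproduced exactly with zero bending.
#'
#' @param points [point_map()] or matrix to warp.
#' @param landmarks a [make_target_landmarks()] result (or list with
#'   `source` and `target` matrices).
#' @param stiffness dimensionless regularization weight (default 0 =
#'   exact interpolation).
#' @return warped points, same container type as the input.
#' @export
tps_warp <- function(points, landmarks, stiffness = 0) {
  S <- landmarks$source
  Tt <- landmarks$target
  p <- nrow(S)
  stopifnot(p >= 3, nrow(Tt) == p)
  if (collinear(S)) stop("collinear landmarks: TPS system is singular")
  D <- as.matrix(dist(S))
  K <- tps_u(D)
  if (stiffness > 0) {
    dbar <- mean(D[upper.tri(D)])
    K <- K + diag(p) * stiffness * dbar^2
  }
  P <- cbind(1, S)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(Tt, matrix(0, 3, 2))
  coefs <- solve(L, rhs)
  W <- coefs[1:p, , drop = FALSE]
  Aff <- coefs[(p + 1):(p + 3), , drop = FALSE]
  X <- unclass(points)
  U <- tps_u(cross_dist(X, S))
  out <- cbind(1, X) %*% Aff + U %*% W
  if (inherits(points, "point_map"))
    point_map(out, ids = rownames(points), units = pm_units(points))
  else out
}

tps_u <- function(d) ifelse(d > 0, d^2 * log(d), 0)

cross_dist <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, `+`) - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' Morph a reconstructed cloud onto a known sample shape
#'
#' Pipeline of [centroid_radius()], [alpha_boundary()],
#' [make_target_landmarks()] and [tps_warp()]: detects the reconstructed
#' boundary, maps it radially onto the target (circle of the cloud's own
#' radius by default), and warps the full cloud accordingly. A soft
#' regularization (positive `stiffness`) gives the gentle adjustment
#' appropriate when the prior shape knowledge is approximate.
#'
#' @param points [point_map()] to morph.
#' @param alpha alpha-shape detail parameter or `"auto"`.
#' @param target `"circle"` or a star-convex polygon matrix.
#' @param stiffness TPS regularization (see [tps_warp()]).
#' @param max_landmarks cap on landmark count (boundary subsampled evenly
#'   beyond it, keeping the TPS solve small).
#' @param boundary_points boundary detection runs on a seeded subsample of
#'   at most this many points for large clouds (the O(n^2) alpha-edge scan
#'   dominates otherwise; a few thousand points pin the outline to well
#'   under the warp's own softness).
#' @param seed seed for the boundary subsample.
#' @return list with `points` (morphed [point_map()]), `landmarks`,
#'   `alpha`.
#' @export
morph <- function(points, alpha = "auto", target = "circle",
                  stiffness = 0.05, max_landmarks = 200,
                  boundary_points = 2500, seed = 1) {
  cr <- centroid_radius(points)
  bpts <- points
  if (nrow(points) > boundary_points) {
    idx <- with_seed(seed, sample.int(nrow(points), boundary_points))
    bpts <- unclass(points)[idx, , drop = FALSE]
  }
  bnd <- alpha_boundary(bpts, alpha)
  if (nrow(bnd$coords) > max_landmarks) {
    pick <- unique(round(seq(1, nrow(bnd$coords),
                             length.out = max_landmarks)))
    bnd$indices <- bnd$indices[pick]
    bnd$coords <- bnd$coords[pick, , drop = FALSE]
  }
  lm <- make_target_landmarks(bnd, cr$centroid, cr$r, target)
  warped <- tps_warp(points, lm, stiffness)
  list(points = warped, landmarks = lm, alpha = bnd$alpha)
}
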