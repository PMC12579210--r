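# Fixture builders shared across test files. Everything is generated in
# code so tests are self-contained and seeded.

# A small random bipartite network with the given node counts; edge
# presence Bernoulli(p), UMIs uniform 1..umi_max.
random_net <- function(n_cells, n_beads, p = 0.2, umi_max = 5, seed = 1) {
  withr::local_seed(seed)
  grid <- expand.grid(cell = sprintf("c%02d", seq_len(n_cells)),
                      bead = sprintf("b%02d", seq_len(n_beads)),
                      stringsAsFactors = FALSE)
  keep <- runif(nrow(grid)) < p
  e <- grid[keep, , drop = FALSE]
  e$umi <- sample.int(umi_max, nrow(e), replace = TRUE)
  bead_network(e, cells = sprintf("c%02d", seq_len(n_cells)),
               beads = sprintf("b%02d", seq_len(n_beads)))
}

# Uniform random point map on [0, extent]^2.
random_points <- function(n, extent = 100, seed = 1, ids = NULL,
                          units = "um") {
  withr::local_seed(seed)
  if (is.null(ids)) ids <- sprintf("p%04d", seq_len(n))
  point_map(cbind(runif(n, 0, extent), runif(n, 0, extent)),
            ids = ids, units = units)
}

# Apply a random similarity transform (rotation + optional mirror + scale +
# translation) to a point map.
similarity_transform <- function(p, angle = NULL, scale = NULL,
                                 shift = NULL, mirror = FALSE, seed = 1) {
  withr::local_seed(seed)
  if (is.null(angle)) angle <- runif(1, 0, 2 * pi)
  if (is.null(scale)) scale <- runif(1, 0.5, 3)
  if (is.null(shift)) shift <- runif(2, -50, 50)
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
  if (mirror) R <- R %*% diag(c(-1, 1))
  out <- sweep(unclass(p) %*% R * scale, 2, shift, `+`)
  point_map(out, ids = rownames(p), units = attr(p, "units"))
}

# Brute-force unipartite projection: O(cells^2 x beads) shared-bead counts.
brute_projection <- function(net) {
  cells <- net$cells
  nb <- lapply(cells, function(cl) net$edges$bead[net$edges$cell == cl])
  names(nb) <- cells
  rows <- list()
  for (i in seq_along(cells)) for (j in seq_len(i - 1L)) {
    w <- length(intersect(nb[[i]], nb[[j]]))
    if (w > 0)
      rows[[length(rows) + 1]] <- data.frame(ci = cells[j], cj = cells[i],
                                             w = w)
  }
  if (!length(rows)) return(data.frame(ci = character(), cj = character(),
                                       w = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$ci, out$cj), ]
}

# Brute-force K nearest neighbor ids (self excluded, ties by id order).
brute_knn <- function(p, K) {
  ids <- sort(rownames(p))
  X <- unclass(p)[ids, , drop = FALSE]
  t(vapply(seq_along(ids), function(i) {
    d <- sqrt(rowSums((X - matrix(X[i, ], nrow(X), 2, byrow = TRUE))^2))
    d[i] <- Inf
    order(d, seq_along(ids))[seq_len(K)]
  }, integer(K)))
}
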