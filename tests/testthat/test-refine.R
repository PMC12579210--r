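# DBSCAN-based edge pruning and the theta/theta2 subgraph procedure.

# build a reconstruction-like object directly from coordinates
fake_rec <- function(coords, classes) {
  structure(list(points = coords, classes = classes,
                 provenance = list(seed = 0)),
            class = "reconstruction")
}

# a network of `n_cells` cells whose beads live in a tight blob each, plus
# optional far-flung outlier beads per cell
blob_net <- function(n_cells = 4, beads_per_cell = 10, outliers = 0,
                     seed = 1) {
  withr::local_seed(seed)
  edges <- NULL
  pts <- NULL
  for (i in seq_len(n_cells)) {
    ctr <- c(100 * i, 0)
    ids <- sprintf("b%02d_%02d", i, seq_len(beads_per_cell))
    xy <- cbind(rnorm(beads_per_cell, ctr[1], 1),
                rnorm(beads_per_cell, ctr[2], 1))
    if (outliers > 0) {
      oid <- sprintf("o%02d_%02d", i, seq_len(outliers))
      ids <- c(ids, oid)
      xy <- rbind(xy, cbind(rnorm(outliers, ctr[1], 1),
                            rnorm(outliers, 2000, 1)))
    }
    edges <- rbind(edges, data.frame(cell = sprintf("c%02d", i), bead = ids,
                                     umi = 1))
    rownames(xy) <- ids
    pts <- rbind(pts, xy)
  }
  cells_xy <- cbind(100 * seq_len(n_cells), rep(0, n_cells))
  rownames(cells_xy) <- sprintf("c%02d", seq_len(n_cells))
  all_xy <- rbind(pts, cells_xy)
  net <- bead_network(edges)
  rec <- fake_rec(point_map(all_xy, units = "arbitrary"),
                  setNames(c(rep("bead", nrow(pts)),
                             rep("cell", n_cells)), rownames(all_xy)))
  list(net = net, rec = rec)
}

test_that("tight bead blobs keep all their edges", {
  f <- blob_net(n_cells = 3, beads_per_cell = 10)
  out <- dbscan_edge_filter(f$net, f$rec, min_samples = 5, verbose = FALSE)
  expect_equal(nrow(out$edges), nrow(f$net$edges))
  expect_setequal(out$beads, f$net$beads)
})

test_that("a far-flung bead loses exactly its edge, bead node retained", {
  f <- blob_net(n_cells = 2, beads_per_cell = 9, outliers = 1)
  out <- dbscan_edge_filter(f$net, f$rec, min_samples = 5, verbose = FALSE)
  expect_equal(nrow(out$edges), nrow(f$net$edges) - 2)  # one outlier per cell
  expect_false(any(grepl("^o", out$edges$bead)))
  expect_true(all(grepl("^o", setdiff(f$net$beads, out$edges$bead))))
  expect_setequal(out$beads, f$net$beads)  # beads themselves stay
})

test_that("clusterless cells are removed with their edges", {
  f <- blob_net(n_cells = 2, beads_per_cell = 2)
  out <- dbscan_edge_filter(f$net, f$rec, min_samples = 5, verbose = FALSE)
  expect_equal(nrow(out$edges), 0)
  expect_length(out$cells, 0)
  expect_equal(attr(out, "cells_removed"), 2)
})

test_that("the edge filter never adds edges and only shrinks cells", {
  withr::local_seed(44)
  sim <- simulate_network(sim_config(n_cells = 150, n_beads = 300,
                                     diameter = 800,
                                     powerlaw_exponent = 1.2,
                                     rounds_max = 200, noise_ratio = 0.2),
                          seed = 44)
  rec <- fake_rec(sim$truth$positions,
                  setNames(c(rep("cell", 150), rep("bead", 300)),
                           rownames(sim$truth$positions)))
  out <- dbscan_edge_filter(sim$network, rec, min_samples = 3,
                            verbose = FALSE)
  key <- function(n) paste(n$edges$cell, n$edges$bead)
  expect_true(all(key(out) %in% key(sim$network)))
  expect_true(all(out$cells %in% sim$network$cells))
  expect_setequal(out$beads, sim$network$beads)
})

test_that("auto min_samples maximizes single-cluster cells (exhaustive oracle)", {
  # all blobs tight: every candidate yields one cluster, smallest wins
  f <- blob_net(n_cells = 4, beads_per_cell = 12)
  eps <- 0.05 * beadnet:::cloud_diameter(unclass(f$rec$points))
  expect_equal(as.integer(auto_min_samples(f$net, f$rec, eps,
                                           search_range = 2:8)), 2L)

  # constructed case: cells have a 6-bead blob plus a 3-bead clump far
  # away; small min_samples sees two clusters, larger sees one
  withr::local_seed(45)
  edges <- NULL; xy <- NULL
  for (i in 1:5) {
    main <- sprintf("m%d_%d", i, 1:6)
    side <- sprintf("s%d_%d", i, 1:3)
    edges <- rbind(edges, data.frame(cell = paste0("c", i),
                                     bead = c(main, side), umi = 1))
    pts <- rbind(cbind(rnorm(6, 100 * i, 1), rnorm(6, 0, 1)),
                 cbind(rnorm(3, 100 * i, 1), rnorm(3, 500, 1)))
    rownames(pts) <- c(main, side)
    xy <- rbind(xy, pts)
  }
  cells <- cbind(100 * (1:5), rep(0, 5)); rownames(cells) <- paste0("c", 1:5)
  rec <- fake_rec(point_map(rbind(xy, cells), units = "arbitrary"),
                  setNames(c(rep("bead", nrow(xy)), rep("cell", 5)),
                           c(rownames(xy), rownames(cells))))
  net <- bead_network(edges)
  eps <- 30
  # brute-force the count of single-cluster cells per candidate
  counts <- vapply(2:8, function(ms) {
    sum(vapply(split(net$edges$bead, net$edges$cell), function(b) {
      lab <- beadnet:::dbscan_points(unclass(rec$points)[b, ], eps, ms)
      length(unique(lab[lab > 0])) == 1
    }, TRUE))
  }, 0)
  best <- (2:8)[which.max(counts)]
  got <- auto_min_samples(net, rec, eps, search_range = 2:8)
  expect_equal(as.integer(got), best)
  expect_equal(unname(attr(got, "counts")), counts)
  expect_equal(best, 4L)  # 3-bead side clump stops clustering at 4

  expect_error(auto_min_samples(net, rec, eps, search_range = integer(0)),
               "empty")
})

test_that("threshold subgraphs equal brute-force components", {
  g <- cell_graph(data.frame(
    ci = c("a", "b", "c", "d", "e"),
    cj = c("b", "c", "d", "e", "a"),
    w = c(9, 9, 2, 9, 1)))
  # theta 1: single component of all five cells
  expect_length(threshold_subgraphs(g, 1), 1)
  # theta 7: a-b-c stay, d-e stays, plus nothing else
  comps <- threshold_subgraphs(g, 7)
  expect_equal(unname(sort(vapply(comps, length, 0L),
                           decreasing = TRUE)[1:2]), c(3L, 2L))
  expect_setequal(comps[[1]], c("a", "b", "c"))
  # theta above max: all singletons
  expect_true(all(vapply(threshold_subgraphs(g, 10), length, 0L) == 1))

  # random fixture vs igraph-free union-find oracle
  withr::local_seed(46)
  ids <- sprintf("v%02d", 1:20)
  e <- data.frame(ci = sample(ids, 40, TRUE), cj = sample(ids, 40, TRUE),
                  w = sample(1:8, 40, TRUE))
  e <- e[e$ci != e$cj, ]
  e <- e[!duplicated(paste(pmin(e$ci, e$cj), pmax(e$ci, e$cj))), ]
  g2 <- cell_graph(e, cells = ids)
  for (th in c(2, 5)) {
    comps <- threshold_subgraphs(g2, th)
    # union-find oracle
    parent <- setNames(ids, ids)
    find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    keep <- e[e$w >= th, ]
    for (r in seq_len(nrow(keep)))
      parent[[find(keep$ci[r])]] <- find(keep$cj[r])
    roots <- vapply(ids, find, "")
    oracle <- split(ids, roots)
    expect_setequal(unname(lapply(comps, sort)), unname(lapply(oracle, sort)))
  }
})

test_that("threshold partitions refine as theta grows", {
  withr::local_seed(47)
  ids <- sprintf("v%02d", 1:25)
  e <- data.frame(ci = sample(ids, 60, TRUE), cj = sample(ids, 60, TRUE),
                  w = sample(1:6, 60, TRUE))
  e <- e[e$ci != e$cj, ]
  e <- e[!duplicated(paste(pmin(e$ci, e$cj), pmax(e$ci, e$cj))), ]
  g <- cell_graph(e, cells = ids)
  coarse <- threshold_subgraphs(g, 1)
  fine <- threshold_subgraphs(g, 4)
  # every high-threshold component is inside one low-threshold component
  for (cf in fine) {
    holders <- vapply(coarse, function(cc) all(cf %in% cc), TRUE)
    expect_equal(sum(holders), 1L)
  }
})

test_that("subgraph enrichment adds only in-component lower-weight edges", {
  g <- cell_graph(data.frame(
    ci = c("a", "b", "a", "c", "d"),
    cj = c("b", "c", "c", "d", "e"),
    w = c(7, 7, 3, 2, 9)))
  comp <- c("a", "b", "c")
  enriched <- enrich_subgraph(comp, g, theta2 = 2)
  # the weight-3 a-c edge appears; edges touching d or e never do
  expect_true(any(enriched$edges$ci == "a" & enriched$edges$cj == "c"))
  expect_false(any(c(enriched$edges$ci, enriched$edges$cj) %in% c("d", "e")))
  # theta2 = theta1 reduces to the thresholded component
  same <- enrich_subgraph(comp, g, theta2 = 7)
  expect_setequal(paste(same$edges$ci, same$edges$cj), c("a b", "b c"))
  # baseline rule: theta2 = 1 requires the explicit override
  expect_error(enrich_subgraph(comp, g, theta2 = 1), "theta2")
  expect_silent(enrich_subgraph(comp, g, theta2 = 1, allow_theta2_1 = TRUE))
})

test_that("iterative refinement runs rounds and records provenance", {
  sim <- simulate_network(sim_config(n_cells = 150, n_beads = 300,
                                     diameter = 800,
                                     powerlaw_exponent = 1.2,
                                     rounds_max = 200, noise_ratio = 0.2),
                          seed = 48)
  cfg <- strnd_config(walks_per_node = 5, walk_length = 10, dim = 16,
                      epochs = 2, layout_epochs = 60)
  res <- iterative_refine(sim$network, cfg, rounds = 2, min_samples = 3,
                          seed = 49, verbose = FALSE)
  expect_s3_class(res$reconstruction, "reconstruction")
  expect_lte(nrow(res$network$edges), nrow(sim$network$edges))
  expect_equal(res$rounds[[1]]$round, 1)
  expect_true(res$rounds[[2]]$edges_before <= res$rounds[[1]]$edges_after)
})
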