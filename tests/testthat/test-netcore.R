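# Network data model, I/O, initial filtering, projection, degree
# statistics, distance profile, downsampling.

test_that("edge list reading collapses duplicates and rejects bad rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cell_barcode\tbead_barcode\tumi",
               "A\tB\t2", "A\tB\t3", "C\tB\t1"), f)
  net <- read_edgelist(f, verbose = FALSE)
  expect_equal(nrow(net$edges), 2)
  ab <- net$edges[net$edges$cell == "A", ]
  expect_equal(ab$umi, 5)

  # empty file -> empty network
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("cell_barcode\tbead_barcode\tumi", f2)
  empty <- read_edgelist(f2, verbose = FALSE)
  expect_equal(nrow(empty$edges), 0)
  expect_length(empty$cells, 0)

  # 10 rows, 2 malformed -> 8 edges + warning
  f3 <- withr::local_tempfile(fileext = ".tsv")
  rows <- sprintf("C%d\tB%d\t%d", 1:10, 101:110, c(1:4, -1, 6:9, NA))
  writeLines(c("cell_barcode\tbead_barcode\tumi", rows), f3)
  expect_warning(net3 <- read_edgelist(f3, verbose = FALSE), "malformed")
  expect_equal(nrow(net3$edges), 8)

  # missing column is fatal and names it
  expect_error(read_edgelist(f, columns = c("nope", "bead_barcode", "umi"),
                             verbose = FALSE),
               "missing column 'nope'")
})

test_that("edge list round-trips through write_edgelist", {
  net <- random_net(6, 10, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edgelist(net, f)
  back <- read_edgelist(f, verbose = FALSE)
  o1 <- order(back$edges$cell, back$edges$bead)
  o2 <- order(net$edges$cell, net$edges$bead)
  expect_equal(back$edges[o1, ], net$edges[o2, ], ignore_attr = TRUE)
})

test_that("bead UMI filtering removes beads by summed count only", {
  net <- bead_network(data.frame(
    cell = c("c1", "c2", "c3"), bead = c("b1", "b1", "b2"),
    umi = c(400, 200, 100)))
  out <- filter_bead_umi(net, 500, verbose = FALSE)
  expect_false("b1" %in% out$beads)       # 600 > 500
  expect_true("b2" %in% out$beads)
  expect_equal(sort(out$cells), c("c1", "c2", "c3"))  # cells never removed

  expect_equal(filter_bead_umi(net, Inf, verbose = FALSE)$edges, net$edges)

  # brute-force oracle on a random fixture at the 80th percentile
  big <- random_net(20, 50, p = 0.3, seed = 7)
  totals <- tapply(big$edges$umi, big$edges$bead, sum)
  thr <- unname(quantile(totals, 0.8))
  out2 <- filter_bead_umi(big, thr, verbose = FALSE)
  survivors <- names(totals)[totals <= thr]
  expect_setequal(intersect(out2$beads, names(totals)), survivors)
})

test_that("singleton-bead removal drops exactly degree-1 beads", {
  net <- bead_network(data.frame(
    cell = c("c1", "c1", "c2", "c3"),
    bead = c("b1", "b2", "b2", "b3"), umi = 1))
  out <- drop_singleton_beads(net, verbose = FALSE)
  expect_setequal(out$beads, "b2")
  expect_equal(nrow(out$edges), 2)

  # all beads degree >= 2 -> unchanged
  net2 <- bead_network(data.frame(
    cell = c("c1", "c2", "c1", "c2"), bead = c("b1", "b1", "b2", "b2"),
    umi = 1))
  expect_equal(drop_singleton_beads(net2, verbose = FALSE)$edges, net2$edges)

  # star: one cell, 10 degree-1 beads -> nothing left
  star <- bead_network(data.frame(
    cell = "hub", bead = sprintf("b%02d", 1:10), umi = 1))
  expect_equal(nrow(drop_singleton_beads(star, verbose = FALSE)$edges), 0)
})

test_that("unipartite projection counts shared beads (brute-force oracle)", {
  net <- bead_network(data.frame(cell = c("A", "B"), bead = "X", umi = 1))
  g <- project_unipartite(net)
  expect_equal(g$edges$w, 1)
  expect_equal(sort(c(g$edges$ci, g$edges$cj)), c("A", "B"))

  none <- bead_network(data.frame(cell = c("A", "B"), bead = c("X", "Y"),
                                  umi = 1))
  expect_equal(nrow(project_unipartite(none)$edges), 0)

  for (seed in 1:5) {
    net <- random_net(20, 30, p = 0.15, seed = seed)
    g <- project_unipartite(net)
    expect_equal(g$edges, brute_projection(net), ignore_attr = TRUE)
  }
})

test_that("degree histograms match brute-force adjacency counting", {
  net <- bead_network(data.frame(
    cell = c("c1", "c1", "c2", "c2", "c3", "c3", "c3", "c3"),
    bead = sprintf("b%d", c(1, 2, 3, 4, 5, 6, 7, 8)), umi = 1))
  h <- degree_histogram(net, "cell")
  expect_equal(h$count[h$degree == 2], 2)
  expect_equal(h$count[h$degree == 4], 1)
  expect_equal(attr(h, "stats")$mean, 8 / 3)

  rnet <- random_net(15, 25, seed = 11)
  h2 <- degree_histogram(rnet, "bead")
  brute <- table(table(factor(rnet$edges$bead, levels = rnet$beads)))
  expect_equal(setNames(h2$count, h2$degree),
               setNames(as.integer(brute), names(brute)))
  # counts sum to the number of nodes of the class
  expect_equal(sum(h2$count), length(rnet$beads))

  expect_error(degree_histogram(rnet, "nucleus"))
})

test_that("edge distance profile equals brute-force pair enumeration", {
  p <- random_points(30, extent = 10, seed = 5)
  # connect each point to its nearest neighbor only
  nn <- brute_knn(p, 1)
  ids <- sort(rownames(p))
  e <- data.frame(ci = ids, cj = ids[nn[, 1]], w = 1)
  e <- e[e$ci < e$cj, ]
  e <- e[!duplicated(paste(e$ci, e$cj)), ]
  g <- cell_graph(e, cells = ids)
  bw <- 1
  prof <- edge_distance_profile(g, p, bin_width = bw)
  # brute force
  D <- as.matrix(dist(unclass(p)[ids, ]))
  pair_d <- D[upper.tri(D)]
  edge_d <- D[cbind(match(e$ci, ids), match(e$cj, ids))]
  for (b in seq_len(nrow(prof))) {
    inbin <- function(d) sum(d >= prof$lower[b] & d < prof$upper[b])
    expect_equal(prof$possible[b], inbin(pair_d))
    expect_equal(prof$observed[b], inbin(edge_d))
  }
  # short-range bins elevated for a nearest-neighbor graph
  nz <- prof[prof$possible > 0, ]
  expect_gt(mean(nz$frequency[1:3]), mean(tail(nz$frequency, 3)))

  # complete graph -> frequency 1 in every non-empty bin
  allpairs <- t(combn(ids, 2))
  gc <- cell_graph(data.frame(ci = allpairs[, 1], cj = allpairs[, 2], w = 1))
  pc <- edge_distance_profile(gc, p, bin_width = 2)
  nz <- pc[pc$possible > 0, ]
  expect_true(all(nz$frequency == 1))

  # no edges -> all zero
  g0 <- cell_graph(data.frame(ci = character(), cj = character(),
                              w = numeric()), cells = ids)
  expect_true(all(edge_distance_profile(g0, p, 2)$frequency == 0))

  expect_error(edge_distance_profile(g, p[1, , drop = FALSE], 1),
               "at least 2")
})

test_that("edge distance profile is invariant under rotation/translation", {
  p <- random_points(40, seed = 9)
  ids <- sort(rownames(p))
  nn <- brute_knn(p, 2)
  e <- unique(data.frame(ci = pmin(rep(ids, 2), ids[as.vector(nn)]),
                         cj = pmax(rep(ids, 2), ids[as.vector(nn)]), w = 1))
  g <- cell_graph(e)
  prof1 <- edge_distance_profile(g, p, bin_width = 5)
  p2 <- similarity_transform(p, scale = 1, seed = 2)  # rigid motion only
  prof2 <- edge_distance_profile(g, p2, bin_width = 5)
  # break vectors can differ in length (they stretch to the bounding-box
  # diagonal); frequencies must agree bin-by-bin and be zero beyond
  n <- min(nrow(prof1), nrow(prof2))
  expect_equal(prof1$frequency[1:n], prof2$frequency[1:n], tolerance = 1e-12)
  expect_true(all(prof1$frequency[-(1:n)] == 0))
  expect_true(all(prof2$frequency[-(1:n)] == 0))
})

test_that("downsampling reaches the target exactly and reproducibly", {
  net <- random_net(15, 30, p = 0.3, umi_max = 6, seed = 13)

  expect_equal(downsample(net, "edges", nrow(net$edges), seed = 1)$edges,
               net$edges)
  expect_equal(nrow(downsample(net, "beads", 0, seed = 1)$edges), 0)

  half <- floor(sum(net$edges$umi) / 2)
  ds <- downsample(net, "umis", half, seed = 4)
  expect_equal(sum(ds$edges$umi), half)            # exact conservation
  expect_true(all(ds$edges$umi >= 1))

  # bit-reproducible under a fixed seed
  expect_identical(downsample(net, "umis", half, seed = 4),
                   downsample(net, "umis", half, seed = 4))
  expect_identical(downsample(net, "beads", 10, seed = 2),
                   downsample(net, "beads", 10, seed = 2))

  expect_error(downsample(net, "cells", 1000), "exceeds")
})

test_that("filtering operations are monotone (outputs subset inputs)", {
  for (seed in 1:3) {
    net <- random_net(12, 20, p = 0.25, seed = seed)
    for (out in list(filter_bead_umi(net, 6, verbose = FALSE),
                     drop_singleton_beads(net, verbose = FALSE),
                     downsample(net, "edges", 10, seed = seed))) {
      expect_true(all(out$cells %in% net$cells))
      expect_true(all(out$beads %in% net$beads))
      key <- function(n) paste(n$edges$cell, n$edges$bead)
      expect_true(all(key(out) %in% key(net)))
    }
  }
})

test_that("network invariants are enforced by the constructor", {
  expect_error(bead_network(data.frame(cell = "a", bead = "a", umi = 1)),
               "disjoint")
  expect_error(bead_network(data.frame(cell = "a", bead = "b", umi = 0)),
               "umi")
  # duplicates collapse by summation rather than duplication
  net <- bead_network(data.frame(cell = c("a", "a"), bead = c("b", "b"),
                                 umi = c(2, 3)))
  expect_equal(net$edges$umi, 5)
})
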