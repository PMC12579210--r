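# Ground-truthed synthetic data: the diffusion-tagging network simulator
# and the image-colored contact-tessellation network.

#' Simulation configuration
#'
#' Defines the study conditions for a simulated tagging network: beads and
#' cells uniform at random across a disc-shaped tissue (3 mm diameter by
#' default), each bead performing a power-law-distributed number of tagging
#' rounds, each round tagging one cell with probability proportional to the
#' Fickian concentration at the bead-cell distance, and a fraction of edges
#' replaced by fully random cell-bead pairs.
#'
#' @param n_cells,n_beads node counts.
#' @param diameter disc diameter, micrometers.
#' @param D,t diffusion coefficient (um^2/s) and diffusion time (s).
#' @param powerlaw_exponent,rounds_max discrete power law p(k) ~ k^-gamma on
#'   1..rounds_max for per-bead tagging rounds.
#' @param noise_ratio fraction of edges replaced by uniform random pairs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cells = 4000, n_beads = 8000, diameter = 3000,
                       D = 26, t = 480, powerlaw_exponent = 1.2,
                       rounds_max = 1000, noise_ratio = 0.1) {
  stopifnot(n_cells >= 1, n_beads >= 1, diameter > 0, D > 0, t > 0,
            powerlaw_exponent > 0, rounds_max >= 1,
            noise_ratio >= 0, noise_ratio <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a diffusion-tagging cell-bead network with ground truth
#'
#' Nodes are placed uniformly in the disc. Per bead, the number of tagging
#' rounds is drawn from the truncated discrete power law; each round tags
#' one cell with categorical probability proportional to
#' exp(-d^2 / (4 D t)) over all cells (cells beyond 6 sqrt(4 D t), where
#' the weight is below ~1e-8 of the peak, are pruned for speed). Each round
#' contributes one UMI; repeated tagging of the same pair increments the
#' edge's UMI count. Finally `floor(noise_ratio * n_edges)` distinct edges
#' are replaced by uniformly random cell-bead pairs (one UMI each); a
#' random pair colliding with an existing edge merges into it, and the
#' merged edge is labeled by its majority UMI mass (noise on ties).
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed; fixed seed reproduces the network exactly.
#' @return list with `network` (a [bead_network()]) and `truth` (a
#'   `sim_truth`: true `positions` [point_map()] in micrometers, per-edge
#'   `labels` (`"spatial"`/`"noise"`, aligned with `network$edges` rows),
#'   and the `config` echo with the seed).
#' @export
simulate_network <- function(cfg = sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  R <- cfg$diameter / 2
  sig2 <- 4 * cfg$D * cfg$t                  # squared diffusion length scale
  if (sqrt(sig2) > 2 * R)
    warning("diffusion length exceeds the disc; edge lengths are ",
            "boundary-dominated")
  with_seed(seed, {
    cell_ids <- sprintf("C%05d", seq_len(cfg$n_cells))
    bead_ids <- sprintf("B%05d", seq_len(cfg$n_beads))
    cells <- runif_disc(cfg$n_cells, R)
    beads <- runif_disc(cfg$n_beads, R)
    rounds <- sample_powerlaw(cfg$n_beads, cfg$powerlaw_exponent,
                              cfg$rounds_max)
    cutoff2 <- (6 * sqrt(sig2))^2
    ev_bead <- rep.int(seq_len(cfg$n_beads), rounds)
    ev_cell <- integer(length(ev_bead))
    pos <- 1L
    for (b in seq_len(cfg$n_beads)) {
      k <- rounds[b]
      d2 <- (cells[, 1] - beads[b, 1])^2 + (cells[, 2] - beads[b, 2])^2
      near <- which(d2 <= cutoff2)
      if (!length(near)) near <- which.min(d2)
      wgt <- exp(-d2[near] / sig2)
      picks <- if (length(near) == 1L) rep.int(near, k)
               else near[sample.int(length(near), k, replace = TRUE,
                                    prob = wgt)]
      ev_cell[pos:(pos + k - 1L)] <- picks
      pos <- pos + k
    }
    key <- (as.double(ev_cell) - 1) * cfg$n_beads + as.double(ev_bead)
    agg <- rowsum(rep(1, length(key)), key)
    ukey <- as.double(rownames(agg))
    e_cell <- as.integer((ukey - 1) %/% cfg$n_beads) + 1L
    e_bead <- as.integer((ukey - 1) %% cfg$n_beads) + 1L
    e_umi <- as.numeric(agg[, 1])
    label <- rep("spatial", length(ukey))

    n_noise <- floor(cfg$noise_ratio * length(ukey))
    if (n_noise > 0) {
      drop <- sample.int(length(ukey), n_noise)
      keep <- setdiff(seq_along(ukey), drop)
      e_cell <- e_cell[keep]; e_bead <- e_bead[keep]
      e_umi <- e_umi[keep]; label <- label[keep]
      r_cell <- sample.int(cfg$n_cells, n_noise, replace = TRUE)
      r_bead <- sample.int(cfg$n_beads, n_noise, replace = TRUE)
      e_cell <- c(e_cell, r_cell); e_bead <- c(e_bead, r_bead)
      e_umi <- c(e_umi, rep(1, n_noise))
      label <- c(label, rep("noise", n_noise))
      # collapse collisions (including noise-noise duplicates)
      key2 <- (as.double(e_cell) - 1) * cfg$n_beads + as.double(e_bead)
      if (anyDuplicated(key2)) {
        umi_s <- rowsum(ifelse(label == "spatial", e_umi, 0), key2)
        umi_n <- rowsum(ifelse(label == "noise", e_umi, 0), key2)
        ukey2 <- as.double(rownames(umi_s))
        e_cell <- as.integer((ukey2 - 1) %/% cfg$n_beads) + 1L
        e_bead <- as.integer((ukey2 - 1) %% cfg$n_beads) + 1L
        e_umi <- as.numeric(umi_s[, 1] + umi_n[, 1])
        label <- ifelse(umi_s[, 1] > umi_n[, 1], "spatial", "noise")
      }
    }
    edges <- data.frame(cell = cell_ids[e_cell], bead = bead_ids[e_bead],
                        umi = e_umi)
    o <- order(edges$cell, edges$bead)
    edges <- edges[o, , drop = FALSE]
    label <- label[o]
    net <- bead_network(edges, cells = cell_ids, beads = bead_ids)
    pos_all <- point_map(rbind(cells, beads),
                         ids = c(cell_ids, bead_ids), units = "um")
    truth <- structure(
      list(positions = pos_all,
           labels = setNames(label, paste(edges$cell, edges$bead)),
           config = c(unclass(cfg), list(seed = seed))),
      class = "sim_truth")
    list(network = net, truth = truth)
  })
}

runif_disc <- function(n, R) {
  r <- R * sqrt(runif(n))
  a <- runif(n, 0, 2 * pi)
  cbind(r * cos(a), r * sin(a))
}

sample_powerlaw <- function(n, gamma, kmax) {
  k <- seq_len(kmax)
  p <- k^(-gamma)
  sample.int(kmax, n, replace = TRUE, prob = p / sum(p))
}

#' Synthetic contact-tessellation network over an image
#'
#' The idealized demonstration network: points are placed uniformly at
#' random over a raster image, colored by the pixel under them, and
#' connected to their contact neighbors - pairs whose surrounding regions
#' touch, i.e. the adjacency of the tessellation generated by the points
#' (computed by the exact empty-circumcircle edge test restricted to
#' nearest-neighbor candidates). Reconstructing this network from topology
#' alone and recovering the image is the baseline check that a spatial
#' network's structure suffices to recover its geometry.
#'
#' @param n_points number of points (>= 4).
#' @param image raster: numeric matrix (grayscale) or h x w x 3 array (RGB)
#'   with values in `[0, 1]`, or a PNG file path (read via the `png`
#'   package), or `NULL` for the built-in two-arm helix test pattern.
#' @param seed RNG seed.
#' @param knn_candidates neighbor candidates per point for the tessellation
#'   edge test.
#' @return list with `graph` (a [cell_graph()], unit weights), `positions`
#'   (true [point_map()], pixel units), `colors` (named hex vector).
#' @export
image_network <- function(n_points, image = NULL, seed = 1,
                          knn_candidates = 24) {
  stopifnot(n_points >= 4)
  img <- load_raster(image)
  h <- dim(img)[1]; w <- dim(img)[2]
  with_seed(seed, {
    ids <- sprintf("P%05d", seq_len(n_points))
    xy <- cbind(runif(n_points, 0, w), runif(n_points, 0, h))
    k <- min(knn_candidates, n_points - 1)
    nn <- cpp_knn(xy, k)
    E <- cpp_delaunay_edges(xy, nn)
    g <- cell_graph(data.frame(ci = ids[E[, 1]], cj = ids[E[, 2]], w = 1),
                    cells = ids)
    px <- pmin(pmax(ceiling(xy[, 1]), 1), w)
    py <- pmin(pmax(ceiling(h - xy[, 2]), 1), h)   # y up, rows top-down
    cols <- vapply(seq_len(n_points), function(i) {
      if (length(dim(img)) == 3)
        grDevices::rgb(img[py[i], px[i], 1], img[py[i], px[i], 2],
                       img[py[i], px[i], 3])
      else grDevices::gray(img[py[i], px[i]])
    }, "")
    list(graph = g, positions = point_map(xy, ids = ids, units = "um"),
         colors = setNames(cols, ids))
  })
}

load_raster <- function(image) {
  if (is.null(image)) return(helix_image())
  if (is.character(image)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG files requires the 'png' package")
    return(png::readPNG(image)[, , 1:3, drop = FALSE])
  }
  stopifnot(is.numeric(image))
  image
}

#' Built-in test pattern: a stylized double-helix on a light background
#'
#' Generated procedurally (no image file shipped): two sinusoidal strands
#' in contrasting colors with rungs, giving distinct hues across the field
#' so both global orientation and local structure are visible after
#' reconstruction.
#'
#' @param width,height raster size in pixels.
#' @return h x w x 3 array in `[0, 1]`.
#' @export
helix_image <- function(width = 240, height = 160) {
  img <- array(0.94, dim = c(height, width, 3))
  xs <- seq_len(width)
  phase <- 2 * pi * xs / (width / 2.2)
  y1 <- height / 2 + height * 0.3 * sin(phase)
  y2 <- height / 2 + height * 0.3 * sin(phase + pi)
  paint <- function(img, x, y, col, rad = 6) {
    y0 <- max(1, round(y - rad)); y1_ <- min(height, round(y + rad))
    if (y0 > y1_) return(img)
    for (yy in y0:y1_) img[yy, x, ] <- col
    img
  }
  for (i in xs) {
    img <- paint(img, i, y1[i], c(0.85, 0.15, 0.25))
    img <- paint(img, i, y2[i], c(0.10, 0.35, 0.80))
    if (i %% 16 < 2) {  # rungs
      lo <- min(y1[i], y2[i]); hi <- max(y1[i], y2[i])
      yy <- round(seq(lo, hi, length.out = 20))
      yy <- yy[yy >= 1 & yy <= height]
      for (y in yy) img[y, i, ] <- c(0.2, 0.65, 0.3)
    }
  }
  # horizontal hue ramp in the background so left/right is identifiable
  bg <- img[, , 1] == 0.94 & img[, , 2] == 0.94 & img[, , 3] == 0.94
  ramp <- matrix(rep((xs - 1) / (width - 1), each = height), height, width)
  img[, , 1][bg] <- 0.80 + 0.15 * ramp[bg]
  img[, , 3][bg] <- 0.95 - 0.25 * ramp[bg]
  img
}

#' Total-variation divergence between two degree histograms
#'
#' Compares a simulated degree distribution against an empirical target:
#' half the L1 distance between the two distributions (0 for identical, 1
#' for disjoint supports), over the union of supports.
#'
#' @param hist_a,hist_b [degree_histogram()] objects (or data.frames with
#'   `degree` and `count`), over the same node class.
#' @return divergence in `[0, 1]`.
#' @export
degree_emulation_check <- function(hist_a, hist_b) {
  ca <- attr(hist_a, "node_class"); cb <- attr(hist_b, "node_class")
  if (!is.null(ca) && !is.null(cb) && !identical(ca, cb))
    stop("histograms are over different node classes")
  p <- tapply(hist_a$count, hist_a$degree, sum)
  q <- tapply(hist_b$count, hist_b$degree, sum)
  supp <- sort(unique(as.numeric(c(names(p), names(q)))))
  pv <- setNames(numeric(length(supp)), supp)
  qv <- pv
  pv[names(p)] <- p / sum(p)
  qv[names(q)] <- q / sum(q)
  sum(abs(pv - qv)) / 2
}
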