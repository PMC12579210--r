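# Bipartite cell-bead network: data model, I/O, initial filtering,
# degree statistics, downsampling.

#' Construct a bipartite cell-bead network
#'
#' Cells and beads are two disjoint node classes; an edge is a UMI-supported
#' tagging event between one cell and one bead. Duplicate (cell, bead) rows
#' are collapsed by summing their UMI counts, so multiplicity is always
#' carried by `umi`, never by duplicated edges.
#'
#' @param edges data.frame with columns `cell`, `bead`, `umi` (positive).
#' @param cells,beads optional node id vectors; defaults to the ids present
#'   in `edges`. Extra isolated nodes may be listed.
#' @return a `bead_network` object.
#' @export
bead_network <- function(edges, cells = NULL, beads = NULL) {
  stopifnot(all(c("cell", "bead", "umi") %in% names(edges)))
  edges$cell <- as.character(edges$cell)
  edges$bead <- as.character(edges$bead)
  edges$umi <- as.numeric(edges$umi)
  if (nrow(edges) > 0 && any(!is.finite(edges$umi) | edges$umi < 1))
    stop("umi counts must be finite and >= 1")
  if (nrow(edges) > 0) {
    key <- paste(edges$cell, edges$bead, sep = "\r")
    if (anyDuplicated(key)) {
      umi <- rowsum(edges$umi, key)
      first <- !duplicated(key)
      edges <- edges[first, c("cell", "bead", "umi")]
      edges$umi <- umi[match(paste(edges$cell, edges$bead, sep = "\r"),
                             rownames(umi)), 1]
    }
  }
  cells <- sort(unique(c(as.character(cells %||% character()), edges$cell)))
  beads <- sort(unique(c(as.character(beads %||% character()), edges$bead)))
  overlap <- intersect(cells, beads)
  if (length(overlap))
    stop("node classes must be disjoint; shared ids e.g. ", overlap[1])
  rownames(edges) <- NULL
  structure(list(edges = edges[c("cell", "bead", "umi")],
                 cells = cells, beads = beads),
            class = "bead_network")
}

#' @export
print.bead_network <- function(x, ...) {
  cat(sprintf(
    "bead_network: %d cells, %d beads, %d edges, %.0f total UMIs\n",
    length(x$cells), length(x$beads), nrow(x$edges), sum(x$edges$umi)))
  invisible(x)
}

#' Read a cell-bead edge list from delimited text
#'
#' Columns may be addressed by name or index; the default dialect is a
#' tab-separated file with header columns `cell_barcode`, `bead_barcode`,
#' `umi`. Barcodes are opaque strings and are never validated against any
#' chemistry. Duplicate rows are collapsed by summing UMIs; rows with a
#' missing or non-positive count are rejected with a warning.
#'
#' @param path file path.
#' @param columns length-3 vector (name or index) for the cell-barcode,
#'   bead-barcode and UMI-count columns.
#' @param sep field separator (passed to [data.table::fread()]).
#' @param verbose log accepted/rejected row counts.
#' @param ... further arguments to [data.table::fread()].
#' @return a [bead_network()].
#' @export
read_edgelist <- function(path,
                          columns = c("cell_barcode", "bead_barcode", "umi"),
                          sep = "\t", verbose = TRUE, ...) {
  dt <- data.table::fread(path, sep = sep, data.table = FALSE, ...)
  if (nrow(dt) == 0)
    return(bead_network(data.frame(cell = character(), bead = character(),
                                   umi = numeric())))
  cols <- resolve_columns(dt, columns, c("cell_barcode", "bead_barcode", "umi"))
  raw <- data.frame(cell = as.character(dt[[cols[1]]]),
                    bead = as.character(dt[[cols[2]]]),
                    umi = suppressWarnings(as.numeric(dt[[cols[3]]])))
  bad <- !is.finite(raw$umi) | raw$umi < 1 | is.na(raw$cell) | is.na(raw$bead) |
    raw$cell == "" | raw$bead == ""
  if (any(bad))
    warning(sum(bad), " malformed row(s) rejected (missing barcode or ",
            "non-positive count)")
  net <- bead_network(raw[!bad, , drop = FALSE])
  if (verbose)
    message(sprintf("read_edgelist: %d rows -> %d accepted -> %d edges",
                    nrow(raw), sum(!bad), nrow(net$edges)))
  net
}

#' Write a network as a delimited edge list
#'
#' The edge triples plus node lists form a lossless archive of the network;
#' isolated nodes are preserved through the optional sidecar files.
#'
#' @param net a [bead_network()].
#' @param path output edge-list path (TSV with header).
#' @param nodes_sidecar write `<path>.cells` / `<path>.beads` node lists so
#'   isolated nodes survive a round trip.
#' @export
write_edgelist <- function(net, path, nodes_sidecar = FALSE) {
  data.table::fwrite(
    data.frame(cell_barcode = net$edges$cell, bead_barcode = net$edges$bead,
               umi = net$edges$umi),
    path, sep = "\t")
  if (nodes_sidecar) {
    writeLines(net$cells, paste0(path, ".cells"))
    writeLines(net$beads, paste0(path, ".beads"))
  }
  invisible(path)
}

#' Remove beads whose total UMI count exceeds a threshold
#'
#' High-UMI beads reflect non-informative noise rather than local tagging;
#' the thresholds used for the published samples were chosen per sample from
#' the bead-UMI count distribution, slightly above where it departs from its
#' power-law-like appearance (1500, 800 and 500 for the tonsil, embryonic
#' brain and hippocampus networks; see [bead_umi_presets]). The threshold is
#' always a user decision - nothing is auto-applied.
#'
#' @param net a [bead_network()].
#' @param max_total_umi beads whose UMI sum exceeds this are dropped with all
#'   their edges. `Inf` leaves the network unchanged. Cells are never removed
#'   here.
#' @param verbose log the stage counts.
#' @return filtered [bead_network()].
#' @export
filter_bead_umi <- function(net, max_total_umi, verbose = TRUE) {
  stopifnot(max_total_umi >= 1)
  before <- net_counts(net)
  totals <- rowsum(net$edges$umi, net$edges$bead)
  bad <- rownames(totals)[totals[, 1] > max_total_umi]
  out <- net
  out$edges <- net$edges[!(net$edges$bead %in% bad), , drop = FALSE]
  out$beads <- setdiff(net$beads, bad)
  rownames(out$edges) <- NULL
  log_stage("filter_bead_umi", before, net_counts(out), verbose)
  out
}

#' Per-sample bead-UMI threshold presets
#'
#' Upper bead-UMI thresholds chosen for the three published sample networks.
#' @format named numeric vector.
#' @export
bead_umi_presets <- c(tonsil = 1500, embryonic_brain = 800, hippocampus = 500)

#' Suggest a bead-UMI threshold from the count distribution (knee heuristic)
#'
#' Fits the power-law-like initial slope of the bead-UMI survival curve on
#' log-log axes (over the lower `fit_quantile` of totals) and returns the
#' smallest total where the observed curve falls below the fitted line by
#' `factor`. A convenience for eyeballing thresholds; never applied
#' automatically.
#'
#' @param net a [bead_network()].
#' @param fit_quantile quantile of bead totals used to fit the reference
#'   slope.
#' @param factor departure factor (in survival probability) that defines the
#'   knee.
#' @return suggested threshold (numeric scalar).
#' @export
bead_umi_knee <- function(net, fit_quantile = 0.9, factor = 3) {
  totals <- sort(as.numeric(rowsum(net$edges$umi, net$edges$bead)))
  n <- length(totals)
  if (n < 10) stop("too few beads for a knee estimate")
  surv <- 1 - (seq_len(n) - 1) / n
  lo <- totals <= quantile(totals, fit_quantile) & totals > 0
  fit <- stats::lm(log(surv[lo]) ~ log(totals[lo]))
  pred <- exp(predict_lm(fit, log(totals)))
  dep <- which(totals > 1 & surv < pred / factor)
  if (!length(dep)) return(max(totals))
  totals[dep[1]]
}

# minimal predict for the internal lm above (newdata on one covariate)
predict_lm <- function(fit, x) unname(stats::coef(fit)[1] + stats::coef(fit)[2] * x)

#' Remove beads with a single edge
#'
#' Degree-1 beads carry no relative-position information. A single pass is
#' the default; `iterate = TRUE` repeats to a fixpoint (a bead can only lose
#' edges here through repeated passes when combined with other filters, so
#' iteration rarely changes anything).
#'
#' @param net a [bead_network()].
#' @param iterate repeat until no degree-1 bead remains.
#' @param verbose log stage counts.
#' @return filtered [bead_network()].
#' @export
drop_singleton_beads <- function(net, iterate = FALSE, verbose = TRUE) {
  before <- net_counts(net)
  repeat {
    deg <- table(net$edges$bead)
    single <- names(deg)[deg == 1]
    lonely <- setdiff(net$beads, net$edges$bead)  # degree 0
    drop <- c(single, lonely)
    if (!length(drop)) break
    net$edges <- net$edges[!(net$edges$bead %in% single), , drop = FALSE]
    net$beads <- setdiff(net$beads, drop)
    if (!iterate) break
  }
  rownames(net$edges) <- NULL
  log_stage("drop_singleton_beads", before, net_counts(net), verbose)
  net
}

#' Degree histogram of one node class
#'
#' Exact per-node degree counts (number of incident edges; UMI multiplicity
#' is ignored), optionally split by a grouping label such as cell type.
#' Isolated listed nodes count with degree 0.
#'
#' @param net a [bead_network()].
#' @param node_class `"cell"` or `"bead"`.
#' @param group_by optional named vector mapping every node of the class to a
#'   group label.
#' @return a `degree_histogram`: data.frame (`group`, `degree`, `count`) with
#'   per-group mean/sd in attributes.
#' @export
degree_histogram <- function(net, node_class = c("cell", "bead"),
                             group_by = NULL) {
  node_class <- match.arg(node_class)
  ids <- if (node_class == "cell") net$cells else net$beads
  end <- if (node_class == "cell") net$edges$cell else net$edges$bead
  deg <- setNames(integer(length(ids)), ids)
  tab <- table(end)
  deg[names(tab)] <- as.integer(tab)
  if (is.null(group_by)) {
    grp <- rep("all", length(ids))
  } else {
    if (!all(ids %in% names(group_by)))
      stop("group_by must label every ", node_class)
    grp <- as.character(group_by[ids])
  }
  df <- aggregate(list(count = deg), by = list(group = grp, degree = deg),
                  FUN = length)
  df <- df[order(df$group, df$degree), c("group", "degree", "count")]
  rownames(df) <- NULL
  stats <- do.call(rbind, lapply(split(deg, grp), function(d)
    data.frame(mean = mean(d), sd = if (length(d) > 1) sd(d) else NA_real_,
               n = length(d))))
  structure(df, class = c("degree_histogram", "data.frame"),
            node_class = node_class, stats = stats)
}

#' @export
print.degree_histogram <- function(x, ...) {
  st <- attr(x, "stats")
  cat(sprintf("degree_histogram (%s nodes)\n", attr(x, "node_class")))
  print.data.frame(x, ...)
  cat("mean degree:\n"); print(st)
  invisible(x)
}

#' Randomly downsample a network along one axis
#'
#' Uniform removal without replacement down to `target` beads, edges, cells,
#' or total UMIs. For `axis = "umis"` individual UMI units are removed
#' uniformly across edges (multivariate hypergeometric) and edges whose
#' count reaches zero are deleted; the surviving UMI total equals `target`
#' exactly. Node lists shrink only along the sampled axis; the other class
#' keeps all its nodes (they may become isolated).
#'
#' @param net a [bead_network()].
#' @param axis `"beads"`, `"edges"`, `"umis"` or `"cells"`.
#' @param target size to reach along `axis` (must not exceed current size).
#' @param seed RNG seed; a fixed seed reproduces the sample exactly.
#' @return downsampled [bead_network()].
#' @export
downsample <- function(net, axis = c("beads", "edges", "umis", "cells"),
                       target, seed = NULL) {
  axis <- match.arg(axis)
  current <- switch(axis,
    beads = length(net$beads), cells = length(net$cells),
    edges = nrow(net$edges), umis = sum(net$edges$umi))
  if (target > current)
    stop("target (", target, ") exceeds current ", axis, " (", current, ")")
  with_seed(seed, {
    out <- net
    if (axis == "beads") {
      keep <- sort(sample(net$beads, target))
      out$beads <- keep
      out$edges <- net$edges[net$edges$bead %in% keep, , drop = FALSE]
    } else if (axis == "cells") {
      keep <- sort(sample(net$cells, target))
      out$cells <- keep
      out$edges <- net$edges[net$edges$cell %in% keep, , drop = FALSE]
    } else if (axis == "edges") {
      keep <- sort(sample.int(nrow(net$edges), target))
      out$edges <- net$edges[keep, , drop = FALSE]
    } else {
      umi <- as.integer(net$edges$umi)
      total <- sum(umi)
      kept <- integer(length(umi))
      remaining_target <- as.integer(target)
      remaining_total <- total
      # sequential multivariate hypergeometric draw
      for (i in seq_along(umi)) {
        if (remaining_target == 0L) break
        k <- stats::rhyper(1, umi[i], remaining_total - umi[i],
                           remaining_target)
        kept[i] <- k
        remaining_target <- remaining_target - k
        remaining_total <- remaining_total - umi[i]
      }
      out$edges <- net$edges[kept > 0, , drop = FALSE]
      out$edges$umi <- as.numeric(kept[kept > 0])
    }
    rownames(out$edges) <- NULL
    out
  })
}
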