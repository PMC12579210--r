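# Internal helpers: seeded evaluation, seed ladders, point maps, logging.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. seed = NULL leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a ladder of per-replicate seeds from one master seed
#'
#' Replicated experiments draw their seeds from a deterministic arithmetic
#' ladder rather than from hidden global RNG state, so every replicate is
#' individually reproducible from the recorded master seed.
#'
#' @param seed master seed (integer).
#' @param n number of seeds to derive.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  as.integer((as.double(seed) + 1000003 * seq_len(n)) %% 2147483647L)
}

#' Construct a point map
#'
#' A point map is the package's layout container: a numeric matrix with one
#' row per node (rownames are node ids) and columns `x`, `y`, plus a units
#' tag (`"um"` for physical reference maps, `"arbitrary"` for embeddings,
#' whose scale, rotation and mirroring are not meaningful).
#'
#' @param x numeric matrix or data.frame with 2 coordinate columns.
#' @param ids node identifiers (defaults to rownames of `x`).
#' @param units `"um"` or `"arbitrary"`.
#' @return a `point_map` matrix.
#' @export
point_map <- function(x, ids = rownames(x), units = c("um", "arbitrary")) {
  units <- match.arg(units)
  m <- as.matrix(x)[, 1:2, drop = FALSE]
  storage.mode(m) <- "double"
  if (is.null(ids)) stop("point_map requires node ids (rownames)")
  if (anyDuplicated(ids)) stop("duplicate node ids in point map")
  if (!all(is.finite(m))) stop("point map coordinates must be finite")
  rownames(m) <- as.character(ids)
  colnames(m) <- c("x", "y")
  attr(m, "units") <- units
  class(m) <- c("point_map", class(m))
  m
}

pm_units <- function(p) attr(p, "units") %||% "arbitrary"

`%||%` <- function(a, b) if (is.null(a)) b else a

# ids present in both maps, in sorted id order (the package's documented
# tie-break order for neighbor queries).
common_ids <- function(a, b) sort(intersect(rownames(a), rownames(b)))

#' Read a reference position table
#'
#' Expects delimited text with a barcode column followed by x and y in
#' micrometers, matching the layout of the public position depositions.
#'
#' @param path file path.
#' @param columns length-3 character or integer vector naming/indexing the
#'   barcode, x and y columns.
#' @param ... passed to [data.table::fread()].
#' @return a [point_map()] in micrometers.
#' @export
read_positions <- function(path, columns = c(1L, 2L, 3L), ...) {
  dt <- data.table::fread(path, data.table = FALSE, ...)
  cols <- resolve_columns(dt, columns, c("barcode", "x", "y"))
  pm <- cbind(as.numeric(dt[[cols[2]]]), as.numeric(dt[[cols[3]]]))
  point_map(pm, ids = as.character(dt[[cols[1]]]), units = "um")
}

#' Write a position table
#' @param p a [point_map()].
#' @param path output file.
#' @export
write_positions <- function(p, path) {
  data.table::fwrite(
    data.frame(barcode = rownames(p), x = p[, 1], y = p[, 2]),
    path, sep = "\t"
  )
}

resolve_columns <- function(df, columns, roles) {
  if (length(columns) != length(roles))
    stop("expected ", length(roles), " column specifiers")
  idx <- integer(length(columns))
  for (i in seq_along(columns)) {
    ci <- columns[[i]]
    if (is.character(ci)) {
      j <- match(ci, names(df))
      if (is.na(j))
        stop("missing column '", ci, "' (role: ", roles[i],
             "); file has columns: ", paste(names(df), collapse = ", "))
      idx[i] <- j
    } else {
      j <- as.integer(ci)
      if (j < 1 || j > ncol(df))
        stop("column index ", j, " (role: ", roles[i],
             ") out of range; file has ", ncol(df), " columns")
      idx[i] <- j
    }
  }
  idx
}

# Structured stage logging: one line per filtering/processing stage with
# before/after node and edge counts, the audit trail users need to match
# per-stage counts.
log_stage <- function(stage, before, after, verbose = TRUE) {
  if (!isTRUE(verbose)) return(invisible(NULL))
  message(sprintf(
    "[%s] cells %d -> %d | beads %d -> %d | edges %d -> %d",
    stage, before["cells"], after["cells"], before["beads"], after["beads"],
    before["edges"], after["edges"]
  ))
  invisible(NULL)
}

net_counts <- function(net) {
  c(cells = length(net$cells), beads = length(net$beads),
    edges = nrow(net$edges))
}

# Cheap deterministic content hash for provenance records (not
# cryptographic): 32-bit polynomial roll over the edge triples.
net_hash <- function(net) {
  if (nrow(net$edges) == 0) return("00000000")
  ci <- match(net$edges$cell, sort(unique(net$edges$cell)))
  bi <- match(net$edges$bead, sort(unique(net$edges$bead)))
  o <- order(ci, bi)
  v <- (as.double(ci[o]) * 2654435761 + as.double(bi[o]) * 40503 +
          as.double(net$edges$umi[o])) %% 2^31
  h <- 0
  for (chunk in split(v, ceiling(seq_along(v) / 65536)))
    h <- (h * 31 + sum(chunk)) %% 2^31
  sprintf("%08x", as.integer(h))
}
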