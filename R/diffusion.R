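# Bead->partner displacement profiling and the Fickian + random-chord
# mixture model for diffusion-coefficient estimation.
#
# The physical picture: oligonucleotide barcodes released from a bead at
# time 0 spread by 2D Fickian diffusion, so the concentration around the
# bead after time t is Gaussian with variance 2Dt per axis. Tagging events
# to spatially uncorrelated locations instead look like random point pairs
# in the (disc-shaped) specimen, whose distance follows the classic disc
# line-picking (chord-length) density. A pooled histogram of bead->partner
# distances is therefore a two-component mixture from which D can be
# extracted once the experiment's diffusion time t is fixed.

#' Pooled radial displacement profile of bead-partner connections
#'
#' Every bead is placed at the origin and the relative positions of its
#' connected cells are pooled over all beads; the profile is the histogram
#' of displacement magnitudes. Edges with an unpositioned endpoint are
#' skipped and counted.
#'
#' @param net a [bead_network()].
#' @param positions [point_map()] covering the beads and cells used
#'   (reference or reconstructed coordinates; micrometers for physical
#'   fits).
#' @param bins number of bins (default 50, up to the maximum observed
#'   distance) or an explicit vector of break points.
#' @return a `radial_profile`: `breaks`, `counts`, `density` (integrates to
#'   1), `n_edges`, `n_skipped`, and the raw distances in `samples`.
#' @export
relative_profile <- function(net, positions, bins = 50) {
  pos_ids <- rownames(positions)
  ok <- net$edges$cell %in% pos_ids & net$edges$bead %in% pos_ids
  n_skipped <- sum(!ok)
  e <- net$edges[ok, , drop = FALSE]
  if (nrow(e) == 0) stop("no edge has both endpoints positioned")
  P <- unclass(positions)
  r <- sqrt(rowSums((P[e$cell, , drop = FALSE] -
                       P[e$bead, , drop = FALSE])^2))
  breaks <- if (length(bins) > 1) bins
            else seq(0, max(r) * (1 + 1e-9), length.out = bins + 1)
  counts <- tabulate(findInterval(r, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  widths <- diff(breaks)
  dens <- counts / (sum(counts) * widths)
  structure(list(breaks = breaks, counts = counts, density = dens,
                 n_edges = nrow(e), n_skipped = n_skipped, samples = r),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf(
    "radial_profile: %d edges pooled (%d skipped), range [0, %.4g], %d bins\n",
    x$n_edges, x$n_skipped, max(x$breaks), length(x$counts)))
  invisible(x)
}

#' Planar concentration of a point release under 2D Fickian diffusion
#'
#' C(r, t) = M / (4 pi D t) * exp(-r^2 / (4 D t)): the solution of Fick's
#' second law in two dimensions for an initial condition with all material
#' M concentrated at the origin (Dirac delta). Total mass is conserved:
#' the integral of C * 2 pi r dr over r >= 0 equals M.
#'
#' @param r radial distance (vector, micrometers).
#' @param t elapsed time (seconds, > 0; t = 0 is rejected because the delta
#'   initial condition has no pointwise density).
#' @param D diffusion coefficient (um^2/s, > 0).
#' @param M total material (default 1).
#' @return concentration per unit area at radius `r`.
#' @export
gaussian2d_density <- function(r, t, D, M = 1) {
  stopifnot(t > 0, D > 0)
  M / (4 * pi * D * t) * exp(-r^2 / (4 * D * t))
}

# Rayleigh-type density of the displacement *magnitude* for the same
# diffusion cloud: the planar Gaussian times the 2 pi r Jacobian,
# normalized. Integrates to 1 over r >= 0.
radial_gaussian_density <- function(r, t, D) {
  stopifnot(t > 0, D > 0)
  r / (2 * D * t) * exp(-r^2 / (4 * D * t))
}

#' Chord-length density of a disc (random line segments)
#'
#' Density of the distance between two independent uniform points in a disc
#' of radius R:
#' P(l) = (4 l / (pi R^2)) acos(l / 2R) - (2 l^2 / (pi R^3)) sqrt(1 - l^2 / 4R^2),
#' supported on `[0, 2R]` (0 outside), vanishing at both endpoints and
#' integrating to 1. Models the distance of spatially uncorrelated (noise)
#' connections across a disc-shaped specimen.
#'
#' @param l segment length (vector).
#' @param R disc radius.
#' @return density values.
#' @export
chord_pdf <- function(l, R) {
  stopifnot(R > 0)
  out <- numeric(length(l))
  ok <- l >= 0 & l <= 2 * R
  x <- l[ok]
  out[ok] <- 4 * x / (pi * R^2) * acos(x / (2 * R)) -
    2 * x^2 / (pi * R^3) * sqrt(pmax(0, 1 - x^2 / (4 * R^2)))
  out
}

#' Chord-length cumulative distribution (numerical)
#' @param l evaluation points.
#' @param R disc radius.
#' @param n_grid quadrature grid size.
#' @return CDF values in `[0, 1]`.
#' @export
chord_cdf <- function(l, R, n_grid = 4096) {
  g <- seq(0, 2 * R, length.out = n_grid)
  p <- chord_pdf(g, R)
  cdf <- cumsum((p[-1] + p[-n_grid]) / 2 * diff(g))
  cdf <- c(0, cdf) / cdf[n_grid - 1]
  f <- approxfun(g, pmin(cdf, 1), yleft = 0, yright = 1)
  f(pmin(pmax(l, 0), 2 * R))
}

#' Fit the diffusion + random-chord mixture to a radial profile
#'
#' Nonlinear least squares of the two-component distance-density model
#' against the profile's histogram density:
#' h(r) = A P(r, R) + B (r / 2Dt) exp(-r^2 / 4Dt)
#' where P is [chord_pdf()] and the second term is the diffusion component
#' with its 2D radial Jacobian (both terms are then densities in r, so A
#' and B are the mixture masses). `jacobian = FALSE` drops the Jacobian and
#' fits the planar form B exp(-r^2/4Dt) literally, appropriate when the
#' profile is a per-unit-area scatter density rather than a distance
#' histogram. t is a fixed experimental input (release + incubation time;
#' 480 s for the published protocol), never fitted jointly with D since
#' only the product Dt is identified. A multistart over a D grid guards
#' against local minima; bins are weighted by their sample counts.
#'
#' @param profile a [relative_profile()] result.
#' @param R disc radius of the specimen (micrometers).
#' @param t diffusion time in seconds (default 480).
#' @param jacobian include the 2D radial Jacobian in the diffusion term
#'   (default TRUE; see Details).
#' @param D_grid multistart grid for D (um^2/s).
#' @return a `diffusion_fit`: `D`, `A`, `B`, `t`, `R`, `residual` (weighted
#'   RSS), `fitted` (function of r), `flag` (`"ok"` or
#'   `"D_unidentifiable"`).
#' @export
fit_profile <- function(profile, R, t = 480, jacobian = TRUE,
                        D_grid = 10^seq(-1, 4, length.out = 11)) {
  stopifnot(inherits(profile, "radial_profile"), R > 0, t > 0)
  mid <- (head(profile$breaks, -1) + profile$breaks[-1]) / 2
  h <- profile$density
  w <- profile$counts
  use <- w > 0
  # all mass in the first bin: pure point release, D unidentifiable
  if (sum(profile$counts[-1]) == 0) {
    return(structure(list(D = NA_real_, A = 0, B = 1, t = t, R = R,
                          residual = 0, fitted = NULL,
                          flag = "D_unidentifiable"),
                     class = "diffusion_fit"))
  }
  if (sum(use) < 4) stop("profile too degenerate to fit")
  gterm <- function(r, D) {
    if (jacobian) radial_gaussian_density(r, t, D)
    else exp(-r^2 / (4 * D * t))
  }
  model <- function(r, A, B, D) A * chord_pdf(r, R) + B * gterm(r, D)
  df <- data.frame(mid = mid[use], h = h[use], w = w[use])
  best <- NULL
  for (D0 in D_grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        h ~ model(mid, A, B, D),
        data = df,
        start = list(A = 0.5, B = 0.5, D = D0),
        lower = c(0, 0, 1e-8),
        weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2 * df$w)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("mixture fit failed from every start")
  cf <- stats::coef(best$fit)
  structure(list(D = unname(cf["D"]), A = unname(cf["A"]),
                 B = unname(cf["B"]), t = t, R = R, residual = best$rss,
                 fitted = function(r) model(r, cf["A"], cf["B"], cf["D"]),
                 flag = "ok"),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf(
    "diffusion_fit: D = %.4g um^2/s (t = %g s fixed), A = %.3g, B = %.3g [%s]\n",
    x$D, x$t, x$A, x$B, x$flag))
  invisible(x)
}
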