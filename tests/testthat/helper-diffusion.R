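# Helpers for diffusion-profile tests.

# distances between independent uniform point pairs in a disc of radius R
runif_pairs_disc <- function(n, R) {
  r1 <- R * sqrt(runif(n)); a1 <- runif(n, 0, 2 * pi)
  r2 <- R * sqrt(runif(n)); a2 <- runif(n, 0, 2 * pi)
  sqrt((r1 * cos(a1) - r2 * cos(a2))^2 + (r1 * sin(a1) - r2 * sin(a2))^2)
}

# wrap a raw distance sample into the radial_profile container by building
# a one-bead star network at the origin
profile_from_samples <- function(r, bins = 50) {
  n <- length(r)
  ang <- seq(0, 2 * pi, length.out = n + 1)[-1]
  ids <- sprintf("c%06d", seq_len(n))
  pos <- point_map(rbind(c(0, 0), cbind(r * cos(ang), r * sin(ang))),
                   ids = c("origin", ids), units = "um")
  net <- bead_network(data.frame(cell = ids, bead = "origin", umi = 1))
  relative_profile(net, pos, bins = bins)
}
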