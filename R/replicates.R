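# Experiment orchestration: replicated metric runs and downsampling sweeps.

#' Run a stochastic task over independent seeds and summarize
#'
#' Reconstruction is stochastic, so quality metrics are reported as mean
#' and standard deviation over replicates with independent seeds (derived
#' from the master seed by [derive_seeds()] and recorded per row). A failed
#' replicate is recorded and the summary covers the successes.
#'
#' @param task function of one argument (the replicate seed) returning a
#'   named numeric vector of metrics.
#' @param n_replicates number of replicates.
#' @param seed master seed, or `seeds` to give the ladder explicitly.
#' @param seeds optional explicit integer vector (overrides `seed`).
#' @return list with `results` (data.frame: replicate, seed, one column per
#'   metric), `summary` (per-metric mean, sd - `NA` when n = 1 - and n),
#'   and `failures` (messages keyed by replicate).
#' @export
run_replicates <- function(task, n_replicates, seed = 1, seeds = NULL) {
  stopifnot(n_replicates >= 1)
  if (is.null(seeds)) seeds <- derive_seeds(seed, n_replicates)
  stopifnot(length(seeds) == n_replicates)
  rows <- list()
  failures <- list()
  for (i in seq_len(n_replicates)) {
    res <- tryCatch(task(seeds[i]), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[as.character(i)]] <- conditionMessage(res)
      next
    }
    rows[[length(rows) + 1]] <-
      cbind(data.frame(replicate = i, seed = seeds[i]),
            as.data.frame(as.list(res)))
  }
  if (!length(rows)) stop("every replicate failed; first error: ",
                          failures[[1]])
  results <- do.call(rbind, rows)
  metrics <- setdiff(names(results), c("replicate", "seed"))
  summary <- do.call(rbind, lapply(metrics, function(m) data.frame(
    metric = m, mean = mean(results[[m]]),
    sd = if (nrow(results) > 1) sd(results[[m]]) else NA_real_,
    n = nrow(results))))
  list(results = results, summary = summary, failures = failures)
}

#' Downsampling sweep: metrics across axes, targets and nested replicates
#'
#' Full factorial: each axis/target combination is downsampled
#' `n_samples` times (independent sampling seeds) and every downsampled
#' network is evaluated `n_recons` times (independent evaluation seeds),
#' separating sampling variance from reconstruction variance.
#'
#' @param net a [bead_network()].
#' @param targets named list: axis name (`"beads"`, `"edges"`, `"umis"`,
#'   `"cells"`) -> vector of target sizes.
#' @param evaluate function(net, seed) returning a named numeric metric
#'   vector (typically reconstruct + score against a fixed truth).
#' @param n_samples,n_recons nesting factors.
#' @param seed master seed.
#' @return tidy data.frame: axis, target, sample, recon, seeds, metrics.
#' @export
downsample_sweep <- function(net, targets, evaluate, n_samples = 5,
                             n_recons = 5, seed = 1) {
  combos <- do.call(rbind, lapply(names(targets), function(ax)
    data.frame(axis = ax, target = targets[[ax]])))
  rows <- list()
  cnt <- 0L
  for (ci in seq_len(nrow(combos))) {
    ax <- combos$axis[ci]; tg <- combos$target[ci]
    for (s in seq_len(n_samples)) {
      cnt <- cnt + 1L
      s_seed <- derive_seeds(seed, cnt * 2L)[cnt * 2L - 1L]
      ds <- downsample(net, axis = ax, target = tg, seed = s_seed)
      rseeds <- derive_seeds(s_seed, n_recons)
      for (r in seq_len(n_recons)) {
        met <- evaluate(ds, rseeds[r])
        rows[[length(rows) + 1]] <- cbind(
          data.frame(axis = ax, target = tg, sample = s, recon = r,
                     sample_seed = s_seed, recon_seed = rseeds[r]),
          as.data.frame(as.list(met)))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
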