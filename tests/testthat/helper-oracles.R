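# Independent oracles used across the suite. These deliberately use
# different algorithms from the package implementation.

# Equal-tailed credible bound of p2 - p1 by grid integration: both beta
# posteriors discretized at `step`, convolved to the distribution of the
# difference, quantiles read from the discrete CDF.
grid_cdif <- function(m1, t1, m2, t2, prior = c(1, 1), level = 0.95,
                      step = 1e-3) {
  br <- seq(0, 1, by = step)
  w1 <- diff(pbeta(br, m1 + prior[1], t1 - m1 + prior[2]))
  w2 <- diff(pbeta(br, m2 + prior[1], t2 - m2 + prior[2]))
  pmf <- convolve(w2, w1, type = "open")
  d <- seq(-1 + step, 1 - step, by = step)
  cdf <- cumsum(pmf)
  lo <- d[which(cdf >= (1 - level) / 2)[1]]
  hi <- d[which(cdf >= 1 - (1 - level) / 2)[1]]
  if (lo > 0) lo else if (hi < 0) hi else 0
}

# Brute-force DMR enumeration: every maximal index run [i, j] in which all
# DMCs share direction and every adjacent gap is <= window; runs with at
# least min_run members qualify. O(n^2), independent of merge_dmrs().
enumerate_dmrs <- function(pos, direction, window = 300, min_run = 4) {
  n <- length(pos)
  out <- list()
  i <- 1
  ok_pair <- function(a, b) {
    direction[a] == direction[b] && pos[b] - pos[a] <= window
  }
  while (i <= n) {
    j <- i
    while (j < n && ok_pair(j, j + 1)) j <- j + 1
    if (j - i + 1 >= min_run) {
      out[[length(out) + 1]] <- tibble::tibble(
        start = pos[i], end = pos[j] + 1L, direction = direction[i],
        n_dmcs = j - i + 1L)
    }
    i <- j + 1
  }
  dplyr::bind_rows(out)
}

# Brute-force upper Poisson tail P(X >= k) by direct summation.
pois_tail <- function(k, lambda, terms = 2000) {
  if (k <= 0) return(1)
  sum(dpois(seq.int(k, k + terms), lambda))
}

# Small simulation configs for fast unit tests.
quick_cfg <- function(...) {
  args <- utils::modifyList(
    list(genome_length = 2e6, n_canyons = 4, n_umrs = 10,
         n_latent_canyons = 6, n_latent_umrs = 8, n_genes = 100,
         n_de_genes = 70, occ_bin_width = 20, seed = 7),
    list(...))
  do.call(sim_config, args)
}

# Flat-density, noise-free config for exact geometric checks on
# occupancy tracks (no CpGs, no genes: signal is baseline + planted peaks).
flat_cfg <- function(...) {
  args <- utils::modifyList(
    list(genome_length = 1e6, n_canyons = 2, n_umrs = 2,
         n_latent_canyons = 0, n_latent_umrs = 0,
         background_cpg_rate = 0, island_cpg_rate = 0,
         shore_cpg_rate = 0, n_genes = 0, n_de_genes = 0,
         occ_noise_sd = 0, occ_bin_width = 20,
         calibrate_crossing = FALSE, seed = 5),
    list(...))
  do.call(sim_config, args)
}

# Per-planted-region best Jaccard against a set of called regions.
recovery_jaccard <- function(truth, called) {
  vapply(seq_len(nrow(truth)), function(i) {
    same <- called[called$chrom == truth$chrom[i], , drop = FALSE]
    if (nrow(same) == 0) return(0)
    max(canyonscape:::interval_jaccard(same$start, same$end,
                                       truth$start[i], truth$end[i]))
  }, numeric(1))
}
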