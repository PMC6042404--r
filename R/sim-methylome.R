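#' Simulate a per-CpG WGBS methylome with planted ground truth
#'
#' Draws per-CpG coverage from a Poisson around `coverage_mean` and
#' methylated counts from a beta-binomial whose mean follows the planted
#' landscape: `background_meth_mean` in bulk sequence, `umr_meth_mean`
#' inside planted regions, `latent_meth_mean` inside latent regions.
#' Knockout conditions reshape the landscape: `Dnmt3aKO`/`DKO` lower the
#' background by `dnmt3a_global_shift`, extend planted regions by
#' `region_extension` per side, and activate latent regions (canyon/UMR
#' expansion); `Tet1KO`/`DKO` add `tet1_flank_gain` methylation in the 2-kb
#' flanks of planted regions (flank hypermethylation after loss of TET1
#' boundary protection).
#'
#' @param genome A [simulate_genome()] result.
#' @param config A [sim_config()]; defaults to the genome's config. The
#'   `condition` field selects the genotype.
#' @param condition Optional override of `config$condition`.
#' @return A list of class `sim_methylome`: `track` (tibble
#'   `chrom, pos, meth, total, ratio`), `regions` (the condition's true
#'   hypomethylated intervals with `type` recomputed from extended length),
#'   and `condition`.
#' @export
simulate_methylome <- function(genome, config = genome$config,
                               condition = config$condition) {
  stopifnot(inherits(genome, "canyon_genome"))
  config <- validate_sim_config(config)
  if (!is.numeric(config$coverage_mean) || config$coverage_mean <= 0) {
    abort("`coverage_mean` must be > 0", class = "canyonscape_config_error")
  }
  config$condition <- condition
  config <- validate_sim_config(config)

  truth <- true_hypo_regions(genome, config)
  cond_idx <- match(condition, c("WT", "Dnmt3aKO", "Tet1KO", "DKO"))

  chroms <- genome$chrom_sizes$chrom
  track <- purrr::map(seq_along(chroms), function(i) {
    cpg <- dplyr::filter(genome$cpg, .data$chrom == chroms[i])
    mu <- cpg_meth_means(cpg$pos, chroms[i], truth, genome, config)
    set.seed(chrom_seed(config$seed, i, salt = 10L + cond_idx))
    total <- rpois(nrow(cpg), config$coverage_mean)
    meth <- rbetabinom(total, mu, config$meth_dispersion)
    tibble::tibble(chrom = chroms[i], pos = cpg$pos,
                   meth = meth, total = total,
                   ratio = compute_ratio(meth, total))
  }) |> dplyr::bind_rows()

  structure(list(track = track, regions = truth, condition = condition),
            class = "sim_methylome")
}

# Planted hypomethylated intervals realised under a genotype: latent
# regions activate and regions extend under Dnmt3a loss; class labels are
# recomputed from the realised length.
true_hypo_regions <- function(genome, config) {
  regions <- genome$regions
  ko3a <- has_dnmt3a_ko(config$condition)
  active <- regions[!regions$latent | ko3a, , drop = FALSE]
  if (ko3a && nrow(active) > 0) {
    ext <- as.integer(config$region_extension)
    active$start <- pmax(0L, active$start - ext)
    active$end <- pmin(genome$chrom_sizes$length[
      match(active$chrom, genome$chrom_sizes$chrom)], active$end + ext)
  }
  active$type <- ifelse(active$end - active$start >= 3500, "canyon", "umr")
  dplyr::arrange(active, .data$chrom, .data$start)
}

# Per-CpG mean methylation under the planted landscape for one chromosome.
cpg_meth_means <- function(pos, chrom, truth, genome, config) {
  bg <- config$background_meth_mean +
    if (has_dnmt3a_ko(config$condition)) config$dnmt3a_global_shift else 0
  mu <- rep(min(max(bg, 0), 1), length(pos))

  reg <- truth[truth$chrom == chrom, , drop = FALSE]
  all_reg <- genome$regions[genome$regions$chrom == chrom, , drop = FALSE]

  if (has_tet1_ko(config$condition) && nrow(all_reg) > 0) {
    flank <- dplyr::filter(all_reg, !.data$latent)
    if (nrow(flank) > 0) {
      in_fl <- positions_in_intervals(pos, c(flank$start - 2000L, flank$end),
                                      c(flank$start, flank$end + 2000L))
      mu[in_fl] <- pmin(1, mu[in_fl] + config$tet1_flank_gain)
    }
  }
  if (nrow(all_reg) > 0 && !has_dnmt3a_ko(config$condition)) {
    lat <- dplyr::filter(all_reg, .data$latent)
    if (nrow(lat) > 0) {
      mu[positions_in_intervals(pos, lat$start, lat$end)] <- config$latent_meth_mean
    }
  }
  if (nrow(reg) > 0) {
    mu[positions_in_intervals(pos, reg$start, reg$end)] <- config$umr_meth_mean
  }
  mu
}

# logical: is each (sorted or unsorted) position inside any [start, end)?
positions_in_intervals <- function(pos, start, end) {
  if (length(start) == 0) return(rep(FALSE, length(pos)))
  ord <- order(start)
  start <- start[ord]; end <- end[ord]
  i <- findInterval(pos, start)
  i > 0 & pos < end[pmax(i, 1)]
}

# Beta-binomial draw with mean mu and dispersion rho (rho = 0 -> binomial).
rbetabinom <- function(total, mu, rho) {
  n <- length(total)
  mu <- rep_len(mu, n)
  p <- mu
  if (rho > 0) {
    nu <- 1 / rho - 1
    mid <- mu > 0 & mu < 1
    if (any(mid)) p[mid] <- rbeta(sum(mid), mu[mid] * nu, (1 - mu[mid]) * nu)
  }
  rbinom(n, total, p)
}
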