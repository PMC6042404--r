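#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by every
#' `simulate_*()` generator. The defaults describe the study conditions the
#' package is validated against: a serum-grown mouse-ESC-like methylome with
#' high (~75%) background CpG methylation, planted under-methylated regions
#' spanning the UMR (1-3.5 kb) and canyon (>= 3.5 kb) length classes at ~30x
#' coverage, CpG-density structure with island-like stretches inside planted
#' regions, and the knockout effect directions reported for Dnmt3a and Tet1
#' loss (global hypomethylation with UMR/canyon expansion; DNMT3A1
#' height/width expansion with flank hypermethylation).
#'
#' @param genome_length Chromosome length in bp.
#' @param n_chroms Number of chromosomes.
#' @param background_cpg_rate,island_cpg_rate,shore_cpg_rate CpGs per 100 bp
#'   in bulk sequence, island-like stretches (planted regions, CpG-rich
#'   promoters), and island shores respectively.
#' @param n_canyons,n_umrs Planted under-methylated regions per class that
#'   are hypomethylated in every condition.
#' @param n_latent_canyons,n_latent_umrs Regions at intermediate methylation
#'   in WT that become hypomethylated under `Dnmt3aKO`/`DKO` (canyon/UMR
#'   expansion after loss of de novo methylation).
#' @param canyon_length_range,umr_length_range Planted lengths (bp);
#'   UMRs must lie in `[1000, 3500)`, canyons at `>= 3500`.
#' @param background_meth_mean,umr_meth_mean,latent_meth_mean Mean
#'   methylation fractions outside planted regions, inside planted regions,
#'   and inside latent regions under WT.
#' @param meth_dispersion Beta-binomial dispersion (0 = binomial).
#' @param coverage_mean Mean reads per CpG (Poisson).
#' @param condition One of `"WT"`, `"Dnmt3aKO"`, `"Tet1KO"`, `"DKO"`.
#' @param dnmt3a_global_shift Additive change of background methylation in
#'   `Dnmt3aKO`/`DKO` (negative = hypomethylation).
#' @param region_extension bp added to each side of planted regions in
#'   `Dnmt3aKO`/`DKO`.
#' @param tet1_flank_gain Methylation gain in 2-kb flanks of planted regions
#'   in `Tet1KO`/`DKO` (magnitude is a free parameter of the generator).
#' @param tet1_height_mult,tet1_width_mult DNMT3A1 edge-peak height and
#'   width multipliers in `Tet1KO`/`DKO`.
#' @param crossing_density Planted CpG density (per 100 bp) at which
#'   normalized TET1 and DNMT3A1 density-response curves cross.
#' @param calibrate_crossing When `TRUE`, the density-response midpoint is
#'   calibrated per genome so the planted crossing lands at
#'   `crossing_density`; when `FALSE`, `tet1_activation_density` is used
#'   directly.
#' @param occ_bin_width Occupancy track bin width (bp).
#' @param occ_baseline Occupancy baseline signal per bin.
#' @param occ_amp Amplitude of the CpG-density binding response.
#' @param tet1_activation_density CpG density (per 100 bp) below which the
#'   TET1 density response is exactly zero.
#' @param density_response_scale Density scale (per 100 bp) of the
#'   saturating response.
#' @param edge_height DNMT3A1 edge-peak height above baseline.
#' @param promoter_bump_sd Gaussian sd (bp) of promoter occupancy peaks.
#' @param occ_noise_sd Multiplicative noise sd on occupancy bins (0 = none).
#' @param occ_depth Total tag count an occupancy track is scaled to
#'   represent.
#' @param spike_base Spike-in tag count of a track at reference depth.
#' @param edge_offset,edge_sd Center offset (bp, outside the region
#'   boundary) and Gaussian sd of DNMT3A1 edge peaks.
#' @param n_genes Genes per genome.
#' @param gene_length_range Gene body lengths (bp).
#' @param n_de_genes Differentially expressed genes split evenly over the 7
#'   planted expression archetypes C1-C7.
#' @param expr_effect Archetype log2 fold-change unit `a` (condition shifts
#'   are small integer multiples of it).
#' @param expr_noise_sd Per-gene, per-condition log2 expression noise sd.
#' @param satellite_fraction Fraction of 1-kb windows flagged as satellite.
#' @param seed Master seed; all generator randomness flows from it through
#'   deterministic per-chromosome sub-streams.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 2e7,
                       n_chroms = 1,
                       background_cpg_rate = 1,
                       island_cpg_rate = 8,
                       shore_cpg_rate = 3,
                       n_canyons = 30,
                       n_umrs = 100,
                       n_latent_canyons = 90,
                       n_latent_umrs = 100,
                       canyon_length_range = c(4000, 9000),
                       umr_length_range = c(1200, 3200),
                       background_meth_mean = 0.75,
                       umr_meth_mean = 0.03,
                       latent_meth_mean = 0.45,
                       meth_dispersion = 0.02,
                       coverage_mean = 30,
                       condition = "WT",
                       dnmt3a_global_shift = -0.12,
                       region_extension = 400,
                       tet1_flank_gain = 0.15,
                       tet1_height_mult = 2,
                       tet1_width_mult = 2,
                       crossing_density = 1.5,
                       calibrate_crossing = TRUE,
                       occ_bin_width = 10,
                       occ_baseline = 0.2,
                       occ_amp = 3,
                       tet1_activation_density = 0.5,
                       density_response_scale = 1,
                       edge_height = 3,
                       promoter_bump_sd = 300,
                       occ_noise_sd = 0.05,
                       occ_depth = 1e6,
                       spike_base = 5e4,
                       edge_offset = 1000,
                       edge_sd = 600,
                       n_genes = 600,
                       gene_length_range = c(2000, 20000),
                       n_de_genes = 280,
                       expr_effect = 2,
                       expr_noise_sd = 0.25,
                       satellite_fraction = 0.01,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> condition:", x$condition,
      sprintf("| %d chrom x %.1f Mb | %d canyons + %d UMRs | seed %d\n",
              x$n_chroms, x$genome_length / 1e6, x$n_canyons, x$n_umrs,
              as.integer(x$seed)))
  invisible(x)
}

validate_sim_config <- function(cfg) {
  assert_count(cfg$genome_length, "genome_length")
  assert_count(cfg$n_chroms, "n_chroms")
  for (f in c("background_meth_mean", "umr_meth_mean", "latent_meth_mean",
              "meth_dispersion", "satellite_fraction")) {
    assert_fraction(cfg[[f]], f)
  }
  for (f in c("n_canyons", "n_umrs", "n_latent_canyons", "n_latent_umrs",
              "n_genes", "n_de_genes")) {
    assert_count(cfg[[f]], f, positive = FALSE)
  }
  if (!is.numeric(cfg$coverage_mean) || cfg$coverage_mean <= 0) {
    abort("`coverage_mean` must be > 0", class = "canyonscape_config_error")
  }
  if (cfg$umr_length_range[1] < 1000 || cfg$umr_length_range[2] >= 3500) {
    abort("`umr_length_range` must lie within [1000, 3500)",
          class = "canyonscape_config_error")
  }
  if (cfg$canyon_length_range[1] < 3500) {
    abort("`canyon_length_range` must start at >= 3500",
          class = "canyonscape_config_error")
  }
  if (!cfg$condition %in% c("WT", "Dnmt3aKO", "Tet1KO", "DKO")) {
    abort("`condition` must be one of WT, Dnmt3aKO, Tet1KO, DKO",
          class = "canyonscape_config_error")
  }
  for (f in c("background_cpg_rate", "island_cpg_rate", "shore_cpg_rate")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 100) {
      abort(sprintf("`%s` must be in [0, 100] CpGs per 100 bp", f),
            class = "canyonscape_config_error")
    }
  }
  cfg
}

# TRUE when the condition carries a Dnmt3a (resp. Tet1) deletion
has_dnmt3a_ko <- function(condition) condition %in% c("Dnmt3aKO", "DKO")
has_tet1_ko <- function(condition) condition %in% c("Tet1KO", "DKO")
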