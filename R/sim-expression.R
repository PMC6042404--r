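# Condition shift patterns (units of `expr_effect`) for the seven planted
# differential-expression archetypes: C1/C5 change in both knockouts with
# additive combination in the double knockout, C2/C6 are Tet1-specific,
# C3/C4/C7 Dnmt3a-specific.
DEG_SHIFTS <- rbind(
  C1 = c(WT = 0, Dnmt3aKO = 1, Tet1KO = 1, DKO = 2),
  C2 = c(0, 0, 1, 1),
  C3 = c(0, 1, 0, 1),
  C4 = c(0, -1, 0, -1),
  C5 = c(0, -1, -1, -2),
  C6 = c(0, 0, -1, -1),
  C7 = c(0, -1, 0, 0)
)

# baseline log2 FPKM per promoter archetype (G2 CpG-rich/TET1-high genes are
# the most expressed, G3 CpG-poor genes the least)
GROUP_BASE_LOG2 <- c(G1 = 3, G2 = 6, G3 = 0.5, G4 = 4, G5 = 2)

#' Simulate per-gene expression across genotypes with planted DEG clusters
#'
#' Produces an FPKM table over the four genotypes (WT, Dnmt3aKO, Tet1KO,
#' DKO). Baseline expression depends on the gene's planted promoter
#' archetype; genes carrying a planted DEG archetype (C1-C7) receive
#' condition-specific log2 shifts in units of `expr_effect`, with the
#' C1/C5 shifts additive in the double knockout. Non-DE genes have
#' exchangeable condition means.
#'
#' @param genome A [simulate_genome()] result.
#' @param config A [sim_config()]; defaults to the genome's.
#' @return A list of class `sim_expression`: `expression` (tibble
#'   `gene_id, WT, Dnmt3aKO, Tet1KO, DKO` in FPKM, plus `de` flag),
#'   `truth` (tibble `gene_id, cluster_true, tss_group_true`).
#' @export
simulate_expression <- function(genome, config = genome$config) {
  stopifnot(inherits(genome, "canyon_genome"))
  config <- validate_sim_config(config)
  genes <- genome$genes
  if (nrow(genes) < 7) {
    abort("fewer genes than expression clusters (need >= 7)",
          class = "canyonscape_config_error")
  }
  set.seed(chrom_seed(config$seed, 0L, salt = 7L))
  base <- GROUP_BASE_LOG2[genes$tss_group_true]
  de <- !is.na(genes$deg_cluster_true) & config$expr_effect > 0
  shifts <- matrix(0, nrow(genes), 4,
                   dimnames = list(NULL, colnames(DEG_SHIFTS)))
  if (any(de)) {
    shifts[de, ] <- DEG_SHIFTS[genes$deg_cluster_true[de], , drop = FALSE] *
      config$expr_effect
  }
  noise <- matrix(rnorm(nrow(genes) * 4, 0, config$expr_noise_sd),
                  nrow(genes), 4)
  log2fpkm <- base + shifts + noise
  fpkm <- tibble::as_tibble(2^log2fpkm)
  structure(list(
    expression = dplyr::bind_cols(
      tibble::tibble(gene_id = genes$gene_id), fpkm,
      tibble::tibble(de = de)),
    truth = tibble::tibble(gene_id = genes$gene_id,
                           cluster_true = genes$deg_cluster_true,
                           tss_group_true = genes$tss_group_true)
  ), class = "sim_expression")
}
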