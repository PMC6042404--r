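sim_cluster_inputs <- function(seed = 7) {
  g <- simulate_genome(quick_cfg(seed = seed))
  mats <- purrr::map(c(DNMT3A1 = "DNMT3A1", DNMT3A2 = "DNMT3A2",
                       DNMT3B1 = "DNMT3B1"),
                     function(p) tss_matrix(simulate_occupancy(g, p)$track,
                                            g$genes))
  list(genome = g, mats = mats, expr = simulate_expression(g))
}

test_that("TSS groups recover planted archetypes deterministically", {
  inp <- sim_cluster_inputs(7)
  gr <- kmeans_tss_groups(inp$mats, k = 5, seed = 3)
  truth <- inp$genome$genes$tss_group_true[
    match(gr$assignment$gene_id, inp$genome$genes$gene_id)]
  expect_gte(adjusted_rand_index(gr$assignment$group, truth), 0.9)

  # determinism and input-order invariance
  gr2 <- kmeans_tss_groups(inp$mats, k = 5, seed = 3)
  expect_identical(gr$assignment, gr2$assignment)
  shuffled <- purrr::map(inp$mats, function(m) m[sample(nrow(m)), ])
  gr3 <- kmeans_tss_groups(shuffled, k = 5, seed = 3)
  expect_identical(gr$assignment, gr3$assignment)

  # sizes partition the gene set
  expect_equal(nrow(gr$assignment), nrow(inp$genome$genes))
  expect_false(anyNA(gr$assignment$group))

  expect_error(kmeans_tss_groups(purrr::map(inp$mats, ~ .x[1:4, ]), k = 5),
               "exceeds")
  misaligned <- inp$mats
  misaligned[[2]] <- misaligned[[2]][-1, ]
  expect_error(kmeans_tss_groups(misaligned, k = 5), "aligned")
})

test_that("degenerate identical profiles collapse to one effective group", {
  m <- structure(
    dplyr::bind_cols(tibble::tibble(gene_id = paste0("g", 1:20)),
                     tibble::as_tibble(matrix(1, 20, 40,
                                              dimnames = list(NULL,
                                                              paste0("b", 1:40))))),
    class = c("tss_matrix", class(tibble::tibble())))
  gr <- kmeans_tss_groups(list(x = m), k = 5, seed = 1)
  expect_equal(length(unique(gr$assignment$group)), 1)
  expect_equal(gr$empty_groups, paste0("G", 2:5))
})

test_that("DEG clusters standardize, recover archetypes, and label stably", {
  inp <- sim_cluster_inputs(8)
  expr <- inp$expr$expression
  dc <- deg_clusters(expr, k = 7, seed = 3)

  # per-gene standardization: mean 0, unit variance (recomputed)
  x <- log2(as.matrix(expr[expr$de, c("WT", "Dnmt3aKO", "Tet1KO", "DKO")]) + 1)
  x <- x[order(expr$gene_id[expr$de]), ]
  z <- (x - rowMeans(x)) / apply(x, 1, sd)
  expect_true(all(abs(rowMeans(z)) < 1e-12))
  expect_true(all(abs(apply(z, 1, var) - 1) < 1e-9))

  truth <- inp$expr$truth$cluster_true[
    match(dc$assignment$gene_id, inp$expr$truth$gene_id)]
  expect_gte(adjusted_rand_index(dc$assignment$cluster, truth), 0.9)

  dc2 <- deg_clusters(expr, k = 7, seed = 3)
  expect_identical(dc$assignment, dc2$assignment)

  # relabeling orders patterns: C1 up-in-both first, C5-like down-in-both last
  ctr <- dc$centers
  shift <- ctr[, "DKO"] - ctr[, "WT"]
  expect_equal(order(shift, decreasing = TRUE)[1], 1)

  # additive archetype: the DKO shift of the C1 cluster mean trajectory is
  # the sum of the single-knockout shifts (on log expression)
  c1_genes <- dc$assignment$gene_id[dc$assignment$cluster ==
                                      dc$assignment$cluster[
                                        match(inp$expr$truth$gene_id[
                                          which(inp$expr$truth$cluster_true == "C1")[1]],
                                          dc$assignment$gene_id)]]
  lg <- log2(as.matrix(expr[match(c1_genes, expr$gene_id),
                            c("WT", "Dnmt3aKO", "Tet1KO", "DKO")]))
  sh <- colMeans(lg) - mean(lg[, "WT"])
  expect_lt(abs(abs(sh[["DKO"]]) - (abs(sh[["Dnmt3aKO"]]) + abs(sh[["Tet1KO"]]))),
            0.35)

  # constant-expression genes are excluded with a warning
  flat <- expr
  flat[1, c("WT", "Dnmt3aKO", "Tet1KO", "DKO")] <- 4
  flat$de[1] <- TRUE
  expect_warning(deg_clusters(flat, k = 7, seed = 3), "constant")
})

test_that("group summaries conserve membership and show the expected gradients", {
  inp <- sim_cluster_inputs(9)
  g <- inp$genome
  truth_asg <- tibble::tibble(gene_id = g$genes$gene_id,
                              group = g$genes$tss_group_true)
  dens <- promoter_cpg_density(g$genes, g$cpg, g$chrom_sizes)
  expr_wt <- dplyr::select(inp$expr$expression, "gene_id", "WT")
  gs <- group_summaries(truth_asg, tss_matrices = inp$mats[1],
                        expression = expr_wt, promoter_density = dens)
  expect_equal(sum(gs$members$n), nrow(g$genes))
  # G2 archetype (TET1/H3K4me3-high, CpG-rich) is the most expressed
  med <- gs$expression$median[match(paste0("G", 1:5), gs$expression$group)]
  expect_equal(which.max(med), 2)
  # promoter CpG density: island archetypes above background archetypes
  dmed <- gs$cpg_density$median[match(paste0("G", 1:5), gs$cpg_density$group)]
  expect_gt(min(dmed[1:2]), max(dmed[c(3, 5)]))

  # single group containing all genes reproduces the global mean profile
  one <- group_summaries(dplyr::mutate(truth_asg, group = "all"),
                         tss_matrices = inp$mats[1])
  glob <- colMeans(as.matrix(inp$mats[[1]][, -1]), na.rm = TRUE)
  expect_equal(one$profiles$value, as.numeric(glob), tolerance = 1e-12)
})

test_that("tidiers and ARI cross-check against the reference implementation", {
  inp <- sim_cluster_inputs(10)
  gr <- kmeans_tss_groups(inp$mats, k = 5, seed = 2)
  td <- tidy(gr)
  expect_equal(sum(td$size), nrow(gr$assignment))
  gl <- glance(gr)
  expect_equal(gl$k, 5)
  expect_gt(gl$inertia, 0)

  dc <- deg_clusters(inp$expr$expression, k = 7, seed = 2)
  expect_equal(nrow(tidy(dc)), 7)
  expect_equal(glance(dc)$n_genes, nrow(dc$assignment))

  skip_if_not_installed("mclust")
  a <- gr$assignment$group
  b <- inp$genome$genes$tss_group_true[
    match(gr$assignment$gene_id, inp$genome$genes$gene_id)]
  expect_equal(adjusted_rand_index(a, b),
               mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
})
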