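test_that("simulators are deterministic and conserve planted structure", {
  cfg <- quick_cfg()
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$cpg, g2$cpg)
  expect_identical(g1$regions, g2$regions)

  # conservation of planted counts
  expect_equal(sum(g1$regions$type == "canyon" & !g1$regions$latent), 4)
  expect_equal(sum(g1$regions$type == "umr" & !g1$regions$latent), 10)
  # intervals within bounds, non-overlapping, strictly increasing CpGs
  expect_true(all(g1$regions$start >= 0 &
                    g1$regions$end <= g1$chrom_sizes$length[1]))
  r <- g1$regions[order(g1$regions$start), ]
  expect_true(all(r$start[-1] >= r$end[-nrow(r)]))
  expect_true(all(diff(g1$cpg$pos) > 0))
  # length classes honour the configured ranges
  len <- g1$regions$end - g1$regions$start
  expect_true(all(len[g1$regions$type == "canyon"] >= 3500))
  expect_true(all(len[g1$regions$type == "umr"] >= 1000 &
                    len[g1$regions$type == "umr"] < 3500))

  m1 <- simulate_methylome(g1)
  m2 <- simulate_methylome(g1)
  expect_identical(m1$track, m2$track)
  expect_true(all(m1$track$meth <= m1$track$total))

  o1 <- simulate_occupancy(g1, "TET1")
  o2 <- simulate_occupancy(g1, "TET1")
  expect_identical(o1$track, o2$track)
  expect_true(all(o1$track$value >= 0))
})

test_that("CpG density field reflects the configured island/background rates", {
  cfg <- quick_cfg(background_cpg_rate = 1, island_cpg_rate = 8, seed = 21)
  g <- simulate_genome(cfg)
  wins <- build_windows(g$chrom_sizes, g$cpg)
  mid <- (wins$start + wins$end) / 2
  regions <- g$regions
  in_region <- canyonscape:::positions_in_intervals(
    mid[wins$chrom == "chr1"], regions$start, regions$end)
  # windows fully inside planted regions only
  core <- canyonscape:::positions_in_intervals(mid, regions$start + 1000,
                                               regions$end - 1000)
  shoreless <- !canyonscape:::positions_in_intervals(
    mid, regions$start - 2500, regions$end + 2500)
  prom <- g$genes$tss[g$genes$tss_group_true %in% c("G1", "G2")]
  near_prom <- vapply(mid, function(x) any(abs(x - prom) < 2000), logical(1))
  ratio <- mean(wins$cpg_density[core]) /
    mean(wins$cpg_density[shoreless & !near_prom])
  expect_gt(ratio, 8 * 0.85)
  expect_lt(ratio, 8 * 1.15)

  # degenerate equal rates: window counts consistent with one Poisson rate
  cfg0 <- quick_cfg(island_cpg_rate = 1, shore_cpg_rate = 1,
                    background_cpg_rate = 1, n_genes = 0, n_de_genes = 0,
                    seed = 22)
  g0 <- simulate_genome(cfg0)
  w0 <- build_windows(g0$chrom_sizes, g0$cpg)
  counts <- w0$cpg_density * 10  # back to counts per 1-kb window
  expect_gt(var(counts) / mean(counts), 0.85)
  expect_lt(var(counts) / mean(counts), 1.15)
})

test_that("methylome emulates background level, planted regions, and KO shifts", {
  g <- simulate_genome(quick_cfg(genome_length = 5e6, seed = 31))
  m <- simulate_methylome(g)
  # law of large numbers: genome mean close to configured background
  bg <- !canyonscape:::positions_in_intervals(
    m$track$pos, g$regions$start - 2000, g$regions$end + 2000)
  expect_lt(abs(mean(m$track$ratio[bg], na.rm = TRUE) - 0.75), 0.02)

  # planted regions carry the configured low mean
  inside <- canyonscape:::positions_in_intervals(
    m$track$pos, m$regions$start, m$regions$end)
  expect_lt(mean(m$track$ratio[inside], na.rm = TRUE), 0.10)

  # Dnmt3a loss direction: global hypomethylation
  mk <- simulate_methylome(g, condition = "Dnmt3aKO")
  expect_lt(mean(mk$track$ratio, na.rm = TRUE),
            mean(m$track$ratio, na.rm = TRUE))

  # Tet1 loss: flank hypermethylation around planted regions
  mt <- simulate_methylome(g, condition = "Tet1KO")
  planted <- g$regions[!g$regions$latent, ]
  fl <- canyonscape:::positions_in_intervals(
    m$track$pos, c(planted$start - 2000L, planted$end),
    c(planted$start, planted$end + 2000L))
  expect_gt(mean(mt$track$ratio[fl], na.rm = TRUE),
            mean(m$track$ratio[fl], na.rm = TRUE) + 0.05)

  # noiseless degenerate case: zero methylation inside planted regions
  g0 <- simulate_genome(quick_cfg(umr_meth_mean = 0, meth_dispersion = 0,
                                  seed = 32))
  m0 <- simulate_methylome(g0)
  in0 <- canyonscape:::positions_in_intervals(m0$track$pos,
                                              m0$regions$start,
                                              m0$regions$end)
  expect_true(all(m0$track$meth[in0] == 0))
})

test_that("occupancy generator enforces protein labels and config validity", {
  g <- simulate_genome(flat_cfg())
  expect_error(simulate_occupancy(g, "NRF1"), "allowed")
  expect_error(sim_config(coverage_mean = 0), "coverage_mean")
  expect_error(sim_config(umr_length_range = c(500, 3000)), "umr_length_range")
  expect_error(sim_config(background_meth_mean = 1.5), "background_meth_mean")
  expect_error(sim_config(condition = "TKO"), "condition")
})

test_that("DNMT3A1 peaks at canyon edges and TET1 responds to density", {
  g <- simulate_genome(quick_cfg(occ_noise_sd = 0, seed = 41))
  a1 <- simulate_occupancy(g, "DNMT3A1")
  canyons <- g$regions[g$regions$type == "canyon" & !g$regions$latent, ]
  prof <- scaled_region_profile(a1$track, canyons)
  peak <- which.max(prof$value)
  expect_true(prof$segment[peak] %in% c("upstream", "downstream"))
  expect_lte(abs(prof$offset[peak]), 2000)  # within the 2-kb edge

  # flat low-density genome: TET1 exactly at baseline (up to depth scaling)
  g0 <- simulate_genome(flat_cfg())
  t0 <- simulate_occupancy(g0, "TET1")
  expect_lt(diff(range(t0$track$value)), 1e-9)

  # Tet1 loss widens DNMT3A1 peaks by the configured width multiplier
  a1w <- simulate_occupancy(g0, "DNMT3A1")
  a1k <- simulate_occupancy(g0, "DNMT3A1", condition = "Tet1KO")
  # left edge peak of a canyon: its partner peak sits >= 6 kb away and
  # cannot contaminate the half-max measurement
  canyon <- g0$regions[g0$regions$type == "canyon", ][1, ]
  edge <- canyon$start - 1000
  span <- function(track, center) {
    w <- track[track$start > center - 3500 & track$start < center + 3500, ]
    v <- w$value - min(w$value)
    sum(v > 0.5 * max(v)) * 20
  }
  ratio <- span(a1k$track, edge) / span(a1w$track, edge)
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("expression archetypes are planted with additive double-knockout", {
  g <- simulate_genome(quick_cfg(seed = 51))
  ex <- simulate_expression(g)
  expect_identical(sort(ex$expression$gene_id), sort(g$genes$gene_id))

  # additive archetype C1: DKO shift is the sum of the single-KO shifts
  lg <- log2(as.matrix(ex$expression[, c("WT", "Dnmt3aKO", "Tet1KO", "DKO")]))
  c1 <- ex$truth$cluster_true == "C1" & !is.na(ex$truth$cluster_true)
  sh <- colMeans(lg[c1, , drop = FALSE]) - mean(lg[c1, "WT"])
  expect_lt(abs(sh[["DKO"]] - (sh[["Dnmt3aKO"]] + sh[["Tet1KO"]])), 0.3)

  # zero effect sizes: no DE label, no fold change beyond noise
  g0 <- simulate_genome(quick_cfg(expr_effect = 0, seed = 52))
  ex0 <- simulate_expression(g0)
  expect_false(any(ex0$expression$de))
  lg0 <- log2(as.matrix(ex0$expression[, c("WT", "DKO")]))
  expect_lt(max(abs(lg0[, 2] - lg0[, 1])), 8 * 0.25)  # noise-only spread

  expect_error(
    simulate_expression(structure(list(genes = g$genes[1:3, ],
                                       config = g$config),
                                  class = "canyon_genome")),
    "fewer genes")
})
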