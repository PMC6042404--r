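toy_track <- function(values, bin = 10L) {
  new_occupancy_track(
    tibble::tibble(chrom = "chr1",
                   start = seq.int(0L, by = bin, length.out = length(values)),
                   value = values),
    bin_width = bin)
}

test_that("depth normalization and input subtraction behave as contracted", {
  raw <- toy_track(c(2, 4, 6, 8))
  inp <- toy_track(c(1, 2, 3, 4))  # same shape up to a factor
  out <- normalize_track(raw, inp, target_depth = 100)
  expect_true(all(out$value == 0))

  a <- toy_track(c(1, 2, 3, 4))
  b <- toy_track(c(10, 20, 30, 40))
  expect_equal(normalize_track(a, target_depth = 50)$value,
               normalize_track(b, target_depth = 50)$value)

  # idempotence of depth normalization
  once <- normalize_track(a, target_depth = 50)
  twice <- normalize_track(once, target_depth = 50)
  expect_equal(once$value, twice$value)

  # negative differences floor at zero
  spiky <- normalize_track(toy_track(c(0, 10, 0, 0)), toy_track(c(5, 5, 5, 5)),
                           target_depth = 20)
  expect_true(all(spiky$value >= 0))

  expect_error(normalize_track(raw, toy_track(1:3)), "grid")

  # simulated enrichment recovered within 5% after normalization
  g <- simulate_genome(flat_cfg())
  chip <- simulate_occupancy(g, "DNMT3A1")
  inp2 <- simulate_occupancy(g, "input")
  norm <- normalize_track(chip$track, inp2$track, target_depth = 1e6)
  shape <- canyonscape:::noiseless_occupancy(
    norm$start + 10, "chr1", "DNMT3A1", g, g$config)
  # compare profiles after matching scale (input is flat, so normalization
  # preserves shape up to an affine shift)
  fit <- lm(norm$value ~ shape)
  expect_gt(summary(fit)$r.squared, 0.99)
  pred <- fitted(fit)
  big <- shape > max(shape) * 0.8  # peak region, clear of the zero floor
  expect_lt(max(abs(pred[big] - norm$value[big]) / norm$value[big]), 0.05)
})

test_that("spike-in factors equalize depth-varied replicates", {
  expect_equal(spike_in_factor(1e5, 1e5), 1)
  expect_equal(spike_in_factor(2e5, 1e5), 0.5)
  expect_error(spike_in_factor(0, 1e5), "> 0")

  g <- simulate_genome(flat_cfg())
  s1 <- simulate_occupancy(g, "DNMT3A1", depth_factor = 1)
  s3 <- simulate_occupancy(g, "DNMT3A1", depth_factor = 3)
  t1 <- apply_spike(s1$track, spike_in_factor(s1$spike))
  t3 <- apply_spike(s3$track, spike_in_factor(s3$spike))
  expect_lt(max(abs(t1$value - t3$value) / pmax(t1$value, 1e-12)), 1e-6)

  # factors compose multiplicatively
  tr <- toy_track(c(1, 2, 3))
  expect_equal(apply_spike(apply_spike(tr, 2), 3)$value,
               apply_spike(tr, 6)$value)
})

test_that("window construction applies the satellite/coverage exclusions", {
  sizes <- tibble::tibble(chrom = "chr1", length = 10000L)
  cpg <- tibble::tibble(chrom = "chr1", pos = c(500L, 1500L, 2500L, 8500L))
  w <- build_windows(sizes, cpg)
  expect_equal(nrow(w), 10)
  expect_equal(w$cpg_density[1], 0.1)

  sat <- tibble::tibble(chrom = "chr1", start = 2999L, end = 3400L)
  wgbs <- tibble::tibble(chrom = "chr1", pos = c(500L, 1500L, 8500L),
                         total = c(10L, 5L, 8L), meth = c(1L, 1L, 1L))
  w2 <- build_windows(sizes, cpg, wgbs_track = wgbs, satellite = sat)
  expect_true(w2$satellite[3])        # 1-bp overlap with window [2000,3000)
  expect_true(w2$satellite[4])
  expect_false(w2$satellite[5])
  expect_true(w2$no_wgbs[3])          # CpG present but not covered
  expect_false(w2$no_wgbs[1])
  expect_false(w2$included[3])
  expect_false(any(w2$included & (w2$satellite | w2$no_wgbs)))
})

test_that("feature enrichment is relative to the genomic mean", {
  sizes <- tibble::tibble(chrom = "chr1", length = 10000L)
  cpg <- tibble::tibble(chrom = "chr1", pos = seq(50L, 9950L, by = 100L))
  wins <- build_windows(sizes, cpg)
  uniform <- toy_track(rep(2, 1000))
  feats <- tibble::tibble(chrom = "chr1", start = c(0L, 4000L),
                          end = c(2000L, 6000L),
                          class = c("promoter", "exon"))
  fe <- feature_enrichment(uniform, feats, wins)
  expect_equal(fe$enrichment, c(1, 1))
  expect_equal(fe$log2_enrichment, c(0, 0))

  # doubled signal in one class: enrichment 2 / (overall mean scaling)
  v <- rep(1, 1000); v[1:200] <- 2   # windows 1-2 (class "first")
  fe2 <- feature_enrichment(toy_track(v),
                            tibble::tibble(chrom = "chr1", start = 0L,
                                           end = 2000L, class = "first"),
                            wins)
  expect_equal(fe2$enrichment, 2 / mean(c(2, 2, rep(1, 8))))

  # all-windows class is exactly 1 (conservation)
  all_fe <- feature_enrichment(toy_track(v),
                               tibble::tibble(chrom = "chr1", start = 0L,
                                              end = 10000L, class = "all"),
                               wins)
  expect_equal(all_fe$enrichment, 1)

  expect_warning(
    empty <- feature_enrichment(uniform,
                                tibble::tibble(chrom = "chr2", start = 0L,
                                               end = 100L, class = "off"),
                                wins),
    "omitted")
  expect_equal(nrow(empty), 0)
})

test_that("differential occupancy is a signed Poisson tail score", {
  a <- toy_track(c(5, 20, 7, 0))
  r <- toy_track(c(5, 5, 9, 0))
  d <- differential_occupancy(a, r)
  expect_equal(d$score[1], 0)
  expect_equal(d$score[4], 0)
  expect_gt(d$score[2], 0)       # A above reference
  expect_lt(d$score[3], 0)

  # |log10 P| against brute-force tail summation, P(X >= 20 | mean 5)
  expect_equal(abs(d$score[2]), -log10(pois_tail(20, 5)), tolerance = 1e-9)

  # antisymmetry is exact
  rev <- differential_occupancy(r, a)
  expect_identical(d$score, -rev$score)

  # extreme contrasts cap at 300
  cap <- differential_occupancy(toy_track(c(1e6, 1)), toy_track(c(1, 1e6)))
  expect_equal(cap$score, c(300, -300))

  expect_error(differential_occupancy(a, toy_track(1:3)), "grid")
})

test_that("simulated DNMT3A1 reproduces the canyon-edge enrichment pattern", {
  g <- simulate_genome(quick_cfg(seed = 81))
  m <- simulate_methylome(g)
  a1 <- normalize_track(simulate_occupancy(g, "DNMT3A1")$track)
  wins <- build_windows(g$chrom_sizes, g$cpg, wgbs_track = m$track,
                        satellite = g$satellite)
  canyons <- m$regions[m$regions$type == "canyon", ]
  edges <- canyon_edges(canyons, 2000, g$chrom_sizes)
  genes <- g$genes
  prox <- tibble::tibble(chrom = genes$chrom, start = genes$tss - 500L,
                         end = genes$tss + 500L, class = "proximal_promoter")
  distal <- tibble::tibble(
    chrom = genes$chrom,
    start = ifelse(genes$strand == "+", genes$tss - 3000L, genes$tss + 500L),
    end = ifelse(genes$strand == "+", genes$tss - 500L, genes$tss + 3000L),
    class = "distal_promoter")
  feats <- dplyr::bind_rows(
    dplyr::mutate(canyons[, c("chrom", "start", "end")], class = "canyon"),
    dplyr::mutate(edges[, c("chrom", "start", "end")], class = "canyon_edge"),
    prox, distal)
  fe <- feature_enrichment(a1, feats, wins)
  expect_equal(fe$class[which.max(fe$enrichment)], "canyon_edge")
  expect_lt(fe$enrichment[fe$class == "canyon"], 1)
})
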