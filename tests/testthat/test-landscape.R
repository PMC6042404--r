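test_that("meta-profiles are flat on constant tracks and length-invariant", {
  const <- new_occupancy_track(
    tibble::tibble(chrom = "chr1", start = seq.int(0L, 99950L, 50L),
                   value = 3.5), bin_width = 50L)
  regions <- tibble::tibble(chrom = "chr1", start = c(20000L, 60000L),
                            end = c(24000L, 64000L))
  prof <- scaled_region_profile(const, regions, flank = 5000)
  expect_true(all(abs(prof$value - 3.5) < 1e-12))
  expect_equal(nrow(prof), 100 + 2 * 100)  # body + two 5-kb flanks at 50 bp

  # two regions of very different length, same shape after scaling
  tri <- function(s, e) {
    pos <- seq.int(0L, 199950L, 50L)
    x <- (pos + 25 - s) / (e - s)
    v <- ifelse(x >= 0 & x <= 1, 1 - abs(x - 0.5) * 2, 0)
    new_occupancy_track(tibble::tibble(chrom = "chr1", start = pos, value = v),
                        bin_width = 50L)
  }
  r1 <- tibble::tibble(chrom = "chr1", start = 20000L, end = 24000L)
  r2 <- tibble::tibble(chrom = "chr1", start = 100000L, end = 140000L)
  p1 <- scaled_region_profile(tri(20000, 24000), r1, flank = 1000)
  p2 <- scaled_region_profile(tri(100000, 140000), r2, flank = 1000)
  body <- p1$segment == "body"
  expect_lt(max(abs(p1$value[body] - p2$value[body])), 0.05)

  expect_warning(scaled_region_profile(
    const, dplyr::bind_rows(regions, tibble::tibble(chrom = "chr1",
                                                    start = 10L, end = 30L))),
    "skipped")
  expect_error(scaled_region_profile(const, regions[0, ]), "empty")
})

test_that("TSS matrices are strand-oriented with missing flanks as NA", {
  pos <- seq.int(0L, 49950L, 50L)
  v <- numeric(length(pos))
  v[pos == 20000] <- 10        # point signal at the TSS
  v[pos == 21000] <- 5         # asymmetric downstream marker
  track <- new_occupancy_track(tibble::tibble(chrom = "chr1", start = pos,
                                              value = v), bin_width = 50L)
  genes <- tibble::tibble(gene_id = c("plus", "minus"), chrom = "chr1",
                          tss = 20025L, strand = c("+", "-"))
  m <- tss_matrix(track, genes, flank = 5000, bin = 50)
  vals <- as.matrix(m[, -1])
  expect_equal(ncol(vals), 200)
  # center column maximal for the plus-strand gene (TSS between bins 100/101)
  expect_true(which.max(vals["plus" == m$gene_id, ]) %in% c(100, 101))
  # minus-strand row is the reverse of the plus-strand row
  expect_equal(as.numeric(vals[2, ]), rev(as.numeric(vals[1, ])))

  # gene near the chromosome start: upstream bins are missing
  edge <- tss_matrix(track, tibble::tibble(gene_id = "e", chrom = "chr1",
                                           tss = 1000L, strand = "+"),
                     flank = 5000, bin = 50)
  ev <- as.numeric(as.matrix(edge[, -1]))
  expect_true(any(is.na(ev[1:10])))
  expect_false(anyNA(ev[150:200]))

  expect_error(tss_matrix(track, tibble::tibble(gene_id = "x", chrom = "chr1",
                                                tss = 100L, strand = ".")),
               "strand")
})

test_that("density bins are equal-count and the crossing interpolates", {
  sizes <- tibble::tibble(chrom = "chr1", length = 200000L)
  set.seed(5)
  cpg <- tibble::tibble(chrom = "chr1",
                        pos = sort(sample.int(200000L, 4000L)))
  wins <- build_windows(sizes, cpg)
  v <- rep(1, 20000)
  up <- new_occupancy_track(tibble::tibble(chrom = "chr1",
                                           start = seq.int(0L, 199990L, 10L),
                                           value = seq(0.5, 1.5,
                                                       length.out = 20000)),
                            bin_width = 10L)
  flat <- new_occupancy_track(tibble::tibble(chrom = "chr1",
                                             start = seq.int(0L, 199990L, 10L),
                                             value = v), bin_width = 10L)
  dp <- density_profile(list(a = up, b = flat), wins, n_bins = 10)
  pops <- table(ceiling(seq_len(sum(wins$included)) /
                          (sum(wins$included) / 10)))
  expect_lte(max(pops) - min(pops), 1)
  expect_equal(nrow(dp), 20)

  # forced-arithmetic crossing: difference -1 at density 1, +1 at density 2
  prof <- tibble::tibble(bin = rep(1:2, 2), density = rep(c(1, 2), 2),
                         track = rep(c("A", "B"), each = 2),
                         enrichment = c(0, 2, 1, 1))
  expect_equal(crossing_point(prof, "A", "B"), 1.5)
  # one track uniformly above: no crossing
  prof2 <- dplyr::mutate(prof, enrichment = c(2, 3, 1, 1))
  expect_true(is.na(crossing_point(prof2, "A", "B")))

  expect_error(density_profile(list(a = up, b = flat), wins[1:5, ],
                               n_bins = 10), "fewer")
})

test_that("peak coordinates map center to 0 and edges to +/-1, invertibly", {
  expect_equal(to_peak_coordinate(1500, 1000, 2000), 0)
  expect_equal(to_peak_coordinate(2000, 1000, 2000), 1)
  expect_equal(to_peak_coordinate(1000, 1000, 2000), -1)
  expect_equal(to_peak_coordinate(500, 1000, 2000), -2)  # linear beyond
  expect_error(to_peak_coordinate(1, 10, 10), "length")

  # invertible within a peak: map then unmap returns the position
  pos <- seq(1000, 2000, by = 7)
  u <- to_peak_coordinate(pos, 1000, 2000)
  back <- 1500 + u * 500
  expect_true(all(abs(back - pos) < 1))
  expect_true(all(diff(u) > 0))  # strictly monotone

  peaks <- tibble::tibble(chrom = "chr1", start = c(1000L, 5000L),
                          end = c(2000L, 7000L))
  dmrs <- tibble::tibble(chrom = "chr1",
                         start = c(1400L, 1900L, 5900L, 3480L),
                         end = c(1600L, 2100L, 6100L, 3520L))
  h <- dmr_peak_histogram(dmrs, peaks, u_range = c(-3, 3), n_bins = 12)
  # midpoints 1500 and 6000 map to u = 0 of their nearest peaks, 2000 to
  # u = 1; 3500 maps to u = 4 of the first peak and falls outside the range
  expect_equal(sum(h$count), 3)
  expect_equal(sum(h$density) * 0.5, 1)
  expect_equal(sum(h$count[abs(h$u_mid) == 0.25]), 2)
  expect_error(dmr_peak_histogram(dmrs, peaks[0, ]), "empty")
})

test_that("promoter CpG density uses the strand-aware -1kb..+0.5kb window", {
  cpg <- tibble::tibble(chrom = "chr1",
                        pos = as.integer(seq(100, 29900, by = 100)))
  genes <- tibble::tibble(gene_id = c("p", "m"), chrom = "chr1",
                          tss = c(10000L, 10000L), strand = c("+", "-"))
  d <- promoter_cpg_density(genes, cpg)
  expect_equal(d$cpg_density, c(1, 1))  # 15 CpGs in 1.5 kb -> 1 per 100 bp

  # brute-force strand-flip oracle on an asymmetric field
  cpg2 <- tibble::tibble(chrom = "chr1",
                         pos = c(seq(9000L, 9999L, 50L),   # upstream of 10 kb
                                 seq(10000L, 10499L, 250L)))
  d2 <- promoter_cpg_density(genes, cpg2)
  plus_count <- sum(cpg2$pos >= 9000 & cpg2$pos < 10500)
  minus_count <- sum(cpg2$pos >= 9500 & cpg2$pos < 11000)
  expect_equal(d2$cpg_density[1], plus_count / 1500 * 100)
  expect_equal(d2$cpg_density[2], minus_count / 1500 * 100)

  # truncation at the chromosome start uses the truncated length
  g0 <- tibble::tibble(gene_id = "t", chrom = "chr1", tss = 400L,
                       strand = "+")
  d0 <- promoter_cpg_density(g0, cpg)
  expect_equal(d0$cpg_density, sum(cpg$pos < 900) / 900 * 100)

  expect_equal(promoter_cpg_density(genes, cpg[0, ])$cpg_density, c(0, 0))
})

test_that("simulated TET1 is higher at G2-archetype than G3-archetype genes", {
  g <- simulate_genome(quick_cfg(seed = 91))
  tet1 <- simulate_occupancy(g, "TET1")
  tm <- tss_matrix(tet1$track, g$genes)
  truth <- g$genes$tss_group_true[match(tm$gene_id, g$genes$gene_id)]
  vals <- as.matrix(tm[, -1])
  expect_gt(mean(vals[truth == "G2", ], na.rm = TRUE),
            mean(vals[truth == "G3", ], na.rm = TRUE))
})

test_that("TSS-associated peak selection uses the center-distance rule", {
  peaks <- tibble::tibble(chrom = "chr1",
                          start = c(900L, 5000L, 9000L),
                          end = c(1100L, 6000L, 9400L))
  genes <- tibble::tibble(chrom = "chr1", tss = c(1000L, 6450L))
  sel <- tss_associated_peaks(peaks, genes, max_dist = 1000)
  # centers: 1000 (dist 0), 5500 (dist 950), 9200 (dist 2750)
  expect_equal(sel$start, c(900L, 5000L))
  expect_equal(nrow(tss_associated_peaks(peaks, genes, max_dist = 100)), 1)
})
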