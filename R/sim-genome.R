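#' Simulate a genome skeleton with planted methylation structure
#'
#' Generates chromosome sizes, CpG positions from an inhomogeneous
#' Bernoulli-per-bp process with a piecewise density field (background,
#' shore, and island rates), gene/TSS annotations with planted promoter
#' archetypes, satellite 1-kb windows, and the planted under-methylated
#' region set that every downstream generator and ground-truth comparison
#' refers to. Island-like CpG-dense stretches coincide with planted regions
#' and with CpG-rich promoter archetypes, which creates the CpG-density
#' gradient the binding simulators respond to.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `canyon_genome` with elements `chrom_sizes`,
#'   `cpg`, `genes`, `regions` (planted truth, with `latent` flag),
#'   `satellite`, and the `config` used.
#' @export
simulate_genome <- function(config) {
  config <- validate_sim_config(config)
  L <- config$genome_length
  chroms <- paste0("chr", seq_len(config$n_chroms))

  per_chrom <- purrr::map(seq_len(config$n_chroms), function(i) {
    set.seed(chrom_seed(config$seed, i, salt = 1L))
    regions <- place_regions(L, chroms[i], config, i)
    genes <- place_genes(L, chroms[i], config, i)
    cpg <- sample_cpgs(L, chroms[i], regions, genes, config)
    sat <- sample_satellites(L, chroms[i], regions, config)
    list(regions = regions, genes = genes, cpg = cpg, satellite = sat)
  })

  genes <- dplyr::bind_rows(purrr::map(per_chrom, "genes"))
  # DE-cluster labels assigned genome-wide so chromosome count does not
  # change per-cluster balance
  set.seed(chrom_seed(config$seed, 0L, salt = 5L))
  genes$deg_cluster_true <- NA_character_
  n_de <- min(config$n_de_genes, nrow(genes))
  if (n_de >= 7) {
    de_idx <- sample.int(nrow(genes), n_de)
    genes$deg_cluster_true[de_idx] <- paste0("C", rep_len(1:7, n_de))
  }

  structure(list(
    chrom_sizes = tibble::tibble(chrom = chroms, length = L),
    cpg = dplyr::bind_rows(purrr::map(per_chrom, "cpg")),
    genes = genes,
    regions = dplyr::bind_rows(purrr::map(per_chrom, "regions")),
    satellite = dplyr::bind_rows(purrr::map(per_chrom, "satellite")),
    config = config
  ), class = "canyon_genome")
}

#' @export
print.canyon_genome <- function(x, ...) {
  cat(sprintf(
    "<canyon_genome> %d chrom(s) x %.1f Mb | %s CpGs | %d planted regions | %d genes\n",
    nrow(x$chrom_sizes), x$chrom_sizes$length[1] / 1e6,
    format(nrow(x$cpg), big.mark = ","), nrow(x$regions), nrow(x$genes)))
  invisible(x)
}

# Non-overlapping placement by assigning each region to a shuffled slot of
# the chromosome, with margin for edge peaks and flank effects.
place_regions <- function(L, chrom, config, chrom_index) {
  counts <- c(canyon = config$n_canyons, umr = config$n_umrs,
              latent_canyon = config$n_latent_canyons,
              latent_umr = config$n_latent_umrs)
  # round-robin split across chromosomes
  take <- function(n) {
    base <- as.integer(n) %/% as.integer(config$n_chroms)
    base + as.integer(chrom_index <= as.integer(n) %% as.integer(config$n_chroms))
  }
  n_each <- vapply(counts, take, integer(1))
  total <- sum(n_each)
  if (total == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), type = character(),
                          latent = logical(), region_id = character()))
  }
  margin <- 12000
  slot_len <- floor((L - 2 * margin) / total)
  max_len <- max(config$canyon_length_range[2], config$umr_length_range[2])
  if (slot_len < max_len + margin) {
    abort("genome_length too small for the requested number of planted regions",
          class = "canyonscape_config_error")
  }
  kind <- rep(names(n_each), n_each)
  len_range <- function(k) {
    if (grepl("canyon", k)) config$canyon_length_range else config$umr_length_range
  }
  lens <- vapply(kind, function(k) {
    r <- len_range(k)
    as.integer(round(runif(1, r[1], r[2])))
  }, integer(1))
  slot <- sample.int(total)  # shuffle region order over slots
  start <- margin + (slot - 1L) * slot_len +
    vapply(seq_len(total), function(j) {
      as.integer(floor(runif(1, 0, slot_len - lens[j] - margin / 2)))
    }, integer(1))
  tibble::tibble(
    chrom = chrom,
    start = start,
    end = start + lens,
    type = ifelse(grepl("canyon", kind), "canyon", "umr"),
    latent = grepl("latent", kind),
    region_id = sprintf("%s_r%03d", chrom, seq_len(total))
  ) |> dplyr::arrange(.data$start)
}

place_genes <- function(L, chrom, config, chrom_index) {
  n <- config$n_genes %/% config$n_chroms +
    as.integer(chrom_index <= config$n_genes %% config$n_chroms)
  if (n == 0) {
    return(tibble::tibble(chrom = character(), gene_id = character(),
                          tss = integer(), strand = character(),
                          start = integer(), end = integer(),
                          tss_group_true = character()))
  }
  # spread TSSs over shuffled slots so genes do not pile up
  margin <- 25000
  slot_len <- floor((L - 2 * margin) / n)
  slot <- sample.int(n)
  tss <- as.integer(margin + (slot - 1L) * slot_len +
                      floor(runif(n, 0, max(1, slot_len - margin))))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  len <- as.integer(round(runif(n, config$gene_length_range[1],
                                config$gene_length_range[2])))
  group <- sample(paste0("G", 1:5), n, replace = TRUE,
                  prob = c(0.15, 0.20, 0.15, 0.20, 0.30))
  tibble::tibble(
    chrom = chrom,
    gene_id = sprintf("%s_g%04d", chrom, seq_len(n)),
    tss = tss,
    strand = strand,
    start = ifelse(strand == "+", tss, pmax(0L, tss - len)),
    end = ifelse(strand == "+", pmin(as.integer(L), tss + len), tss),
    tss_group_true = group
  )
}

# CpG positions from a piecewise-constant density field, realised per
# 100-bp tile then collapsed to constant-rate runs for sampling.
sample_cpgs <- function(L, chrom, regions, genes, config) {
  tile <- 100L
  n_tiles <- L %/% tile
  rate <- rep(config$background_cpg_rate / 100, n_tiles)

  paint <- function(start, end, r) {
    i0 <- pmax(1L, start %/% tile + 1L)
    i1 <- pmin(n_tiles, (end - 1L) %/% tile + 1L)
    for (j in seq_along(i0)) {
      if (i1[j] >= i0[j]) {
        idx <- i0[j]:i1[j]
        rate[idx] <<- pmax(rate[idx], r)
      }
    }
  }
  if (nrow(regions) > 0) {
    # island shores flank every planted region
    paint(regions$start - 1000L, regions$end + 1000L, config$shore_cpg_rate / 100)
    paint(regions$start, regions$end, config$island_cpg_rate / 100)
  }
  if (nrow(genes) > 0) {
    prom_rate <- dplyr::case_match(genes$tss_group_true,
                                   c("G1", "G2") ~ config$island_cpg_rate,
                                   "G4" ~ config$shore_cpg_rate,
                                   .default = config$background_cpg_rate) / 100
    keep <- prom_rate > config$background_cpg_rate / 100
    if (any(keep)) {
      ord <- order(prom_rate[keep])  # paint higher rates last
      st <- (genes$tss[keep] - 500L)[ord]
      en <- (genes$tss[keep] + 500L)[ord]
      rr <- prom_rate[keep][ord]
      for (j in seq_along(st)) paint(st[j], en[j], rr[j])
    }
  }

  runs <- rle(rate)
  run_end <- cumsum(runs$lengths) * tile
  run_start <- run_end - runs$lengths * tile
  pos <- purrr::map2(seq_along(runs$values), runs$values, function(j, p) {
    len <- run_end[j] - run_start[j]
    k <- rbinom(1, len, p)
    if (k == 0) return(integer())
    sort(sample.int(len, k)) + run_start[j] - 1L
  })
  tibble::tibble(chrom = chrom, pos = as.integer(unlist(pos)))
}

sample_satellites <- function(L, chrom, regions, config) {
  n_win <- L %/% 1000L
  n_sat <- round(config$satellite_fraction * n_win)
  if (n_sat == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  idx <- sample.int(n_win, min(n_sat * 2L, n_win))
  start <- (idx - 1L) * 1000L
  # keep satellites off planted regions so they only exercise the
  # window-exclusion logic
  if (nrow(regions) > 0) {
    hit <- purrr::map_lgl(start, function(s) {
      any(interval_overlap(s, s + 1000L, regions$start - 2000L,
                           regions$end + 2000L) > 0)
    })
    start <- start[!hit]
  }
  start <- sort(head(start, n_sat))
  tibble::tibble(chrom = chrom, start = start, end = start + 1000L)
}
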