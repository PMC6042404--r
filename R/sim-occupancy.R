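OCC_PROTEINS <- c("TET1", "DNMT3A1", "DNMT3A2", "DNMT3B1",
                  "H3K4me3", "H3K27me3", "input")

# promoter (TSS) and gene-body peak heights per planted promoter archetype
ARCHETYPE_AMPS <- list(
  TET1    = c(G1 = 4.0, G2 = 8.0, G3 = 0.2, G4 = 2.0, G5 = 0.5),
  DNMT3A1 = c(G1 = 12.0, G2 = 2.0, G3 = 0.0, G4 = 0.0, G5 = 0.0),
  DNMT3A2 = c(G1 = 12.0, G2 = 8.0, G3 = 6.0, G4 = 0.0, G5 = 0.0),
  DNMT3B1 = c(G1 = 0.0, G2 = 12.0, G3 = 0.0, G4 = 8.0, G5 = 0.0),  # gene body
  H3K4me3 = c(G1 = 6.0, G2 = 8.0, G3 = 0.4, G4 = 2.0, G5 = 1.0),
  H3K27me3 = c(G1 = 6.0, G2 = 0.4, G3 = 1.0, G4 = 1.0, G5 = 0.6),
  input = c(G1 = 0, G2 = 0, G3 = 0, G4 = 0, G5 = 0)
)

# extra DNMT3A1 promoter binding gained after Tet1 loss (invasion of former
# TET1 peaks), largest at the TET1-rich archetypes
DNMT3A1_INVASION <- c(G1 = 6.0, G2 = 8.0, G3 = 0.8, G4 = 2.0, G5 = 0.8)

#' Simulate a binned chromatin occupancy track with peaks and spike-ins
#'
#' Builds a fixed-step occupancy track for one protein/mark under the
#' planted landscape. TET1 signal is a saturating, increasing function of
#' local CpG density (zero response below `tet1_activation_density`);
#' DNMT3A1 carries the opposite density response plus Gaussian peaks
#' centered `edge_offset` bp outside planted region boundaries, so its
#' profile peaks in the 2-kb flanks of canyons while being depleted inside
#' them. When `calibrate_crossing` is set, the shared density-response
#' midpoint is calibrated so the two depth-normalized enrichment curves
#' cross at `crossing_density`. `Tet1KO`/`DKO` removes TET1 signal, multiplies
#' DNMT3A1 peak heights by `tet1_height_mult` and widths by
#' `tet1_width_mult`, and adds DNMT3A1 binding over former TET1 promoter
#' peaks. `input` is a flat noisy baseline. Spike-in tag counts scale with
#' `depth_factor`.
#'
#' @param genome A [simulate_genome()] result.
#' @param protein One of `r paste(OCC_PROTEINS, collapse = ", ")`.
#' @param config A [sim_config()]; defaults to the genome's.
#' @param condition Optional override of `config$condition`.
#' @param depth_factor Relative sequencing depth of this sample (scales the
#'   track total and the spike-in tag count, not the noise stream).
#' @return A list of class `sim_occupancy`: `track` (occupancy tibble),
#'   `peaks` (BED-style tibble), `spike` (spike-in counts), `truth`
#'   (planted crossing density and peak geometry), `protein`, `condition`.
#' @export
simulate_occupancy <- function(genome, protein, config = genome$config,
                               condition = config$condition,
                               depth_factor = 1) {
  stopifnot(inherits(genome, "canyon_genome"))
  if (!protein %in% OCC_PROTEINS) {
    abort(sprintf("unknown protein '%s'; allowed: %s", protein,
                  paste(OCC_PROTEINS, collapse = ", ")))
  }
  config <- validate_sim_config(config)
  config$condition <- condition
  config <- validate_sim_config(config)
  bw <- as.integer(config$occ_bin_width)
  cond_idx <- match(condition, c("WT", "Dnmt3aKO", "Tet1KO", "DKO"))
  prot_idx <- match(protein, OCC_PROTEINS)

  chroms <- genome$chrom_sizes$chrom
  pieces <- purrr::map(seq_along(chroms), function(i) {
    L <- genome$chrom_sizes$length[i]
    start <- seq.int(0L, L - bw, by = bw)
    center <- start + bw / 2
    value <- noiseless_occupancy(center, chroms[i], protein, genome, config)
    set.seed(chrom_seed(config$seed, i, salt = 40L + 4L * prot_idx + cond_idx))
    if (config$occ_noise_sd > 0) {
      value <- value * exp(rnorm(length(value), 0, config$occ_noise_sd))
    }
    tibble::tibble(chrom = chroms[i], start = start, value = value)
  })
  track <- dplyr::bind_rows(pieces)
  target_total <- config$occ_depth * depth_factor
  track$value <- track$value * (target_total / sum(track$value))
  track <- new_occupancy_track(track, bin_width = bw,
                               sample = paste(protein, condition, sep = "_"),
                               total_tags = target_total)

  spike <- tibble::tibble(
    sample = paste(protein, condition, sep = "_"),
    spike_count = round(config$spike_base * depth_factor),
    reference_count = config$spike_base
  )

  structure(list(
    track = track,
    peaks = occupancy_peaks(genome, protein, config),
    spike = spike,
    truth = list(crossing_density = config$crossing_density,
                 edge_offset = config$edge_offset,
                 edge_sd = config$edge_sd,
                 promoter_bump_sd = config$promoter_bump_sd),
    protein = protein,
    condition = condition
  ), class = "sim_occupancy")
}

# Deterministic (noise-free, unscaled) signal per bin center. `center`
# must be a uniformly spaced grid.
noiseless_occupancy <- function(center, chrom, protein, genome, config) {
  cpg <- genome$cpg$pos[genome$cpg$chrom == chrom]
  d <- (findInterval(center + 500, cpg) - findInterval(center - 500, cpg)) / 10
  tet1_off <- has_tet1_ko(config$condition)

  d_act <- if (protein %in% c("TET1", "DNMT3A1")) {
    effective_activation(genome, config)
  } else {
    config$tet1_activation_density
  }
  sat <- function(x) {
    pmax(0, 1 - exp(-pmax(0, x - d_act) / config$density_response_scale))
  }
  value <- rep(config$occ_baseline, length(center))

  genes <- genome$genes[genome$genes$chrom == chrom, , drop = FALSE]
  regions <- genome$regions[genome$regions$chrom == chrom &
                              !genome$regions$latent, , drop = FALSE]
  amps <- ARCHETYPE_AMPS[[protein]]

  if (protein == "input") return(rep(1, length(center)))

  if (protein == "TET1") {
    if (tet1_off) return(value)
    value <- value + config$occ_amp * sat(d)
    value <- add_gaussian_bumps(value, center, genes$tss,
                                amps[genes$tss_group_true],
                                config$promoter_bump_sd)
    return(value)
  }

  if (protein == "DNMT3A1") {
    hm <- if (tet1_off) config$tet1_height_mult else 1
    wm <- if (tet1_off) config$tet1_width_mult else 1
    value <- value + config$occ_amp * (1 - sat(d))
    if (nrow(regions) > 0) {
      value <- add_gaussian_bumps(
        value, center,
        c(regions$start - config$edge_offset, regions$end + config$edge_offset),
        rep(config$edge_height * hm, 2L * nrow(regions)),
        config$edge_sd * wm)
    }
    amp_tss <- amps[genes$tss_group_true] * hm +
      if (tet1_off) DNMT3A1_INVASION[genes$tss_group_true] else 0
    value <- add_gaussian_bumps(value, center, genes$tss, amp_tss,
                                config$promoter_bump_sd * wm)
    return(value)
  }

  if (protein == "DNMT3B1") {
    # gene-body binding: peak 2 kb downstream of the TSS (strand-oriented)
    body <- genes$tss + ifelse(genes$strand == "+", 2000, -2000)
    return(add_gaussian_bumps(value, center, body,
                              amps[genes$tss_group_true], 1000))
  }

  # DNMT3A2 and histone marks: promoter peaks per archetype
  add_gaussian_bumps(value, center, genes$tss, amps[genes$tss_group_true],
                     config$promoter_bump_sd)
}

# value + sum of Gaussian bumps (height may be vector; sd scalar or vector)
add_gaussian_bumps <- function(value, center, bump_center, height, sd) {
  if (length(bump_center) == 0) return(value)
  height <- rep_len(height, length(bump_center))
  sd <- rep_len(sd, length(bump_center))
  bw <- if (length(center) > 1) center[2] - center[1] else 1
  for (j in seq_along(bump_center)) {
    if (height[j] <= 0) next
    lo <- max(1L, floor((bump_center[j] - 4 * sd[j] - center[1]) / bw) + 1L)
    hi <- min(length(center), ceiling((bump_center[j] + 4 * sd[j] - center[1]) / bw) + 1L)
    if (hi < lo) next
    idx <- lo:hi
    value[idx] <- value[idx] +
      height[j] * exp(-0.5 * ((center[idx] - bump_center[j]) / sd[j])^2)
  }
  value
}

# Effective activation density of the shared saturating CpG-density
# response. When config$calibrate_crossing is TRUE the activation is
# shifted (deterministic grid search over window-level noiseless curves,
# WT geometry, equal-count density bins as in density_profile()) so that
# the depth-normalized TET1 and DNMT3A1 enrichment curves cross at
# config$crossing_density; otherwise config$tet1_activation_density is
# used as-is. Cached per genome/config.
effective_activation <- function(genome, config) {
  if (!isTRUE(config$calibrate_crossing)) return(config$tet1_activation_density)
  key <- paste(config$seed, config$crossing_density, config$occ_amp,
               config$occ_baseline, config$tet1_activation_density,
               nrow(genome$cpg), nrow(genome$genes), sep = "_")
  cached <- crossing_cal_cache[[key]]
  if (!is.null(cached)) return(cached)

  cfg <- config
  cfg$condition <- "WT"
  step <- 200L
  vals <- purrr::map(seq_len(nrow(genome$chrom_sizes)), function(i) {
    ch <- genome$chrom_sizes$chrom[i]
    L <- genome$chrom_sizes$length[i]
    pts <- seq.int(100L, L - 100L, by = step)  # 5 points per 1-kb window
    n_win <- length(pts) %/% 5L
    pts <- pts[seq_len(n_win * 5L)]
    win <- rep(seq_len(n_win), each = 5L)
    cpg <- genome$cpg$pos[genome$cpg$chrom == ch]
    wc <- (seq_len(n_win) - 0.5) * 1000
    base <- rep(config$occ_baseline, length(pts))
    genes <- genome$genes[genome$genes$chrom == ch, , drop = FALSE]
    regions <- genome$regions[genome$regions$chrom == ch &
                                !genome$regions$latent, , drop = FALSE]
    t_b <- add_gaussian_bumps(base, pts, genes$tss,
                              ARCHETYPE_AMPS$TET1[genes$tss_group_true],
                              config$promoter_bump_sd)
    a_b <- add_gaussian_bumps(base, pts, genes$tss,
                              ARCHETYPE_AMPS$DNMT3A1[genes$tss_group_true],
                              config$promoter_bump_sd)
    if (nrow(regions) > 0) {
      a_b <- add_gaussian_bumps(
        a_b, pts,
        c(regions$start - config$edge_offset, regions$end + config$edge_offset),
        rep(config$edge_height, 2L * nrow(regions)), config$edge_sd)
    }
    list(d = (findInterval(wc + 500, cpg) - findInterval(wc - 500, cpg)) / 10,
         t_bump = as.numeric(tapply(t_b, win, mean)),
         a_bump = as.numeric(tapply(a_b, win, mean)))
  })
  d <- unlist(purrr::map(vals, "d"))
  t_bump <- unlist(purrr::map(vals, "t_bump"))
  a_bump <- unlist(purrr::map(vals, "a_bump"))

  n_bins <- 20L
  ord <- order(d)
  grp <- ceiling(seq_along(ord) / (length(ord) / n_bins))
  bin_mean <- function(x) as.numeric(tapply(x[ord], grp, mean))
  d_bin <- bin_mean(d)

  crossing_at <- function(d_act) {
    s <- pmax(0, 1 - exp(-pmax(0, d - d_act) / config$density_response_scale))
    tt <- bin_mean(t_bump + config$occ_amp * s)
    aa <- bin_mean(a_bump + config$occ_amp * (1 - s))
    dd <- tt / mean(tt) - aa / mean(aa)
    cross <- which(dd[-length(dd)] * dd[-1] < 0)
    if (length(cross) == 0) return(NA_real_)
    j <- cross[1]
    d_bin[j] + (0 - dd[j]) * (d_bin[j + 1] - d_bin[j]) / (dd[j + 1] - dd[j])
  }
  grid <- seq(config$tet1_activation_density,
              max(config$crossing_density * 2, 3), by = 0.01)
  cross <- vapply(grid, crossing_at, numeric(1))
  err <- abs(cross - config$crossing_density)
  out <- if (all(is.na(err))) config$tet1_activation_density else
    grid[which.min(err)]
  crossing_cal_cache[[key]] <- out
  out
}

crossing_cal_cache <- new.env(parent = emptyenv())

# Peak intervals implied by the planted landscape for one protein.
occupancy_peaks <- function(genome, protein, config) {
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          score = integer(), strand = character(),
                          tss_associated = logical())
  regions <- genome$regions[!genome$regions$latent, , drop = FALSE]
  genes <- genome$genes
  prom_peaks <- function(groups, label) {
    g <- genes[genes$tss_group_true %in% groups, , drop = FALSE]
    tibble::tibble(chrom = g$chrom, start = g$tss - 750L, end = g$tss + 750L,
                   name = label, score = 0L, strand = ".",
                   tss_associated = TRUE)
  }
  out <- switch(
    protein,
    TET1 = dplyr::bind_rows(
      tibble::tibble(chrom = regions$chrom, start = regions$start,
                     end = regions$end, name = "TET1_peak", score = 0L,
                     strand = ".", tss_associated = FALSE),
      prom_peaks(c("G1", "G2"), "TET1_peak")),
    DNMT3A1 = dplyr::bind_rows(
      tibble::tibble(chrom = regions$chrom,
                     start = pmax(0L, regions$start - 2000L),
                     end = regions$start, name = "DNMT3A1_edge", score = 0L,
                     strand = ".", tss_associated = FALSE),
      tibble::tibble(chrom = regions$chrom, start = regions$end,
                     end = regions$end + 2000L, name = "DNMT3A1_edge",
                     score = 0L, strand = ".", tss_associated = FALSE)),
    H3K4me3 = prom_peaks(c("G1", "G2"), "H3K4me3_peak"),
    H3K27me3 = prom_peaks("G1", "H3K27me3_peak"),
    empty
  )
  if (is.null(out)) out <- empty
  dplyr::arrange(out, .data$chrom, .data$start)
}
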