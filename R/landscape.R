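# per-chromosome linear interpolators over bin centers
track_interpolators <- function(track) {
  bw <- track_bin_width(track)
  split(track, track$chrom) |>
    purrr::map(function(tr) {
      stats::approxfun(tr$start + bw / 2, tr$value, rule = 1)
    })
}

#' Length-normalized meta-profile over a region set
#'
#' Each region's body is resampled to `body_bins` equal-width bins by
#' linear interpolation of the binned signal, flanks are binned at
#' `flank_bin` bp, and bins are averaged across regions with equal weight
#' regardless of region length. Positions beyond the track (chromosome
#' ends) are missing and excluded from the mean.
#'
#' @param track Occupancy track.
#' @param regions Tibble `chrom, start, end`.
#' @param body_bins Number of body bins (default 100).
#' @param flank Flank width in bp (default 5000; use 3000 for gene-body
#'   profiles).
#' @param flank_bin Flank bin width in bp (default 50).
#' @return A tibble of class `meta_profile`:
#'   `segment ("upstream"/"body"/"downstream"), bin, offset, value, n`.
#'   `offset` is bp from the region start (upstream) / fraction of body
#'   length / bp from the region end (downstream).
#' @export
scaled_region_profile <- function(track, regions, body_bins = 100,
                                  flank = 5000, flank_bin = 50) {
  assert_cols(regions, c("chrom", "start", "end"), "regions")
  if (nrow(regions) == 0) abort("`regions` is empty")
  bw <- track_bin_width(track)
  keep <- (regions$end - regions$start) >= bw
  if (any(!keep)) {
    warn(sprintf("%d region(s) shorter than one track bin skipped",
                 sum(!keep)))
    regions <- regions[keep, , drop = FALSE]
  }
  fns <- track_interpolators(track)
  n_fl <- as.integer(flank / flank_bin)

  rows <- purrr::pmap(regions[, c("chrom", "start", "end")],
                      function(chrom, start, end) {
    f <- fns[[chrom]]
    if (is.null(f)) return(NULL)
    up <- f(start - flank + (seq_len(n_fl) - 0.5) * flank_bin)
    body <- f(start + (seq_len(body_bins) - 0.5) / body_bins * (end - start))
    down <- f(end + (seq_len(n_fl) - 0.5) * flank_bin)
    c(up, body, down)
  })
  mat <- do.call(rbind, rows)
  prof <- tibble::tibble(
    segment = rep(c("upstream", "body", "downstream"),
                  c(n_fl, body_bins, n_fl)),
    bin = seq_len(2L * n_fl + body_bins),
    offset = c((seq_len(n_fl) - 0.5) * flank_bin - flank,
               (seq_len(body_bins) - 0.5) / body_bins,
               (seq_len(n_fl) - 0.5) * flank_bin),
    value = colMeans(mat, na.rm = TRUE),
    n = colSums(!is.na(mat))
  )
  structure(prof, class = c("meta_profile", class(prof)),
            body_bins = body_bins, flank = flank, flank_bin = flank_bin,
            n_regions = nrow(mat))
}

#' Strand-oriented occupancy matrix around TSSs
#'
#' One row per gene, binned signal over TSS +/- `flank`; minus-strand rows
#' are reversed so downstream of the TSS is always rightward. Positions
#' off the end of the track are `NA`.
#'
#' @param track Occupancy track.
#' @param genes Tibble `gene_id, chrom, tss, strand`.
#' @param flank Flank width in bp (default 5000).
#' @param bin Bin width in bp (default 50).
#' @return Tibble of class `tss_matrix`: `gene_id` plus `2 * flank / bin`
#'   signal columns `b1..bN` ordered upstream to downstream.
#' @export
tss_matrix <- function(track, genes, flank = 5000, bin = 50) {
  assert_cols(genes, c("gene_id", "chrom", "tss", "strand"), "genes")
  bad <- !genes$strand %in% c("+", "-")
  if (any(bad)) {
    abort(sprintf("unknown strand for gene(s): %s",
                  paste(head(genes$gene_id[bad], 5), collapse = ", ")))
  }
  fns <- track_interpolators(track)
  n_bins <- as.integer(2 * flank / bin)
  offsets <- -flank + (seq_len(n_bins) - 0.5) * bin
  rows <- purrr::pmap(genes[, c("chrom", "tss", "strand")],
                      function(chrom, tss, strand) {
    f <- fns[[chrom]]
    if (is.null(f)) return(rep(NA_real_, n_bins))
    v <- f(tss + offsets)
    if (strand == "-") rev(v) else v
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- paste0("b", seq_len(n_bins))
  out <- dplyr::bind_cols(tibble::tibble(gene_id = genes$gene_id),
                          tibble::as_tibble(mat))
  structure(out, class = c("tss_matrix", class(out)),
            flank = flank, bin = bin)
}

#' CpG-density-stratified binding profile and crossing point
#'
#' Included windows are ranked by CpG density and grouped into
#' `n_bins` equal-count bins; each bin records its mean density and the
#' mean enrichment (window signal over the track's included-window mean)
#' of every track. The crossing point of two tracks is the density at
#' which the sign of their enrichment difference changes, located by
#' linear interpolation between adjacent bin centers.
#'
#' @param tracks Named list of occupancy tracks.
#' @param windows [build_windows()] output.
#' @param n_bins Number of equal-count density bins (default 20).
#' @return Tibble of class `density_profile`:
#'   `bin, density, track, enrichment`.
#' @export
density_profile <- function(tracks, windows, n_bins = 20) {
  if (length(tracks) < 2 || is.null(names(tracks))) {
    abort("`tracks` must be a named list of at least two tracks")
  }
  wins <- windows[windows$included, , drop = FALSE]
  if (nrow(wins) < n_bins) {
    abort("fewer included windows than density bins",
          class = "canyonscape_data_error")
  }
  ord <- order(wins$cpg_density)
  grp <- ceiling(seq_along(ord) / (length(ord) / n_bins))
  out <- purrr::imap(tracks, function(tr, nm) {
    sig <- window_signal(tr, wins)
    enr <- sig / mean(sig, na.rm = TRUE)
    tibble::tibble(
      bin = seq_len(n_bins),
      density = as.numeric(tapply(wins$cpg_density[ord], grp, mean)),
      track = nm,
      enrichment = as.numeric(tapply(enr[ord], grp, mean, na.rm = TRUE)))
  }) |> dplyr::bind_rows()
  structure(out, class = c("density_profile", class(out)), n_bins = n_bins)
}

#' @rdname density_profile
#' @param profile A `density_profile` tibble.
#' @param track_a,track_b Track names to compare.
#' @return `crossing_point()`: the CpG density (per 100 bp) at the first
#'   sign change of `enrichment(track_a) - enrichment(track_b)`, or `NA`
#'   if the curves never cross.
#' @export
crossing_point <- function(profile, track_a, track_b) {
  a <- profile[profile$track == track_a, , drop = FALSE]
  b <- profile[profile$track == track_b, , drop = FALSE]
  stopifnot(nrow(a) == nrow(b), nrow(a) >= 2)
  d <- a$enrichment - b$enrichment
  s <- which(d[-length(d)] * d[-1] < 0)
  if (length(s) == 0) {
    z <- which(d == 0)
    return(if (length(z) > 0) a$density[z[1]] else NA_real_)
  }
  j <- s[1]
  a$density[j] + (0 - d[j]) * (a$density[j + 1] - a$density[j]) /
    (d[j + 1] - d[j])
}

#' Normalized peak coordinate
#'
#' Maps a genomic position to the coordinate system of a peak: 0 at the
#' peak center, -1/+1 at the left/right peak edges, linear beyond the peak
#' in half-width units. Strictly monotone and invertible.
#'
#' @param pos Genomic position(s).
#' @param peak_start,peak_end Peak interval (half-open, `end > start`).
#' @return Numeric `u` value(s).
#' @export
#' @examples
#' to_peak_coordinate(c(1000, 1500, 2000), 1000, 2000)
to_peak_coordinate <- function(pos, peak_start, peak_end) {
  if (any(peak_end <= peak_start)) {
    abort("peak length must be > 0", class = "canyonscape_data_error")
  }
  center <- (peak_start + peak_end) / 2
  half_width <- (peak_end - peak_start) / 2
  (pos - center) / half_width
}

#' Histogram of DMR positions in peak coordinates
#'
#' Each DMR midpoint is mapped to the normalized coordinate of its nearest
#' peak (minimal center distance on the same chromosome; ties resolved to
#' the lower-coordinate peak) and counts are binned over `u_range`,
#' normalized to a density.
#'
#' @param dmrs Tibble `chrom, start, end`.
#' @param peaks Tibble `chrom, start, end` of peaks (non-empty).
#' @param u_range Range of the normalized coordinate (default `c(-3, 3)`).
#' @param n_bins Histogram bins (default 60).
#' @return Tibble `u_mid, count, density`.
#' @export
dmr_peak_histogram <- function(dmrs, peaks, u_range = c(-3, 3), n_bins = 60) {
  if (nrow(peaks) == 0) abort("`peaks` is empty",
                              class = "canyonscape_data_error")
  mid <- (dmrs$start + dmrs$end) / 2
  u <- purrr::map_dbl(seq_len(nrow(dmrs)), function(i) {
    p <- peaks[peaks$chrom == dmrs$chrom[i], , drop = FALSE]
    if (nrow(p) == 0) return(NA_real_)
    pc <- (p$start + p$end) / 2
    dist <- abs(mid[i] - pc)
    j <- which(dist == min(dist))
    j <- j[which.min(p$start[j])]
    to_peak_coordinate(mid[i], p$start[j], p$end[j])
  })
  u <- u[!is.na(u) & u >= u_range[1] & u <= u_range[2]]
  breaks <- seq(u_range[1], u_range[2], length.out = n_bins + 1)
  counts <- as.integer(table(cut(u, breaks, include.lowest = TRUE)))
  width <- diff(breaks)[1]
  tibble::tibble(u_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 count = counts,
                 density = if (length(u) > 0) counts / (length(u) * width)
                           else 0)
}

#' Promoter CpG density
#'
#' CpGs per 100 bp in the strand-oriented promoter window `[TSS - 1 kb,
#' TSS + 0.5 kb)`; for minus-strand genes the window covers
#' `[TSS - 0.5 kb, TSS + 1 kb)` in plus-strand coordinates. Windows
#' truncated at chromosome bounds use the truncated length.
#'
#' @param genes Tibble `gene_id, chrom, tss, strand`.
#' @param cpg Tibble `chrom, pos`.
#' @param chrom_sizes Optional tibble `chrom, length`.
#' @param upstream,downstream Window extent in bp (defaults 1000 and 500).
#' @return Tibble `gene_id, cpg_density`.
#' @export
promoter_cpg_density <- function(genes, cpg, chrom_sizes = NULL,
                                 upstream = 1000, downstream = 500) {
  assert_cols(genes, c("gene_id", "chrom", "tss", "strand"), "genes")
  bad <- !genes$strand %in% c("+", "-")
  if (any(bad)) abort("unknown strand in `genes`")
  lo <- ifelse(genes$strand == "+", genes$tss - upstream,
               genes$tss - downstream)
  hi <- ifelse(genes$strand == "+", genes$tss + downstream,
               genes$tss + upstream)
  lo <- pmax(lo, 0)
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes$length[match(genes$chrom, chrom_sizes$chrom)]
    hi <- pmin(hi, lim)
  }
  cpg_by <- split(sort(cpg$pos), cpg$chrom)
  count <- purrr::map_dbl(seq_len(nrow(genes)), function(i) {
    p <- cpg_by[[genes$chrom[i]]] %||% integer()
    findInterval(hi[i] - 1e-9, p) - findInterval(lo[i] - 1e-9, p)
  })
  tibble::tibble(gene_id = genes$gene_id,
                 cpg_density = count / (hi - lo) * 100)
}

#' Select TSS-associated peaks
#'
#' Peaks whose center lies within `max_dist` bp of any TSS. This is the
#' selection rule used before peak-coordinate analyses of promoter-bound
#' TET1; the distance threshold is configurable.
#'
#' @param peaks Tibble `chrom, start, end`.
#' @param genes Tibble `chrom, tss`.
#' @param max_dist Maximum center-to-TSS distance in bp (default 1000).
#' @return The subset of `peaks` passing the rule.
#' @export
tss_associated_peaks <- function(peaks, genes, max_dist = 1000) {
  assert_cols(peaks, c("chrom", "start", "end"), "peaks")
  assert_cols(genes, c("chrom", "tss"), "genes")
  keep <- vapply(seq_len(nrow(peaks)), function(i) {
    tss <- genes$tss[genes$chrom == peaks$chrom[i]]
    if (length(tss) == 0) return(FALSE)
    center <- (peaks$start[i] + peaks$end[i]) / 2
    any(abs(center - tss) <= max_dist)
  }, logical(1))
  peaks[keep, , drop = FALSE]
}
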