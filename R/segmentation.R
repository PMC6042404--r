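#' Segmentation parameters
#'
#' Parameters for two-state HMM methylome segmentation and UMR/canyon
#' classification. Defaults implement the standard definitions: regions
#' with mean methylation at or below 10%, a 1-kb minimum length, the
#' 3.5-kb canyon threshold, and 2-kb canyon edges.
#'
#' @param max_region_meth Maximum region mean methylation (default 0.10).
#' @param min_umr_len Minimum reported region length, bp (default 1000).
#' @param canyon_len Length (bp) at and above which a region is a canyon
#'   (default 3500).
#' @param edge_flank Canyon edge width, bp (default 2000).
#' @param max_cpg_gap CpG runs are broken where consecutive CpGs are
#'   farther apart than this (default 2000 bp), so CpG deserts are never
#'   bridged.
#' @param p_low,p_high Initial emission methylation probabilities of the
#'   low/high state (re-estimated by EM).
#' @param trans_stay_low,trans_stay_high Initial self-transition
#'   probabilities.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @return A validated list of class `seg_params`.
#' @export
seg_params <- function(max_region_meth = 0.10, min_umr_len = 1000,
                       canyon_len = 3500, edge_flank = 2000,
                       max_cpg_gap = 2000, p_low = 0.05, p_high = 0.75,
                       trans_stay_low = 0.98, trans_stay_high = 0.999,
                       max_iter = 50, tol = 1e-4) {
  p <- as.list(environment())
  assert_fraction(p$max_region_meth, "max_region_meth", open = TRUE)
  if (p$min_umr_len >= p$canyon_len) {
    abort("`min_umr_len` must be smaller than `canyon_len`",
          class = "canyonscape_config_error")
  }
  if (p$edge_flank < 0) {
    abort("`edge_flank` must be >= 0", class = "canyonscape_config_error")
  }
  structure(p, class = "seg_params")
}

#' Segment a methylome into candidate low-methylation regions
#'
#' Decodes a two-state (low/high methylation) hidden Markov model over the
#' per-CpG counts: emissions are binomial with state-specific methylation
#' probabilities re-estimated by EM (deterministic initialization, no
#' random restarts), decoding is by posterior state probability with a 0.5
#' threshold (ties fall to the high state). Maximal runs of low-state CpGs
#' become candidate segments spanning first to last CpG of the run; runs
#' are broken at CpG gaps larger than `max_cpg_gap`, and candidates whose
#' coverage-weighted mean methylation exceeds `max_region_meth` are
#' discarded.
#'
#' @param track Methylome tibble (`chrom, pos, meth, total`), sorted by
#'   position within chromosome. Zero-coverage sites are ignored.
#' @param params A [seg_params()] object.
#' @return Tibble of candidate segments:
#'   `chrom, start, end, n_cpgs, mean_ratio` (half-open coordinates).
#' @export
segment_methylome <- function(track, params = seg_params()) {
  stopifnot(inherits(params, "seg_params"))
  assert_cols(track, c("chrom", "pos", "meth", "total"), "track")
  track <- track[track$total > 0, , drop = FALSE]
  if (nrow(track) < 2) {
    warn("fewer than 2 covered CpGs; no segmentation performed")
    return(empty_segments())
  }
  track <- dplyr::arrange(track, .data$chrom, .data$pos)

  # blocks: per chromosome, split at CpG gaps > max_cpg_gap
  new_chrom <- track$chrom != dplyr::lag(track$chrom, default = "")
  gap <- c(TRUE, diff(track$pos) > params$max_cpg_gap)
  block <- cumsum(new_chrom | gap)
  blocks <- split(seq_len(nrow(track)), block)

  fit <- hmm_em(track$meth, track$total, blocks, params)
  low <- fit$gamma_low > 0.5  # tie -> high state (conservative)

  segs <- purrr::map(blocks, function(idx) {
    runs <- rle(low[idx])
    if (!any(runs$values)) return(NULL)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- which(runs$values)
    purrr::map(keep, function(k) {
      i <- idx[starts[k]:ends[k]]
      tibble::tibble(chrom = track$chrom[i[1]],
                     start = track$pos[i[1]],
                     end = track$pos[i[length(i)]] + 1L,
                     n_cpgs = length(i),
                     mean_ratio = sum(track$meth[i]) / sum(track$total[i]))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (nrow(segs) == 0) return(empty_segments())
  segs <- segs[segs$mean_ratio <= params$max_region_meth, , drop = FALSE]
  dplyr::arrange(segs, .data$chrom, .data$start)
}

empty_segments <- function() {
  tibble::tibble(chrom = character(), start = integer(), end = integer(),
                 n_cpgs = integer(), mean_ratio = numeric())
}

# Baum-Welch over binomial emissions; state 1 is kept as the low state.
hmm_em <- function(meth, total, blocks, params) {
  p <- c(params$p_low, params$p_high)
  trans <- matrix(c(params$trans_stay_low, 1 - params$trans_stay_low,
                    1 - params$trans_stay_high, params$trans_stay_high),
                  2, 2, byrow = TRUE)
  pi0 <- c(0.1, 0.9)
  prev_ll <- -Inf
  gamma_low <- numeric(length(meth))

  for (iter in seq_len(params$max_iter)) {
    ll <- 0
    g_m <- c(0, 0); g_t <- c(0, 0)
    xi <- matrix(0, 2, 2)
    init <- c(0, 0)
    for (idx in blocks) {
      emis <- cbind(dbinom(meth[idx], total[idx], p[1]),
                    dbinom(meth[idx], total[idx], p[2]))
      emis[emis < 1e-300] <- 1e-300
      fb <- fb_two_state(emis, trans, pi0)
      ll <- ll + fb$loglik
      gamma_low[idx] <- fb$gamma[, 1]
      g_m <- g_m + c(sum(fb$gamma[, 1] * meth[idx]),
                     sum(fb$gamma[, 2] * meth[idx]))
      g_t <- g_t + c(sum(fb$gamma[, 1] * total[idx]),
                     sum(fb$gamma[, 2] * total[idx]))
      xi <- xi + fb$xi
      init <- init + fb$initial
    }
    converged <- is.finite(prev_ll) &&
      abs(ll - prev_ll) < params$tol * (abs(prev_ll) + 1)
    prev_ll <- ll
    if (converged) break

    p_new <- pmin(pmax(g_m / pmax(g_t, 1e-12), 1e-6), 1 - 1e-6)
    if (p_new[1] > p_new[2]) p_new <- rev(p_new)  # state 1 stays "low"
    p <- p_new
    if (sum(xi) > 0) {
      trans <- xi / pmax(rowSums(xi), 1e-12)
      trans <- pmin(pmax(trans, 1e-6), 1 - 1e-6)
      trans <- trans / rowSums(trans)
    }
    pi0 <- pmin(pmax(init / length(blocks), 1e-6), 1 - 1e-6)
    pi0 <- pi0 / sum(pi0)
  }
  list(gamma_low = gamma_low, p = p, trans = trans, pi = pi0,
       loglik = prev_ll, iterations = iter)
}

#' Classify candidate segments into UMRs and canyons
#'
#' Segments shorter than `min_umr_len` are excluded; lengths in
#' `[min_umr_len, canyon_len)` are UMRs; lengths at or above `canyon_len`
#' are canyons.
#'
#' @param segments Output of [segment_methylome()].
#' @param params A [seg_params()] object.
#' @return Tibble of regions with `klass` (`"UMR"`/`"CANYON"`) and
#'   `region_id`.
#' @export
classify_regions <- function(segments, params = seg_params()) {
  stopifnot(inherits(params, "seg_params"))
  len <- segments$end - segments$start
  out <- segments[len >= params$min_umr_len, , drop = FALSE]
  len <- out$end - out$start
  out$klass <- ifelse(len >= params$canyon_len, "CANYON", "UMR")
  out$region_id <- if (nrow(out) > 0) {
    sprintf("%s_%s_%05d", out$klass, out$chrom, seq_len(nrow(out)))
  } else character()
  out
}

#' Call UMRs and canyons from a methylome track
#'
#' Convenience wrapper: [segment_methylome()] then [classify_regions()].
#'
#' @inheritParams segment_methylome
#' @return Classified region tibble (see [classify_regions()]).
#' @export
call_meth_regions <- function(track, params = seg_params()) {
  classify_regions(segment_methylome(track, params), params)
}

#' Canyon edge intervals
#'
#' The canyon edge is the pair of `flank`-bp intervals immediately flanking
#' a region: left `[start - flank, start)` and right `[end, end + flank)`,
#' truncated at chromosome bounds.
#'
#' @param regions Region tibble (`chrom, start, end`, optionally
#'   `region_id`).
#' @param flank Edge width in bp (default 2000).
#' @param chrom_sizes Optional tibble `chrom, length` for right-side
#'   truncation.
#' @return Tibble `region_id, side, chrom, start, end` with two rows per
#'   region.
#' @export
#' @examples
#' canyon_edges(tibble::tibble(chrom = "chr1", start = 10000, end = 14000))
canyon_edges <- function(regions, flank = 2000, chrom_sizes = NULL) {
  assert_cols(regions, c("chrom", "start", "end"), "regions")
  if (flank < 0) abort("`flank` must be >= 0")
  id <- if ("region_id" %in% names(regions)) regions$region_id else
    as.character(seq_len(nrow(regions)))
  left <- tibble::tibble(region_id = id, side = "left",
                         chrom = regions$chrom,
                         start = pmax(0L, as.integer(regions$start - flank)),
                         end = as.integer(regions$start))
  right <- tibble::tibble(region_id = id, side = "right",
                          chrom = regions$chrom,
                          start = as.integer(regions$end),
                          end = as.integer(regions$end + flank))
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes$length[match(right$chrom, chrom_sizes$chrom)]
    right$end <- pmin(right$end, as.integer(lim))
    right$start <- pmin(right$start, right$end)
  }
  dplyr::arrange(dplyr::bind_rows(left, right), .data$chrom, .data$start)
}
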