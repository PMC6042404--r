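#' Occupancy track constructor and accessors
#'
#' An occupancy track is a tibble `chrom, start, value` on a constant bin
#' grid; `bin_width`, and optionally `sample` and `total_tags`, travel as
#' attributes.
#'
#' @param df Tibble with `chrom, start, value`.
#' @param bin_width Bin width in bp.
#' @param sample,total_tags Optional labels.
#' @return The tibble with track attributes set.
#' @export
new_occupancy_track <- function(df, bin_width, sample = NULL,
                                total_tags = NULL) {
  assert_cols(df, c("chrom", "start", "value"), "df")
  attr(df, "bin_width") <- as.integer(bin_width)
  if (!is.null(sample)) attr(df, "sample") <- sample
  if (!is.null(total_tags)) attr(df, "total_tags") <- total_tags
  df
}

#' @rdname new_occupancy_track
#' @param track An occupancy track.
#' @export
track_bin_width <- function(track) {
  bw <- attr(track, "bin_width")
  if (!is.null(bw)) return(as.integer(bw))
  s <- sort(unique(track$start))
  if (length(s) < 2) return(1L)
  as.integer(min(diff(s)))
}

check_same_grid <- function(a, b) {
  if (nrow(a) != nrow(b) || !identical(a$chrom, b$chrom) ||
      !identical(as.integer(a$start), as.integer(b$start))) {
    abort("tracks are not on the same bin grid",
          class = "canyonscape_data_error")
  }
  invisible(TRUE)
}

#' Depth-normalize a track and subtract its matched input
#'
#' Both tracks are scaled to a common total tag count (`target_depth`),
#' the input is subtracted bin-wise, and negative results are floored at 0
#' (occupancy cannot be negative). Depth normalization alone is
#' idempotent.
#'
#' @param raw Occupancy track.
#' @param input Matched input track on the same grid, or `NULL` to skip
#'   subtraction.
#' @param target_depth Common total tag count (default 1e6).
#' @return Normalized occupancy track.
#' @export
normalize_track <- function(raw, input = NULL, target_depth = 1e6) {
  assert_cols(raw, c("chrom", "start", "value"), "raw")
  out <- raw
  out$value <- raw$value * (target_depth / sum(raw$value))
  if (!is.null(input)) {
    check_same_grid(raw, input)
    inp <- input$value * (target_depth / sum(input$value))
    out$value <- pmax(0, out$value - inp)
  }
  new_occupancy_track(out, track_bin_width(raw),
                      sample = attr(raw, "sample"),
                      total_tags = target_depth)
}

#' Spike-in scale factor and its application
#'
#' The spike-in factor for a sample is `reference_count / spike_count`,
#' computed from exogenous (e.g. Drosophila) chromatin tags sequenced
#' alongside the sample; multiplying the occupancy signal by it puts
#' conditions on a common scale. Factors compose multiplicatively.
#'
#' @param spike_count Spike-genome tag count of the sample (> 0), or a
#'   tibble with `spike_count` and `reference_count` columns.
#' @param reference_count Reference tag count (> 0).
#' @return A single scale factor.
#' @export
#' @examples
#' spike_in_factor(2e5, 1e5)  # sequenced 2x deeper -> factor 0.5
spike_in_factor <- function(spike_count, reference_count = NULL) {
  if (is.data.frame(spike_count)) {
    reference_count <- spike_count$reference_count
    spike_count <- spike_count$spike_count
  }
  if (any(spike_count <= 0) || any(reference_count <= 0)) {
    abort("spike-in counts must be > 0", class = "canyonscape_data_error")
  }
  reference_count / spike_count
}

#' @rdname spike_in_factor
#' @param track Occupancy track.
#' @param factor Scale factor from [spike_in_factor()].
#' @export
apply_spike <- function(track, factor) {
  track$value <- track$value * factor
  track
}

#' Tile the genome into 1-kb analysis windows with exclusions
#'
#' Windows overlapping satellite repeats (by >= 1 bp), windows with no
#' WGBS-covered CpG, and windows with no input coverage are flagged and
#' excluded from downstream statistics. Per-window CpG density is recorded
#' as CpGs per 100 bp.
#'
#' @param chrom_sizes Tibble `chrom, length`.
#' @param cpg Tibble `chrom, pos` of CpG positions.
#' @param wgbs_track Optional methylome tibble (`chrom, pos, total`); when
#'   given, windows with no covered CpG are excluded.
#' @param input_track Optional input occupancy track; windows with zero
#'   input signal are excluded.
#' @param satellite Optional tibble `chrom, start, end` of satellite
#'   intervals.
#' @param window Window width in bp (default 1000).
#' @return Tibble `chrom, start, end, cpg_density, satellite, no_wgbs,
#'   no_input, included`.
#' @export
build_windows <- function(chrom_sizes, cpg, wgbs_track = NULL,
                          input_track = NULL, satellite = NULL,
                          window = 1000) {
  assert_cols(chrom_sizes, c("chrom", "length"), "chrom_sizes")
  wins <- purrr::map2(chrom_sizes$chrom, chrom_sizes$length, function(ch, L) {
    start <- seq.int(0L, L - window, by = window)
    tibble::tibble(chrom = ch, start = start, end = start + as.integer(window))
  }) |> dplyr::bind_rows()

  count_in <- function(positions_by_chrom) {
    purrr::map2(chrom_sizes$chrom, chrom_sizes$length, function(ch, L) {
      p <- positions_by_chrom[[ch]] %||% integer()
      w <- wins[wins$chrom == ch, ]
      findInterval(w$end, p) - findInterval(w$start, p)
    }) |> unlist()
  }
  cpg_by <- split(sort(cpg$pos), cpg$chrom)
  wins$cpg_density <- count_in(cpg_by) / window * 100

  wins$satellite <- FALSE
  if (!is.null(satellite) && nrow(satellite) > 0) {
    for (ch in unique(satellite$chrom)) {
      s <- satellite[satellite$chrom == ch, ]
      i <- wins$chrom == ch
      wins$satellite[i] <- purrr::map_lgl(which(i), function(j) {
        any(interval_overlap(wins$start[j], wins$end[j], s$start, s$end) > 0)
      })
    }
  }

  wins$no_wgbs <- FALSE
  if (!is.null(wgbs_track)) {
    cov <- wgbs_track[wgbs_track$total > 0, , drop = FALSE]
    cov_by <- split(sort(cov$pos), cov$chrom)
    wins$no_wgbs <- count_in(cov_by) == 0
  }

  wins$no_input <- FALSE
  if (!is.null(input_track)) {
    sig <- window_signal(input_track, wins)
    wins$no_input <- is.na(sig) | sig <= 0
  }

  wins$included <- !wins$satellite & !wins$no_wgbs & !wins$no_input
  wins
}

# Mean track signal per window (bins assigned by bin start).
window_signal <- function(track, windows) {
  bw <- track_bin_width(track)
  w <- windows$end[1] - windows$start[1]
  agg <- track |>
    dplyr::mutate(wstart = (.data$start %/% w) * as.integer(w)) |>
    dplyr::summarise(signal = mean(.data$value),
                     .by = c("chrom", "wstart"))
  agg$signal[match(paste(windows$chrom, windows$start),
                   paste(agg$chrom, agg$wstart))]
}

#' Relative binding enrichment by genomic feature class
#'
#' Enrichment of a feature class is the mean included-window signal over
#' windows assigned to the class divided by the mean signal over all
#' included windows ("average genomic distribution"). Windows are assigned
#' to a class when their midpoint falls inside one of its intervals;
#' classes need not be mutually exclusive. Empty classes are dropped with
#' a warning.
#'
#' @param track Normalized occupancy track.
#' @param features Tibble `chrom, start, end, class` of feature intervals
#'   (strand-aware classes such as distal promoters should be built
#'   strand-aware upstream).
#' @param windows [build_windows()] output.
#' @return Tibble `class, n_windows, enrichment, log2_enrichment`.
#' @export
feature_enrichment <- function(track, features, windows) {
  assert_cols(features, c("chrom", "start", "end", "class"), "features")
  wins <- windows[windows$included, , drop = FALSE]
  wins$signal <- window_signal(track, wins)
  wins <- wins[!is.na(wins$signal), , drop = FALSE]
  global_mean <- mean(wins$signal)
  mid <- (wins$start + wins$end) / 2

  out <- purrr::map(unique(features$class), function(cl) {
    f <- features[features$class == cl, , drop = FALSE]
    hit <- rep(FALSE, nrow(wins))
    for (ch in unique(f$chrom)) {
      fi <- f[f$chrom == ch, ]
      i <- which(wins$chrom == ch)
      if (length(i) == 0) next
      hit[i] <- positions_in_intervals(mid[i], fi$start, fi$end)
    }
    if (!any(hit)) {
      warn(sprintf("feature class '%s' matched no included window; omitted", cl))
      return(NULL)
    }
    tibble::tibble(class = cl, n_windows = sum(hit),
                   enrichment = mean(wins$signal[hit]) / global_mean)
  }) |> dplyr::bind_rows()
  if (nrow(out) == 0) {
    return(tibble::tibble(class = character(), n_windows = integer(),
                          enrichment = numeric(),
                          log2_enrichment = numeric()))
  }
  dplyr::mutate(out, log2_enrichment = log2(.data$enrichment))
}

#' Signed log10-P differential occupancy
#'
#' Per bin, the occupancy difference between a condition and its reference
#' is scored as `sign(A - ref) * |log10 P|`, where `P` is the upper-tail
#' Poisson probability of the larger of the two bin values given the
#' smaller as its expectation (symmetric treatment). Equal bins score 0;
#' `|log10 P|` is capped at 300.
#'
#' @param track_a Condition track (normalized to common depth).
#' @param track_ref Reference track on the same grid.
#' @param cap Maximum `|log10 P|` (default 300).
#' @return Occupancy-track-shaped tibble with `score` instead of `value`.
#' @export
differential_occupancy <- function(track_a, track_ref, cap = 300) {
  check_same_grid(track_a, track_ref)
  a <- track_a$value
  r <- track_ref$value
  hi <- pmax(a, r)
  lo <- pmin(a, r)
  k <- ceiling(hi)
  lp10 <- ppois(k - 1, lo, lower.tail = FALSE, log.p = TRUE) / log(10)
  mag <- pmin(cap, -lp10)
  score <- sign(a - r) * mag
  score[a == r] <- 0
  out <- tibble::tibble(chrom = track_a$chrom, start = track_a$start,
                        score = score)
  attr(out, "bin_width") <- track_bin_width(track_a)
  out
}
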