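#' Per-CpG methylation ratio
#'
#' The methylation ratio of a CpG is the number of methylated (bisulfite
#' unconverted) read observations divided by all read observations covering
#' the site. Sites with zero coverage are flagged as `NA`, never reported
#' as 0.
#'
#' @param meth,total Non-negative integer vectors, `meth <= total`.
#' @return Numeric vector of fractions in `[0, 1]`, `NA` where `total == 0`.
#' @export
#' @examples
#' compute_ratio(c(3, 0, 7), c(10, 5, 7))
compute_ratio <- function(meth, total) {
  if (any(meth < 0 | total < 0, na.rm = TRUE)) {
    abort("counts must be non-negative", class = "canyonscape_data_error")
  }
  if (any(meth > total, na.rm = TRUE)) {
    abort("methylated count exceeds total count",
          class = "canyonscape_data_error")
  }
  ifelse(total > 0, meth / total, NA_real_)
}

#' Trim base calls near the repair end of a read
#'
#' End repair during library construction fills in bases with unmethylated
#' cytosines, biasing calls at the repaired end (visible in an M-bias plot).
#' Calls within `n_bases` of the flagged repair end are dropped; all other
#' calls are preserved in order. Reads shorter than `n_bases` lose all of
#' their calls.
#'
#' @param calls Read-observation tibble with columns
#'   `read_id, mate_id, chrom, strand, start, end, repair_side, pos, meth`;
#'   `repair_side` is `"start"`, `"end"`, or `"none"`, in read coordinates
#'   on the reference.
#' @param n_bases Bases to trim from the repair end (default 3).
#' @return The filtered calls tibble.
#' @export
mbias_trim <- function(calls, n_bases = 3) {
  assert_count(n_bases, "n_bases", positive = FALSE)
  assert_cols(calls, c("read_id", "start", "end", "repair_side", "pos"), "calls")
  if (n_bases == 0 || nrow(calls) == 0) return(calls)
  drop <- (calls$repair_side == "end" & calls$pos >= calls$end - n_bases) |
    (calls$repair_side == "start" & calls$pos < calls$start + n_bases)
  calls[!drop, , drop = FALSE]
}

#' Maximum tolerated duplicates under a Poisson model
#'
#' Given the genome-wide mean rate of read starts per position, returns the
#' smallest `k` such that the upper Poisson tail `P(X >= k + 1)` falls below
#' `p_cutoff`: observing more than `k` reads at one start position is then
#' attributed to PCR amplification rather than sampling.
#'
#' @param lambda Mean reads per start position (> 0).
#' @param p_cutoff Poisson tail probability cutoff (default 1e-5).
#' @return Integer `max_dup >= 1`.
#' @export
#' @examples
#' clonal_max_dup(0.2)  # the "at most two clonal reads" regime
clonal_max_dup <- function(lambda, p_cutoff = 1e-5) {
  if (!is.numeric(lambda) || lambda <= 0) {
    abort("`lambda` must be > 0", class = "canyonscape_data_error")
  }
  k <- 1L
  while (ppois(k, lambda, lower.tail = FALSE) >= p_cutoff) k <- k + 1L
  k
}

#' Remove clonal (PCR duplicate) reads
#'
#' Reads sharing an identical start coordinate and strand beyond the
#' Poisson-justified multiplicity [clonal_max_dup()] are removed; retained
#' reads are chosen deterministically by input order.
#'
#' @inheritParams mbias_trim
#' @param genome_length Total mappable genome length (bp), used with the
#'   read count to set the Poisson rate.
#' @param p_cutoff Poisson tail cutoff (default 1e-5).
#' @param max_dup Optional explicit duplicate cap; when `NULL` it is
#'   computed from the data.
#' @return A list with `max_dup` and the filtered `calls`.
#' @export
clonal_filter <- function(calls, genome_length, p_cutoff = 1e-5,
                          max_dup = NULL) {
  assert_cols(calls, c("read_id", "chrom", "strand", "start"), "calls")
  reads <- dplyr::distinct(calls, .data$read_id, .data$chrom, .data$strand,
                           .data$start)
  if (is.null(max_dup)) {
    lambda <- nrow(reads) / genome_length
    max_dup <- clonal_max_dup(lambda, p_cutoff)
  }
  reads <- reads |>
    dplyr::mutate(.ord = dplyr::row_number()) |>
    dplyr::group_by(.data$chrom, .data$strand, .data$start) |>
    dplyr::mutate(.dup = dplyr::row_number()) |>
    dplyr::ungroup()
  keep_ids <- reads$read_id[reads$.dup <= max_dup]
  list(max_dup = max_dup,
       calls = calls[calls$read_id %in% keep_ids, , drop = FALSE])
}

#' Count mate-overlapping CpG calls once
#'
#' Where the two mates of a read pair overlap, each CpG in the overlap is
#' counted exactly once: the call is taken from the mate that still carries
#' the position after trimming, with ties resolved in favor of the
#' first mate (lower start, then input order). Non-overlapping calls are
#' all preserved.
#'
#' @inheritParams mbias_trim
#' @return Calls tibble with duplicate (mate pair, position) entries
#'   collapsed.
#' @export
mate_overlap_dedup <- function(calls) {
  assert_cols(calls, c("read_id", "mate_id", "chrom", "pos"), "calls")
  if (nrow(calls) == 0) return(calls)
  ord <- order(match(calls$mate_id, unique(calls$mate_id)), calls$start,
               match(calls$read_id, unique(calls$read_id)))
  out <- calls[ord, , drop = FALSE]
  dup <- duplicated(out[, c("mate_id", "chrom", "pos")])
  out[!dup, , drop = FALSE]
}

#' Aggregate filtered read calls into a methylome track
#'
#' Pools calls per CpG (strand-collapsed) into methylated/total counts and
#' the per-site [compute_ratio()]. Intended to run after [mbias_trim()],
#' [clonal_filter()], and [mate_overlap_dedup()].
#'
#' @inheritParams mbias_trim
#' @return Methylome tibble `chrom, pos, meth, total, ratio`, sorted.
#' @export
pileup_methylome <- function(calls) {
  if (nrow(calls) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          meth = integer(), total = integer(),
                          ratio = numeric()))
  }
  assert_cols(calls, c("chrom", "pos", "meth"), "calls")
  calls |>
    dplyr::summarise(meth = sum(.data$meth), total = dplyr::n(),
                     .by = c("chrom", "pos")) |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::mutate(ratio = compute_ratio(.data$meth, .data$total))
}

#' Expand a methylome track into per-read call observations
#'
#' Testing/round-trip helper: emits one single-end call row per covering
#' read of every site, with distinct read ids and starts, so that
#' [pileup_methylome()] run after the read-level filters reproduces the
#' generating counts exactly.
#'
#' @param track Methylome tibble (`chrom, pos, meth, total`).
#' @param read_length Nominal read length used for `start`/`end`.
#' @return A calls tibble in the [mbias_trim()] layout.
#' @export
simulate_read_calls <- function(track, read_length = 100) {
  assert_cols(track, c("chrom", "pos", "meth", "total"), "track")
  track <- track[track$total > 0, , drop = FALSE]
  idx <- rep.int(seq_len(nrow(track)), track$total)
  within <- sequence(track$total)
  start <- pmax(0L, track$pos[idx] - (within * 7L) %% read_length)
  tibble::tibble(
    read_id = sprintf("r%s_%d", track$pos[idx], within),
    mate_id = sprintf("m%s_%d", track$pos[idx], within),
    chrom = track$chrom[idx],
    strand = "+",
    start = start,
    end = start + as.integer(read_length),
    repair_side = "none",
    pos = track$pos[idx],
    meth = as.integer(within <= track$meth[idx])
  )
}
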