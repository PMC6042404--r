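#' Read and write per-CpG methylation tables
#'
#' The on-disk format is a bedGraph-style TSV with columns
#' `chrom, start, end, ratio, meth, total` (0-based half-open; `start` is the
#' position of the C of the CpG on the plus strand). In memory a methylome
#' track is a tibble with columns `chrom, pos, meth, total, ratio`.
#'
#' @param track A methylome tibble (`chrom, pos, meth, total`).
#' @param path File path.
#' @return `read_cpg_table()` returns a methylome tibble; the writer returns
#'   `path` invisibly.
#' @export
write_cpg_table <- function(track, path) {
  assert_cols(track, c("chrom", "pos", "meth", "total"), "track")
  out <- tibble::tibble(
    chrom = track$chrom,
    start = track$pos,
    end = track$pos + 1L,
    ratio = round(compute_ratio(track$meth, track$total), 6),
    meth = track$meth,
    total = track$total
  )
  readr::write_tsv(out, path, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' @rdname write_cpg_table
#' @export
read_cpg_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(df, c("chrom", "start", "meth", "total"), "cpg table")
  tibble::tibble(
    chrom = as.character(df$chrom),
    pos = as.integer(df$start),
    meth = as.integer(df$meth),
    total = as.integer(df$total),
    ratio = compute_ratio(df$meth, df$total)
  )
}

#' Read and write fixed-step occupancy tracks as bedGraph
#'
#' Occupancy tracks are tibbles with columns `chrom, start, value` on a
#' constant bin grid; the bin width is carried in the `bin_width` attribute
#' and reconstructed on read from the first interval.
#'
#' @param track Occupancy tibble with `bin_width` attribute.
#' @param path File path.
#' @export
write_bedgraph <- function(track, path) {
  assert_cols(track, c("chrom", "start", "value"), "track")
  bw <- track_bin_width(track)
  out <- tibble::tibble(chrom = track$chrom, start = track$start,
                        end = track$start + bw, value = round(track$value, 6))
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                        show_col_types = FALSE, progress = FALSE)
  new_occupancy_track(tibble::tibble(
    chrom = as.character(df$chrom), start = as.integer(df$start),
    value = as.numeric(df$value)
  ), bin_width = as.integer(df$end[1] - df$start[1]))
}

#' Read and write interval sets as BED6
#'
#' Regions (UMRs/canyons, edges, peaks, satellite windows) travel as BED6:
#' `chrom, start, end, name, score, strand`. Missing name/score/strand
#' columns are filled with `"."`, `0`, `"."`.
#'
#' @param regions Tibble with at least `chrom, start, end`.
#' @param path File path.
#' @export
write_bed <- function(regions, path) {
  assert_cols(regions, c("chrom", "start", "end"), "regions")
  out <- tibble::tibble(
    chrom = regions$chrom,
    start = regions$start,
    end = regions$end,
    name = if ("name" %in% names(regions)) regions$name else ".",
    score = if ("score" %in% names(regions)) regions$score else 0L,
    strand = if ("strand" %in% names(regions)) regions$strand else "."
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                            "score", "strand"),
                        show_col_types = FALSE, progress = FALSE)
  tibble::tibble(chrom = as.character(df$chrom), start = as.integer(df$start),
                 end = as.integer(df$end), name = as.character(df$name),
                 score = df$score, strand = as.character(df$strand))
}
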