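#' Differential methylation parameters
#'
#' Defaults implement the standard calling rules: DMCs at credible
#' difference `>= 0.2` for CpGs with at least three reads in both samples,
#' and DMRs as runs of more than three (i.e. at least four) same-direction
#' DMCs with consecutive spacing within 300 bp.
#'
#' @param cdif_cutoff Minimum `|credible difference|` for a DMC.
#' @param min_reads Minimum coverage required in both samples.
#' @param merge_window Maximum spacing (bp) between consecutive DMCs of a
#'   DMR.
#' @param min_run Minimum number of same-direction DMCs in a DMR.
#' @param credible_level Credible level of the equal-tailed interval.
#' @param prior Beta prior pseudo-counts `c(alpha, beta)` (uniform by
#'   default).
#' @param n_draws Monte-Carlo posterior draws per site.
#' @return A validated list of class `dm_params`.
#' @export
dm_params <- function(cdif_cutoff = 0.2, min_reads = 3, merge_window = 300,
                      min_run = 4, credible_level = 0.95,
                      prior = c(1, 1), n_draws = 40000) {
  p <- as.list(environment())
  assert_fraction(p$cdif_cutoff, "cdif_cutoff", open = TRUE)
  assert_count(p$min_reads, "min_reads")
  if (p$min_run < 2) abort("`min_run` must be >= 2",
                           class = "canyonscape_config_error")
  assert_fraction(p$credible_level, "credible_level", open = TRUE)
  structure(p, class = "dm_params")
}

#' Credible methylation difference between two samples
#'
#' With independent `Beta(m + alpha, t - m + beta)` posteriors for the two
#' methylation proportions, the credible difference is the conservative
#' bound of the equal-tailed credible interval of `p2 - p1`: the lower
#' bound when the interval lies above 0, the upper bound when it lies below
#' 0, and exactly 0 when the interval spans 0. Intervals are computed by
#' Monte Carlo over `n_draws` posterior draws with a fixed seed
#' (deterministic given `seed`); antisymmetry under sample swap is exact
#' because each pair is evaluated in a canonical order and sign-flipped.
#'
#' @param m1,t1,m2,t2 Methylated/total counts in sample 1 and sample 2
#'   (vectorized).
#' @param prior Beta prior pseudo-counts `c(alpha, beta)`.
#' @param level Credible level (default 0.95).
#' @param n_draws Posterior draws per site.
#' @param seed Seed for the posterior draws.
#' @return Signed numeric vector in `[-1, 1]`; positive = sample 2 more
#'   methylated.
#' @export
#' @examples
#' credible_difference(0, 30, 30, 30)
credible_difference <- function(m1, t1, m2, t2, prior = c(1, 1),
                                level = 0.95, n_draws = 40000, seed = 1L) {
  n <- max(length(m1), length(t1), length(m2), length(t2))
  m1 <- rep_len(m1, n); t1 <- rep_len(t1, n)
  m2 <- rep_len(m2, n); t2 <- rep_len(t2, n)
  if (any(t1 < 1 | t2 < 1)) {
    abort("zero-coverage site passed to credible_difference",
          class = "canyonscape_data_error")
  }
  if (any(m1 > t1 | m2 > t2 | m1 < 0 | m2 < 0)) {
    abort("invalid counts", class = "canyonscape_data_error")
  }
  # canonical per-site order makes cdif(a, b) == -cdif(b, a) exactly
  swap <- (m1 > m2) | (m1 == m2 & t1 > t2)
  a1 <- ifelse(swap, m2, m1); b1 <- ifelse(swap, t2, t1)
  a2 <- ifelse(swap, m1, m2); b2 <- ifelse(swap, t1, t2)

  set.seed(as.integer(seed))
  plo <- (1 - level) / 2
  q <- beta_diff_quantiles(a1 + prior[1], b1 - a1 + prior[2],
                           a2 + prior[1], b2 - a2 + prior[2],
                           as.integer(n_draws), plo, 1 - plo)
  out <- ifelse(q[, 1] > 0, q[, 1], ifelse(q[, 2] < 0, q[, 2], 0))
  ifelse(swap, -out, out)
}

#' Call differentially methylated CpGs between two methylome tracks
#'
#' Tests CpGs present in both tracks with coverage of at least
#' `params$min_reads` in both samples; a site is a DMC when
#' `|credible difference| >= params$cdif_cutoff`. Direction is sample 2
#' (`track_b`) relative to sample 1.
#'
#' @param track_a,track_b Methylome tibbles (`chrom, pos, meth, total`).
#' @param params A [dm_params()] object.
#' @param seed Seed forwarded to [credible_difference()].
#' @return Tibble of tested sites:
#'   `chrom, pos, meth_a, total_a, meth_b, total_b, cdif, direction,
#'   is_dmc`. Direction is `"hyper"`/`"hypo"` (of `track_b` vs `track_a`)
#'   or `NA` when `cdif == 0`.
#' @export
call_dmcs <- function(track_a, track_b, params = dm_params(), seed = 1L) {
  stopifnot(inherits(params, "dm_params"))
  assert_cols(track_a, c("chrom", "pos", "meth", "total"), "track_a")
  assert_cols(track_b, c("chrom", "pos", "meth", "total"), "track_b")
  shared <- dplyr::inner_join(
    dplyr::select(track_a, "chrom", "pos", meth_a = "meth", total_a = "total"),
    dplyr::select(track_b, "chrom", "pos", meth_b = "meth", total_b = "total"),
    by = c("chrom", "pos"))
  n_skipped <- nrow(track_a) + nrow(track_b) - 2L * nrow(shared)
  if (n_skipped > 0) {
    rlang::inform(sprintf("%d non-shared site record(s) skipped", n_skipped))
  }
  tested <- shared[shared$total_a >= params$min_reads &
                     shared$total_b >= params$min_reads, , drop = FALSE]
  tested <- dplyr::arrange(tested, .data$chrom, .data$pos)
  if (nrow(tested) == 0) {
    return(dplyr::mutate(tested, cdif = numeric(), direction = character(),
                         is_dmc = logical()))
  }
  cdif <- credible_difference(tested$meth_a, tested$total_a,
                              tested$meth_b, tested$total_b,
                              prior = params$prior,
                              level = params$credible_level,
                              n_draws = params$n_draws, seed = seed)
  dplyr::mutate(tested, cdif = cdif,
                direction = dplyr::case_when(cdif > 0 ~ "hyper",
                                             cdif < 0 ~ "hypo",
                                             TRUE ~ NA_character_),
                is_dmc = abs(cdif) >= params$cdif_cutoff)
}

#' Merge DMC runs into differentially methylated regions
#'
#' Maximal runs of same-direction DMCs in which every adjacent pair lies
#' within `merge_window` bp, with no intervening opposite-direction DMC,
#' become DMRs when the run contains at least `min_run` DMCs. Non-DMC CpGs
#' never break a run.
#'
#' @param dmcs Output of [call_dmcs()] (rows with `is_dmc == FALSE` are
#'   ignored), or any tibble with `chrom, pos, cdif, direction`.
#' @param params A [dm_params()] object.
#' @return Tibble `chrom, start, end, direction, n_dmcs, mean_cdif`.
#' @export
merge_dmrs <- function(dmcs, params = dm_params()) {
  stopifnot(inherits(params, "dm_params"))
  assert_cols(dmcs, c("chrom", "pos", "cdif", "direction"), "dmcs")
  if ("is_dmc" %in% names(dmcs)) dmcs <- dmcs[dmcs$is_dmc, , drop = FALSE]
  dmcs <- dplyr::arrange(dmcs, .data$chrom, .data$pos)
  if (nrow(dmcs) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), direction = character(),
                          n_dmcs = integer(), mean_cdif = numeric()))
  }
  n <- nrow(dmcs)
  brk <- c(TRUE, dmcs$chrom[-1] != dmcs$chrom[-n] |
             dmcs$direction[-1] != dmcs$direction[-n] |
             dmcs$pos[-1] - dmcs$pos[-n] > params$merge_window)
  starts <- which(brk)
  ends <- c(starts[-1] - 1L, n)
  n_dmcs <- ends - starts + 1L
  cs <- cumsum(dmcs$cdif)
  out <- tibble::tibble(
    chrom = dmcs$chrom[starts],
    start = dmcs$pos[starts],
    end = dmcs$pos[ends] + 1L,
    direction = dmcs$direction[starts],
    n_dmcs = n_dmcs,
    mean_cdif = (cs[ends] - c(0, cs[starts[-1] - 1L])) / n_dmcs
  )
  out <- out[out$n_dmcs >= params$min_run, , drop = FALSE]
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Hyper/hypo DMR counts for a comparison
#'
#' @param dmrs Output of [merge_dmrs()].
#' @return Tibble `direction, n` with one row per direction present.
#' @export
dmr_summary <- function(dmrs) {
  dplyr::count(dmrs, .data$direction, name = "n")
}
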