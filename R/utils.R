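#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same objects,
#' used throughout the test-suite and acceptance checks to score recovery of
#' planted group structure. 1 = identical partitions, ~0 = random agreement.
#'
#' @param a,b Vectors of cluster labels (any atomic type), equal length.
#' @return A single number in (-1, 1].
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y"))
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(n)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# intersection length of [s1,e1) with [s2,e2), vectorized
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

# Jaccard index of two half-open intervals
interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- interval_overlap(s1, e1, s2, e2)
  union <- (e1 - s1) + (e2 - s2) - inter
  ifelse(union > 0, inter / union, 0)
}

assert_fraction <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    if (open) (x > 0 && x < 1) else (x >= 0 && x <= 1)
  if (!ok) abort(sprintf("`%s` must be a fraction in [0, 1], got %s", name, format(x)),
                 class = "canyonscape_config_error")
  invisible(x)
}

assert_count <- function(x, name, positive = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) && x == floor(x) &&
    (if (positive) x > 0 else x >= 0)
  if (!ok) abort(sprintf("`%s` must be a %s integer, got %s", name,
                         if (positive) "positive" else "non-negative", format(x)),
                 class = "canyonscape_config_error")
  invisible(x)
}

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# deterministic per-chromosome sub-seed from a master seed
chrom_seed <- function(seed, chrom_index, salt = 0L) {
  (as.integer(seed) * 1009L + as.integer(chrom_index) * 9973L +
     as.integer(salt) * 31L) %% 2147483587L
}
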