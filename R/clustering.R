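#' K-means grouping of TSS occupancy profiles
#'
#' Clusters genes into `k` groups on the concatenated, row-aligned binned
#' occupancy profiles of one or more tracks (seeded k-means, `nstart`
#' restarts, best inertia). Genes are sorted by id before clustering so
#' input order never changes assignments, and groups are relabeled
#' deterministically by descending mean center signal of the first track
#' over its central bins, making labels stable under center permutation.
#' `NA` profile cells (chromosome ends) enter as 0.
#'
#' @param matrices A [tss_matrix()] or named list of them sharing the same
#'   gene set.
#' @param k Number of groups (default 5).
#' @param seed Seed for the k-means restarts.
#' @param nstart Random restarts (default 10).
#' @return Object of class `tss_groups`: list with `assignment`
#'   (`gene_id, group`), `centers`, `inertia`, `k`, `empty_groups`.
#' @export
kmeans_tss_groups <- function(matrices, k = 5, seed = 1L, nstart = 10) {
  if (inherits(matrices, "tss_matrix")) matrices <- list(track1 = matrices)
  stopifnot(length(matrices) >= 1)
  ids <- matrices[[1]]$gene_id
  for (m in matrices) {
    if (!identical(sort(m$gene_id), sort(ids))) {
      abort("matrices are not aligned on the same gene list",
            class = "canyonscape_data_error")
    }
  }
  ord <- order(ids)
  feats <- purrr::map(matrices, function(m) {
    m <- m[order(m$gene_id), , drop = FALSE]
    as.matrix(m[, setdiff(names(m), "gene_id")])
  })
  x <- do.call(cbind, feats)
  x[is.na(x)] <- 0
  ids <- ids[ord]
  if (k > nrow(x)) abort("k exceeds the number of genes",
                         class = "canyonscape_data_error")

  n_distinct <- nrow(unique(x))
  k_eff <- min(k, n_distinct)
  set.seed(as.integer(seed))
  km <- kmeans(x, centers = k_eff, nstart = nstart, iter.max = 300)

  # relabel by descending central signal of the first track
  p1 <- ncol(feats[[1]])
  central <- seq.int(max(1L, floor(p1 * 0.4)), ceiling(p1 * 0.6))
  strength <- rowMeans(km$centers[, central, drop = FALSE])
  relabel <- match(seq_len(k_eff), order(strength, decreasing = TRUE))
  labels <- paste0("G", relabel[km$cluster])
  centers <- km$centers[order(strength, decreasing = TRUE), , drop = FALSE]
  rownames(centers) <- paste0("G", seq_len(k_eff))

  structure(list(
    assignment = tibble::tibble(gene_id = ids, group = labels),
    centers = centers,
    inertia = km$tot.withinss,
    k = k,
    empty_groups = if (k_eff < k) paste0("G", (k_eff + 1):k) else character(),
    track_names = names(matrices) %||% paste0("track", seq_along(matrices)),
    n_features_per_track = vapply(feats, ncol, integer(1))
  ), class = "tss_groups")
}

#' @export
print.tss_groups <- function(x, ...) {
  cat(sprintf("<tss_groups> %d genes in %d groups (inertia %.1f)\n",
              nrow(x$assignment), x$k, x$inertia))
  print(table(x$assignment$group))
  invisible(x)
}

#' K-means clustering of differential expression patterns
#'
#' Expression values are log2-transformed (`log2(FPKM + 1)`) and
#' standardized per gene (zero mean, unit variance across conditions),
#' then clustered into `k` condition patterns with seeded k-means.
#' Clusters are relabeled deterministically by their standardized mean
#' pattern: descending double-knockout shift first, ties broken by the
#' Dnmt3a-knockout then Tet1-knockout shifts, so "up in both knockouts"
#' sorts first and "down in both" last. Genes flagged `de == FALSE` and
#' constant-expression genes are excluded (the latter with a warning).
#'
#' @param expression Tibble with `gene_id`, one FPKM column per condition,
#'   and optionally a logical `de` column restricting the clustered set.
#' @param k Number of clusters (default 7).
#' @param seed Seed for the k-means restarts.
#' @param conditions Condition column names, reference first.
#' @param nstart Random restarts (default 10).
#' @return Object of class `deg_clusters`: list with `assignment`
#'   (`gene_id, cluster`), `centers` (standardized pattern means),
#'   `inertia`, `k`, `excluded`.
#' @export
deg_clusters <- function(expression, k = 7, seed = 1L,
                         conditions = c("WT", "Dnmt3aKO", "Tet1KO", "DKO"),
                         nstart = 10) {
  assert_cols(expression, c("gene_id", conditions), "expression")
  if ("de" %in% names(expression)) {
    expression <- expression[expression$de, , drop = FALSE]
  }
  if (nrow(expression) < k) {
    abort("fewer differentially expressed genes than clusters",
          class = "canyonscape_data_error")
  }
  expression <- expression[order(expression$gene_id), , drop = FALSE]
  x <- log2(as.matrix(expression[, conditions]) + 1)
  mu <- rowMeans(x)
  sdev <- apply(x, 1, sd)
  constant <- sdev == 0
  if (any(constant)) {
    warn(sprintf("%d constant-expression gene(s) excluded", sum(constant)))
  }
  z <- (x[!constant, , drop = FALSE] - mu[!constant]) / sdev[!constant]
  ids <- expression$gene_id[!constant]

  set.seed(as.integer(seed))
  km <- kmeans(z, centers = k, nstart = nstart, iter.max = 300)

  ctr <- km$centers
  shift <- ctr - ctr[, conditions[1]]
  ord <- order(-shift[, "DKO"], -shift[, "Dnmt3aKO"], -shift[, "Tet1KO"])
  relabel <- match(seq_len(k), ord)
  centers <- ctr[ord, , drop = FALSE]
  rownames(centers) <- paste0("C", seq_len(k))

  structure(list(
    assignment = tibble::tibble(gene_id = ids,
                                cluster = paste0("C", relabel[km$cluster])),
    centers = centers,
    inertia = km$tot.withinss,
    k = k,
    conditions = conditions,
    excluded = expression$gene_id[constant]
  ), class = "deg_clusters")
}

#' @export
print.deg_clusters <- function(x, ...) {
  cat(sprintf("<deg_clusters> %d genes in %d clusters (inertia %.1f)\n",
              nrow(x$assignment), x$k, x$inertia))
  print(table(x$assignment$cluster))
  invisible(x)
}

#' Per-group summaries of occupancy, expression, and promoter CpG density
#'
#' @param assignment A `tss_groups`/`deg_clusters` object, or a tibble
#'   with `gene_id` and a label column (`group` or `cluster`).
#' @param tss_matrices Optional named list of [tss_matrix()] objects for
#'   per-group mean profiles.
#' @param expression Optional expression tibble (`gene_id` + FPKM
#'   columns); quartiles of the first condition column are reported.
#' @param promoter_density Optional [promoter_cpg_density()] output.
#' @return Object of class `group_summary`: list of tibbles `members`
#'   (`group, n`), `profiles` (`group, track, bin, value`), `expression`
#'   and `cpg_density` quartile tables.
#' @export
group_summaries <- function(assignment, tss_matrices = NULL,
                            expression = NULL, promoter_density = NULL) {
  if (inherits(assignment, "tss_groups") ||
      inherits(assignment, "deg_clusters")) {
    assignment <- assignment$assignment
  }
  lab_col <- intersect(c("group", "cluster"), names(assignment))[1]
  stopifnot(!is.na(lab_col))
  asg <- dplyr::rename(assignment, group = dplyr::all_of(lab_col))
  out <- list(members = dplyr::count(asg, .data$group, name = "n"))

  if (!is.null(tss_matrices)) {
    if (inherits(tss_matrices, "tss_matrix")) {
      tss_matrices <- list(track1 = tss_matrices)
    }
    out$profiles <- purrr::imap(tss_matrices, function(m, nm) {
      dplyr::inner_join(asg, m, by = "gene_id") |>
        tidyr::pivot_longer(dplyr::starts_with("b"), names_to = "bin",
                            values_to = "value") |>
        dplyr::mutate(bin = as.integer(sub("^b", "", .data$bin)),
                      track = nm) |>
        dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                         .by = c("group", "track", "bin"))
    }) |> dplyr::bind_rows()
  }

  quartiles <- function(df, value_col, out_name) {
    dplyr::inner_join(asg, df, by = "gene_id") |>
      dplyr::summarise(
        q25 = quantile(.data[[value_col]], 0.25, na.rm = TRUE),
        median = median(.data[[value_col]], na.rm = TRUE),
        q75 = quantile(.data[[value_col]], 0.75, na.rm = TRUE),
        n = dplyr::n(), .by = "group") |>
      dplyr::arrange(.data$group)
  }
  if (!is.null(expression)) {
    value_col <- setdiff(names(expression), c("gene_id", "de"))[1]
    out$expression <- quartiles(expression, value_col, "fpkm")
  }
  if (!is.null(promoter_density)) {
    out$cpg_density <- quartiles(promoter_density, "cpg_density", "density")
  }
  structure(out, class = "group_summary")
}
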