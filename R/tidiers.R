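#' Tidy and glance methods for clustering results
#'
#' `tidy()` returns one row per group/cluster with its size and mean
#' center signal; `glance()` returns a one-row model summary.
#'
#' @param x A `tss_groups` or `deg_clusters` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.tss_groups <- function(x, ...) {
  sizes <- table(x$assignment$group)
  tibble::tibble(
    group = rownames(x$centers),
    size = as.integer(sizes[rownames(x$centers)]),
    mean_center_signal = rowMeans(x$centers)
  )
}

#' @rdname tidy.tss_groups
#' @export
glance.tss_groups <- function(x, ...) {
  tibble::tibble(k = x$k, n_genes = nrow(x$assignment),
                 inertia = x$inertia,
                 n_empty_groups = length(x$empty_groups))
}

#' @rdname tidy.tss_groups
#' @export
tidy.deg_clusters <- function(x, ...) {
  sizes <- table(x$assignment$cluster)
  dplyr::bind_cols(
    tibble::tibble(cluster = rownames(x$centers),
                   size = as.integer(sizes[rownames(x$centers)])),
    tibble::as_tibble(x$centers)
  )
}

#' @rdname tidy.tss_groups
#' @export
glance.deg_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, n_genes = nrow(x$assignment),
                 inertia = x$inertia, n_excluded = length(x$excluded))
}
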